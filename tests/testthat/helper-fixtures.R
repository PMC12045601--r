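# Fixture builders shared across the suite. Everything is generated in code;
# expensive phantom objects are cached per test run.

# solid ball label volume (label 1) of radius r_vox voxels
ball_volume <- function(n = 32, r_vox = 10, spacing = 25, label = 1L) {
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  cen <- (n + 1) / 2
  arr <- array(0L, c(n, n, n))
  arr[idx[rowSums(sweep(idx, 2, cen)^2) <= r_vox^2, ]] <- label
  labeled_volume(arr, spacing)
}

# cube-shaped binary cell map
cube_map <- function(n = 16, from, to, spacing = 10,
                     channel = "nuclei") {
  arr <- array(0L, c(n, n, n))
  arr[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  cell_map(arr, spacing, channel = channel)
}

random_landmarks <- function(k = 37, seed = 1, scale = 500) {
  set.seed(seed)
  landmark_set(sprintf("l%02d", seq_len(k)),
               matrix(rnorm(k * 3), ncol = 3) * scale)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# small smooth random displacement field (µm) on an n^3 grid
smooth_random_field <- function(n = 24, spacing = 10, amp = 3, seed = 1) {
  set.seed(seed)
  u <- array(0, c(n, n, n, 3))
  for (c in 1:3) {
    noise <- array(rnorm(n^3), c(n, n, n))
    sm <- prolifatlas:::cpp_gauss3(as.numeric(noise), as.integer(c(n, n, n)),
                                   rep(3, 3))
    sm <- array(sm, c(n, n, n))
    u[, , , c] <- amp * sm / max(abs(sm))
  }
  displacement_transform(u, spacing)
}

# cached phantom specimen (64^3) reused by several tests
phantom_cache <- new.env(parent = emptyenv())
cached_specimen <- function(key = "default", ...) {
  if (is.null(phantom_cache[[key]])) {
    args <- list(...)
    spec <- do.call(phantom_spec, args$spec %||% list(grid_shape = 64,
                                                      seed = 101))
    phantom_cache[[key]] <- generate_specimen(spec, args$group %||% "E10",
                                              args$index %||% 1)
  }
  phantom_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n (exhaustive oracle for small n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(combinat_perms(n - 1), function(p)
      c(i, ifelse(p >= i, p + 1, p)))))
}
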