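#' Plot a proliferative-fraction axis profile
#'
#' Line plot of the proliferative fraction per bin with a shaded band of
#' plus/minus one standard error across specimens.
#'
#' @param profile A tibble from [axis_profile()].
#' @return A ggplot object.
#' @export
plot_axis_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                        y = .data$fraction)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fraction - .data$sem,
                                      ymax = .data$fraction + .data$sem),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "relative position along axis",
                  y = "proliferative fraction") +
    ggplot2::theme_minimal()
}

#' Plot a random-mask null distribution
#'
#' Density of the null mean-proliferation values with the observed
#' significance-mask mean marked by a vertical line.
#'
#' @param null A `null_distribution` from [random_mask_null()].
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null) {
  df <- data.frame(value = null$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey70", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = null$observed, color = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "mean proliferation in mask",
                  y = "density",
                  subtitle = sprintf("observed vs %d random masks, p = %.3g",
                                     null$R, null$p)) +
    ggplot2::theme_minimal()
}

#' Plot two-block PLS latent scores
#'
#' Scatter of the first latent variable of block 1 (proliferation) against
#' block 2 (shape).
#'
#' @param pls A `pls_result` from [two_block_pls()].
#' @param color Optional vector (e.g. somite counts) to colour points.
#' @return A ggplot object.
#' @export
plot_pls <- function(pls, color = NULL) {
  df <- data.frame(block1 = pls$scores1, block2 = pls$scores2)
  p <- if (is.null(color)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$block1, y = .data$block2)) +
      ggplot2::geom_point(color = "steelblue")
  } else {
    df$color <- color
    ggplot2::ggplot(df, ggplot2::aes(x = .data$block1, y = .data$block2,
                                     color = .data$color)) +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "proliferation latent score",
                    y = "shape latent score",
                    subtitle = sprintf("r = %.3f, p = %.3g", pls$r, pls$p)) +
    ggplot2::theme_minimal()
}
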