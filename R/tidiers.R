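#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an island-vs-backbone contrast
#'
#' @param x A `gi_contrast`.
#' @param ... Unused.
#' @return Tibble with one row per region: `region`, `n_snps`,
#'   `aligned_bp`, `frequency`.
#' @export
tidy.gi_contrast <- function(x, ...) {
  tibble::tibble(
    region = c("island", "backbone"),
    n_snps = c(x$island$k, x$backbone$k),
    aligned_bp = c(x$island$n, x$backbone$n),
    frequency = c(x$island$frequency, x$backbone$frequency)
  )
}

#' One-row summary of a contrast
#'
#' @param x A `gi_contrast`.
#' @param ... Unused.
#' @return One-row tibble: `ratio`, `p_value`, `call`, `alpha`,
#'   `ratio_cut`, `alternative`.
#' @export
glance.gi_contrast <- function(x, ...) {
  tibble::tibble(
    ratio = x$ratio, p_value = x$p_value, call = x$call,
    alpha = x$alpha, ratio_cut = x$ratio_cut, alternative = x$alternative
  )
}

#' Plot a windowed SNP track
#'
#' Column histogram of SNP counts per window along the reference -- the
#' classic island-versus-flank divergence picture.
#'
#' @param object A `gi_window_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gi_window_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$n_snps)) +
    ggplot2::geom_col(width = df$effective_length * 0.9, fill = "grey25") +
    ggplot2::labs(x = "reference position (bp)", y = "SNPs per window") +
    ggplot2::theme_minimal()
}

#' Plot an island-vs-backbone contrast
#'
#' @param object A `gi_contrast`.
#' @param ... Unused.
#' @return A ggplot of per-region SNP frequencies (log10 scale).
#' @export
autoplot.gi_contrast <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$frequency)) +
    ggplot2::geom_col(fill = c("#1b9e77", "#7570b3")) +
    ggplot2::scale_y_log10(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::labs(
      x = NULL, y = "SNP frequency (aligned bp)",
      subtitle = sprintf("ratio %.3g, p = %.3g, call: %s",
                         object$ratio, object$p_value, object$call)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SNP windows with the island highlighted
#'
#' @param scan Result of [snp_scan()] (needs `windows`).
#' @param island Optional island interval to shade.
#' @return A ggplot.
#' @export
plot_snp_windows <- function(scan, island = NULL) {
  if (is.null(scan$windows)) abort("scan carries no window track")
  p <- autoplot(scan$windows)
  if (!is.null(island)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = island$start[[1]], xmax = island$end[[1]],
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "#d95f02"
    )
  }
  p
}
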