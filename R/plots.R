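#' Diagnostic plots
#'
#' `plot_force_pdf()` draws the summed-Gaussian unbinding-force PDF with the
#' bimodal decomposition overlaid; `plot_force_vs_rate()` draws per-event
#' forces against loading rate (log axis) with the fitted Bell-Evans
#' most-probable-force line and, optionally, the master-equation double-bond
#' branch. Both need ggplot2 (Suggests).
#'
#' @param pdf a [build_pdf()] result.
#' @param bimodal optional [fit_bimodal()] result.
#' @param events annotated event table.
#' @param bell a fitted [bell_parameters()] from [fit_bell_ml()].
#' @param double optional [predict_double_bond()] result for the same rates.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @name forcespec-plots
NULL

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    fs_abort("ggplot2 is required for plotting", class = "forcespec_missing_pkg")
}

#' @rdname forcespec-plots
#' @export
plot_force_pdf <- function(pdf, bimodal = NULL) {
  need_ggplot()
  df <- data.frame(force = pdf$grid, density = pdf$density / pdf$n_events)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$force, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Unbinding force (pN)", y = "Probability density (1/pN)")
  if (!is.null(bimodal)) {
    mix <- data.frame(force = pdf$grid,
                      density = bimodal$w1 * stats::dnorm(pdf$grid, bimodal$mu1, bimodal$sigma1) +
                                bimodal$w2 * stats::dnorm(pdf$grid, bimodal$mu2, bimodal$sigma2))
    p <- p + ggplot2::geom_line(data = mix, linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname forcespec-plots
#' @export
plot_force_vs_rate <- function(events, bell, double = NULL) {
  need_ggplot()
  rr <- exp(seq(log(min(events$loading_rate)), log(max(events$loading_rate)),
                length.out = 100))
  line <- data.frame(loading_rate = rr, force = attr(bell, "fstar")(rr))
  p <- ggplot2::ggplot(events, ggplot2::aes(.data$loading_rate, .data$force)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_line(data = line, colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Loading rate (pN/s)", y = "Unbinding force (pN)")
  if (!is.null(double)) {
    dd <- data.frame(loading_rate = as.numeric(names(double)),
                     force = attr(double, "modes"))
    p <- p + ggplot2::geom_line(data = dd, colour = "lightblue") +
      ggplot2::geom_point(data = dd, colour = "lightblue")
  }
  p
}
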