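#' Plot a coalescent-time density
#'
#' Line plot of the density over a time grid covering the bulk of the mass,
#' with the breakpoints (gene-flow change point, species divergence) marked.
#'
#' @param object A [coal_density()] object.
#' @param t_max Upper end of the time grid (defaults to the divergence time
#'   plus five mean tail lengths).
#' @param steps Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coal_density <- function(object, t_max = NULL, steps = 512, ...) {
  br <- object$breaks
  if (is.null(t_max)) {
    t_max <- max(br[is.finite(br)]) + 2.5 * object$params$thetaR
  }
  grid <- tibble(t = seq(0, t_max, length.out = steps))
  grid$density <- dcoal(grid$t, object)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$density)) +
    ggplot2::geom_vline(xintercept = br[is.finite(br) & br > 0],
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "coalescent time t (mutations/site)",
                  y = "f(t)",
                  title = sprintf("coalescent-time density (%s)",
                                  object$model)) +
    ggplot2::theme_minimal()
}

#' Plot pseudo-true parameter values against the migration rate
#'
#' One panel per fitted parameter, on a log migration-rate axis, for the
#' output of [sweep_migration_rate()].
#'
#' @param object A `migration_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.migration_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "M", "tauR", "tauS", "thetaR",
                  "thetaS", "phi"),
    -"M", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$M, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "migration rate M (migrants/generation)",
                  y = "pseudo-true value") +
    ggplot2::theme_minimal()
}
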