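#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a psi fit
#'
#' @param x A `psi_fit`.
#' @param ... Unused.
#' @return The per-unit summary tibble (posterior mean, credible interval,
#'   prior parameters, diagnostics).
#' @export
tidy.psi_fit <- function(x, ...) x$summary

#' One-row summary of a psi fit
#'
#' @param x A `psi_fit`.
#' @param ... Unused.
#' @return Tibble with `n_units`, `n_dropout`, `sigma`, `lambda`,
#'   `mean_accept`, `frac_converged`, `n_iter`, `burn_in`.
#' @export
glance.psi_fit <- function(x, ...) {
  tibble(
    n_units = nrow(x$summary),
    n_dropout = sum(x$summary$dropout),
    sigma = x$sigma,
    lambda = x$lambda,
    mean_accept = mean(x$summary$accept_rate),
    frac_converged = mean(x$summary$converged),
    n_iter = x$config$n_total,
    burn_in = x$config$burn_in
  )
}

#' Prior/posterior plot for one event
#'
#' Histogram of the posterior psi draws with the logit-normal prior density
#' overlaid, the posterior mean as a solid line and the 95% credible interval
#' as dashed lines.
#'
#' @param object A `psi_fit`.
#' @param event_id Which unit to plot (defaults to the first).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_fit <- function(object, event_id = NULL, bins = 40L, ...) {
  ids <- colnames(object$draws)
  event_id <- event_id %||% ids[1]
  j <- match(event_id, ids)
  if (is.na(j)) abort(sprintf("unit '%s' not in the fit", event_id))
  s <- object$summary[j, ]
  grid <- seq(0.001, 0.999, length.out = 400)
  prior <- stats::dnorm(logit(grid), s$prior_mu, object$sigma) /
    (grid * (1 - grid))
  df <- tibble(psi = object$draws[, j])
  pdf <- tibble(psi = grid, density = prior)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$psi)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey25", colour = NA) +
    ggplot2::geom_line(data = pdf, ggplot2::aes(y = .data$density),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = s$post_mean, colour = "red") +
    ggplot2::geom_vline(xintercept = c(s$ci_low, s$ci_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = expression(psi), y = "density",
                  title = event_id,
                  subtitle = sprintf("posterior mean %.3f [%.3f, %.3f]",
                                     s$post_mean, s$ci_low, s$ci_high)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of estimates against simulation truth
#'
#' @param fit A `psi_fit`.
#' @param truth Tibble with `event_id` and `psi_true`.
#' @return A ggplot object annotated with the Pearson correlation.
#' @export
plot_truth_scatter <- function(fit, truth) {
  df <- dplyr::inner_join(fit$summary, truth, by = "event_id")
  r <- stats::cor(df$post_mean, df$psi_true)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$psi_true, y = .data$post_mean)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::labs(x = "true psi", y = "posterior mean psi",
                  subtitle = sprintf("Pearson R = %.3f", r)) +
    ggplot2::theme_minimal()
}
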