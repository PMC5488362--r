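#' @name diffsplice
#' @title Differential splicing via relaxed Savage-Dickey Bayes factors
#'
#' @description
#' For two cells (or groups) A and B and delta = psi_A - psi_B, the Bayes
#' factor for differential against identical splicing is the Savage-Dickey
#' ratio of interval masses, `BF = P(|delta| < eps | H1) /
#' P(|delta| < eps | D, H1)`, estimated by re-sampling psi pairs from the two
#' prior and the two posterior draw sets. Both masses are floored at
#' `1 / (M + 1)`, capping the BF at a finite, M-dependent maximum. Events
#' with `BF >= 10` are conventionally called differential.
NULL

#' Savage-Dickey Bayes factor between two draw sets
#'
#' @param post_a,post_b Posterior psi draws of the two cells (non-empty).
#' @param prior_a,prior_b Prior psi draws of the two cells.
#' @param epsilon Half-width of the null interval on psi differences
#'   (default 0.05); must lie strictly in (0, 1).
#' @param M Number of resampled pairs (default 10000, at least 1000).
#' @param seed Optional integer seed.
#' @return One-row tibble: `bf`, `prior_mass`, `posterior_mass`, `epsilon`,
#'   `M`.
#' @export
bayes_factor <- function(post_a, post_b, prior_a, prior_b,
                         epsilon = 0.05, M = 10000L, seed = NULL) {
  if (epsilon <= 0 || epsilon >= 1) abort("`epsilon` must be in (0, 1)")
  if (M < 1000L) abort("`M` must be at least 1000")
  if (!length(post_a) || !length(post_b)) abort("posterior draw sets must be non-empty")
  with_seed_(seed, {
    mass <- function(a, b) {
      d <- sample(a, M, replace = TRUE) - sample(b, M, replace = TRUE)
      max(mean(abs(d) < epsilon), 1 / (M + 1))
    }
    pr <- mass(prior_a, prior_b)
    po <- mass(post_a, post_b)
    tibble(bf = pr / po, prior_mass = pr, posterior_mass = po,
           epsilon = epsilon, M = as.integer(M))
  })
}

# prior psi draws of every unit in a fit: logistic(N(prior_mu, sigma))
prior_draws_fit <- function(fit, M) {
  mu <- fit$summary$prior_mu
  sapply(mu, function(m) logistic(stats::rnorm(M, m, fit$sigma)))
}

#' Differential splicing between two fitted cells
#'
#' Computes, per event shared by the two fits, the Savage-Dickey Bayes factor
#' from the posterior draws and fresh prior draws (logit-normal with each
#' cell's own learned location and scale; independent streams for the two
#' cells).
#'
#' @param fit_a,fit_b `psi_fit` objects for the two cells.
#' @param epsilon,M,seed See [bayes_factor()].
#' @param bf_threshold Events at or above this BF are flagged `called`.
#' @return Tibble with one row per shared event: `event_id`, `bf`,
#'   `prior_mass`, `posterior_mass`, `epsilon`, `M`, `post_mean_a`,
#'   `post_mean_b`, `called`.
#' @export
diff_splicing <- function(fit_a, fit_b, epsilon = 0.05, M = 10000L,
                          bf_threshold = 10, seed = NULL) {
  shared <- intersect(fit_a$summary$event_id, fit_b$summary$event_id)
  if (!length(shared)) abort("the two fits share no events")
  ia <- match(shared, fit_a$summary$event_id)
  ib <- match(shared, fit_b$summary$event_id)
  with_seed_(seed, {
    res <- purrr::map_dfr(seq_along(shared), function(k) {
      pa <- fit_a$draws[, ia[k]]; pb <- fit_b$draws[, ib[k]]
      ra <- logistic(stats::rnorm(M, fit_a$summary$prior_mu[ia[k]], fit_a$sigma))
      rb <- logistic(stats::rnorm(M, fit_b$summary$prior_mu[ib[k]], fit_b$sigma))
      bayes_factor(pa, pb, ra, rb, epsilon = epsilon, M = M)
    })
    dplyr::mutate(res,
                  event_id = shared,
                  post_mean_a = fit_a$summary$post_mean[ia],
                  post_mean_b = fit_b$summary$post_mean[ib],
                  called = .data$bf >= bf_threshold,
                  .before = 1)
  })
}

#' Pool read evidence across the cells of a group
#'
#' Multiplying per-cell likelihoods under a shared psi is equivalent to
#' summing the per-class read counts over cells, which is what this does.
#'
#' @param evidence Evidence tibble for several cells of one group.
#' @return Evidence tibble with one row per event (cell column dropped).
#' @export
pool_evidence <- function(evidence) {
  pooled <- evidence |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(n_inc = sum(.data$n_inc), n_exc = sum(.data$n_exc),
                     n_amb = sum(.data$n_amb),
                     len_inc = .data$len_inc[1], len_exc = .data$len_exc[1],
                     .groups = "drop")
  pooled[match(unique(evidence$event_id), pooled$event_id), , drop = FALSE]
}

#' Group-level differential splicing test
#'
#' Pools the reads of each group into one evidence set per group (shared psi
#' within group), refits the posterior per group, and applies
#' [diff_splicing()]. With one cell per group this reduces exactly to the
#' pairwise test.
#'
#' @param evidence_a,evidence_b Evidence tibbles for the cells of each group.
#' @param features See [quant_psi()].
#' @param config Sampler configuration for the two group fits.
#' @param epsilon,M,bf_threshold,seed See [diff_splicing()].
#' @param ... Passed to [quant_psi()].
#' @return As [diff_splicing()].
#' @export
diff_splicing_groups <- function(evidence_a, evidence_b, features,
                                 config = sampler_config(), epsilon = 0.05,
                                 M = 10000L, bf_threshold = 10, seed = NULL,
                                 ...) {
  fit_a <- quant_psi(pool_evidence(evidence_a), features, config = config, ...)
  fit_b <- quant_psi(pool_evidence(evidence_b), features, config = config, ...)
  diff_splicing(fit_a, fit_b, epsilon = epsilon, M = M,
                bf_threshold = bf_threshold, seed = seed)
}

#' Per-event call fractions over all cell pairs of two groups
#'
#' Runs [diff_splicing()] for every pair of cells (one from each group) and
#' reports, per event, the fraction of pairs in which it was called
#' differential.
#'
#' @param fits_a,fits_b Lists of `psi_fit` objects (one per cell).
#' @param epsilon,M,bf_threshold,seed See [diff_splicing()].
#' @param fraction_cutoff Events called in at least this fraction of pairs
#'   are `flagged`.
#' @return Tibble: `event_id`, `n_pairs`, `n_called`, `call_fraction`,
#'   `flagged`.
#' @export
pairwise_bf <- function(fits_a, fits_b, epsilon = 0.05, M = 10000L,
                        bf_threshold = 10, fraction_cutoff = 0.1,
                        seed = NULL) {
  with_seed_(seed, {
    calls <- purrr::map_dfr(fits_a, function(fa) {
      purrr::map_dfr(fits_b, function(fb) {
        diff_splicing(fa, fb, epsilon = epsilon, M = M,
                      bf_threshold = bf_threshold)[, c("event_id", "called")]
      })
    })
    calls |>
      dplyr::group_by(.data$event_id) |>
      dplyr::summarise(n_pairs = dplyr::n(), n_called = sum(.data$called),
                       .groups = "drop") |>
      dplyr::mutate(call_fraction = .data$n_called / .data$n_pairs,
                    flagged = .data$call_fraction >= fraction_cutoff)
  })
}
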