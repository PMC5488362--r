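#' @name sampler
#' @title Adaptive Metropolis-Hastings inference with collapsed prior updates
#'
#' @description
#' Posterior inference runs a univariate Gaussian random-walk
#' Metropolis-Hastings chain on y = logit(psi) for every unit (an event, or an
#' event-cell pair), in blocks of `block_len` steps. Between blocks the
#' regression prior is collapsed to point estimates: W is set to the ridge
#' posterior mean given the current y values and sigma to the residual
#' standard deviation. The proposal scale is re-adapted every block to
#' `2.38 * sd(chain so far)`. With a fixed prior the regression updates are
#' switched off. Chains for different units are conditionally independent
#' given (W, sigma), which is what makes the blocked, vectorised update exact.
NULL

#' Sampler configuration
#'
#' @param block_len Steps per block between prior updates / proposal
#'   re-adaptation (default 50).
#' @param n_total Total iterations, burn-in included (default 3000 = 1000
#'   burn-in + 2000 retained).
#' @param burn_in Discarded initial iterations (default 1000).
#' @param init_proposal_sd Initial random-walk proposal standard deviation.
#' @param proposal_floor Lower bound on the adapted proposal sd.
#' @param geweke_threshold Convergence is declared at |Z| below this value.
#' @param seed Optional integer seed making the whole run deterministic.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(block_len = 50L, n_total = 3000L, burn_in = 1000L,
                           init_proposal_sd = 1, proposal_floor = 0.01,
                           geweke_threshold = 2, seed = NULL) {
  if (burn_in >= n_total) abort("`burn_in` must be smaller than `n_total`")
  if (block_len < 1L) abort("`block_len` must be positive")
  structure(list(block_len = as.integer(block_len), n_total = as.integer(n_total),
                 burn_in = as.integer(burn_in), init_proposal_sd = init_proposal_sd,
                 proposal_floor = proposal_floor,
                 geweke_threshold = geweke_threshold, seed = seed),
            class = "sampler_config")
}

#' One Metropolis-Hastings step on logit-psi
#'
#' Proposes `y' ~ N(y, proposal_sd^2)` and accepts with probability
#' `min(1, exp(target(y') - target(y)))`, where the target is the read
#' log-likelihood at `logistic(y')` plus the Normal prior log density on the
#' logit scale (no Jacobian: the chain lives on y). The proposal is symmetric
#' so no Hastings correction applies; a non-finite target at the proposal is
#' rejected with a warning.
#'
#' @param y Current logit-psi value.
#' @param evidence One-row evidence tibble.
#' @param x Feature vector of the event (without intercept).
#' @param state A [prior_state()].
#' @param proposal_sd Positive proposal standard deviation.
#' @return List with `y` (new value), `accepted` (logical).
#' @export
mh_step <- function(y, evidence, x, state, proposal_sd) {
  if (proposal_sd < 0) abort("`proposal_sd` must be non-negative")
  mu <- prior_location(state, x)
  target <- function(v) {
    loglik_units(v, evidence$n_inc, evidence$n_exc, evidence$n_amb,
                 evidence$len_inc, evidence$len_exc) +
      stats::dnorm(v, mu, state$sigma, log = TRUE)
  }
  yp <- stats::rnorm(1L, y, proposal_sd)
  tp <- target(yp)
  if (!is.finite(tp)) {
    warn("non-finite target at proposal; rejected")
    return(list(y = y, accepted = FALSE))
  }
  if (log(stats::runif(1L)) < tp - target(y)) {
    list(y = yp, accepted = TRUE)
  } else {
    list(y = y, accepted = FALSE)
  }
}

#' Adapted proposal scale from chain history
#'
#' `2.38 * sd(history)` (population sd), floored.
#'
#' @param history Numeric vector of at least 2 chain draws.
#' @param floor Lower bound of the returned scale.
#' @return Positive scalar.
#' @export
adapt_proposal <- function(history, floor = 0.01) {
  if (length(history) < 2L) abort("need at least 2 draws to adapt")
  max(2.38 * pop_sd(history), floor)
}

#' Geweke convergence Z score
#'
#' Compares the mean of the first 10% of the chain against the mean of the
#' last 50%: `Z = (m1 - m2) / sqrt(v1/n1 + v2/n2)` with sample variances.
#'
#' @param chain Numeric vector of at least 20 draws.
#' @return The Z score; 0 (with a warning) when both segments have zero
#'   variance.
#' @export
geweke_z <- function(chain) {
  if (length(chain) < 20L) abort("chain too short for the Geweke diagnostic")
  n <- length(chain)
  a <- chain[seq_len(max(1L, floor(0.1 * n)))]
  b <- chain[(n - floor(0.5 * n) + 1L):n]
  va <- stats::var(a); vb <- stats::var(b)
  if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
    warn("zero variance in both Geweke segments; returning 0")
    return(0)
  }
  va <- if (is.na(va)) 0 else va
  vb <- if (is.na(vb)) 0 else vb
  (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

#' Quantify inclusion ratios by MCMC with a learned or fixed prior
#'
#' Runs the blocked adaptive sampler over all rows of `evidence`. When
#' `evidence` carries a `cell_id` column with several cells, all event-cell
#' units enter one regression (the shared-prior mode); use [quant_cells()]
#' for per-cell priors. Events with zero reads are valid inputs: their
#' posterior equals the prior (this is what imputes drop-outs).
#'
#' @param evidence Evidence tibble ([read_evidence()]); one row per unit.
#' @param features Feature tibble from [event_features()] (or any tibble of
#'   `event_id` plus numeric regressors), or a numeric matrix with event ids
#'   as rownames. Standardised internally unless `standardize = FALSE`.
#' @param config A [sampler_config()].
#' @param prior Optional [prior_state()]; when given, W and sigma stay fixed
#'   and no regression updates are performed.
#' @param lambda Ridge precision for the learned prior (default 0.1).
#' @param sigma_floor Lower bound on the learned residual scale.
#' @param standardize Z-score the feature columns before regression.
#' @return An object of class `psi_fit`: list with `summary` (tibble with one
#'   row per unit: counts, prior location/scale, posterior mean, 95% credible
#'   interval, Geweke Z, acceptance rate), `draws` (matrix of retained psi
#'   draws, units in columns), `W`, `sigma`, `lambda`, and `config`.
#' @export
quant_psi <- function(evidence, features, config = sampler_config(),
                      prior = NULL, lambda = 0.1, sigma_floor = 0.1,
                      standardize = TRUE) {
  if (!nrow(evidence)) abort("`evidence` has no rows")
  X <- feature_matrix(features)
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, pop_sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  names(ctr) <- names(scl) <- colnames(X)
  missing_ev <- setdiff(evidence$event_id, rownames(X))
  if (length(missing_ev)) {
    abort(paste0("no features for event(s): ",
                 paste(utils::head(missing_ev, 3L), collapse = ", ")))
  }
  Xu <- X[evidence$event_id, , drop = FALSE]
  X1 <- augment_x(Xu)
  U <- nrow(evidence)
  fixed <- !is.null(prior)
  if (!fixed && U < 2L) abort("learning the prior requires at least 2 units")
  if (fixed && length(prior$W) != ncol(X1)) {
    abort("fixed prior W has the wrong dimension for these features")
  }
  cfg <- config

  with_seed_(cfg$seed, {
    n_inc <- evidence$n_inc; n_exc <- evidence$n_exc; n_amb <- evidence$n_amb
    l_inc <- evidence$len_inc; l_exc <- evidence$len_exc
    y <- logit((n_inc + 1) / (n_inc + n_exc + 2))

    if (fixed) {
      W <- prior$W; sigma <- prior$sigma; lambda <- prior$lambda %||% lambda
    } else {
      W <- ridge_weights(X1, y, sigma = 1, lambda = lambda)
      sigma <- residual_sigma(X1, y, W, floor = sigma_floor)
    }
    mu <- drop(X1 %*% W)

    prop_sd <- rep(cfg$init_proposal_sd, U)
    chain <- matrix(NA_real_, nrow = cfg$n_total, ncol = U)
    s1 <- numeric(U); s2 <- numeric(U); n_acc <- numeric(U)
    ll_cur <- loglik_units(y, n_inc, n_exc, n_amb, l_inc, l_exc)
    lt_cur <- ll_cur + stats::dnorm(y, mu, sigma, log = TRUE)
    XtX <- if (!fixed) crossprod(X1) else NULL

    for (it in seq_len(cfg$n_total)) {
      yp <- y + stats::rnorm(U) * prop_sd
      llp <- loglik_units(yp, n_inc, n_exc, n_amb, l_inc, l_exc)
      ltp <- llp + stats::dnorm(yp, mu, sigma, log = TRUE)
      acc <- is.finite(ltp) & (log(stats::runif(U)) < ltp - lt_cur)
      y[acc] <- yp[acc]
      lt_cur[acc] <- ltp[acc]
      chain[it, ] <- y
      s1 <- s1 + y; s2 <- s2 + y * y; n_acc <- n_acc + acc

      if (it %% cfg$block_len == 0L && it < cfg$n_total) {
        sd_hist <- sqrt(pmax(s2 / it - (s1 / it)^2, 0))
        prop_sd <- pmax(2.38 * sd_hist, cfg$proposal_floor)
        if (!fixed) {
          A <- XtX + diag(sigma^2 * lambda, ncol(X1))
          W <- drop(solve(A, crossprod(X1, y)))
          sigma <- max(pop_sd(y - drop(X1 %*% W)), sigma_floor)
          mu <- drop(X1 %*% W)
        }
        # prior parameters moved: refresh the cached target
        lt_cur <- loglik_units(y, n_inc, n_exc, n_amb, l_inc, l_exc) +
          stats::dnorm(y, mu, sigma, log = TRUE)
      }
    }

    kept <- chain[(cfg$burn_in + 1L):cfg$n_total, , drop = FALSE]
    psi_draws <- logistic(kept)
    unit_ids <- if ("cell_id" %in% names(evidence)) {
      paste(evidence$event_id, evidence$cell_id, sep = "@")
    } else {
      evidence$event_id
    }
    colnames(psi_draws) <- unit_ids

    gz <- apply(kept, 2L, geweke_z)
    ci <- apply(psi_draws, 2L, stats::quantile, probs = c(0.025, 0.975))
    summary <- tibble(
      event_id = evidence$event_id,
      n_reads = n_inc + n_exc + n_amb,
      n_inc = n_inc, n_exc = n_exc, n_amb = n_amb,
      prior_mu = mu, prior_sd = sigma,
      post_mean = unname(colMeans(psi_draws)),
      ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
      geweke_z = unname(gz),
      converged = abs(gz) < cfg$geweke_threshold,
      accept_rate = n_acc / cfg$n_total,
      dropout = (n_inc + n_exc + n_amb) == 0L
    )
    if ("cell_id" %in% names(evidence)) {
      summary <- dplyr::mutate(summary, cell_id = evidence$cell_id, .after = 1)
    }
    if (all(summary$dropout)) {
      warn("all units have zero reads; posteriors equal the prior")
    }
    structure(list(summary = summary, draws = psi_draws,
                   W = W, sigma = sigma, lambda = lambda, config = cfg,
                   feature_center = ctr, feature_scale = scl),
              class = "psi_fit")
  })
}

#' @export
print.psi_fit <- function(x, ...) {
  cat(sprintf("<psi_fit> %d unit(s), sigma = %.3f, %d retained draws\n",
              nrow(x$summary), x$sigma,
              x$config$n_total - x$config$burn_in))
  print(x$summary, ...)
  invisible(x)
}

#' Quantify several cells
#'
#' Three prior-sharing modes mirror typical workflows: `"separate"` learns an
#' independent prior per cell, `"shared"` merges all cells' logit-psi values
#' into one regression, and `"fixed"` re-uses a prior learned elsewhere (e.g.
#' on bulk data).
#'
#' @param evidence Evidence tibble with a `cell_id` column.
#' @param features See [quant_psi()].
#' @param mode `"separate"`, `"shared"` or `"fixed"`.
#' @param fixed_prior A [prior_state()], required for `mode = "fixed"`.
#' @param ... Passed to [quant_psi()].
#' @return For `"shared"` a single `psi_fit`; otherwise a named list of
#'   `psi_fit`, one per cell.
#' @export
quant_cells <- function(evidence, features,
                        mode = c("separate", "shared", "fixed"),
                        fixed_prior = NULL, ...) {
  mode <- match.arg(mode)
  if (!"cell_id" %in% names(evidence)) abort("`evidence` must have a cell_id column")
  if (mode == "shared") return(quant_psi(evidence, features, ...))
  if (mode == "fixed" && is.null(fixed_prior)) {
    abort("`fixed_prior` is required for mode = \"fixed\"")
  }
  cells <- split(evidence, evidence$cell_id)
  purrr::map(cells, function(ev) {
    quant_psi(ev, features,
              prior = if (mode == "fixed") fixed_prior else NULL, ...)
  })
}

#' Impute inclusion ratios for drop-out events from a learned prior
#'
#' Applies the fit's feature standardisation and regression weights to new
#' events and returns the prior mean psi (see [prior_mean_psi()]), the
#' imputation used for events with zero reads.
#'
#' @param fit A `psi_fit` with a learned (or fixed) prior.
#' @param features Feature tibble or matrix covering the events to impute,
#'   with the same feature columns the fit was trained on.
#' @param n_draws,seed,method Passed to [prior_mean_psi()].
#' @return Tibble: `event_id`, `psi_imputed`.
#' @export
impute_dropouts <- function(fit, features, n_draws = 5000L, seed = NULL,
                            method = c("mc", "plugin")) {
  X <- feature_matrix(features)
  cols <- names(fit$feature_center)
  if (!all(cols %in% colnames(X))) {
    abort("`features` lacks columns the fit was trained on")
  }
  X <- X[, cols, drop = FALSE]
  X <- sweep(sweep(X, 2L, fit$feature_center), 2L, fit$feature_scale, "/")
  st <- prior_state(fit$W, fit$sigma, fit$lambda)
  tibble(event_id = rownames(X),
         psi_imputed = prior_mean_psi(X, st, n_draws = n_draws, seed = seed,
                                      method = method))
}
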