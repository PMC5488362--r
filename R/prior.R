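#' @name prior_regression
#' @title Sequence-informed prior via Bayesian ridge regression
#'
#' @description
#' The informative prior models logit-psi of event k as `y_k = W' x_k + eps`,
#' `eps ~ N(0, sigma^2)`, with a Gaussian prior `W ~ N(0, (lambda I)^-1)` on
#' the weights. Inside the sampler W and sigma are collapsed to their
#' conditional point estimates: the ridge posterior mean for W and the
#' residual standard deviation for sigma. A constant intercept column is
#' appended to the features and regularised with the same lambda.
NULL

# append the intercept column
augment_x <- function(X) {
  X <- as.matrix(X)
  cbind(X, `(intercept)` = rep(1, nrow(X)))
}

#' Ridge posterior mean of the regression weights
#'
#' Solves `(X'X + sigma^2 lambda I) W = X'Y`, the posterior mean of W given Y
#' under the Gaussian weight prior.
#'
#' @param X Feature matrix (events x features), intercept already included if
#'   wanted (the sampler appends one via its own path).
#' @param Y Response vector (logit-psi), length `nrow(X)`.
#' @param sigma Residual standard deviation (> 0).
#' @param lambda Ridge precision scalar (> 0).
#' @return Weight vector of length `ncol(X)`.
#' @export
ridge_weights <- function(X, Y, sigma, lambda) {
  X <- as.matrix(X)
  if (nrow(X) != length(Y)) abort("nrow(X) must equal length(Y)")
  if (sigma <= 0 || lambda <= 0) abort("`sigma` and `lambda` must be positive")
  A <- crossprod(X) + diag(sigma^2 * lambda, ncol(X))
  drop(solve(A, crossprod(X, Y)))
}

#' Residual standard deviation of the prior regression
#'
#' Population (divide-by-n) standard deviation of `Y - X W`, floored at
#' `floor` so the prior never collapses to a point mass.
#'
#' @inheritParams ridge_weights
#' @param W Weight vector.
#' @param floor Lower bound on the returned scale (default 0.1).
#' @return Positive scalar.
#' @export
residual_sigma <- function(X, Y, W, floor = 0.1) {
  X <- as.matrix(X)
  if (length(Y) < 2L) abort("need at least 2 events to estimate sigma")
  max(pop_sd(Y - drop(X %*% W)), floor)
}

#' Bundle learned prior parameters
#'
#' @param W Weight vector; the last element is the intercept when the state
#'   was learned on intercept-augmented features.
#' @param sigma Residual scale (> 0).
#' @param lambda Ridge precision used during learning.
#' @return List of class `prior_state`.
#' @export
prior_state <- function(W, sigma, lambda = 0.1) {
  if (sigma <= 0) abort("`sigma` must be positive")
  structure(list(W = as.numeric(W), sigma = sigma, lambda = lambda),
            class = "prior_state")
}

# W' x for feature rows (x without the intercept column)
prior_location <- function(state, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  unname(drop(augment_x(x) %*% state$W))
}

#' Log density of the logit-normal prior on psi
#'
#' Normal log density of logit(psi) at location `W' x` and scale sigma, plus
#' the change-of-variable term `-log(psi (1 - psi))`.
#'
#' @param psi Value(s) strictly inside (0, 1).
#' @param x Feature vector of one event (without intercept).
#' @param state A [prior_state()].
#' @return Log density value(s).
#' @export
prior_logpdf <- function(psi, x, state) {
  check_prob_open(psi)
  mu <- prior_location(state, x)
  stats::dnorm(logit(psi), mu, state$sigma, log = TRUE) - log(psi * (1 - psi))
}

#' Prior mean inclusion ratio (the drop-out imputation value)
#'
#' The mean of the logit-normal prior has no closed form; by default it is
#' estimated by Monte Carlo as `mean(logistic(z))`, `z ~ N(W'x, sigma^2)`.
#' `method = "plugin"` returns the faster `logistic(W'x)` approximation,
#' which understates the pull towards 0.5 for large sigma.
#'
#' @param x Feature matrix or vector (events x features, no intercept).
#' @param state A [prior_state()].
#' @param n_draws Monte Carlo draws (default 5000).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @param method `"mc"` (default) or `"plugin"`.
#' @return Numeric vector of prior means in (0, 1), one per row of `x`.
#' @export
prior_mean_psi <- function(x, state, n_draws = 5000L, seed = NULL,
                           method = c("mc", "plugin")) {
  method <- match.arg(method)
  mu <- prior_location(state, x)
  if (method == "plugin" || state$sigma < 1e-12) return(logistic(mu))
  with_seed_(seed, {
    z <- stats::rnorm(n_draws)
    vapply(mu, function(m) mean(logistic(m + state$sigma * z)), numeric(1))
  })
}
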