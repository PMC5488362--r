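#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom methods is
#' @import dplyr
NULL

# logit / inverse-logit on the open unit interval
logit <- function(p) stats::qlogis(p)
logistic <- function(x) stats::plogis(x)

# population (divide-by-n) standard deviation; the convention used throughout
# for residual scales and proposal adaptation
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# evaluate `expr` under a fixed RNG state when `seed` is given, without
# disturbing the caller's RNG; plain evaluation otherwise
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_prob_open <- function(psi, what = "psi") {
  if (any(!is.finite(psi)) || any(psi <= 0) || any(psi >= 1)) {
    abort(sprintf("`%s` must lie strictly inside (0, 1)", what))
  }
  invisible(psi)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
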