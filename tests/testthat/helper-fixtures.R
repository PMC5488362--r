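# Toy fixtures shared across the test files. Everything is generated in code,
# under fixed seeds, at test time.

# a random genome: one chromosome named "1" of the given length
toy_genome <- function(len = 600L, seed = 101L) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    stats::setNames(s, "1")
  })
}

# the canonical toy gene: transcript T1 with exons [1,100], [201,300],
# [401,500]; transcript T2 skipping the middle exon
toy_exons <- function(strand = "+") {
  tibble::tibble(
    gene_id = "G1",
    transcript_id = rep(c("T1", "T2"), c(3L, 2L)),
    chrom = "1",
    start = c(1L, 201L, 401L, 1L, 401L),
    end = c(100L, 300L, 500L, 100L, 500L),
    strand = strand
  )
}

# a single valid event with convenient geometry (from the simulator, which
# honours all six filter rules by construction)
toy_event <- function(seed = 7L, ...) {
  simulate_events(1L, seed = seed, ...)
}

# evidence row with given counts on a 500/300 effective-length event
toy_evidence <- function(n_inc = 0L, n_exc = 0L, n_amb = 0L,
                         len_inc = 500, len_exc = 300) {
  read_evidence("e1", n_inc, n_exc, n_amb, len_inc, len_exc)
}

# deterministic numeric quadrature of likelihood x prior over psi in (0,1):
# the independent oracle for posterior mean and credible interval
quadrature_posterior <- function(evidence, x, state, n_grid = 20001L) {
  post_un <- function(psi) {
    exp(psi_loglik(evidence, psi) + prior_logpdf(psi, x, state))
  }
  Z <- stats::integrate(function(p) vapply(p, post_un, numeric(1)),
                        0, 1, rel.tol = 1e-10)$value
  m <- stats::integrate(function(p) vapply(p, function(q) q * post_un(q), numeric(1)),
                        0, 1, rel.tol = 1e-10)$value / Z
  grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  dens <- vapply(grid, post_un, numeric(1))
  cdf <- cumsum(dens) / sum(dens)
  list(mean = m,
       ci = c(grid[which.min(abs(cdf - 0.025))],
              grid[which.min(abs(cdf - 0.975))]))
}
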