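# one fixed toy event used throughout; geometry is known exactly
lik_event <- function() simulate_events(1, seed = 77)

test_that("read classification separates ambiguous, isoform-specific and incompatible reads", {
  ev <- lik_event()
  rl <- 50L
  el <- effective_lengths(ev, rl)
  aln <- tibble::tibble(
    read_id = c("in_c1", "in_alt", "junc_excl", "junc_excl", "junc_incl",
                "junc_incl", "intronic"),
    chrom = "1",
    start = c(ev$c1_start,                      # fully inside C1
              ev$alt_start,                     # fully inside A
              ev$c1_end - rl / 2 + 1, ev$c2_start,   # C1 -> C2 junction
              ev$c1_end - rl / 2 + 1, ev$alt_start,  # C1 -> A junction
              ev$i1_start),                     # intron
    end = c(ev$c1_start + rl - 1, ev$alt_start + rl - 1,
            ev$c1_end, ev$c2_start + rl / 2 - 1,
            ev$c1_end, ev$alt_start + rl / 2 - 1,
            ev$i1_start + rl - 1)
  )
  cls <- classify_reads(aln, ev, span = rl)
  got <- setNames(cls$class, cls$read_id)
  expect_equal(got[["in_c1"]], "ambiguous")
  expect_equal(got[["in_alt"]], "inclusion")
  expect_equal(got[["junc_excl"]], "exclusion")
  expect_equal(got[["junc_incl"]], "inclusion")
  expect_equal(got[["intronic"]], "incompatible")
  # compatibility probabilities are 1/effective length or zero
  expect_equal(cls$p_inc[cls$read_id == "in_c1"], 1 / el[["inc"]])
  expect_equal(cls$p_exc[cls$read_id == "in_c1"], 1 / el[["exc"]])
  expect_equal(cls$p_inc[cls$read_id == "junc_excl"], 0)
  expect_equal(cls$p_exc[cls$read_id == "junc_excl"], 1 / el[["exc"]])
})

test_that("reads on the wrong chromosome are dropped with a warning", {
  ev <- lik_event()
  aln <- tibble::tibble(read_id = "r1", chrom = "9",
                        start = ev$c1_start, end = ev$c1_start + 49L)
  expect_warning(cls <- classify_reads(aln, ev, span = 50L), "chromosome")
  expect_equal(nrow(cls), 0L)
})

test_that("paired-end classification requires both mates to be compatible", {
  ev <- lik_event()
  rl <- 40L
  pair <- tibble::tibble(
    read_id = "p1", chrom = "1", mate = c(1L, 2L, 2L),
    start = c(ev$c1_start, ev$c1_end - 19L, ev$c2_start),
    end = c(ev$c1_start + rl - 1L, ev$c1_end, ev$c2_start + 19L)
  )
  cls <- classify_reads(pair, ev, span = 200L)
  expect_equal(cls$class, "exclusion")
})

test_that("effective lengths differ by the alternative exon length", {
  ev <- lik_event()
  el <- effective_lengths(ev, 100L)
  expect_equal(el[["inc"]] - el[["exc"]], ev$alt_end - ev$alt_start + 1L)
  expect_error(effective_lengths(ev, 10000L), "exceeds")
})

test_that("ambiguous reads contribute only the mixture-length term", {
  # an ambiguous read has probability 1 / (psi l_inc + (1 - psi) l_exc):
  # its information content vanishes as the effective lengths approach each
  # other, and is exactly zero for equal lengths
  ev <- toy_evidence(n_amb = 25L)
  for (psi in c(0.2, 0.5, 0.8)) {
    expect_equal(psi_loglik(ev, psi), -25 * log(psi * 500 + (1 - psi) * 300))
  }
  near <- read_evidence("e1", 0L, 0L, 25L, len_inc = 300.001, len_exc = 300)
  expect_equal(psi_loglik(near, 0.2), psi_loglik(near, 0.8), tolerance = 1e-6)
})

test_that("the likelihood matches hand arithmetic and the per-read enumeration oracle", {
  # single inclusion-only read: log(w / len_inc)
  ev1 <- toy_evidence(n_inc = 1L, len_inc = 200, len_exc = 100)
  w <- 0.5 * 200 / (0.5 * 200 + 0.5 * 100)
  expect_equal(psi_loglik(ev1, 0.5), log(w / 200))

  # enumeration oracle: sum over the two isoform identities per read
  ev <- toy_evidence(n_inc = 7L, n_exc = 3L, n_amb = 5L)
  for (psi in c(0.1, 0.5, 0.9)) {
    wts <- psi * 500 / (psi * 500 + (1 - psi) * 300)
    per_read <- c(rep(log(1 / 500 * wts + 0 * (1 - wts)), 7),
                  rep(log(0 * wts + 1 / 300 * (1 - wts)), 3),
                  rep(log(1 / 500 * wts + 1 / 300 * (1 - wts)), 5))
    expect_equal(psi_loglik(ev, psi), sum(per_read))
  }
  expect_error(psi_loglik(ev, 1), "inside")
  expect_error(psi_loglik(ev, 0), "inside")
})

test_that("the likelihood is monotone for single-class evidence", {
  grid <- seq(0.05, 0.95, by = 0.05)
  inc <- psi_loglik(toy_evidence(n_inc = 10L), grid)
  exc <- psi_loglik(toy_evidence(n_exc = 10L), grid)
  expect_true(all(diff(inc) > 0))
  expect_true(all(diff(exc) < 0))
})

test_that("the maximum-likelihood psi matches the closed-form class ratio", {
  k <- 14L; m <- 6L
  ev <- toy_evidence(n_inc = k, n_exc = m, len_inc = 500, len_exc = 300)
  w_star <- k / (k + m)
  psi_star <- w_star * 300 / (w_star * 300 + (1 - w_star) * 500)
  opt <- stats::optimize(function(p) psi_loglik(ev, p), c(0.001, 0.999),
                         maximum = TRUE)
  expect_equal(opt$maximum, psi_star, tolerance = 1e-4)
})

test_that("evidence construction enforces its invariants", {
  expect_error(read_evidence("e", 1, 1, 1, 100, 100), "len_inc > len_exc")
  expect_error(read_evidence("e", -1, 0, 0, 200, 100), "non-negative")
})

test_that("evidence built from alignments matches a manual count", {
  ev <- lik_event()
  sim <- simulate_reads(ev, psi_true = 0.6, rpk = 150, read_len = 50L, seed = 9)
  out <- evidence_from_alignments(sim$alignments, ev, span = 50L)
  expect_equal(out$n_inc, sim$evidence$n_inc)
  expect_equal(out$n_exc, sim$evidence$n_exc)
  expect_equal(out$n_amb, sim$evidence$n_amb)
  expect_equal(attr(out, "n_discarded"), 0L)
})
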