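test_that("true psi values follow the logit-normal law", {
  psi <- draw_psi(1e5, mu = 0, sigma = 3, seed = 1)
  expect_true(all(psi > 0 & psi < 1))
  expect_equal(median(psi), 0.5, tolerance = 0.02)
  expect_equal(sd(qlogis(psi)), 3, tolerance = 0.02 * 3)
  expect_equal(draw_psi(5, mu = 1, sigma = 0, seed = 2), rep(plogis(1), 5))
})

test_that("the auxiliary feature achieves the target correlation with logit-psi", {
  psi <- draw_psi(11478, seed = 3)
  f <- make_correlated_feature(psi, target_r = 0.8, seed = 4)
  expect_equal(cor(f, qlogis(psi)), 0.8, tolerance = 0.002)
  # zero noise is requested via target_r = 1
  expect_equal(cor(make_correlated_feature(psi, 1), qlogis(psi)), 1)
  expect_error(make_correlated_feature(rep(0.5, 10)), "non-identical")
})

test_that("null features are uncorrelated with the truth", {
  psi <- draw_psi(11478, seed = 5)
  nf <- null_features(paste0("e", seq_along(psi)), seed = 6)
  rs <- vapply(2:6, function(j) abs(cor(nf[[j]], qlogis(psi))), numeric(1))
  expect_true(all(rs < 0.05))
})

test_that("simulated events honour the six quality filters by construction", {
  evs <- simulate_events(50, seed = 7)
  res <- filter_skipping_events(evs)
  expect_true(all(res$report$passed))
})

test_that("read counts follow the coverage and mixture law", {
  evs <- simulate_events(200, seed = 8)
  psi <- draw_psi(200, seed = 9)
  # rpk = 0 is a drop-out
  e0 <- simulate_read_counts(evs, psi, rpk = 0, seed = 10)
  expect_true(all(e0$n_inc + e0$n_exc + e0$n_amb == 0L))
  # psi near 1 produces no exclusion-only reads
  e1 <- simulate_read_counts(evs, rep(1 - 1e-12, 200), rpk = 100, seed = 11)
  expect_true(all(e1$n_exc == 0L))
  # fixed_n gives the deterministic expected count
  e2 <- simulate_read_counts(evs, psi, rpk = 100, fixed_n = TRUE, seed = 12)
  ln <- evs$c1_end - evs$c1_start + evs$alt_end - evs$alt_start +
    evs$c2_end - evs$c2_start + 3L
  lam <- 100 * (psi * ln + (1 - psi) * (ln - (evs$alt_end - evs$alt_start + 1L))) / 1000
  expect_equal(e2$n_inc + e2$n_exc + e2$n_amb, as.integer(round(lam)))
})

test_that("generated alignments round-trip through read classification", {
  ev <- simulate_events(1, seed = 13)
  sim <- simulate_reads(ev, psi_true = 0.4, rpk = 2000, read_len = 75L, seed = 14)
  gen_classes <- attr(sim$evidence, "classes")
  cls <- classify_reads(sim$alignments, ev, span = 75L)
  got <- setNames(cls$class, cls$read_id)
  ids <- unique(sim$alignments$read_id)
  expect_equal(unname(got[ids]), gen_classes)
  # every alignment is consistent with its generating isoform (or both)
  iso <- sim$alignments$isoform[!duplicated(sim$alignments$read_id)]
  ok <- ifelse(iso == "inclusion", cls$p_inc[match(ids, cls$read_id)],
               cls$p_exc[match(ids, cls$read_id)])
  expect_true(all(ok > 0))
})

test_that("paired-end fragments classify like their generating isoform", {
  ev <- simulate_events(1, seed = 15)
  sim <- simulate_reads(ev, psi_true = 0.5, rpk = 500, read_len = 50L,
                        paired = TRUE, frag_len = 180L, seed = 16)
  expect_true(all(c(1L, 2L) %in% sim$alignments$mate))
  cls <- classify_reads(sim$alignments, ev, span = 180L)
  got <- setNames(cls$class, cls$read_id)
  ids <- unique(sim$alignments$read_id)
  expect_equal(unname(got[ids]), attr(sim$evidence, "classes"))
})

test_that("the differential design mirrors psi between conditions", {
  d <- simulate_differential(400, seed = 17)
  expect_equal(nrow(d), 400L)
  expect_equal(d$psi_cond2, 1 - d$psi_cond1)
  expect_equal(as.vector(table(d$psi_cond1)), rep(50L, 8L))
  expect_false(any(d$psi_cond1 == 0.5))
  expect_equal(sort(unique(round(abs(d$delta_psi), 10))), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(mean(d$delta_psi), 0, tolerance = 1e-12)
  expect_error(simulate_differential(401), "divisible by 8")
})

test_that("drop-out simulation follows the Bernoulli profile and rescales totals", {
  n <- 11478L
  Z <- withr::with_seed(18, rexp(n, 1 / 50))
  # no drop-out probability: output proportional to Z
  none <- simulate_dropout(Z, rep(0, n), total_reads = 1e6, seed = 19)
  expect_false(any(none$dropout))
  expect_equal(sum(none$expression), 1e6)
  expect_equal(cor(none$expression, Z), 1)
  # certain drop-out zeroes the event
  p <- rep(0.3, n); p[1] <- 1
  out <- simulate_dropout(Z, p, seed = 20)
  expect_true(out$dropout[1])
  expect_equal(out$expression[1], 0)
  expect_equal(mean(out$dropout), mean(p), tolerance = 0.02)
  # a logit shift moves the overall drop-out rate
  shifted <- simulate_dropout(Z, rep(0.3, n), logit_shift = 1, seed = 21)
  expect_gt(mean(shifted$dropout), 0.4)
  prof <- dropout_profile(1000, seed = 22)
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("the bundled coverage benchmark wires truth, evidence and features together", {
  sim <- simulate_coverage_benchmark(n_events = 300, rpk = 50,
                                     dropout_frac = 0.2, seed = 23)
  expect_equal(nrow(sim$truth), 300L)
  expect_equal(sum(sim$truth$dropout), 60L)
  zero <- sim$evidence$n_inc + sim$evidence$n_exc + sim$evidence$n_amb == 0L
  expect_true(all(zero[sim$truth$dropout]))
  expect_equal(cor(sim$features$aux, qlogis(sim$truth$psi_true)), 0.8,
               tolerance = 0.002)
  # reproducible under the same seed
  sim2 <- simulate_coverage_benchmark(n_events = 300, rpk = 50,
                                      dropout_frac = 0.2, seed = 23)
  expect_identical(sim, sim2)
})
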