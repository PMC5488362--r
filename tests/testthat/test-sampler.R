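one_feature <- function(ids, value = 0) tibble::tibble(event_id = ids, aux = value)

test_that("proposal adaptation follows the 2.38 x sd rule with a floor", {
  expect_equal(adapt_proposal(c(0, 2)), 2.38)  # population sd of {0,2} is 1
  expect_equal(adapt_proposal(rep(1, 50)), 0.01)
  withr::with_seed(21, {
    expect_equal(adapt_proposal(rnorm(2e4)), 2.38, tolerance = 0.05)
  })
  expect_error(adapt_proposal(1), "at least 2")
})

test_that("the Geweke score flags designed failures and passes calibrated chains", {
  expect_warning(z0 <- geweke_z(rep(3, 100)), "zero variance")
  expect_equal(z0, 0)
  shifted <- c(rnorm(500), rnorm(500, mean = 10))
  expect_gt(abs(geweke_z(shifted)), 5)
  for (s in 1:5) {
    withr::with_seed(100 + s, expect_lt(abs(geweke_z(rnorm(1e4))), 3))
  }
  expect_error(geweke_z(rnorm(10)), "too short")
})

test_that("a zero-sd proposal leaves the chain stuck but accepted", {
  st <- prior_state(c(0, 0), 1)
  out <- mh_step(0.3, toy_evidence(n_amb = 5L), 0, st, proposal_sd = 0)
  expect_true(out$accepted)
  expect_equal(out$y, 0.3)
})

test_that("with a flat likelihood the sampler reproduces the prior distribution", {
  st <- prior_state(c(0, 0.4), sigma = 1.5)
  fit <- suppressWarnings(quant_psi(
    toy_evidence(), one_feature("e1"),
    config = sampler_config(n_total = 21000, burn_in = 1000, seed = 8),
    prior = st, standardize = FALSE))
  y <- qlogis(fit$draws[seq(1, 20000, by = 20), 1])  # thin the chain
  ks <- stats::ks.test(y, "pnorm", 0.4, 1.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("MCMC posterior agrees with deterministic quadrature on one event", {
  ev <- toy_evidence(n_inc = 38L, n_exc = 12L, n_amb = 50L)
  st <- prior_state(c(0, 0.4), sigma = 1.5)
  oracle <- quadrature_posterior(ev, 0, st)
  fit <- quant_psi(ev, one_feature("e1"),
                   config = sampler_config(n_total = 6000, burn_in = 1000, seed = 7),
                   prior = st, standardize = FALSE)
  expect_lt(abs(fit$summary$post_mean - oracle$mean), 0.02)
  expect_lt(abs(fit$summary$ci_low - oracle$ci[1]), 0.02)
  expect_lt(abs(fit$summary$ci_high - oracle$ci[2]), 0.02)
})

test_that("zero-read events fall back to the prior mean (drop-out imputation)", {
  st <- prior_state(c(0, 0.8), sigma = 1)
  fit <- suppressWarnings(quant_psi(
    toy_evidence(), one_feature("e1"),
    config = sampler_config(n_total = 6000, burn_in = 1000, seed = 22),
    prior = st, standardize = FALSE))
  expect_true(fit$summary$dropout)
  target <- prior_mean_psi(0, st, n_draws = 1e5, seed = 23)
  expect_equal(fit$summary$post_mean, target, tolerance = 0.03)
})

test_that("strong data overwhelms a vague fixed prior", {
  ev <- read_evidence("e1", n_inc = 100L, n_exc = 0L, n_amb = 0L,
                      len_inc = 500, len_exc = 300)
  st <- prior_state(c(0, 0), sigma = 3)
  fit <- quant_psi(ev, one_feature("e1"),
                   config = sampler_config(n_total = 4000, burn_in = 1000, seed = 24),
                   prior = st, standardize = FALSE)
  expect_gt(fit$summary$post_mean, 0.95)
})

test_that("runs are deterministic given the seed", {
  sim <- simulate_coverage_benchmark(n_events = 50, rpk = 50, seed = 25)
  cfg <- sampler_config(n_total = 600, burn_in = 200, seed = 26)
  f1 <- quant_psi(sim$evidence, sim$features, config = cfg)
  f2 <- quant_psi(sim$evidence, sim$features, config = cfg)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)
})

test_that("summary fields satisfy their structural invariants", {
  sim <- simulate_coverage_benchmark(n_events = 60, rpk = 80, seed = 27)
  fit <- quant_psi(sim$evidence, sim$features,
                   config = sampler_config(n_total = 800, burn_in = 300, seed = 28))
  s <- fit$summary
  expect_true(all(fit$draws > 0 & fit$draws < 1))
  expect_true(all(s$ci_low <= s$post_mean & s$post_mean <= s$ci_high))
  expect_true(all(s$n_reads == s$n_inc + s$n_exc + s$n_amb))
  expect_equal(colnames(fit$draws), s$event_id)
  expect_gt(fit$sigma, 0)
})

test_that("multi-cell modes share or separate the prior as requested", {
  sim <- simulate_coverage_benchmark(n_events = 40, rpk = 60, seed = 29)
  ev2 <- dplyr::bind_rows(dplyr::mutate(sim$evidence, cell_id = "c1"),
                          dplyr::mutate(sim$evidence, cell_id = "c2"))
  shared <- quant_cells(ev2, sim$features, mode = "shared",
                        config = sampler_config(n_total = 600, burn_in = 200, seed = 30))
  expect_s3_class(shared, "psi_fit")
  expect_equal(nrow(shared$summary), 80L)
  sep <- quant_cells(ev2, sim$features, mode = "separate",
                     config = sampler_config(n_total = 600, burn_in = 200, seed = 31))
  expect_named(sep, c("c1", "c2"))
  expect_equal(nrow(sep$c1$summary), 40L)
  st <- prior_state(c(0, 0), sigma = 2)
  fx <- quant_cells(ev2, sim$features, mode = "fixed", fixed_prior = st,
                    config = sampler_config(n_total = 600, burn_in = 200, seed = 32))
  expect_equal(fx$c1$sigma, 2)
  expect_error(quant_cells(ev2, sim$features, mode = "fixed"), "fixed_prior")
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_coverage_benchmark(n_events = 30, rpk = 60, seed = 33)
  fit <- quant_psi(sim$evidence, sim$features,
                   config = sampler_config(n_total = 600, burn_in = 200, seed = 34))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 30L)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("n_units", "sigma", "mean_accept") %in% names(gl)))
  p <- autoplot(fit, event_id = td$event_id[1])
  expect_s3_class(p, "ggplot")
  p2 <- plot_truth_scatter(fit, sim$truth)
  expect_s3_class(p2, "ggplot")
})
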