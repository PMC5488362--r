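test_that("length features recover closed-form values", {
  ev <- simulate_events(1, c1_range = c(100L, 100L), alt_range = c(100L, 100L),
                        intron_range = c(100L, 100L), c2_range = c(100L, 100L),
                        seed = 1)
  lf <- length_features(ev)
  expect_equal(ncol(lf), 8L)
  expect_equal(unname(lf[1, 1:5]), rep(log(100), 5))
  expect_equal(unname(lf[1, 6:8]), rep(1, 3))

  ev2 <- simulate_events(1, alt_range = c(100L, 100L),
                         intron_range = c(10000L, 10000L), seed = 2)
  expect_equal(unname(length_features(ev2)[1, "len_ratio_alt_i1"]),
               log(100) / log(10000))
})

test_that("length ratios error on a degenerate intron", {
  ev <- dplyr::mutate(toy_event(), i1_end = i1_start)
  expect_error(length_features(ev), "length <= 1")
})

test_that("PWM construction matches the pseudocount closed form", {
  homo <- vapply(c("A", "C", "G", "T"), function(b) strrep(b, 11), character(1))
  pwm <- build_pwm(homo, "5ss", pseudocount = 0)
  expect_true(all(abs(pwm$mat - 0.25) < 1e-12))
  expect_equal(colSums(pwm$mat), rep(1, 11), ignore_attr = TRUE)

  single <- build_pwm("ACGTACGTACG", "5ss", pseudocount = 0)
  expect_equal(unname(single$mat["A", 1]), 1)
  expect_equal(unname(single$mat["C", 1]), 0)

  pc1 <- build_pwm("ACGTACGTACG", "5ss", pseudocount = 1)
  expect_equal(unname(pc1$mat["A", 1]), 2 / 5)
  expect_equal(unname(pc1$mat["C", 1]), 1 / 5)
})

test_that("PWM windows are 11 nt for 5'ss (-4..+6) and 21 nt for 3'ss (-16..+4)", {
  expect_equal(pwm_window("5ss")$width, 11L)
  expect_equal(pwm_window("5ss")$offsets, -4:6)
  expect_equal(pwm_window("3ss")$width, 21L)
  expect_equal(pwm_window("3ss")$offsets, -16:4)
  expect_error(build_pwm("ACGT", "5ss"), "11 nt")
  expect_error(build_pwm(character(), "3ss"), "empty")
})

test_that("splice-site strengths are PWM log-likelihoods", {
  ev <- toy_event(seed = 3)
  uni <- list(ss5 = uniform_pwm("5ss"), ss3 = uniform_pwm("3ss"))
  ss <- splice_site_strength(ev, uni)
  expect_equal(ncol(ss), 4L)
  expect_equal(unname(ss[1, "ss_i1_5ss"]), 11 * log(0.25))
  expect_equal(unname(ss[1, "ss_i2_3ss"]), 21 * log(0.25))

  # brute-force oracle on a trained PWM: per-position product of probabilities
  sites <- withr::with_seed(4, vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  }, character(1)))
  pwm3 <- build_pwm(sites, "3ss", pseudocount = 1)
  win <- paste0(substr(ev$seq_i2, nchar(ev$seq_i2) - 15L, nchar(ev$seq_i2)),
                substr(ev$seq_c2, 1L, 5L))
  chars <- strsplit(win, "")[[1]]
  manual <- sum(vapply(seq_along(chars),
                       function(p) log(pwm3$mat[chars[p], p]), numeric(1)))
  got <- splice_site_strength(ev, list(ss5 = uni$ss5, ss3 = pwm3))
  expect_equal(unname(got[1, "ss_i2_3ss"]), manual)
})

test_that("PWMs trained on annotation recover a planted consensus", {
  # donor sites in the toy gene: end of C1 and end of A; plant G at offset 0
  g <- toy_genome(seed = 55)
  s <- strsplit(g[["1"]], "")[[1]]
  s[c(101, 301)] <- "G"  # first intronic base of both donors
  g[["1"]] <- paste(s, collapse = "")
  pwms <- train_splice_pwms(toy_exons("+"), g, pseudocount = 0)
  # offset 0 is position 5 of the 11-nt window
  expect_equal(unname(pwms$ss5$mat["G", 5]), 1)
})

test_that("conservation features average over covered bases only", {
  ev <- toy_event(seed = 5)
  span <- max(ev$c2_end) + 10L
  const <- list("1" = rep(0.5, span))
  cf <- conservation_features(ev, const)
  expect_equal(ncol(cf), 7L)
  expect_equal(unname(cf[1, ]), rep(0.5, 7))

  # C1 half covered at 1.0, half missing -> mean over covered = 1.0
  half <- rep(NA_real_, span)
  mid <- floor((ev$c1_start + ev$c1_end) / 2)
  half[ev$c1_start:mid] <- 1.0
  cf2 <- conservation_features(ev, list("1" = half))
  expect_equal(unname(cf2[1, "cons_c1"]), 1.0)
  expect_true(is.na(cf2[1, "cons_alt"]))
})

test_that("an RleList conservation source is accepted", {
  ev <- toy_event(seed = 6)
  span <- max(ev$c2_end) + 10L
  rl <- IRanges::RleList("1" = S4Vectors::Rle(0.25, span))
  cf <- conservation_features(ev, rl)
  expect_equal(unname(cf[1, ]), rep(0.25, 7))
})

test_that("k-mer frequencies follow the overlapping-occurrence definition", {
  base <- toy_event(seed = 7)
  ev <- dplyr::mutate(base, seq_alt = "AAAA")
  km <- kmer_features(ev)
  expect_equal(unname(km[1, "kmer_alt_A"]), 1)
  expect_equal(unname(km[1, "kmer_alt_C"]), 0)
  expect_equal(unname(km[1, "kmer_alt_AA"]), 1)
  expect_equal(unname(km[1, "kmer_alt_AAAA"]), 1)

  ev2 <- dplyr::mutate(base, seq_alt = "ACGT")
  km2 <- kmer_features(ev2)
  expect_equal(unname(km2[1, c("kmer_alt_A", "kmer_alt_C", "kmer_alt_G", "kmer_alt_T")]),
               rep(0.25, 4))
  expect_equal(unname(km2[1, "kmer_alt_AC"]), 1 / 3)
  expect_equal(unname(km2[1, "kmer_alt_CG"]), 1 / 3)
  expect_equal(unname(km2[1, "kmer_alt_GT"]), 1 / 3)
  # region shorter than k gives an all-zero block, not an error
  ev3 <- dplyr::mutate(base, seq_alt = "ACG")
  expect_equal(sum(kmer_features(ev3)[1, startsWith(colnames(km), "kmer_alt_") &
                                        nchar(sub("kmer_alt_", "", colnames(km))) == 4]),
               0)
})

test_that("k-mer frequencies for a fixed region and k sum to one", {
  ev <- toy_event(seed = 8)
  km <- kmer_features(ev)
  for (region in c("c1", "alt", "c2")) {
    for (k in 1:3) {
      cols <- startsWith(colnames(km), paste0("kmer_", region, "_")) &
        nchar(sub(paste0("kmer_", region, "_"), "", colnames(km))) == k
      expect_equal(sum(km[1, cols]), 1)
    }
  }
})

test_that("feature assembly produces the fixed 735-column layout", {
  evs <- simulate_events(3, seed = 9)
  f <- event_features(evs)
  expect_equal(ncol(f) - 1L, 735L)
  expect_equal(nrow(f), 3L)
  # identical events produce identical vectors
  f2 <- event_features(evs[c(1, 1), ])
  expect_equal(as.numeric(f2[1, -1]), as.numeric(f2[2, -1]))
  # without a conservation source the 7 conservation entries are the
  # imputation value 0 and everything else is unchanged
  cons_cols <- startsWith(names(f), "cons_")
  expect_true(all(f[, cons_cols] == 0))
  withcons <- event_features(evs, scores = list("1" = rep(1, max(evs$c2_end) + 1)))
  expect_true(all(withcons[, cons_cols] == 1))
  expect_equal(as.matrix(withcons[, !cons_cols]), as.matrix(f[, !cons_cols]))
})

test_that("standardization yields zero-mean unit-variance columns and keeps order", {
  evs <- simulate_events(10, seed = 10)
  f <- event_features(evs, standardize = TRUE)
  m <- feature_matrix(f)
  nontrivial <- apply(m, 2, function(x) any(x != 0))
  expect_true(all(abs(colMeans(m[, nontrivial])) < 1e-10))
  expect_true(all(abs(apply(m[, nontrivial], 2, function(x) sqrt(mean((x - mean(x))^2))) - 1) < 1e-10))
  # permuting events permutes rows identically
  perm <- c(3, 1, 2, 4:10)
  fp <- event_features(evs[perm, ], standardize = TRUE)
  expect_equal(feature_matrix(fp), m[perm, ])
})
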