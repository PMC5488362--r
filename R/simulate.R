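#' @name simulate
#' @title Synthetic benchmark generator
#'
#' @description
#' Reproduces the three benchmark designs used to validate the method:
#' coverage robustness (logit-normal true psi, fixed reads-per-kilobase, one
#' auxiliary feature correlated 0.8 with logit-psi), differential splicing
#' (eight psi levels mirrored between two conditions) and drop-out /
#' imputation (Bernoulli drop-outs driven by a per-event drop-out-probability
#' profile). Reads are generated natively under the same uniform-start,
#' length-adjusted mixture law that the likelihood assumes, either as class
#' counts (fast path) or as genome-coordinate alignments with junction gaps.
NULL

#' Draw true inclusion ratios from a logit-normal distribution
#'
#' `psi = logistic(z)`, `z ~ N(mu, sigma^2)`; the defaults match the
#' empirical distribution of bulk exon-inclusion ratios (`mu = 0`,
#' `sigma = 3`).
#'
#' @param n_events Number of events.
#' @param mu,sigma Location and scale on the logit scale (`sigma > 0`).
#' @param seed Optional integer seed.
#' @return Numeric vector of psi values in (0, 1).
#' @export
draw_psi <- function(n_events, mu = 0, sigma = 3, seed = NULL) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  with_seed_(seed, logistic(stats::rnorm(n_events, mu, sigma)))
}

#' Construct an auxiliary feature with a target correlation to logit-psi
#'
#' Adds Gaussian noise to logit(psi) and rescales the noise so the realised
#' Pearson correlation with logit(psi) equals `target_r` (up to numerical
#' root-finding tolerance, well inside +-0.02).
#'
#' @param psi_true True inclusion ratios (at least 3, not all equal).
#' @param target_r Target Pearson correlation in (0, 1].
#' @param seed Optional integer seed.
#' @return Numeric feature vector, same length as `psi_true`.
#' @export
make_correlated_feature <- function(psi_true, target_r = 0.8, seed = NULL) {
  if (target_r <= 0 || target_r > 1) abort("`target_r` must be in (0, 1]")
  z <- logit(psi_true)
  if (length(z) < 3L || pop_sd(z) == 0) {
    abort("`psi_true` must contain at least 3 non-identical values")
  }
  if (target_r == 1) return(z)
  with_seed_(seed, {
    e <- stats::rnorm(length(z), 0, pop_sd(z) * sqrt(1 / target_r^2 - 1))
    f <- function(c) stats::cor(z + c * e, z) - target_r
    # cor(z + c e, z) decreases from 1 towards 0 as c grows
    hi <- 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    c_star <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
    z + c_star * e
  })
}

#' Uninformative uniform features (the null-prior control)
#'
#' @param event_id Event identifiers.
#' @param k Number of independent Uniform(0, 1) features (default 5).
#' @param seed Optional integer seed.
#' @return Feature tibble usable by [quant_psi()].
#' @export
null_features <- function(event_id, k = 5L, seed = NULL) {
  with_seed_(seed, {
    m <- matrix(stats::runif(length(event_id) * k), ncol = k,
                dimnames = list(NULL, paste0("null_", seq_len(k))))
    dplyr::bind_cols(tibble(event_id = event_id), as_tibble(m))
  })
}

#' Random event geometries for simulation
#'
#' Synthetic exon-skipping events laid head-to-tail along one synthetic
#' chromosome, with random sequences that satisfy the AG/GT dinucleotide
#' rule, intron lengths of at least 100 bp, and TSS/TTS distances of 500 bp.
#'
#' @param n_events Number of events.
#' @param c1_range,alt_range,intron_range,c2_range Length ranges (bp) to
#'   sample uniformly.
#' @param chrom Chromosome name of the synthetic contig.
#' @param seed Optional integer seed.
#' @return An events tibble as from [extract_skipping_events()].
#' @export
simulate_events <- function(n_events, c1_range = c(100L, 300L),
                            alt_range = c(50L, 450L),
                            intron_range = c(100L, 500L),
                            c2_range = c(100L, 300L), chrom = "1",
                            seed = NULL) {
  rint <- function(n, r) {
    if (r[1] == r[2]) rep(as.integer(r[1]), n)
    else sample(seq(r[1], r[2]), n, replace = TRUE)
  }
  rseq <- function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }
  with_seed_(seed, {
    lc1 <- rint(n_events, c1_range); la <- rint(n_events, alt_range)
    lc2 <- rint(n_events, c2_range)
    li1 <- rint(n_events, intron_range); li2 <- rint(n_events, intron_range)
    gap <- 1000L
    pos <- gap + c(0L, cumsum((lc1 + li1 + la + li2 + lc2 + gap)[-n_events]))
    seq_i1 <- vapply(li1, function(l) paste0(rseq(l - 2L), "AG"), character(1))
    seq_i2 <- vapply(li2, function(l) paste0("GT", rseq(l - 2L)), character(1))
    tibble(
      event_id = sprintf("sim%05d", seq_len(n_events)),
      gene_id = sprintf("gene%05d", seq_len(n_events)),
      chrom = chrom, strand = "+",
      c1_start = pos, c1_end = pos + lc1 - 1L,
      i1_start = pos + lc1, i1_end = pos + lc1 + li1 - 1L,
      alt_start = pos + lc1 + li1, alt_end = pos + lc1 + li1 + la - 1L,
      i2_start = pos + lc1 + li1 + la, i2_end = pos + lc1 + li1 + la + li2 - 1L,
      c2_start = pos + lc1 + li1 + la + li2,
      c2_end = pos + lc1 + li1 + la + li2 + lc2 - 1L,
      tss_distance = 500, tts_distance = 500,
      seq_c1 = vapply(lc1, rseq, character(1)),
      seq_i1 = seq_i1,
      seq_alt = vapply(la, rseq, character(1)),
      seq_i2 = seq_i2,
      seq_c2 = vapply(lc2, rseq, character(1))
    )
  })
}

# per-event class probabilities under the uniform-start mixture law
class_probabilities <- function(len_c1, len_alt, len_c2, psi, read_len) {
  L_inc <- len_c1 + len_alt + len_c2
  L_exc <- len_c1 + len_c2
  l_inc <- L_inc - read_len + 1
  l_exc <- L_exc - read_len + 1
  if (any(l_exc < 1)) abort("read length exceeds the exclusion isoform")
  amb <- pmax(len_c1 - read_len + 1, 0) + pmax(len_c2 - read_len + 1, 0)
  w <- mixing_weight(psi, l_inc, l_exc)
  list(
    p_inc = w * (l_inc - amb) / l_inc,
    p_exc = (1 - w) * (l_exc - amb) / l_exc,
    p_amb = w * amb / l_inc + (1 - w) * amb / l_exc,
    l_inc = l_inc, l_exc = l_exc, L_inc = L_inc, L_exc = L_exc, w = w
  )
}

#' Simulate per-event read class counts at fixed coverage
#'
#' The fast, count-level read generator: for each event the total read count
#' is Poisson with mean `rpk` times the psi-weighted transcript length in kb
#' (or exactly that mean with `fixed_n = TRUE`), each read picks its isoform
#' with the length-adjusted inclusion weight, and its class follows from a
#' uniform start position. `rpk = 0` produces zero reads (a drop-out).
#'
#' @param events Events tibble (only the region lengths are used).
#' @param psi_true True inclusion ratio per event.
#' @param rpk Reads per kilobase; scalar or per-event vector.
#' @param read_len Read length in nt (default 100).
#' @param fixed_n Use the deterministic expected count instead of Poisson.
#' @param seed Optional integer seed.
#' @return Evidence tibble ([read_evidence()]).
#' @export
simulate_read_counts <- function(events, psi_true, rpk, read_len = 100L,
                                 fixed_n = FALSE, seed = NULL) {
  ln <- event_lengths(events)
  check_prob_open(psi_true, "psi_true")
  p <- class_probabilities(ln$len_c1, ln$len_alt, ln$len_c2, psi_true, read_len)
  with_seed_(seed, {
    lam <- rpk * (psi_true * p$L_inc + (1 - psi_true) * p$L_exc) / 1000
    n <- if (fixed_n) round(lam) else stats::rpois(length(lam), lam)
    cls <- t(vapply(seq_along(n), function(i) {
      if (n[i] == 0L) return(c(0, 0, 0))
      drop(stats::rmultinom(1L, n[i], c(p$p_inc[i], p$p_exc[i], p$p_amb[i])))
    }, numeric(3)))
    read_evidence(ln$event_id, n_inc = cls[, 1], n_exc = cls[, 2],
                  n_amb = cls[, 3], len_inc = p$l_inc, len_exc = p$l_exc)
  })
}

# map a transcript interval to genomic blocks on `exons` (genomic order)
tx_to_blocks <- function(s, e, exons) {
  widths <- exons[, 2] - exons[, 1] + 1L
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  hit <- which(ends >= s & starts <= e)
  cbind(exons[hit, 1] + pmax(s - starts[hit], 0L),
        exons[hit, 1] + pmin(e - starts[hit], widths[hit] - 1L))
}

#' Simulate aligned reads for one event
#'
#' The alignment-level generator: draws the read count and isoform identities
#' exactly as [simulate_read_counts()], places each read (or read pair)
#' uniformly on its isoform, and emits genome-coordinate aligned blocks with
#' junction gaps, plus the matching evidence summary. [classify_reads()] on
#' the emitted alignments reproduces the generator's classes exactly.
#'
#' @param event One-row events tibble.
#' @param psi_true True inclusion ratio.
#' @param rpk Reads per kilobase.
#' @param read_len Read length in nt.
#' @param paired Generate read pairs of two `read_len` mates spanning
#'   `frag_len` nt.
#' @param frag_len Fragment length for paired-end reads.
#' @param fixed_n Deterministic read count.
#' @param seed Optional integer seed.
#' @return List with `alignments` (block tibble: `read_id`, `chrom`, `start`,
#'   `end`, `mate`, `isoform`) and `evidence` (one-row evidence tibble
#'   computed from the generator's own class labels, stored in the
#'   `classes` attribute).
#' @export
simulate_reads <- function(event, psi_true, rpk, read_len = 100L,
                           paired = FALSE, frag_len = 250L, fixed_n = FALSE,
                           seed = NULL) {
  check_prob_open(psi_true, "psi_true")
  span <- if (paired) frag_len else read_len
  ln <- event_lengths(event)
  with_seed_(seed, {
    L_inc <- ln$len_c1 + ln$len_alt + ln$len_c2
    L_exc <- ln$len_c1 + ln$len_c2
    l_inc <- L_inc - span + 1L; l_exc <- L_exc - span + 1L
    if (l_exc < 1L) abort("fragment span exceeds the exclusion isoform")
    lam <- rpk * (psi_true * L_inc + (1 - psi_true) * L_exc) / 1000
    n <- if (fixed_n) round(lam) else stats::rpois(1L, lam)
    w <- mixing_weight(psi_true, l_inc, l_exc)
    iso <- stats::rbinom(n, 1L, w)  # 1 = inclusion
    ex_inc <- isoform_exons(event, "inclusion")
    ex_exc <- isoform_exons(event, "exclusion")
    rows <- vector("list", n)
    classes <- character(n)
    for (r in seq_len(n)) {
      if (iso[r] == 1L) { exons <- ex_inc; l <- l_inc; tot <- L_inc }
      else { exons <- ex_exc; l <- l_exc; tot <- L_exc }
      s <- sample.int(l, 1L)
      first_len <- exons[1, 2] - exons[1, 1] + 1L
      last_start_tx <- tot - (exons[nrow(exons), 2] - exons[nrow(exons), 1] + 1L) + 1L
      # a sequenced interval is informative only if it leaves the flanks; for
      # pairs the inner gap is unsequenced, so each mate is judged on its own
      mate_iv <- if (paired) {
        rbind(c(s, s + read_len - 1L), c(s + span - read_len, s + span - 1L))
      } else {
        rbind(c(s, s + span - 1L))
      }
      informative <- any(!(mate_iv[, 2] <= first_len | mate_iv[, 1] >= last_start_tx))
      classes[r] <- if (!informative) "ambiguous"
        else if (iso[r] == 1L) "inclusion" else "exclusion"
      mk_mate <- function(ms, me, mate) {
        b <- tx_to_blocks(ms, me, exons)
        tibble(read_id = sprintf("r%06d", r), chrom = event$chrom,
               start = b[, 1], end = b[, 2], mate = mate,
               isoform = if (iso[r] == 1L) "inclusion" else "exclusion")
      }
      rows[[r]] <- if (paired) {
        dplyr::bind_rows(mk_mate(s, s + read_len - 1L, 1L),
                         mk_mate(s + span - read_len, s + span - 1L, 2L))
      } else {
        mk_mate(s, s + span - 1L, 1L)
      }
    }
    alignments <- if (n > 0) dplyr::bind_rows(rows) else
      tibble(read_id = character(), chrom = character(), start = integer(),
             end = integer(), mate = integer(), isoform = character())
    evidence <- read_evidence(event$event_id,
                              n_inc = sum(classes == "inclusion"),
                              n_exc = sum(classes == "exclusion"),
                              n_amb = sum(classes == "ambiguous"),
                              len_inc = l_inc, len_exc = l_exc)
    attr(evidence, "classes") <- classes
    list(alignments = alignments, evidence = evidence)
  })
}

#' Two-condition differential design
#'
#' Eight psi levels (0.1 to 0.9 without 0.5) are spread equally over the
#' events; condition 2 receives the mirrored value `1 - psi`, giving effect
#' sizes |delta psi| of 0.2, 0.4, 0.6 and 0.8.
#'
#' @param n_events Number of events, divisible by 8 (default 400).
#' @param seed Optional integer seed (shuffles the level assignment).
#' @return Tibble: `event_id`, `psi_cond1`, `psi_cond2`, `delta_psi`.
#' @export
simulate_differential <- function(n_events = 400L, seed = NULL) {
  levels <- setdiff(seq(0.1, 0.9, by = 0.1), 0.5)
  if (n_events %% 8L != 0L) abort("`n_events` must be divisible by 8")
  with_seed_(seed, {
    psi1 <- sample(rep(levels, each = n_events / 8L))
    tibble(event_id = sprintf("sim%05d", seq_len(n_events)),
           psi_cond1 = psi1, psi_cond2 = 1 - psi1,
           delta_psi = (1 - psi1) - psi1)
  })
}

#' Synthetic per-event drop-out probability profile
#'
#' A Beta-distributed stand-in for a drop-out probability profile estimated
#' from a panel of real cells: broad, with substantial mass at high drop-out
#' probabilities. Purely synthetic; any empirical profile (one probability
#' per event) can be used in its place.
#'
#' @param n_events Number of events.
#' @param shape1,shape2 Beta shape parameters (default 0.6 / 0.4, mean 0.6).
#' @param seed Optional integer seed.
#' @return Numeric vector of drop-out probabilities in `[0, 1]`.
#' @export
dropout_profile <- function(n_events, shape1 = 0.6, shape2 = 0.4, seed = NULL) {
  with_seed_(seed, stats::rbeta(n_events, shape1, shape2))
}

#' Apply Bernoulli drop-outs to a bulk expression profile
#'
#' Each event keeps its bulk expression with probability `1 - p'` and drops
#' to zero otherwise, where `p'` is the drop-out probability shifted by
#' `logit_shift` on the logit scale; the kept values are rescaled by a common
#' factor alpha so the total equals `total_reads` (when given).
#'
#' @param Z Non-negative bulk expression per event (e.g. FPKM or RPK).
#' @param p Per-event drop-out probabilities in `[0, 1]`.
#' @param total_reads Optional target total of the output vector.
#' @param logit_shift Shift of the drop-out probabilities on the logit scale
#'   (0 keeps the profile unchanged).
#' @param seed Optional integer seed.
#' @return Tibble: `expression` (the simulated single-cell level) and
#'   `dropout` (logical).
#' @export
simulate_dropout <- function(Z, p, total_reads = NULL, logit_shift = 0,
                             seed = NULL) {
  if (any(Z < 0)) abort("`Z` must be non-negative")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  p_shift <- if (logit_shift == 0) p else logistic(logit(p) + logit_shift)
  with_seed_(seed, {
    keep <- stats::rbinom(length(Z), 1L, 1 - p_shift)
    if (all(keep == 0L)) warn("all events dropped out")
    expr <- keep * Z
    if (!is.null(total_reads) && sum(expr) > 0) {
      expr <- expr * total_reads / sum(expr)
    }
    tibble(expression = expr, dropout = keep == 0L)
  })
}

#' One-call coverage benchmark data set
#'
#' Bundles the coverage-design generator: random event geometries, true psi
#' from logit-Normal(mu, sigma), the auxiliary feature correlated `target_r`
#' with logit-psi, the five-uniform-feature null regressor set, and read
#' class counts at fixed RPK. An optional `dropout_frac` forces that fraction
#' of events (chosen at random) to zero reads.
#'
#' @param n_events Number of events.
#' @param rpk Reads per kilobase for expressed events.
#' @param mu,sigma Logit-normal parameters of true psi.
#' @param target_r Feature-truth correlation.
#' @param read_len Read length (nt).
#' @param dropout_frac Fraction of events forced to zero reads.
#' @param seed Optional integer seed (drives all stages).
#' @return List: `truth` (tibble `event_id`, `psi_true`, `rpk`, `dropout`),
#'   `events`, `evidence`, `features` (auxiliary), `features_null`.
#' @export
simulate_coverage_benchmark <- function(n_events = 11478L, rpk = 100,
                                        mu = 0, sigma = 3, target_r = 0.8,
                                        read_len = 100L, dropout_frac = 0,
                                        seed = NULL) {
  with_seed_(seed, {
    events <- simulate_events(n_events)
    psi <- draw_psi(n_events, mu, sigma)
    feat <- make_correlated_feature(psi, target_r)
    nullf <- null_features(events$event_id)
    drop <- rep(FALSE, n_events)
    if (dropout_frac > 0) {
      drop[sample.int(n_events, round(dropout_frac * n_events))] <- TRUE
    }
    rpk_vec <- ifelse(drop, 0, rpk)
    evidence <- simulate_read_counts(events, psi, rpk_vec, read_len)
    list(
      truth = tibble(event_id = events$event_id, psi_true = psi,
                     rpk = rpk_vec, dropout = drop),
      events = events,
      evidence = evidence,
      features = tibble(event_id = events$event_id, aux = feat),
      features_null = nullf
    )
  })
}
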