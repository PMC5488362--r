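#' @name features
#' @title Sequence-derived splicing regulatory features
#'
#' @description
#' Each exon-skipping event is summarised by 735 features computed from seven
#' genomic regions: C1 (upstream constitutive exon), I1-5ss and I1-3ss (the
#' intronic windows of up to 300 nt anchored at the 5' and 3' splice sites of
#' intron 1), A (alternative exon), I2-5ss and I2-3ss (the same windows for
#' intron 2), and C2 (downstream constitutive exon). The blocks are, in order:
#' 8 length features, 4 splice-site PWM strengths, 7 mean conservation scores
#' and 716 k-mer frequencies.
NULL

DNA_BASES <- c("A", "C", "G", "T")

# intronic sub-regions are at most this long; shorter introns use the whole
# intron (the event filter guarantees introns of >= 100 bp)
SS_WINDOW <- 300L

#' Length features of an event
#'
#' Returns the eight length-derived regressors: log lengths of C1, A, C2, I1,
#' I2 and the ratios log(A)/log(I1), log(A)/log(I2), log(I1)/log(I2) (natural
#' logs of lengths in bp).
#'
#' @param events Events tibble.
#' @return Numeric matrix, one row per event, 8 named columns.
#' @export
length_features <- function(events) {
  ln <- event_lengths(events)
  bad <- ln$len_i1 <= 1L | ln$len_i2 <= 1L
  if (any(bad)) {
    i <- which(bad)[1]
    reg <- if (ln$len_i1[i] <= 1L) "intron 1" else "intron 2"
    abort(sprintf("event %s: %s has length <= 1, log-length ratio undefined",
                  ln$event_id[i], reg))
  }
  m <- cbind(
    len_log_c1 = log(ln$len_c1),
    len_log_alt = log(ln$len_alt),
    len_log_c2 = log(ln$len_c2),
    len_log_i1 = log(ln$len_i1),
    len_log_i2 = log(ln$len_i2),
    len_ratio_alt_i1 = log(ln$len_alt) / log(ln$len_i1),
    len_ratio_alt_i2 = log(ln$len_alt) / log(ln$len_i2),
    len_ratio_i1_i2 = log(ln$len_i1) / log(ln$len_i2)
  )
  rownames(m) <- ln$event_id
  m
}

#' Splice-site PWM window conventions
#'
#' Window offsets are relative to the first base *after* the boundary: for a
#' 5' (donor) site offset 0 is the first intronic base, so -4..+6 spans the
#' last 4 exonic and first 7 intronic nucleotides (11 nt); for a 3' (acceptor)
#' site offset 0 is the first exonic base, so -16..+4 spans the last 16
#' intronic and first 5 exonic nucleotides (21 nt).
#'
#' @param site_kind `"5ss"` or `"3ss"`.
#' @return List with `offsets` and `width`.
#' @export
pwm_window <- function(site_kind = c("5ss", "3ss")) {
  site_kind <- match.arg(site_kind)
  offsets <- if (site_kind == "5ss") -4:6 else -16:4
  list(offsets = offsets, width = length(offsets))
}

#' Build a position weight matrix from aligned splice-site sequences
#'
#' @param sites Character vector of window sequences, all of the window width
#'   for `site_kind` (11 nt for 5'ss, 21 nt for 3'ss), alphabet ACGT.
#' @param site_kind `"5ss"` or `"3ss"`.
#' @param pseudocount Added to every base count before normalisation; each
#'   position's probabilities are `(count + pseudocount) / (n + 4 pseudocount)`.
#' @return An object of class `splice_pwm`: list with `site_kind`, `offsets`
#'   and `mat`, a 4 x width probability matrix (rows A, C, G, T; columns sum
#'   to 1 within each position).
#' @export
build_pwm <- function(sites, site_kind = c("5ss", "3ss"), pseudocount = 1) {
  site_kind <- match.arg(site_kind)
  win <- pwm_window(site_kind)
  if (!length(sites)) abort("`sites` is empty; cannot build a PWM")
  if (any(nchar(sites) != win$width)) {
    abort(sprintf("all %s sites must be %d nt", site_kind, win$width))
  }
  chars <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  mat <- apply(chars, 2L, function(col) {
    cnt <- table(factor(col, levels = DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (length(col) + 4 * pseudocount)
  })
  rownames(mat) <- DNA_BASES
  structure(list(site_kind = site_kind, offsets = win$offsets, mat = mat),
            class = "splice_pwm")
}

#' Uninformative (uniform) splice-site PWM
#'
#' @inheritParams build_pwm
#' @return A `splice_pwm` with probability 0.25 everywhere.
#' @export
uniform_pwm <- function(site_kind = c("5ss", "3ss")) {
  site_kind <- match.arg(site_kind)
  win <- pwm_window(site_kind)
  mat <- matrix(0.25, nrow = 4L, ncol = win$width, dimnames = list(DNA_BASES, NULL))
  structure(list(site_kind = site_kind, offsets = win$offsets, mat = mat),
            class = "splice_pwm")
}

#' Train donor and acceptor PWMs from an exon annotation
#'
#' Collects every internal donor (exon|intron) and acceptor (intron|exon)
#' boundary of every multi-exon transcript, extracts the window sequences on
#' the transcribed strand, and averages them into PWMs. Windows extending past
#' chromosome ends or containing non-ACGT characters are skipped.
#'
#' @inheritParams extract_skipping_events
#' @param pseudocount Passed to [build_pwm()].
#' @return List with elements `ss5` and `ss3`, both `splice_pwm`.
#' @export
train_splice_pwms <- function(exons, genome, pseudocount = 1) {
  genome <- load_genome(genome)
  d5 <- character(); a3 <- character()
  for (t in split(as_tibble(exons), exons$transcript_id)) {
    t <- t[order(t$start), , drop = FALSE]
    n <- nrow(t)
    if (n < 2L || !t$chrom[1] %in% names(genome)) next
    chrom <- t$chrom[1]; strand <- t$strand[1]
    chrom_len <- length(genome[[chrom]])
    grab <- function(start, end, rc) {
      if (start < 1L || end > chrom_len) return(NA_character_)
      s <- genome_seq(genome, chrom, start, end, if (rc) "-" else "+")
      if (grepl("[^ACGT]", s)) NA_character_ else s
    }
    if (strand == "+") {
      d5 <- c(d5, vapply(t$end[-n], function(e) grab(e - 3L, e + 7L, FALSE), character(1)))
      a3 <- c(a3, vapply(t$start[-1L], function(s) grab(s - 16L, s + 4L, FALSE), character(1)))
    } else {
      d5 <- c(d5, vapply(t$start[-1L], function(s) grab(s - 7L, s + 3L, TRUE), character(1)))
      a3 <- c(a3, vapply(t$end[-n], function(e) grab(e - 4L, e + 16L, TRUE), character(1)))
    }
  }
  list(ss5 = build_pwm(d5[!is.na(d5)], "5ss", pseudocount),
       ss3 = build_pwm(a3[!is.na(a3)], "3ss", pseudocount))
}

# window sequences of the four splice sites of an event, transcribed strand
splice_site_windows <- function(events) {
  tail_n <- function(s, n) substr(s, nchar(s) - n + 1L, nchar(s))
  head_n <- function(s, n) substr(s, 1L, n)
  need <- function(s, n, site) {
    if (any(nchar(s) < n)) {
      i <- which(nchar(s) < n)[1]
      abort(sprintf("event %s: sequence too short for the %s window",
                    events$event_id[i], site))
    }
  }
  need(events$seq_c1, 4L, "I1-5'ss"); need(events$seq_i1, 16L, "I1 splice-site")
  need(events$seq_alt, 5L, "I1-3'ss"); need(events$seq_i2, 16L, "I2 splice-site")
  need(events$seq_c2, 5L, "I2-3'ss")
  tibble(
    event_id = events$event_id,
    i1_5ss = paste0(tail_n(events$seq_c1, 4L), head_n(events$seq_i1, 7L)),
    i1_3ss = paste0(tail_n(events$seq_i1, 16L), head_n(events$seq_alt, 5L)),
    i2_5ss = paste0(tail_n(events$seq_alt, 4L), head_n(events$seq_i2, 7L)),
    i2_3ss = paste0(tail_n(events$seq_i2, 16L), head_n(events$seq_c2, 5L))
  )
}

# log-likelihood of each sequence under a PWM (sum of per-position log probs)
score_pwm <- function(seqs, pwm) {
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  if (ncol(chars) != ncol(pwm$mat)) abort("sequence width does not match the PWM window")
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) abort("splice-site windows must contain only A/C/G/T")
  lp <- matrix(log(pwm$mat[cbind(idx, rep(seq_len(ncol(chars)), each = nrow(chars)))]),
               nrow = nrow(chars))
  rowSums(lp)
}

#' Splice-site strength features
#'
#' Log-probability of each of the four splice-site windows (I1-5'ss, I1-3'ss,
#' I2-5'ss, I2-3'ss) under the matching PWM.
#'
#' @param events Events tibble.
#' @param pwms List with `ss5` and `ss3` [build_pwm()] objects.
#' @return Numeric matrix, one row per event, 4 named columns.
#' @export
splice_site_strength <- function(events, pwms) {
  w <- splice_site_windows(events)
  m <- cbind(
    ss_i1_5ss = score_pwm(w$i1_5ss, pwms$ss5),
    ss_i1_3ss = score_pwm(w$i1_3ss, pwms$ss3),
    ss_i2_5ss = score_pwm(w$i2_5ss, pwms$ss5),
    ss_i2_3ss = score_pwm(w$i2_3ss, pwms$ss3)
  )
  rownames(m) <- events$event_id
  m
}

# genomic intervals of the 7 conservation regions (strand-aware windows)
conservation_regions <- function(ev, window = SS_WINDOW) {
  w1 <- min(window, ev$i1_end - ev$i1_start + 1L)
  w2 <- min(window, ev$i2_end - ev$i2_start + 1L)
  fwd <- ev$strand == "+"
  list(
    c1 = c(ev$c1_start, ev$c1_end),
    i1_5ss = if (fwd) c(ev$i1_start, ev$i1_start + w1 - 1L) else c(ev$i1_end - w1 + 1L, ev$i1_end),
    i1_3ss = if (fwd) c(ev$i1_end - w1 + 1L, ev$i1_end) else c(ev$i1_start, ev$i1_start + w1 - 1L),
    alt = c(ev$alt_start, ev$alt_end),
    i2_5ss = if (fwd) c(ev$i2_start, ev$i2_start + w2 - 1L) else c(ev$i2_end - w2 + 1L, ev$i2_end),
    i2_3ss = if (fwd) c(ev$i2_end - w2 + 1L, ev$i2_end) else c(ev$i2_start, ev$i2_start + w2 - 1L),
    c2 = c(ev$c2_start, ev$c2_end)
  )
}

# mean score over covered bases in [start, end]; NA when nothing is covered
cons_mean <- function(scores, chrom, start, end) {
  if (is.null(scores)) return(NA_real_)
  v <- if (is.list(scores)) {
    x <- scores[[chrom]]
    if (is.null(x)) return(NA_real_)
    idx <- start:end
    ifelse(idx >= 1L & idx <= length(x), x[pmax(pmin(idx, length(x)), 1L)], NA_real_)
  } else if (methods::is(scores, "RleList")) {
    if (!chrom %in% names(scores)) return(NA_real_)
    x <- scores[[chrom]]
    end2 <- min(end, length(x))
    if (start > end2) return(NA_real_)
    as.numeric(IRanges::Views(x, start, end2)[[1]])
  } else {
    abort("`scores` must be NULL, a named list of per-base numeric vectors, or an RleList")
  }
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Mean conservation score over the seven event regions
#'
#' Bases without a score are excluded from each region's mean; a region with
#' no scored base at all yields `NA` (imputed later by [event_features()]).
#'
#' @param events Events tibble.
#' @param scores Per-base conservation source: a named list of numeric vectors
#'   (one per chromosome, `NA` where no score exists), an `RleList` such as
#'   returned by `rtracklayer::import(..., as = "RleList")` on a bigWig file,
#'   or `NULL` for no source.
#' @param window Intronic window size in nt (default 300).
#' @return Numeric matrix, one row per event, 7 named columns (`cons_c1`,
#'   `cons_i1_5ss`, `cons_i1_3ss`, `cons_alt`, `cons_i2_5ss`, `cons_i2_3ss`,
#'   `cons_c2`).
#' @export
conservation_features <- function(events, scores = NULL, window = SS_WINDOW) {
  out <- matrix(NA_real_, nrow = nrow(events), ncol = 7L,
                dimnames = list(events$event_id,
                                paste0("cons_", c("c1", "i1_5ss", "i1_3ss", "alt",
                                                  "i2_5ss", "i2_3ss", "c2"))))
  if (is.null(scores)) return(out)
  for (i in seq_len(nrow(events))) {
    regs <- conservation_regions(events[i, ], window)
    out[i, ] <- vapply(regs, function(r) {
      cons_mean(scores, events$chrom[i], r[1], r[2])
    }, numeric(1))
  }
  out
}

# all k-mers of width k in lexicographic (A < C < G < T) order
all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k))[seq_len(k)]))
}

# overlapping-occurrence frequencies of 1..max_k-mers for one set of sequences
kmer_block <- function(seqs, max_k, prefix) {
  blocks <- lapply(seq_len(max_k), function(k) {
    km <- sort(all_kmers(k))
    cnt <- matrix(0, nrow = length(seqs), ncol = length(km),
                  dimnames = list(NULL, km))
    long <- nchar(seqs) >= k
    if (any(long)) {
      f <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(seqs[long]), width = k)
      cnt[long, colnames(f)] <- f
    }
    denom <- pmax(nchar(seqs) - k + 1L, 1L)
    out <- cnt / denom
    out[!long, ] <- 0
    colnames(out) <- paste0(prefix, "_", km)
    out
  })
  do.call(cbind, blocks)
}

#' k-mer frequency features
#'
#' Overlapping-occurrence frequencies (count / number of possible positions)
#' of short sequences in the seven regions: 1-3-mers for C1, I1-3ss, I2-5ss
#' and C2 (84 each), 1-2-mers for I1-5ss and I2-3ss (20 each), and 1-4-mers
#' for the alternative exon (340); 716 features in total. k-mers within each
#' block follow lexicographic order; a region shorter than k contributes an
#' all-zero k-block.
#'
#' @inheritParams conservation_features
#' @return Numeric matrix, one row per event, 716 named columns.
#' @export
kmer_features <- function(events, window = SS_WINDOW) {
  head_n <- function(s, n) substr(s, 1L, pmin(n, nchar(s)))
  tail_n <- function(s, n) substr(s, pmax(nchar(s) - n + 1L, 1L), nchar(s))
  regions <- list(
    c1 = list(seq = events$seq_c1, k = 3L),
    i1_5ss = list(seq = head_n(events$seq_i1, window), k = 2L),
    i1_3ss = list(seq = tail_n(events$seq_i1, window), k = 3L),
    alt = list(seq = events$seq_alt, k = 4L),
    i2_5ss = list(seq = head_n(events$seq_i2, window), k = 3L),
    i2_3ss = list(seq = tail_n(events$seq_i2, window), k = 2L),
    c2 = list(seq = events$seq_c2, k = 3L)
  )
  m <- do.call(cbind, lapply(names(regions), function(rn) {
    kmer_block(regions[[rn]]$seq, regions[[rn]]$k, paste0("kmer_", rn))
  }))
  rownames(m) <- events$event_id
  m
}

#' Assemble the full 735-dimensional feature vector per event
#'
#' Concatenates, in fixed order, the 8 length features, 4 splice-site
#' strengths, 7 conservation means and 716 k-mer frequencies. Missing
#' conservation values are imputed with the across-event mean of the feature;
#' with no conservation source at all they are set to 0 (the post-
#' standardisation mean).
#'
#' @param events Events tibble.
#' @param pwms Splice-site PWMs from [train_splice_pwms()] or [build_pwm()];
#'   `NULL` uses uniform PWMs (constant strength features).
#' @param scores Conservation source, see [conservation_features()].
#' @param standardize Apply [standardize_features()] before returning.
#' @param window Intronic window size in nt.
#' @return A tibble: `event_id` plus 735 numeric feature columns.
#' @export
event_features <- function(events, pwms = NULL, scores = NULL,
                           standardize = FALSE, window = SS_WINDOW) {
  if (is.null(pwms)) pwms <- list(ss5 = uniform_pwm("5ss"), ss3 = uniform_pwm("3ss"))
  cons <- conservation_features(events, scores, window)
  for (j in seq_len(ncol(cons))) {
    nas <- is.na(cons[, j])
    cons[nas, j] <- if (all(nas)) 0 else mean(cons[, j], na.rm = TRUE)
  }
  m <- cbind(length_features(events), splice_site_strength(events, pwms),
             cons, kmer_features(events, window))
  stopifnot(ncol(m) == 735L)
  out <- dplyr::bind_cols(tibble(event_id = events$event_id), as_tibble(m))
  if (standardize) out <- standardize_features(out) else out
}

#' Z-score feature columns across events
#'
#' Centers and scales each numeric column to zero mean and unit variance
#' (population variance); constant columns become 0.
#'
#' @param features Tibble from [event_features()] (an `event_id` column plus
#'   numeric features), or a numeric matrix.
#' @return Same shape as the input.
#' @export
standardize_features <- function(features) {
  scale_col <- function(x) {
    s <- pop_sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  if (is.matrix(features)) {
    return(apply(features, 2L, scale_col))
  }
  dplyr::mutate(features, dplyr::across(dplyr::where(is.numeric), scale_col))
}

#' Feature tibble to numeric matrix
#'
#' @param features Tibble with an `event_id` column and numeric feature
#'   columns (or already a matrix, returned unchanged).
#' @return Numeric matrix with event ids as rownames.
#' @export
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  ids <- features$event_id
  m <- as.matrix(dplyr::select(features, dplyr::where(is.numeric)))
  rownames(m) <- ids
  m
}
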