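#' @name likelihood
#' @title Mixture-of-isoforms read likelihood
#'
#' @description
#' Reads overlapping an exon-skipping event are classified against the two
#' isoforms (inclusion = C1+A+C2, exclusion = C1+C2) under a uniform
#' fragment-start model: a read compatible with isoform I contributes
#' `P(R | I) = 1 / effective_length(I)`, zero otherwise, where the effective
#' length is the number of valid fragment start positions. The likelihood of
#' the inclusion ratio psi is the product over reads of
#' `P(R|inc) w + P(R|exc) (1 - w)` with the length-adjusted mixing weight
#' `w = psi l_inc / (psi l_inc + (1 - psi) l_exc)`.
NULL

# genomic exon intervals of the two isoforms, sorted by genomic start
isoform_exons <- function(event, isoform = c("inclusion", "exclusion")) {
  isoform <- match.arg(isoform)
  ex <- rbind(c(event$c1_start, event$c1_end),
              c(event$alt_start, event$alt_end),
              c(event$c2_start, event$c2_end))
  if (isoform == "exclusion") ex <- ex[-2L, , drop = FALSE]
  ex[order(ex[, 1]), , drop = FALSE]
}

isoform_length <- function(event, isoform) {
  ex <- isoform_exons(event, isoform)
  sum(ex[, 2] - ex[, 1] + 1L)
}

#' Effective isoform lengths of an event
#'
#' Number of valid fragment start positions on each isoform for a fragment of
#' `span` nt (the read length for single-end data, the fragment length for
#' paired-end data).
#'
#' @param event One-row events tibble.
#' @param span Fragment span in nt.
#' @return Named numeric vector `c(inc = , exc = )`.
#' @export
effective_lengths <- function(event, span) {
  l_inc <- isoform_length(event, "inclusion") - span + 1L
  l_exc <- isoform_length(event, "exclusion") - span + 1L
  if (l_exc < 1L) {
    abort(sprintf("event %s: fragment span %d exceeds the exclusion isoform",
                  event$event_id, span))
  }
  c(inc = l_inc, exc = l_exc)
}

# TRUE when the blocks (genomic [start,end] rows, sorted) describe a
# contiguous path through `exons` (a sorted genomic exon matrix)
blocks_compatible <- function(blocks, exons) {
  offs <- cumsum(c(0L, exons[, 2] - exons[, 1] + 1L))[seq_len(nrow(exons))]
  to_tx <- function(pos) {
    i <- which(exons[, 1] <= pos & pos <= exons[, 2])
    if (!length(i)) return(NA_integer_)
    offs[i[1]] + (pos - exons[i[1], 1]) + 1L
  }
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  prev_end <- NA_integer_
  for (b in seq_len(nrow(blocks))) {
    ts <- to_tx(blocks[b, 1]); te <- to_tx(blocks[b, 2])
    if (is.na(ts) || is.na(te)) return(FALSE)
    # a block whose transcript span differs from its genomic span crosses an
    # intron without a junction gap
    if (te - ts != blocks[b, 2] - blocks[b, 1]) return(FALSE)
    # gaps between consecutive blocks must land exactly on exon junctions
    if (!is.na(prev_end) && ts != prev_end + 1L) return(FALSE)
    prev_end <- te
  }
  TRUE
}

#' Classify reads against the two isoforms of an event
#'
#' Each read (or read pair, when a `mate` column is present) is tested for
#' compatibility with the inclusion and exclusion isoform: all aligned blocks
#' must fall inside isoform exons and junction gaps must match the isoform's
#' exon boundaries. Reads wholly inside C1 or C2 are compatible with both
#' (`ambiguous`); reads touching A or its junctions are `inclusion`-only;
#' reads spanning the C1-C2 junction are `exclusion`-only; reads consistent
#' with neither isoform (e.g. extending into an intron) are `incompatible` and
#' excluded from the evidence.
#'
#' @param alignments Tibble with one row per aligned block: `read_id`,
#'   `chrom`, `start`, `end` (1-based closed), optionally `mate` (1/2) for
#'   paired-end data.
#' @param event One-row events tibble.
#' @param span Fragment span used for effective lengths; defaults to the most
#'   common total aligned width per read.
#' @return Tibble with one row per read: `read_id`, `class`, `p_inc`, `p_exc`
#'   (compatibility probabilities, `1/effective length` or 0).
#' @export
classify_reads <- function(alignments, event, span = NULL) {
  if (!nrow(alignments)) {
    return(tibble(read_id = character(), class = character(),
                  p_inc = numeric(), p_exc = numeric()))
  }
  wrong_chrom <- alignments$chrom != event$chrom
  if (any(wrong_chrom)) {
    warn(sprintf("%d block(s) on a different chromosome than event %s; dropped",
                 sum(wrong_chrom), event$event_id))
    alignments <- alignments[!wrong_chrom, , drop = FALSE]
  }
  if (is.null(span)) {
    widths <- tapply(alignments$end - alignments$start + 1L, alignments$read_id, sum)
    span <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
  }
  el <- effective_lengths(event, span)
  ex_inc <- isoform_exons(event, "inclusion")
  ex_exc <- isoform_exons(event, "exclusion")

  per_read <- split(alignments, alignments$read_id)
  res <- purrr::map_dfr(per_read, function(r) {
    mates <- if ("mate" %in% names(r)) split(r, r$mate) else list(r)
    comp <- function(exons) {
      all(vapply(mates, function(m) {
        blocks_compatible(cbind(m$start, m$end), exons)
      }, logical(1)))
    }
    ok_inc <- comp(ex_inc); ok_exc <- comp(ex_exc)
    cls <- if (ok_inc && ok_exc) "ambiguous" else if (ok_inc) "inclusion"
      else if (ok_exc) "exclusion" else "incompatible"
    tibble(read_id = r$read_id[1], class = cls,
           p_inc = if (ok_inc) 1 / el[["inc"]] else 0,
           p_exc = if (ok_exc) 1 / el[["exc"]] else 0)
  })
  res
}

#' Construct per-event read evidence
#'
#' The count-level summary the likelihood needs: reads by compatibility class
#' and the two effective lengths.
#'
#' @param event_id Character vector of event ids.
#' @param n_inc,n_exc,n_amb Read counts by class (inclusion-only,
#'   exclusion-only, ambiguous).
#' @param len_inc,len_exc Effective isoform lengths (inclusion must exceed
#'   exclusion, which must be >= 1).
#' @param cell_id Optional cell identifier.
#' @return Evidence tibble, one row per event (x cell).
#' @export
read_evidence <- function(event_id, n_inc, n_exc, n_amb, len_inc, len_exc,
                          cell_id = NULL) {
  if (any(len_exc < 1) || any(len_inc <= len_exc)) {
    abort("effective lengths must satisfy len_inc > len_exc >= 1")
  }
  if (any(c(n_inc, n_exc, n_amb) < 0)) abort("read counts must be non-negative")
  ev <- tibble(event_id = event_id, n_inc = as.integer(n_inc),
               n_exc = as.integer(n_exc), n_amb = as.integer(n_amb),
               len_inc = as.numeric(len_inc), len_exc = as.numeric(len_exc))
  if (!is.null(cell_id)) ev <- dplyr::mutate(ev, cell_id = cell_id, .after = 1)
  ev
}

#' Summarise classified reads into evidence
#'
#' @inheritParams classify_reads
#' @return One-row evidence tibble (see [read_evidence()]), with an attribute
#'   `n_discarded` counting reads compatible with neither isoform.
#' @export
evidence_from_alignments <- function(alignments, event, span = NULL) {
  cls <- classify_reads(alignments, event, span)
  if (is.null(span)) {
    if (nrow(alignments)) {
      widths <- tapply(alignments$end - alignments$start + 1L,
                       alignments$read_id, sum)
      span <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    } else {
      span <- 1L
    }
  }
  el <- effective_lengths(event, span)
  out <- read_evidence(event$event_id,
                       n_inc = sum(cls$class == "inclusion"),
                       n_exc = sum(cls$class == "exclusion"),
                       n_amb = sum(cls$class == "ambiguous"),
                       len_inc = el[["inc"]], len_exc = el[["exc"]])
  attr(out, "n_discarded") <- sum(cls$class == "incompatible")
  out
}

#' Read alignments overlapping a region from SAM/BAM
#'
#' Thin wrapper over [GenomicAlignments::readGAlignments()] keeping mapped,
#' primary, non-duplicate alignments above a mapping-quality threshold, and
#' flattening aligned blocks into the tibble layout used by
#' [classify_reads()].
#'
#' @param path SAM or BAM path (SAM files are converted in memory).
#' @param region Optional `GRanges` restricting the query (BAM only, requires
#'   an index).
#' @param min_mapq Minimum mapping quality (default 10).
#' @return Alignment-block tibble: `read_id`, `chrom`, `start`, `end`.
#' @export
read_alignments <- function(path, region = NULL, min_mapq = 10L) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, mapqFilter = min_mapq,
    which = if (is.null(region)) IRanges::IRangesList() else region)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
    path <- bam
  }
  if (is.null(region)) param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
  ga <- GenomicAlignments::readGAlignments(path, param = param, use.names = TRUE)
  bl <- GenomicAlignments::grglist(ga)
  ul <- unlist(bl, use.names = FALSE)
  tibble(
    read_id = rep(names(bl), S4Vectors::elementNROWS(bl)),
    chrom = as.character(GenomicRanges::seqnames(ul)),
    start = GenomicRanges::start(ul),
    end = GenomicRanges::end(ul)
  )
}

# mixing weight: probability that a read comes from the inclusion isoform
mixing_weight <- function(psi, len_inc, len_exc) {
  psi * len_inc / (psi * len_inc + (1 - psi) * len_exc)
}

# count * log(value), with 0 * log(anything) == 0
nlog <- function(n, v) ifelse(n > 0, n * log(v), 0)

# vectorised over units: log-likelihood at logit-psi y (used by the sampler)
loglik_units <- function(y, n_inc, n_exc, n_amb, len_inc, len_exc) {
  psi <- logistic(y)
  w <- mixing_weight(psi, len_inc, len_exc)
  nlog(n_inc, w / len_inc) + nlog(n_exc, (1 - w) / len_exc) +
    nlog(n_amb, w / len_inc + (1 - w) / len_exc)
}

#' Log-likelihood of the inclusion ratio
#'
#' @param evidence One-row evidence tibble ([read_evidence()]).
#' @param psi Inclusion ratio(s), strictly inside (0, 1); vectorised.
#' @return Numeric vector of log-likelihood values.
#' @export
psi_loglik <- function(evidence, psi) {
  check_prob_open(psi)
  if (nrow(evidence) != 1L) abort("`evidence` must have exactly one row")
  loglik_units(logit(psi), evidence$n_inc, evidence$n_exc, evidence$n_amb,
               evidence$len_inc, evidence$len_exc)
}
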