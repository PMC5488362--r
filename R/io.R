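#' Write simulated alignments as SAM
#'
#' Emits a sorted, headered single-end SAM file; each aligned block run
#' becomes an M operation and each junction gap an N operation. Paired-end
#' simulations are written as two records per fragment with `/1` and `/2`
#' read-name suffixes.
#'
#' @param alignments Alignment-block tibble ([simulate_reads()] layout).
#' @param chrom_lengths Named integer vector of reference lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, as.integer(chrom_lengths[[ch]])), con)
  }
  if (!nrow(alignments)) return(invisible(path))
  key <- if ("mate" %in% names(alignments)) {
    paste0(alignments$read_id, "/", alignments$mate)
  } else {
    alignments$read_id
  }
  recs <- purrr::map_dfr(split(alignments, key), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    cig <- character()
    for (b in seq_len(nrow(r))) {
      if (b > 1L) cig <- c(cig, sprintf("%dN", r$start[b] - r$end[b - 1L] - 1L))
      cig <- c(cig, sprintf("%dM", r$end[b] - r$start[b] + 1L))
    }
    qname <- if ("mate" %in% names(r)) paste0(r$read_id[1], "/", r$mate[1]) else r$read_id[1]
    tibble(qname = qname, chrom = r$chrom[1], pos = r$start[1],
           cigar = paste(cig, collapse = ""))
  })
  recs <- recs[order(recs$chrom, recs$pos), , drop = FALSE]
  writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                     recs$qname, recs$chrom, recs$pos, recs$cigar), con)
  invisible(path)
}

# TSV writers carry a small metadata header of "#key=value" lines
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta$package_version <- as.character(utils::packageVersion("psiprior"))
  for (k in names(meta)) writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  x <- utils::read.delim(text = lines[setdiff(seq_along(lines), meta_lines)],
                         sep = "\t", stringsAsFactors = FALSE)
  attr(x, "metadata") <- meta
  as_tibble(x)
}

#' Write / read an evidence table
#'
#' @param evidence Evidence tibble.
#' @param path TSV path.
#' @param meta Named list of metadata strings written as `#key=value` header
#'   lines (e.g. the seed).
#' @return `path` (writer) / evidence tibble with a `metadata` attribute
#'   (reader).
#' @export
write_evidence_tsv <- function(evidence, path, meta = list()) {
  write_tsv_meta(evidence, path, meta)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  x <- read_tsv_meta(path)
  need <- c("event_id", "n_inc", "n_exc", "n_amb", "len_inc", "len_exc")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("evidence file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x
}

#' Write / read a learned prior
#'
#' Serialises the regression weights and residual scale so a prior trained on
#' one data set (e.g. bulk) can be fixed and reused on another.
#'
#' @param state A [prior_state()].
#' @param path TSV path.
#' @return `path` (writer) / a `prior_state` (reader).
#' @export
write_prior_tsv <- function(state, path) {
  write_tsv_meta(tibble(index = seq_along(state$W), weight = state$W), path,
                 meta = list(sigma = state$sigma, lambda = state$lambda))
}

#' @rdname write_prior_tsv
#' @export
read_prior_tsv <- function(path) {
  x <- read_tsv_meta(path)
  meta <- attr(x, "metadata")
  prior_state(x$weight, as.numeric(meta$sigma), as.numeric(meta$lambda))
}

#' Write a fit summary as TSV
#'
#' @param fit A `psi_fit`.
#' @param path TSV path.
#' @param meta Extra metadata entries.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path, meta = list()) {
  meta$sigma <- fit$sigma
  meta$lambda <- fit$lambda
  if (!is.null(fit$config$seed)) meta$seed <- fit$config$seed
  write_tsv_meta(fit$summary, path, meta)
}
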