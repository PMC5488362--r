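#' Read exon records from a GTF/GFF3 annotation
#'
#' Imports an annotation with [rtracklayer::import()] and returns the exon
#' features as a tibble with one row per exon, the minimal hierarchy needed for
#' exon-skipping event extraction.
#'
#' @param path Path to a GTF or GFF3 file (plain or gzipped).
#' @param protein_coding_only Keep only exons whose gene is annotated as
#'   protein coding (when the annotation carries a `gene_type`/`gene_biotype`
#'   attribute). Default `TRUE`.
#'
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` (1-based closed coordinates, as in the GTF itself).
#' @export
read_gtf_exons <- function(path, protein_coding_only = TRUE) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  biotype <- md$gene_type %||% md$gene_biotype
  if (protein_coding_only && !is.null(biotype)) {
    gr <- gr[biotype == "protein_coding"]
    md <- S4Vectors::mcols(gr)
  }
  if (is.null(md$gene_id) || is.null(md$transcript_id)) {
    abort("annotation exons must carry gene_id and transcript_id attributes")
  }
  tibble(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Resolve a genome argument to a named DNAStringSet.
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("`genome` must be a named DNAStringSet, a named character vector, or a FASTA path")
}

# Fetch a sub-sequence on the transcribed strand (1-based closed coordinates).
genome_seq <- function(genome, chrom, start, end, strand) {
  s <- as.character(Biostrings::subseq(genome[[chrom]], start = start, end = end))
  if (strand == "-") s <- reverse_complement(s) else s
}

#' Enumerate exon-skipping events from an exon annotation
#'
#' An exon-skipping event is a triplet of exons (C1, A, C2) such that some
#' transcript of the gene contains C1, A, C2 as consecutive exons (inclusion
#' isoform) and another transcript of the same gene contains C1 and C2 as
#' consecutive exons with identical boundaries (exclusion isoform). C1 denotes
#' the upstream constitutive exon in *transcription* order, so on the minus
#' strand C1 is the rightmost exon in genomic coordinates. Region sequences are
#' reported on the transcribed strand.
#'
#' @param exons Tibble of exons as returned by [read_gtf_exons()]: columns
#'   `gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`.
#' @param genome Named `DNAStringSet`, named character vector of chromosome
#'   sequences, or a FASTA path.
#'
#' @return A tibble of events, ordered by (chrom, start), one row per distinct
#'   (gene, C1, A, C2) triplet, with genomic intervals for the five regions
#'   (`c1_*`, `i1_*`, `alt_*`, `i2_*`, `c2_*`; all 1-based closed, start <=
#'   end), `tss_distance`/`tts_distance` in genomic bp from the boundary of A
#'   to the nearest start/end among transcripts containing the event, and the
#'   five region sequences `seq_c1`, `seq_i1`, `seq_alt`, `seq_i2`, `seq_c2` on
#'   the transcribed strand. Genes whose chromosome is missing from the genome
#'   are skipped; they are recorded in the `errors` attribute (a tibble of
#'   `gene_id`, `reason`) and reported with a warning.
#' @export
extract_skipping_events <- function(exons, genome) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols)) {
    abort(paste0("`exons` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  genome <- load_genome(genome)

  errors <- list()
  rows <- list()
  for (g in split(as_tibble(exons), exons$gene_id)) {
    gene_id <- g$gene_id[[1]]
    chrom <- g$chrom[[1]]
    strand <- g$strand[[1]]
    if (!chrom %in% names(genome)) {
      errors[[length(errors) + 1L]] <-
        tibble(gene_id = gene_id, reason = paste0("chromosome not in genome: ", chrom))
      next
    }
    tx <- lapply(split(g, g$transcript_id), function(t) t[order(t$start), , drop = FALSE])
    # transcript spans for TSS/TTS distances
    spans <- lapply(tx, function(t) c(min(t$start), max(t$end)))

    # candidate triplets from inclusion transcripts; skip junctions from all
    trip <- list()
    for (tn in names(tx)) {
      t <- tx[[tn]]
      n <- nrow(t)
      if (n >= 3L) {
        for (i in seq_len(n - 2L)) {
          trip[[length(trip) + 1L]] <- list(
            tx = tn,
            e = c(t$start[i], t$end[i], t$start[i + 1L], t$end[i + 1L],
                  t$start[i + 2L], t$end[i + 2L])
          )
        }
      }
    }
    pairs <- dplyr::bind_rows(lapply(tx, function(t) {
      n <- nrow(t)
      if (n < 2L) return(NULL)
      tibble(tx = t$transcript_id[-n], s1 = t$start[-n], e1 = t$end[-n],
             s2 = t$start[-1L], e2 = t$end[-1L])
    }))
    if (!length(trip) || is.null(pairs) || !nrow(pairs)) next

    seen <- character()
    for (tr in trip) {
      e <- tr$e
      # exclusion isoform: C1-C2 consecutive in a *different* transcript
      hit <- any(pairs$tx != tr$tx & pairs$s1 == e[1] & pairs$e1 == e[2] &
                   pairs$s2 == e[5] & pairs$e2 == e[6])
      if (!hit) next
      key <- paste(e, collapse = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      # introns must be non-empty
      if (e[3] - e[2] < 2L || e[5] - e[4] < 2L) next

      # genomic-order regions; map to transcription order by strand
      left <- c(e[1], e[2]); mid <- c(e[3], e[4]); right <- c(e[5], e[6])
      int1 <- c(e[2] + 1L, e[3] - 1L); int2 <- c(e[4] + 1L, e[5] - 1L)
      if (strand == "-") {
        c1 <- right; i1 <- int2; a <- mid; i2 <- int1; c2 <- left
      } else {
        c1 <- left; i1 <- int1; a <- mid; i2 <- int2; c2 <- right
      }
      # TSS/TTS distance among transcripts containing the full triplet
      incl <- vapply(tx, function(t) {
        any(t$start == e[3] & t$end == e[4]) &&
          any(t$start == e[1] & t$end == e[2]) &&
          any(t$start == e[5] & t$end == e[6])
      }, logical(1))
      sp <- spans[incl]
      if (strand == "-") {
        tss <- min(vapply(sp, function(s) s[2] - a[2], numeric(1)))
        tts <- min(vapply(sp, function(s) a[1] - s[1], numeric(1)))
      } else {
        tss <- min(vapply(sp, function(s) a[1] - s[1], numeric(1)))
        tts <- min(vapply(sp, function(s) s[2] - a[2], numeric(1)))
      }
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        c1_start = c1[1], c1_end = c1[2],
        i1_start = i1[1], i1_end = i1[2],
        alt_start = a[1], alt_end = a[2],
        i2_start = i2[1], i2_end = i2[2],
        c2_start = c2[1], c2_end = c2[2],
        tss_distance = tss, tts_distance = tts,
        seq_c1 = genome_seq(genome, chrom, c1[1], c1[2], strand),
        seq_i1 = genome_seq(genome, chrom, i1[1], i1[2], strand),
        seq_alt = genome_seq(genome, chrom, a[1], a[2], strand),
        seq_i2 = genome_seq(genome, chrom, i2[1], i2[2], strand),
        seq_c2 = genome_seq(genome, chrom, c2[1], c2[2], strand)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_events()
  if (nrow(out)) {
    out <- dplyr::arrange(out, .data$chrom, pmin(.data$c1_start, .data$c2_start))
    base <- paste0(out$gene_id, ".", out$chrom, ":", out$alt_start, "-", out$alt_end)
    out <- dplyr::mutate(out, event_id = make.unique(base, sep = "_"), .before = 1)
  }
  err <- if (length(errors)) dplyr::bind_rows(errors) else NULL
  if (!is.null(err)) {
    warn(paste0(nrow(err), " gene(s) skipped (chromosome absent from genome)"))
    attr(out, "errors") <- err
  }
  out
}

empty_events <- function() {
  tibble(
    event_id = character(), gene_id = character(), chrom = character(),
    strand = character(),
    c1_start = integer(), c1_end = integer(), i1_start = integer(),
    i1_end = integer(), alt_start = integer(), alt_end = integer(),
    i2_start = integer(), i2_end = integer(), c2_start = integer(),
    c2_end = integer(), tss_distance = numeric(), tts_distance = numeric(),
    seq_c1 = character(), seq_i1 = character(), seq_alt = character(),
    seq_i2 = character(), seq_c2 = character()
  )
}

# region lengths, derived from intervals
event_lengths <- function(events) {
  tibble(
    event_id = events$event_id,
    len_c1 = events$c1_end - events$c1_start + 1L,
    len_i1 = events$i1_end - events$i1_start + 1L,
    len_alt = events$alt_end - events$alt_start + 1L,
    len_i2 = events$i2_end - events$i2_start + 1L,
    len_c2 = events$c2_end - events$c2_start + 1L
  )
}

#' Quality-filter configuration for exon-skipping events
#'
#' @param min_intron_len Minimum length of each surrounding intron (bp).
#' @param alt_exon_range Allowed length range of the alternative exon (bp).
#' @param min_end_dist Minimum genomic distance of the alternative exon from
#'   the transcription start and termination sites (bp).
#' @return A list of class `event_filter_config`.
#' @export
event_filter_config <- function(min_intron_len = 100L,
                                alt_exon_range = c(50L, 450L),
                                min_end_dist = 500L) {
  structure(list(min_intron_len = min_intron_len,
                 alt_exon_range = alt_exon_range,
                 min_end_dist = min_end_dist),
            class = "event_filter_config")
}

#' Apply the six quality filters to exon-skipping events
#'
#' The six rules: (1) event lies on a primary chromosome (1-22 and X for
#' human; 1-19 and X for mouse); (2) the alternative exon is not overlapped by
#' the alternative exon of any other event (either strand; events of the same
#' gene with an identical A interval, i.e. alternative flank choices for the
#' same skipped exon, do not count as overlap); (3) both surrounding introns
#' are at least `min_intron_len` bp; (4) the alternative exon length falls in
#' `alt_exon_range`; (5) the alternative exon lies at least `min_end_dist` bp
#' from the transcription start and termination sites; (6) the event is
#' surrounded by the canonical splice dinucleotides, AG immediately upstream
#' and GT immediately downstream of the alternative exon on the transcribed
#' strand (acceptor AG ending intron 1, donor GT opening intron 2).
#'
#' Filtering classifies, it never fails: the report names the violated rules
#' per event. Applying the filter to an already-filtered set is a no-op.
#'
#' @param events Events tibble from [extract_skipping_events()].
#' @param species `"human"` or `"mouse"` (controls the chromosome whitelist).
#' @param config An [event_filter_config()].
#'
#' @return A list with `events` (the rows passing all six rules) and `report`,
#'   a tibble with `event_id`, `passed`, and `failed_rules` (comma-separated
#'   identifiers from `chrom`, `overlap`, `intron_len`, `alt_exon_len`,
#'   `tss_tts_dist`, `splice_dinucleotide`; empty string when passed).
#' @export
filter_skipping_events <- function(events, species = c("human", "mouse"),
                                   config = event_filter_config()) {
  species <- match.arg(species)
  if (!nrow(events)) {
    return(list(events = events,
                report = tibble(event_id = character(), passed = logical(),
                                failed_rules = character())))
  }
  chroms_ok <- c(as.character(seq_len(if (species == "human") 22L else 19L)), "X")
  ln <- event_lengths(events)

  ok_chrom <- sub("^chr", "", events$chrom) %in% chroms_ok
  # rule 2: A intersects the A of any other event (exempting same-gene
  # events that share the identical A interval)
  n <- nrow(events)
  ok_overlap <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same_chrom <- events$chrom == events$chrom[i]
    inter <- same_chrom &
      events$alt_start <= events$alt_end[i] &
      events$alt_end >= events$alt_start[i]
    same_exon <- events$gene_id == events$gene_id[i] &
      events$alt_start == events$alt_start[i] &
      events$alt_end == events$alt_end[i]
    inter[i] <- FALSE
    ok_overlap[i] <- !any(inter & !same_exon)
  }
  ok_intron <- ln$len_i1 >= config$min_intron_len & ln$len_i2 >= config$min_intron_len
  ok_alt <- ln$len_alt >= config$alt_exon_range[1] & ln$len_alt <= config$alt_exon_range[2]
  ok_dist <- events$tss_distance >= config$min_end_dist &
    events$tts_distance >= config$min_end_dist
  up2 <- substr(events$seq_i1, nchar(events$seq_i1) - 1L, nchar(events$seq_i1))
  down2 <- substr(events$seq_i2, 1L, 2L)
  ok_dinuc <- up2 == "AG" & down2 == "GT"

  fails <- cbind(chrom = !ok_chrom, overlap = !ok_overlap, intron_len = !ok_intron,
                 alt_exon_len = !ok_alt, tss_tts_dist = !ok_dist,
                 splice_dinucleotide = !ok_dinuc)
  failed_rules <- apply(fails, 1L, function(f) paste(colnames(fails)[f], collapse = ","))
  passed <- !apply(fails, 1L, any)
  list(
    events = events[passed, , drop = FALSE],
    report = tibble(event_id = events$event_id, passed = passed,
                    failed_rules = failed_rules)
  )
}

#' Write events as GFF3 with inclusion and exclusion transcripts
#'
#' Each event becomes a gene feature with two mRNA children: the inclusion
#' isoform (C1, A, C2) and the exclusion isoform (C1, C2).
#'
#' @param events Events tibble.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_events_gff3 <- function(events, path) {
  grs <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    span <- c(min(ev$c1_start, ev$c2_start), max(ev$c1_end, ev$c2_end))
    gid <- ev$event_id
    mk <- function(start, end, type, id, parent = NA_character_) {
      GenomicRanges::GRanges(
        ev$chrom, IRanges::IRanges(start, end), strand = ev$strand,
        type = type, ID = id, Parent = parent
      )
    }
    ex_in <- rbind(c(ev$c1_start, ev$c1_end), c(ev$alt_start, ev$alt_end),
                   c(ev$c2_start, ev$c2_end))
    ex_ex <- rbind(c(ev$c1_start, ev$c1_end), c(ev$c2_start, ev$c2_end))
    grs[[length(grs) + 1L]] <- c(
      mk(span[1], span[2], "gene", gid),
      mk(span[1], span[2], "mRNA", paste0(gid, ".in"), gid),
      mk(span[1], span[2], "mRNA", paste0(gid, ".out"), gid),
      mk(ex_in[, 1], ex_in[, 2], "exon",
         paste0(gid, ".in.e", seq_len(3)), paste0(gid, ".in")),
      mk(ex_ex[, 1], ex_ex[, 2], "exon",
         paste0(gid, ".out.e", seq_len(2)), paste0(gid, ".out"))
    )
  }
  gr <- do.call(c, grs)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
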