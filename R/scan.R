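#' Read a FASTA file into a genome tibble
#'
#' Residues are normalized to the uppercase U-alphabet (T accepted on input);
#' record order is preserved; wrapped records are supported. Characters
#' outside \{A,C,G,T,U,N\} raise a format error.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `contig`, `residues`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf(
                    "malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) abort(sprintf("FASTA '%s' contains no records", path))
  ids <- sub("\\s.*$", "", names(set))
  res <- normalize_residues(as.character(set))
  tibble(contig = ids, residues = unname(res),
         length = unname(nchar(res)))
}

#' Write a genome tibble as FASTA
#'
#' @param genome tibble with `contig` and `residues` columns.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genome))) {
    writeLines(paste0(">", genome$contig[i]), con)
    s <- genome$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# map hits found on the reverse complement back to forward coordinates
flip_hits <- function(hits, contig_length) {
  if (nrow(hits) == 0L) return(hits)
  s <- hits$start
  hits$start <- contig_length - hits$end
  hits$end <- contig_length - s
  hits$strand <- "-"
  hits
}

# Overlap resolution: identical (contig, start, end, strand) duplicates are
# collapsed, then each cluster of mutually overlapping co-stranded hits is
# reduced to its best folding: most total base pairs, ties broken by leftmost
# start then shortest span. Output order is (contig, start, strand).
select_best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- dplyr::arrange(hits, .data$contig, .data$strand, .data$start,
                         .data$end)
  hits <- dplyr::group_by(hits, .data$contig, .data$strand)
  hits <- dplyr::mutate(
    hits,
    cluster = cumsum(.data$start >=
                       dplyr::lag(cummax(.data$end), default = -1L)))
  hits <- dplyr::group_by(hits, .data$contig, .data$strand, .data$cluster)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$total_bp), .data$start,
                         .data$end - .data$start, .by_group = TRUE)
  hits <- dplyr::slice_head(hits, n = 1L)
  hits <- dplyr::ungroup(hits)
  hits$cluster <- NULL
  dplyr::arrange(hits, .data$contig, .data$start, .data$strand)
}

# enumerate matches on one strand of one normalized sequence
scan_one_strand <- function(seq, d, elems, contig) {
  chars <- seq_chars(seq)
  n <- length(chars)
  cumN <- c(0L, cumsum(chars == "N"))
  if (d$max_core_mismatches == 0L) {
    # anchor on box1: any match must place box1 at an exact occurrence
    pat <- chartr("U", "U", d$box1)
    rx <- gsub("H", "[ACU]", gsub("N", "[ACGU]", pat, fixed = TRUE),
               fixed = TRUE)
    m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
    anchors <- if (m[1] == -1L) integer(0) else as.integer(m)
    idx_box1 <- which(vapply(elems, function(e) identical(e$id, "box1"),
                             logical(1)))
    pre <- if (idx_box1 > 1L) {
      elements_span_range(elems[seq_len(idx_box1 - 1L)])
    } else c(0L, 0L)
    starts <- unique(unlist(lapply(anchors, function(p) {
      lo <- max(1L, p - pre[2]); hi <- p - pre[1]
      if (hi < lo) integer(0) else lo:hi
    })))
    starts <- sort(starts)
  } else {
    starts <- seq_len(n)
  }
  codes <- match(chars, c("A", "C", "G", "U"))
  pm <- pairing_lookup(d$allow_gu_wobble)
  raw <- list()
  for (s in starts) {
    raw <- c(raw, enumerate_hits_at(chars, cumN, s, elems, d, codes, pm))
  }
  raw_hits_to_tibble(raw, chars, elems, d, contig = contig)
}

#' Scan a genome for HHR motifs on both strands
#'
#' Runs the descriptor grammar over every admissible window of every contig,
#' forward and reverse complement. Reverse-strand hits are reported in
#' forward coordinates with strand "-". Identical-span duplicates are
#' removed, overlapping alternative foldings are resolved to the
#' most-base-paired one, and the result is sorted by (contig, start, strand),
#' so output is a pure function of input.
#'
#' @param genome a genome tibble from [read_fasta()] (or a named character
#'   vector of sequences).
#' @param d an `hhr_descriptor`.
#' @return A tibble of annotated hits; coordinates 0-based half-open.
#' @export
scan_genome <- function(genome, d) {
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("seq", seq_along(genome))
    genome <- tibble(contig = nm, residues = normalize_residues(genome),
                     length = nchar(genome))
  }
  if (nrow(genome) == 0L) return(annotate_hits(empty_hits(), d))
  elems <- build_elements(d)
  out <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    seq <- normalize_residues(genome$residues[i])
    fwd <- scan_one_strand(seq, d, elems, genome$contig[i])
    rev <- flip_hits(scan_one_strand(revcomp(seq), d, elems,
                                     genome$contig[i]), nchar(seq))
    dplyr::bind_rows(fwd, rev)
  })
  out <- select_best_hits(out)
  out <- annotate_hits(out, d)
  if (nrow(out)) {
    out$hit_id <- sprintf("%s:%d-%d(%s)", out$contig, out$start, out$end,
                          out$strand)
  } else {
    out$hit_id <- character(0)
  }
  out
}

#' Reference scanner: exhaustive enumeration at every offset
#'
#' Semantics-defining oracle for [scan_genome()]: enumerates the grammar from
#' every position of both strands with no anchoring shortcuts, then applies
#' the same duplicate/overlap resolution. Guarded to short sequences.
#'
#' @param seq a single nucleotide string (<= 1000 nt).
#' @param d an `hhr_descriptor`.
#' @param contig contig name used in the output (default "seq").
#' @return A tibble of annotated hits, comparable to [scan_genome()] output.
#' @export
brute_force_scan <- function(seq, d, contig = "seq") {
  seq <- normalize_residues(seq)
  if (nchar(seq) > 1000L) {
    abort("brute_force_scan is limited to sequences of <= 1000 nt")
  }
  elems <- build_elements(d)
  one <- function(s) {
    chars <- seq_chars(s)
    cumN <- c(0L, cumsum(chars == "N"))
    codes <- match(chars, c("A", "C", "G", "U"))
    pm <- pairing_lookup(d$allow_gu_wobble)
    raw <- list()
    for (p in seq_along(chars)) {
      raw <- c(raw, enumerate_hits_at(chars, cumN, p, elems, d, codes, pm))
    }
    raw_hits_to_tibble(raw, chars, elems, d, contig = contig)
  }
  fwd <- one(seq)
  rev <- flip_hits(one(revcomp(seq)), nchar(seq))
  out <- select_best_hits(dplyr::bind_rows(fwd, rev))
  out <- annotate_hits(out, d)
  if (nrow(out)) {
    out$hit_id <- sprintf("%s:%d-%d(%s)", out$contig, out$start, out$end,
                          out$strand)
  } else {
    out$hit_id <- character(0)
  }
  out
}

#' Write hits as BED6
#'
#' 0-based half-open coordinates; the score column carries the total
#' base-pair count of the motif.
#'
#' @param hits a hit tibble from [scan_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- tibble(
    chrom = hits$contig, start = hits$start, end = hits$end,
    name = hits$hit_id %||% sprintf("%s:%d-%d(%s)", hits$contig, hits$start,
                                    hits$end, hits$strand),
    score = hits$total_bp, strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write hits as GFF3
#'
#' Emits one `ribozyme` feature per hit (1-based closed coordinates) with
#' `topology`, `variant` and `predicted_mode` attributes.
#'
#' @param hits a hit tibble from [scan_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(hits)) hits$contig else character(0),
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = if (nrow(hits)) hits$strand else character(0)
  )
  gr$type <- rep("ribozyme", nrow(hits))
  gr$ID <- hits$hit_id
  gr$topology <- hits$topology
  gr$variant <- hits$variant
  gr$predicted_mode <- hits$predicted_mode
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
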