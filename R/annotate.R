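# Tandem-repeat locus annotation: grouping HHR hits into arrays, period and
# copy-number estimation, GC and target-site-duplication measurement,
# retrozyme classification and greedy family clustering.

#' Group hits into tandem clusters
#'
#' Consecutive co-oriented hits on one contig whose start-to-start spacing is
#' at most `max_gap` are assigned to the same cluster; singletons are
#' allowed. The default gap is twice the largest metazoan retrozyme monomer
#' considered (2 x 450 nt).
#'
#' @param hits a hit tibble from [scan_genome()].
#' @param max_gap maximum start-to-start spacing within a cluster (nt).
#' @return The hit tibble with a `tandem_id` column added.
#' @export
group_tandem <- function(hits, max_gap = 900L) {
  if (nrow(hits) == 0L) {
    hits$tandem_id <- integer(0)
    return(hits)
  }
  hits <- dplyr::arrange(hits, .data$contig, .data$strand, .data$start)
  hits <- dplyr::group_by(hits, .data$contig, .data$strand)
  hits <- dplyr::mutate(
    hits,
    new_cluster = c(TRUE, diff(.data$start) > max_gap))
  hits <- dplyr::ungroup(hits)
  hits$tandem_id <- cumsum(hits$new_cluster)
  hits$new_cluster <- NULL
  dplyr::arrange(hits, .data$contig, .data$start, .data$strand)
}

#' Estimate the monomer period and copy number of a tandem cluster
#'
#' The period is the median of consecutive start-to-start differences of the
#' cluster's hits; the copy number is the number of hits (one HHR per
#' monomer is assumed). A singleton cluster has no defined period.
#'
#' @param starts hit start coordinates of one cluster.
#' @return A tibble with `monomer_period` (NA for singletons) and
#'   `copy_number`.
#' @export
estimate_period <- function(starts) {
  starts <- sort(as.numeric(starts))
  n <- length(starts)
  if (n < 2L) {
    return(tibble(monomer_period = NA_real_, copy_number = n))
  }
  tibble(monomer_period = stats::median(diff(starts)), copy_number = n)
}

#' Repeat self-identity of a locus at a given period
#'
#' Fraction of positions i in the locus for which residue(i) equals
#' residue(i + period); 1.0 for a perfect tandem array, about 0.25 for
#' unrelated sequence at uniform composition. Used as a QC score guarding
#' against coincidental HHR spacing.
#'
#' @param residues contig sequence (normalized string).
#' @param start,end locus span, 0-based half-open.
#' @param period monomer period (nt).
#' @return Identity fraction in [0, 1]; NA with a warning when the span is
#'   shorter than two periods.
#' @export
validate_repeat <- function(residues, start, end, period) {
  if (is.na(period) || (end - start) < 2 * period) {
    warn("locus span shorter than two periods; repeat identity undefined")
    return(NA_real_)
  }
  ch <- seq_chars(substr(residues, start + 1L, end))
  len <- length(ch)
  i <- seq_len(len - period)
  mean(ch[i] == ch[i + period])
}

#' GC percentage of a locus span
#'
#' @param residues contig sequence.
#' @param start,end span, 0-based half-open.
#' @return GC percentage in [0, 100].
#' @export
locus_gc <- function(residues, start, end) {
  if (end <= start) abort("empty locus span")
  100 * gc_fraction(substr(residues, start + 1L, end))
}

#' Detect a target-site duplication flanking a locus
#'
#' Finds the longest k (min_len <= k <= k_max) for which the k-mer
#' immediately 5' of the locus equals the k-mer immediately 3' of it (the
#' duplicated target site brackets the insertion). Exact matches only.
#'
#' @param residues contig sequence.
#' @param start,end locus span, 0-based half-open.
#' @param k_max longest duplication considered (default 20).
#' @param min_len shortest reportable duplication (default 5: metazoan
#'   retrozyme TSDs are larger than the typical 4 bp of plant elements).
#' @return A tibble with `tsd_length` and `tsd_seq` (0 and "" when absent).
#' @export
detect_tsd <- function(residues, start, end, k_max = 20L, min_len = 5L) {
  n <- nchar(residues)
  if (start < min_len || end + min_len > n) {
    warn("locus at contig edge; TSD detection skipped")
    return(tibble(tsd_length = 0L, tsd_seq = ""))
  }
  k_hi <- min(k_max, start, n - end)
  if (k_hi < min_len) return(tibble(tsd_length = 0L, tsd_seq = ""))
  for (k in seq(k_hi, min_len, by = -1L)) {
    left <- substr(residues, start - k + 1L, start)
    right <- substr(residues, end + 1L, end + k)
    if (left == right) {
      return(tibble(tsd_length = as.integer(k), tsd_seq = left))
    }
  }
  tibble(tsd_length = 0L, tsd_seq = "")
}

#' Classify a locus as retrozyme, isolated HHR or ambiguous
#'
#' A locus is a retrozyme when it is tandem (>= 2 copies), its monomer
#' period falls in the metazoan repeat range and its GC content is below the
#' cutoff. Singleton hits are isolated HHRs; everything else is ambiguous.
#'
#' @param copy_number,monomer_period,gc_percent locus statistics
#'   (vectorized).
#' @param monomer_range admissible monomer period, nt (default 150-450).
#' @param gc_max GC cutoff, percent (default 45).
#' @return Character vector of "retrozyme", "isolated_hhr" or "ambiguous".
#' @export
classify_locus <- function(copy_number, monomer_period, gc_percent,
                           monomer_range = c(150, 450), gc_max = 45) {
  dplyr::case_when(
    copy_number < 2L ~ "isolated_hhr",
    monomer_period >= monomer_range[1] & monomer_period <= monomer_range[2] &
      gc_percent < gc_max ~ "retrozyme",
    TRUE ~ "ambiguous"
  )
}

#' Group monomer lengths into length classes
#'
#' Single-linkage chaining on sorted lengths: members whose neighbouring
#' lengths differ by at most `tolerance` share a class. Distinguishes e.g.
#' the two coral monomer variants separated by a 20-nt indel.
#'
#' @param lengths numeric vector of monomer lengths (nt).
#' @param tolerance maximum within-class neighbour difference (default 5).
#' @return A tibble with `length` (class median) and `count`, sorted
#'   ascending by length.
#' @export
monomer_length_classes <- function(lengths, tolerance = 5) {
  lengths <- as.numeric(lengths[!is.na(lengths)])
  if (length(lengths) == 0L) abort("no monomer lengths supplied")
  s <- sort(lengths)
  cls <- cumsum(c(TRUE, diff(s) > tolerance))
  out <- tibble(length = as.numeric(tapply(s, cls, stats::median)),
                count = as.integer(tapply(s, cls, length)))
  dplyr::arrange(out, .data$length)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment under unit scoring (match +1,
#' mismatch 0, gap -1 per residue); identity is matches over alignment
#' columns.
#'
#' @param a,b nucleotide strings.
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  a <- chartr("U", "T", normalize_residues(a))
  b <- chartr("U", "T", normalize_residues(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global")
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

#' Greedy centroid clustering of sequences into families
#'
#' Iterates sequences in input order; each joins the first existing family
#' whose centroid identity reaches the threshold, otherwise founds a new
#' family with itself as centroid. Deterministic in the input order.
#'
#' @param sequences character vector (optionally named) of monomer
#'   sequences.
#' @param threshold identity threshold in (0, 1) (default 0.8).
#' @return A list with `members` (tibble: member_id, family_id, identity)
#'   and `centroids` (tibble: family_id, centroid_seq).
#' @export
cluster_families <- function(sequences, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  centroids <- character(0)
  fam <- character(0)
  idty <- numeric(0)
  for (i in seq_along(sequences)) {
    assigned <- NA_character_
    got <- NA_real_
    for (j in seq_along(centroids)) {
      p <- pairwise_identity(sequences[[i]], centroids[[j]])
      if (p >= threshold) {
        assigned <- sprintf("F%02d", j)
        got <- p
        break
      }
    }
    if (is.na(assigned)) {
      centroids <- c(centroids, sequences[[i]])
      assigned <- sprintf("F%02d", length(centroids))
      got <- 1
    }
    fam <- c(fam, assigned)
    idty <- c(idty, got)
  }
  list(
    members = tibble(member_id = ids, family_id = fam, identity = idty),
    centroids = tibble(family_id = sprintf("F%02d", seq_along(centroids)),
                       centroid_seq = centroids)
  )
}

# monomer sequence of a locus in element orientation (first repeat unit,
# anchored at the strand-5' HHR)
extract_monomer <- function(residues, start, end, strand, period) {
  if (is.na(period)) return(NA_character_)
  period <- as.integer(round(period))
  if (strand == "+") {
    substr(residues, start + 1L, start + period)
  } else {
    revcomp(substr(residues, end - period + 1L, end))
  }
}

#' Assemble annotated retrozyme loci from scan hits
#'
#' Full annotation chain: tandem grouping, period and copy number, locus
#' span, repeat-identity QC, GC content, TSD detection, classification and
#' (optionally) family clustering of monomer sequences of retrozyme loci.
#' Locus spans cover whole arrays: from the strand-5' HHR start to the end
#' of the last monomer (copy_number x period nucleotides).
#'
#' @param genome a genome tibble from [read_fasta()].
#' @param hits a hit tibble from [scan_genome()].
#' @param max_gap tandem join distance (nt).
#' @param monomer_range,gc_max classification bounds (see
#'   [classify_locus()]).
#' @param tsd_k_max,tsd_min TSD search bounds (see [detect_tsd()]).
#' @param family_threshold identity threshold for family clustering; set to
#'   NULL to skip clustering.
#' @return A locus tibble, one row per tandem cluster.
#' @export
call_loci <- function(genome, hits, max_gap = 900L,
                      monomer_range = c(150, 450), gc_max = 45,
                      tsd_k_max = 20L, tsd_min = 5L,
                      family_threshold = 0.8) {
  empty <- tibble(
    locus_id = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), monomer_period = numeric(),
    copy_number = integer(), gc_percent = numeric(),
    repeat_identity = numeric(), tsd_length = integer(),
    tsd_seq = character(), classification = character(),
    family_id = character(), monomer_seq = character(), hit_ids = list()
  )
  if (nrow(hits) == 0L) return(empty)
  res_of <- stats::setNames(genome$residues, genome$contig)
  grouped <- group_tandem(hits, max_gap = max_gap)
  loci <- purrr::map_dfr(split(grouped, grouped$tandem_id), function(cl) {
    residues <- res_of[[cl$contig[1]]]
    pc <- estimate_period(cl$start)
    if (pc$copy_number >= 2L) {
      period <- pc$monomer_period
      if (cl$strand[1] == "+") {
        s <- min(cl$start)
        e <- as.integer(round(min(cl$start) +
                                pc$copy_number * period))
      } else {
        e <- max(cl$end)
        s <- as.integer(round(max(cl$end) - pc$copy_number * period))
      }
      s <- max(0L, s); e <- min(nchar(residues), e)
    } else {
      period <- NA_real_
      s <- min(cl$start); e <- max(cl$end)
    }
    ident <- withCallingHandlers(
      validate_repeat(residues, s, e, if (is.na(period)) NA else
        as.integer(round(period))),
      warning = function(w) invokeRestart("muffleWarning"))
    tsd <- withCallingHandlers(
      detect_tsd(residues, s, e, k_max = tsd_k_max, min_len = tsd_min),
      warning = function(w) invokeRestart("muffleWarning"))
    tibble(
      contig = cl$contig[1], start = s, end = e, strand = cl$strand[1],
      monomer_period = period, copy_number = pc$copy_number,
      gc_percent = locus_gc(residues, s, e),
      repeat_identity = ident,
      tsd_length = tsd$tsd_length, tsd_seq = tsd$tsd_seq,
      monomer_seq = extract_monomer(residues, s, e, cl$strand[1], period),
      hit_ids = list(cl$hit_id %||% character(0))
    )
  })
  loci$classification <- classify_locus(loci$copy_number,
                                        loci$monomer_period,
                                        loci$gc_percent,
                                        monomer_range = monomer_range,
                                        gc_max = gc_max)
  loci <- dplyr::arrange(loci, .data$contig, .data$start, .data$strand)
  loci$locus_id <- sprintf("RZL%03d", seq_len(nrow(loci)))
  loci$family_id <- NA_character_
  if (!is.null(family_threshold)) {
    is_rz <- loci$classification == "retrozyme"
    if (any(is_rz)) {
      fams <- cluster_families(
        stats::setNames(loci$monomer_seq[is_rz], loci$locus_id[is_rz]),
        threshold = family_threshold)
      loci$family_id[is_rz] <- fams$members$family_id
      attr(loci, "family_centroids") <- fams$centroids
    }
  }
  dplyr::select(loci, "locus_id", "contig", "start", "end", "strand",
                "monomer_period", "copy_number", "gc_percent",
                "repeat_identity", "tsd_length", "tsd_seq",
                "classification", "family_id", "monomer_seq", "hit_ids")
}

#' Write loci as GFF3
#'
#' One `tandem_repeat` feature per locus with period, copies, gc, tsd and
#' family attributes.
#'
#' @param loci a locus tibble from [call_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(loci)) loci$contig else character(0),
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = if (nrow(loci)) loci$strand else character(0)
  )
  gr$type <- rep("tandem_repeat", nrow(loci))
  gr$ID <- loci$locus_id
  gr$period <- loci$monomer_period
  gr$copies <- loci$copy_number
  gr$gc <- round(loci$gc_percent, 2)
  gr$tsd <- loci$tsd_seq
  gr$family <- loci$family_id
  gr$classification <- loci$classification
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the locus report as TSV
#'
#' @param loci a locus tibble from [call_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  flat <- dplyr::mutate(loci, hit_ids = vapply(
    .data$hit_ids, paste, character(1), collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write family centroid sequences as FASTA
#'
#' @param centroids tibble with `family_id` and `centroid_seq` (as produced
#'   by [cluster_families()] or attached to [call_loci()] output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(centroids, path) {
  write_fasta(tibble(contig = centroids$family_id,
                     residues = centroids$centroid_seq), path)
}
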