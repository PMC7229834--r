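# Seeded synthetic genomes with planted retrozyme arrays. The generator is
# the inverse of the matcher: it instantiates the same element grammar, so
# every planted motif is matchable by construction, and emits ground truth
# for end-to-end validation of the pipeline.

#' Species generator profiles
#'
#' Parameter bundles emulating the tandem-repeat retrozyme landscapes of the
#' three study organisms: a stony coral (two monomer length variants, 225 and
#' 245 nt, separated by a 20-nt indel; arrays from dimers up to 62-mers;
#' canonical HHRs with intact loop-loop contacts), a mussel (350-390 nt
#' monomers; HHRs lacking the archetypical tertiary-contact nucleotides), and
#' the axolotl's two ribozyme families (330 nt monomers with a 1-bp helix III
#' capped by a palindromic tetraloop; 350 nt monomers with a 2-bp helix III
#' and a U.U mismatch at the base of helix II). Monomer GC is kept below the
#' 45% retrozyme cutoff.
#'
#' @param name one of "coral", "mussel", "axolotl_1", "axolotl_2".
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name = c("coral", "mussel", "axolotl_1",
                                     "axolotl_2")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("coral", "mussel", "axolotl_1", "axolotl_2")) {
    abort(sprintf("unknown species profile '%s'", as.character(name)[1]))
  }
  base <- list(
    name = name,
    hhr_topology = "I",
    gc_background = 0.42,
    gc_monomer = 0.38,
    tsd_length = 6L,
    indel_length = 0L
  )
  prof <- switch(name,
    coral = list(
      monomer_lengths = c(225L, 245L), monomer_weights = c(0.5, 0.5),
      indel_length = 20L, copy_range = c(2L, 62L),
      hhr_variant_spec = hhr_variant_spec(helix3_bp = 3L,
                                          tertiary_on = TRUE)),
    mussel = list(
      monomer_lengths = 350:390,
      monomer_weights = rep(1 / 41, 41L),
      copy_range = c(2L, 20L),
      hhr_variant_spec = hhr_variant_spec(helix3_bp = 3L,
                                          tertiary_on = FALSE)),
    axolotl_1 = list(
      monomer_lengths = 330L, monomer_weights = 1,
      copy_range = c(2L, 30L),
      hhr_variant_spec = hhr_variant_spec(helix3_bp = 1L,
                                          tertiary_on = TRUE,
                                          palindromic_tetraloop = TRUE)),
    axolotl_2 = list(
      monomer_lengths = 350L, monomer_weights = 1,
      copy_range = c(2L, 30L),
      hhr_variant_spec = hhr_variant_spec(helix3_bp = 2L,
                                          tertiary_on = TRUE,
                                          helix2_mismatch = TRUE))
  )
  structure(utils::modifyList(base, prof), class = "species_profile")
}

#' HHR variant specification for the generator
#'
#' @param helix1_bp,helix2_bp,helix3_bp helix sizes (bp).
#' @param il1a_len,il1b_len internal-loop strand lengths (nt).
#' @param loop2_len,loop3_len terminal loop lengths (nt).
#' @param loop1t_len terminal loop closing helix I (topologies II/III only).
#' @param tertiary_on plant the tertiary-contact motif nucleotides.
#' @param helix2_mismatch plant a U.U pair at the base of helix II.
#' @param palindromic_tetraloop make loop 3 a reverse-complement-palindromic
#'   tetraloop.
#' @return A list of class `hhr_variant_spec`.
#' @export
hhr_variant_spec <- function(helix1_bp = 6L, helix2_bp = 4L, helix3_bp = 3L,
                             il1a_len = 3L, il1b_len = 2L, loop2_len = 6L,
                             loop3_len = 4L, loop1t_len = 4L,
                             tertiary_on = TRUE, helix2_mismatch = FALSE,
                             palindromic_tetraloop = FALSE) {
  structure(
    list(helix1_bp = as.integer(helix1_bp), helix2_bp = as.integer(helix2_bp),
         helix3_bp = as.integer(helix3_bp), il1a_len = as.integer(il1a_len),
         il1b_len = as.integer(il1b_len), loop2_len = as.integer(loop2_len),
         loop3_len = as.integer(loop3_len), loop1t_len = as.integer(loop1t_len),
         tertiary_on = isTRUE(tertiary_on),
         helix2_mismatch = isTRUE(helix2_mismatch),
         palindromic_tetraloop = isTRUE(palindromic_tetraloop)),
    class = "hhr_variant_spec"
  )
}

in_range <- function(x, r) x >= r[1] & x <= r[2]

# instantiate a random helix strand (pure Watson-Crick partner)
random_helix <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# random loop sequence avoiding given pattern chars at the leading positions
loop_avoiding <- function(n, avoid_pattern) {
  pc <- seq_chars(avoid_pattern)
  vapply(seq_len(n), function(i) {
    if (i <= length(pc) && pc[i] != "N") {
      excl <- if (pc[i] == "H") c("A", "C", "U") else pc[i]
      random_base_not(excl)
    } else {
      sample(c("A", "C", "G", "U"), 1L)
    }
  }, character(1)) |> paste(collapse = "")
}

#' Build a concrete HHR sequence from a descriptor and a variant spec
#'
#' Instantiates every grammar element (helices, loops, boxes, cleavage
#' triplet) so that the result is guaranteed to be matched by [match_at()]
#' with the requested topology and helix sizes. Deterministic per seed.
#'
#' @param d an `hhr_descriptor`.
#' @param spec an [hhr_variant_spec()].
#' @param seed optional RNG seed.
#' @return A list with `sequence` and `annotation` (tibble of element spans,
#'   0-based half-open motif-local coordinates).
#' @export
build_hhr_sequence <- function(d, spec = hhr_variant_spec(), seed = NULL) {
  stopifnot(inherits(d, "hhr_descriptor"), inherits(spec, "hhr_variant_spec"))
  if (!is.null(seed)) set.seed(seed)
  hr <- d$helix_ranges; lr <- d$loop_ranges; il <- d$helix1_internal_loop
  ok <- in_range(spec$helix1_bp, hr$helix1) &&
    in_range(spec$helix2_bp, hr$helix2) &&
    in_range(spec$helix3_bp, hr$helix3) &&
    in_range(spec$il1a_len, il) && in_range(spec$il1b_len, il) &&
    in_range(spec$loop2_len, lr$loop2) && in_range(spec$loop3_len, lr$loop3) &&
    (!"l1t" %in% element_order(d$topology) ||
       in_range(spec$loop1t_len, lr$loop1))
  if (!ok) abort("variant spec outside the descriptor's element ranges")
  if (spec$helix2_mismatch && !d$allow_helix2_base_mismatch) {
    abort("descriptor does not admit a helix II base mismatch")
  }
  rule <- d$tertiary_rule

  h1a <- random_helix(spec$helix1_bp); h1b <- revcomp(h1a)
  h2a <- random_helix(spec$helix2_bp); h2b <- revcomp(h2a)
  if (spec$helix2_mismatch) {
    substr(h2a, 1L, 1L) <- "U"
    substr(h2b, spec$helix2_bp, spec$helix2_bp) <- "U"
  }
  h3a <- random_helix(spec$helix3_bp); h3b <- revcomp(h3a)

  il1a <- if (spec$tertiary_on) {
    m <- rule$loop1_required_motif
    if (nchar(m) > spec$il1a_len) {
      abort("il1a too short to carry the loop 1 tertiary motif")
    }
    paste0(m, random_helix(spec$il1a_len - nchar(m)))
  } else {
    loop_avoiding(spec$il1a_len, rule$loop1_required_motif)
  }
  il1b <- random_helix(spec$il1b_len)
  loop2 <- if (spec$tertiary_on) {
    m <- rule$loop2_required_motif
    if (nchar(m) > spec$loop2_len) {
      abort("loop 2 too short to carry the tertiary motif")
    }
    paste0(m, random_helix(spec$loop2_len - nchar(m)))
  } else {
    loop_avoiding(spec$loop2_len, rule$loop2_required_motif)
  }
  loop3 <- if (spec$palindromic_tetraloop) {
    a <- sample(c("A", "C", "G", "U"), 1L)
    b <- sample(c("A", "C", "G", "U"), 1L)
    paste0(a, b, chartr("ACGU", "UGCA", b), chartr("ACGU", "UGCA", a))
  } else {
    repeat {
      l3 <- random_helix(spec$loop3_len)
      if (!(nchar(l3) == 4L && l3 == revcomp(l3))) break
    }
    l3
  }
  l1t <- random_helix(spec$loop1t_len)

  # Forbid inward helix extensions: if the first and last residue of a loop
  # (or of the helix I internal loop) could pair, the matcher would find an
  # alternative folding with one more base pair than the planted one. Where
  # such an extension is admissible under the descriptor ranges, rewrite the
  # trailing residue so it cannot pair with the leading one.
  partners <- function(a) switch(a, A = "U", U = c("A", "G"),
                                 G = c("C", "U"), C = "G")
  guard_tail <- function(s, avoid_extra = character(0)) {
    first <- substr(s, 1L, 1L); L <- nchar(s)
    last <- substr(s, L, L)
    if (can_pair(first, last, gu = d$allow_gu_wobble)) {
      pool <- setdiff(c("A", "C", "G", "U"),
                      c(partners(first), avoid_extra))
      substr(s, L, L) <- if (length(pool) > 1L) sample(pool, 1L) else pool
    }
    s
  }
  if (spec$loop2_len - 2L >= lr$loop2[1]) {
    avoid <- seq_chars(rule$loop2_required_motif)
    avoid <- if (!spec$tertiary_on && spec$loop2_len <= length(avoid)) {
      avoid[spec$loop2_len]
    } else character(0)
    loop2 <- guard_tail(loop2, avoid)
  }
  if (spec$loop3_len - 2L >= lr$loop3[1] && !spec$palindromic_tetraloop) {
    loop3 <- guard_tail(loop3)
  }
  if (spec$il1a_len >= 1L && spec$il1b_len >= 1L) {
    first <- substr(il1a, 1L, 1L); L <- nchar(il1b)
    if (can_pair(first, substr(il1b, L, L), gu = d$allow_gu_wobble)) {
      pool <- setdiff(c("A", "C", "G", "U"), partners(first))
      substr(il1b, L, L) <- if (length(pool) > 1L) sample(pool, 1L) else pool
    }
  }
  if (spec$loop1t_len - 2L >= lr$loop1[1]) {
    l1t <- guard_tail(l1t)
  }

  inst_box <- function(pattern) {
    pc <- seq_chars(pattern)
    pc[pc == "N"] <- sample(c("A", "C", "G", "U"), sum(pc == "N"),
                            replace = TRUE)
    pc[pc == "H"] <- sample(c("A", "C", "U"), sum(pc == "H"), replace = TRUE)
    paste(pc, collapse = "")
  }
  parts <- list(
    h1a = h1a, h1b = h1b, h2a = h2a, h2b = h2b, h3a = h3a, h3b = h3b,
    il1a = il1a, il1b = il1b, loop2 = loop2, loop3 = loop3, l1t = l1t,
    box1 = inst_box(d$box1), box2 = inst_box(d$box2),
    nuh = inst_box(d$cleavage_context)
  )
  ord <- element_order(d$topology)
  pieces <- unlist(parts[ord])
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  annotation <- tibble(element = ord, start = ends - lens, end = ends,
                       seq = unname(pieces))
  list(sequence = paste(pieces, collapse = ""), annotation = annotation)
}

# One monomer: HHR at offset 0, i.i.d. filler at gc_monomer, with
# non-pairing clamp bases at the filler boundaries so the planted helix I
# cannot extend into flanking sequence. The filler is re-drawn until the
# whole monomer's GC is within 2 points of the target, so locus GC stays
# reliably on the retrozyme side of the classification cutoff.
build_monomer <- function(d, spec, monomer_length, gc_monomer) {
  hhr <- build_hhr_sequence(d, spec)
  hlen <- nchar(hhr$sequence)
  fill_len <- monomer_length - hlen
  if (fill_len < 2L) {
    abort(sprintf(
      "monomer length %d too short for a %d-nt HHR plus filler",
      monomer_length, hlen))
  }
  for (try in seq_len(200L)) {
    filler <- random_seq(fill_len, gc_monomer)
    substr(filler, 1L, 1L) <- "C"
    substr(filler, fill_len, fill_len) <- "C"
    monomer <- paste0(hhr$sequence, filler)
    if (abs(gc_fraction(monomer) - gc_monomer) <= 0.02) break
  }
  list(seq = monomer, hhr_length = hlen, hhr_annotation = hhr$annotation)
}

# delete a block at a fixed internal position of the filler (indel variant)
delete_block <- function(monomer, hhr_length, del_len) {
  L <- nchar(monomer)
  start <- max(hhr_length + 10L, L - del_len - 10L)
  if (start + del_len > L - 1L) abort("monomer too short for indel variant")
  paste0(substr(monomer, 1L, start), substr(monomer, start + del_len + 1L, L))
}

# TSD k-mer without period-1/2/3 structure (so the detected duplication
# length is exactly the planted one) and with edge bases that cannot pair
# into the first repeat copy's helix I: in element orientation the residue
# immediately 5' of the array is the TSD's last base (+ strand) or the
# complement of its first base (- strand), and it must not pair with the
# C clamp that opens the monomer filler.
random_tsd <- function(k) {
  repeat {
    s <- random_helix(k)
    ch <- seq_chars(s)
    if (ch[1] == "C" || ch[k] == "G") next
    p1 <- all(ch == ch[1])
    p2 <- k >= 4L && all(ch[seq_len(k - 2L)] == ch[seq_len(k - 2L) + 2L])
    p3 <- k >= 6L && all(ch[seq_len(k - 3L)] == ch[seq_len(k - 3L) + 3L])
    if (!p1 && !p2 && !p3) return(s)
  }
}

#' Generate a synthetic genome with planted retrozyme arrays
#'
#' Builds an i.i.d. background at the profile's background GC, plants
#' `n_loci` tandem arrays per profile (one seeded master monomer per
#' profile, shorter length variants derived by block deletion, one HHR per
#' monomer with the cleavage site at the monomer boundary), flanks each
#' array with a duplicated target site, and inserts arrays at random
#' non-overlapping positions on random strands. Deterministic per seed.
#'
#' @param profile a `species_profile` or list of profiles.
#' @param n_loci loci per profile (recycled over profiles).
#' @param background_length background size before insertions (nt).
#' @param seed RNG seed.
#' @param mutation_rate per-base substitution rate applied independently to
#'   each repeat copy (default 0: exact arrays).
#' @param copy_range optional `c(min, max)` override of the profile's copy
#'   range.
#' @param contig contig name.
#' @param min_separation minimum background distance between insertion
#'   points.
#' @return A list with `genome` (tibble: contig, residues, length), `truth`
#'   (tibble: one row per planted locus) and `descriptor` (the canonical
#'   type I descriptor the motifs instantiate).
#' @export
generate_genome <- function(profile, n_loci = 5L, background_length = 100000L,
                            seed = 1L, mutation_rate = 0,
                            copy_range = NULL, contig = "chr1",
                            min_separation = 2000L) {
  profiles <- if (inherits(profile, "species_profile")) list(profile) else profile
  stopifnot(all(vapply(profiles, inherits, logical(1), "species_profile")))
  n_loci <- rep_len(as.integer(n_loci), length(profiles))
  set.seed(seed)
  d <- default_descriptor("I", "canonical")

  # per-profile master monomers, one per length class
  masters <- lapply(profiles, function(p) {
    max_len <- max(p$monomer_lengths)
    m <- build_monomer(d, p$hhr_variant_spec, max_len, p$gc_monomer)
    list(profile = p, master = m, max_len = max_len)
  })

  # draw locus descriptions
  loci <- list()
  for (gi in seq_along(masters)) {
    mi <- masters[[gi]]
    p <- mi$profile
    cr <- copy_range %||% p$copy_range
    for (li in seq_len(n_loci[gi])) {
      len <- if (length(p$monomer_lengths) > 1L) {
        sample(p$monomer_lengths, 1L, prob = p$monomer_weights)
      } else p$monomer_lengths
      monomer <- if (len < mi$max_len) {
        delete_block(mi$master$seq, mi$master$hhr_length, mi$max_len - len)
      } else mi$master$seq
      copies <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
      copy_seqs <- vapply(seq_len(copies), function(ci) {
        s <- monomer
        if (mutation_rate > 0) {
          ch <- seq_chars(s)
          hit <- which(stats::runif(length(ch)) < mutation_rate)
          for (ix in hit) ch[ix] <- random_base_not(ch[ix])
          s <- paste(ch, collapse = "")
        }
        s
      }, character(1))
      loci[[length(loci) + 1L]] <- list(
        profile_name = p$name, monomer_length = as.integer(len),
        copies = copies, array = paste(copy_seqs, collapse = ""),
        strand = sample(c("+", "-"), 1L),
        tsd = random_tsd(p$tsd_length),
        hhr_length = mi$master$hhr_length
      )
    }
  }

  total <- length(loci)
  margin <- 200L
  if (background_length < 2L * margin + (total + 1L) * min_separation) {
    abort("background too small to place the requested loci")
  }
  positions <- NULL
  for (try in seq_len(1000L)) {
    cand <- sort(sample((margin:(background_length - margin)), total))
    if (total < 2L || all(diff(cand) >= min_separation)) {
      positions <- cand
      break
    }
  }
  if (is.null(positions)) abort("could not place loci without overlap")
  # shuffle which locus goes where, deterministically
  order_ix <- sample(total)

  background <- random_seq(background_length, profiles[[1]]$gc_background)
  bg_chars <- seq_chars(background)
  out_parts <- character(0)
  truth_rows <- list()
  prev <- 0L
  offset <- 0L
  for (k in seq_len(total)) {
    lc <- loci[[order_ix[k]]]
    pos <- positions[k]
    frag <- paste(bg_chars[(prev + 1L):pos], collapse = "")
    # forbid accidental single-base TSD extension: the background base just
    # 5' of the left TSD copy must differ from the one just 3' of the right
    after_base <- bg_chars[pos + 1L]
    if (substr(frag, nchar(frag), nchar(frag)) == after_base) {
      substr(frag, nchar(frag), nchar(frag)) <- random_base_not(after_base)
    }
    oriented <- if (lc$strand == "+") lc$array else revcomp(lc$array)
    insert <- paste0(lc$tsd, oriented, lc$tsd)
    locus_start <- pos + offset + nchar(lc$tsd)
    locus_end <- locus_start + nchar(lc$array)
    M <- lc$monomer_length
    hhr_starts <- if (lc$strand == "+") {
      locus_start + (seq_len(lc$copies) - 1L) * M
    } else {
      sort(locus_end - (seq_len(lc$copies) - 1L) * M - lc$hhr_length)
    }
    truth_rows[[k]] <- tibble(
      contig = contig, start = locus_start, end = locus_end,
      strand = lc$strand, monomer_length = M, copies = lc$copies,
      family_label = lc$profile_name, tsd_seq = lc$tsd,
      hhr_length = lc$hhr_length, hhr_starts = list(hhr_starts)
    )
    out_parts <- c(out_parts, frag, insert)
    offset <- offset + nchar(insert)
    prev <- pos
  }
  out_parts <- c(out_parts, paste(bg_chars[(prev + 1L):background_length],
                                  collapse = ""))
  residues <- paste(out_parts, collapse = "")
  truth <- dplyr::arrange(dplyr::bind_rows(truth_rows), .data$start)
  list(
    genome = tibble(contig = contig, residues = residues,
                    length = nchar(residues)),
    truth = truth,
    descriptor = d
  )
}

#' Write the generator truth table as TSV / BED
#'
#' @param truth truth tibble from [generate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  flat <- dplyr::mutate(truth, hhr_starts = vapply(
    .data$hhr_starts, paste, character(1), collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
write_truth_bed <- function(truth, path) {
  bed <- tibble(chrom = truth$contig, start = truth$start, end = truth$end,
                name = truth$family_label, score = truth$copies,
                strand = truth$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Generate decoy sequences
#'
#' Negative controls for the scanner: `shuffled_core` permutes the
#' nucleotides of the two core boxes (destroying the catalytic consensus
#' while preserving composition), `broken_helix` rewrites one helix II
#' strand to destroy complementarity, and `isolated_hhr` embeds one intact
#' motif in non-repetitive flanks (a true hit, but not a tandem locus).
#'
#' @param kind decoy type.
#' @param n number of decoys.
#' @param seed RNG seed.
#' @param flank flank length around the motif (nt).
#' @return Named character vector of decoy sequences.
#' @export
make_decoys <- function(kind = c("shuffled_core", "broken_helix",
                                 "isolated_hhr"),
                        n = 1L, seed = 1L, flank = 120L) {
  kind <- match.arg(kind)
  if (n < 1L) abort("n must be >= 1")
  set.seed(seed)
  d <- default_descriptor("I", "canonical")
  out <- vapply(seq_len(n), function(i) {
    hhr <- build_hhr_sequence(d, hhr_variant_spec())
    seqs <- stats::setNames(hhr$annotation$seq, hhr$annotation$element)
    if (kind == "shuffled_core") {
      core <- seq_chars(paste0(seqs[["box1"]], seqs[["box2"]]))
      repeat {
        perm <- sample(core)
        b1 <- paste(perm[seq_len(nchar(seqs[["box1"]]))], collapse = "")
        b2 <- paste(perm[-seq_len(nchar(seqs[["box1"]]))], collapse = "")
        if (pattern_mismatches(seq_chars(b1), seq_chars(d$box1)) > 0L &&
            pattern_mismatches(seq_chars(b2), seq_chars(d$box2)) > 0L) break
      }
      seqs[["box1"]] <- b1
      seqs[["box2"]] <- b2
    } else if (kind == "broken_helix") {
      repeat {
        stray <- random_helix(nchar(seqs[["h2b"]]))
        pairs_ok <- can_pair(seq_chars(seqs[["h2a"]]),
                             rev(seq_chars(stray)), gu = TRUE)
        if (sum(!pairs_ok) >= 2L) break
      }
      seqs[["h2b"]] <- stray
    }
    body <- paste(seqs[element_order(d$topology)], collapse = "")
    left <- random_seq(flank, 0.42); right <- random_seq(flank, 0.42)
    substr(left, flank, flank) <- "C"
    substr(right, 1L, 1L) <- "C"
    paste0(left, body, right)
  }, character(1))
  stats::setNames(out, sprintf("%s_%02d", kind, seq_len(n)))
}
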