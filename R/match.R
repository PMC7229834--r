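# Descriptor-driven HHR matching.
#
# The motif grammar is linearized per topology (the topology is named for the
# open-ended helix). Element order, 5'->3':
#   type I   : h1a il1a box1 h2a loop2 h2b box2 h3a loop3 h3b NUH il1b h1b
#   type II  : h2b box2 h3a loop3 h3b NUH il1b h1b l1t h1a il1a box1 h2a
#   type III : h3b NUH il1b h1b l1t h1a il1a box1 h2a loop2 h2b box2 h3a
# il1a/il1b are the two strands of the helix I internal loop (the tertiary
# contact region, "loop 1"); l1t is the terminal loop closing helix I when
# helix I is not the open helix. The open helix never carries a terminal loop.

element_order <- function(topology) {
  switch(topology,
    I = c("h1a", "il1a", "box1", "h2a", "loop2", "h2b", "box2",
          "h3a", "loop3", "h3b", "nuh", "il1b", "h1b"),
    II = c("h2b", "box2", "h3a", "loop3", "h3b", "nuh", "il1b",
           "h1b", "l1t", "h1a", "il1a", "box1", "h2a"),
    III = c("h3b", "nuh", "il1b", "h1b", "l1t", "h1a", "il1a",
            "box1", "h2a", "loop2", "h2b", "box2", "h3a"),
    abort(sprintf("unknown topology '%s'", topology))
  )
}

helix_of <- c(h1a = 1L, h1b = 1L, h2a = 2L, h2b = 2L, h3a = 3L, h3b = 3L)

build_elements <- function(d) {
  ord <- element_order(d$topology)
  seen <- integer(0)
  lapply(ord, function(id) {
    if (id %in% names(helix_of)) {
      h <- helix_of[[id]]
      role <- if (h %in% seen) "second" else "first"
      seen <<- c(seen, h)
      list(kind = "helix", id = id, helix = h, role = role,
           range = d$helix_ranges[[paste0("helix", h)]])
    } else if (id %in% c("il1a", "il1b")) {
      list(kind = "loop", id = id, range = d$helix1_internal_loop)
    } else if (id == "l1t") {
      list(kind = "loop", id = id, range = d$loop_ranges$loop1)
    } else if (id %in% c("loop2", "loop3")) {
      list(kind = "loop", id = id, range = d$loop_ranges[[id]])
    } else if (id == "box1") {
      list(kind = "box", id = id, chars = seq_chars(d$box1))
    } else if (id == "box2") {
      list(kind = "box", id = id, chars = seq_chars(d$box2))
    } else if (id == "nuh") {
      list(kind = "box", id = id, chars = seq_chars(d$cleavage_context))
    } else {
      abort(sprintf("internal: unknown element '%s'", id))
    }
  })
}

# span (min, max) of a run of elements, helix lengths counted per occurrence
elements_span_range <- function(elems) {
  lo <- 0L; hi <- 0L
  for (el in elems) {
    r <- switch(el$kind,
                helix = el$range,
                loop = el$range,
                box = c(length(el$chars), length(el$chars)))
    lo <- lo + r[1]; hi <- hi + r[2]
  }
  c(lo, hi)
}

#' Maximum motif span of a descriptor
#'
#' Sum of the per-element maxima of the linearized grammar; the scanner never
#' has to consider windows longer than this.
#'
#' @param d an `hhr_descriptor`.
#' @return Integer number of nucleotides.
#' @export
max_motif_span <- function(d) {
  elements_span_range(build_elements(d))[2]
}

# is the first-seen strand of helix II the core-proximal one (h2a)?
h2a_is_first <- function(topology) topology %in% c("I", "III")

# Exhaustive depth-first enumeration of all grammar assignments whose first
# element starts at `start0` (1-based index into `chars`). State is a flat
# integer vector of chosen element lengths; spans are reconstructed only for
# the (rare) complete assignments. Returns raw hits.
enumerate_hits_at <- function(chars, cumN, start0, elems, d,
                              codes = NULL, pm = NULL) {
  n <- length(chars)
  allow_mm2 <- d$allow_helix2_base_mismatch
  max_mm <- d$max_core_mismatches
  prox_first <- h2a_is_first(d$topology)
  nel <- length(elems)
  # integer base codes and flat pairing lookup (A=1, C=2, G=3, U=4)
  if (is.null(codes)) codes <- match(chars, c("A", "C", "G", "U"))
  if (is.null(pm)) pm <- pairing_lookup(d$allow_gu_wobble)
  # flattened element attributes
  kind <- vapply(elems, function(e) {
    if (e$kind == "box") 1L else if (e$kind == "loop") 2L
    else if (e$role == "first") 3L else 4L
  }, integer(1))
  lo <- hi <- integer(nel)
  pcs <- vector("list", nel)
  first_idx <- integer(3L)
  helixnum <- integer(nel)
  for (i in seq_len(nel)) {
    el <- elems[[i]]
    if (el$kind == "box") {
      pcs[[i]] <- el$chars
      lo[i] <- hi[i] <- length(el$chars)
    } else {
      lo[i] <- el$range[1]; hi[i] <- el$range[2]
    }
    if (el$kind == "helix") {
      helixnum[i] <- el$helix
      if (el$role == "first") first_idx[el$helix] <- i
    }
  }
  hits <- list()

  rec <- function(i, pos, lens, core_mm) {
    if (i > nel) {
      hits[[length(hits) + 1L]] <<- list(start = start0, end = pos,
                                         lens = lens,
                                         core_mismatches = core_mm)
      return(NULL)
    }
    k <- kind[i]
    if (k == 1L) {
      pc <- pcs[[i]]
      L <- lo[i]
      e <- pos + L - 1L
      if (e > n || cumN[e + 1L] > cumN[pos]) return(NULL)
      sc <- chars[pos:e]
      mm <- sum(!((pc == "N") | (sc == pc) |
                    (pc == "H" & sc != "G")))
      if (core_mm + mm > max_mm) return(NULL)
      lens[i] <- L
      rec(i + 1L, pos + L, lens, core_mm + mm)
    } else if (k == 2L || k == 3L) {
      for (L in lo[i]:hi[i]) {
        e <- pos + L - 1L
        if (e > n) break
        if (L > 0L && cumN[e + 1L] > cumN[pos]) next
        lens[i] <- L
        rec(i + 1L, pos + L, lens, core_mm)
      }
    } else {
      h <- helixnum[i]
      fi <- first_idx[h]
      L <- lens[fi]
      e <- pos + L - 1L
      if (e > n || cumN[e + 1L] > cumN[pos]) return(NULL)
      fs <- start0 + (if (fi > 1L) sum(lens[1:(fi - 1L)]) else 0L)
      ok <- pm[(codes[fs:(fs + L - 1L)] - 1L) * 4L + codes[e:pos]]
      nf <- L - sum(ok)
      if (nf == 0L ||
          (h == 2L && allow_mm2 && nf == 1L &&
           !ok[if (prox_first) 1L else L])) {
        lens[i] <- L
        rec(i + 1L, pos + L, lens, core_mm)
      }
    }
    NULL
  }

  rec(1L, start0, integer(nel), 0L)
  hits
}

# flat 4x4 pairing lookup indexed by (a-1)*4 + b over codes A=1,C=2,G=3,U=4
pairing_lookup <- function(gu = TRUE) {
  pm <- logical(16L)
  set <- function(a, b) pm[(a - 1L) * 4L + b] <<- TRUE
  set(1L, 4L); set(4L, 1L)  # A-U
  set(3L, 2L); set(2L, 3L)  # G-C
  if (gu) { set(3L, 4L); set(4L, 3L) }  # G.U
  pm
}

# Convert raw enumeration records to one tidy hit row each, reconstructing
# element spans from the chosen lengths. Coordinates in the row are 0-based
# half-open on the scanned strand; the caller remaps minus-strand hits to
# forward coordinates.
raw_hits_to_tibble <- function(raw, chars, elems, d,
                               contig = NA_character_) {
  if (length(raw) == 0L) return(empty_hits())
  ids <- vapply(elems, `[[`, character(1), "id")
  gu <- d$allow_gu_wobble
  nr <- length(raw)
  start <- end <- h1 <- h2 <- h3 <- cs <- mm <- integer(nr)
  loop1 <- loop2 <- loop3 <- core <- character(nr)
  mis2 <- logical(nr)
  segments <- vector("list", nr)
  for (ri in seq_len(nr)) {
    r <- raw[[ri]]
    s0 <- r$start
    starts <- s0 + c(0L, cumsum(r$lens))[seq_along(elems)]
    names(starts) <- ids
    lens <- r$lens
    names(lens) <- ids
    piece <- function(id) {
      if (!id %in% ids || lens[[id]] == 0L) return("")
      paste(chars[starts[[id]]:(starts[[id]] + lens[[id]] - 1L)],
            collapse = "")
    }
    helix_pairing <- function(h) {
      a <- starts[[paste0("h", h, "a")]]
      b <- starts[[paste0("h", h, "b")]]
      L <- lens[[paste0("h", h, "a")]]
      sum(can_pair(chars[a:(a + L - 1L)], chars[(b + L - 1L):b], gu))
    }
    h1[ri] <- helix_pairing(1L)
    h2[ri] <- helix_pairing(2L)
    h3[ri] <- helix_pairing(3L)
    start[ri] <- s0 - 1L
    end[ri] <- r$end - 1L
    loop1[ri] <- paste0(piece("il1a"), piece("il1b"))
    loop2[ri] <- piece("loop2")
    loop3[ri] <- piece("loop3")
    core[ri] <- paste0(piece("box1"), piece("box2"), piece("nuh"))
    cs[ri] <- (starts[["nuh"]] - s0) + lens[["nuh"]]
    mis2[ri] <- h2[ri] < lens[["h2a"]]
    mm[ri] <- r$core_mismatches
    segs <- lapply(seq_along(elems), function(i) {
      c(starts[[i]] - s0, starts[[i]] - s0 + lens[[i]])
    })
    names(segs) <- ids
    segments[[ri]] <- segs
  }
  tibble(
    contig = contig, start = start, end = end, strand = "+",
    topology = NA_character_,
    helix1_bp = h1, helix2_bp = h2, helix3_bp = h3,
    total_bp = h1 + h2 + h3,
    loop1_seq = loop1, loop2_seq = loop2, loop3_seq = loop3,
    core_seq = core, cleavage_site = cs,
    helix2_base_mismatch = mis2, core_mismatches = mm,
    segments = segments
  )
}

empty_hits <- function() {
  tibble(
    contig = character(), start = integer(), end = integer(),
    strand = character(), topology = character(),
    helix1_bp = integer(), helix2_bp = integer(), helix3_bp = integer(),
    total_bp = integer(), loop1_seq = character(), loop2_seq = character(),
    loop3_seq = character(), core_seq = character(),
    cleavage_site = integer(), helix2_base_mismatch = logical(),
    core_mismatches = integer(), segments = list()
  )
}

#' Match a descriptor at a fixed offset
#'
#' Enumerates every assignment of helix and loop lengths within the
#' descriptor's ranges such that the motif's first element begins exactly at
#' `window_start`, the core boxes match within the mismatch budget, and every
#' helix is complementary (Watson-Crick, plus G.U when allowed). Windows
#' containing N never match.
#'
#' @param seq a nucleotide string (T or U accepted).
#' @param window_start 0-based offset of the motif start.
#' @param d an `hhr_descriptor`.
#' @param annotate add topology/variant/feature columns (default TRUE).
#' @return A tibble of hits (possibly empty), one row per assignment.
#' @export
match_at <- function(seq, window_start, d, annotate = TRUE) {
  seq <- normalize_residues(seq)
  chars <- seq_chars(seq)
  cumN <- c(0L, cumsum(chars == "N"))
  elems <- build_elements(d)
  raw <- enumerate_hits_at(chars, cumN, as.integer(window_start) + 1L,
                           elems, d)
  hits <- raw_hits_to_tibble(raw, chars, elems, d)
  if (annotate) hits <- annotate_hits(hits, d)
  hits
}

#' Classify the topology of hits from their helix segments
#'
#' Returns, per hit, the label of the helix whose two strands lie at the 5'
#' and 3' extremities of the motif.
#'
#' @param hits a hit tibble with a `segments` list-column.
#' @return Character vector of "I", "II" or "III".
#' @export
classify_topology <- function(hits) {
  vapply(hits$segments, function(segs) {
    if (is.null(segs) || !length(segs)) abort("hit has no helix segments")
    width <- max(vapply(segs, `[`, numeric(1), 2))
    for (h in 1:3) {
      ids <- names(helix_of)[helix_of == h]
      ids <- intersect(ids, names(segs))
      if (length(ids) != 2L) abort("malformed helix segments")
      lo <- min(vapply(segs[ids], `[`, numeric(1), 1))
      hi <- max(vapply(segs[ids], `[`, numeric(1), 2))
      if (lo == 0 && hi == width) return(c("I", "II", "III")[h])
    }
    abort("no helix spans both motif extremities")
  }, character(1))
}

#' Check tertiary (loop-loop) contacts of hits
#'
#' Counts how many constrained positions of the rule's loop motifs are
#' matched at the start of the loop 1 (helix I internal loop) and loop 2
#' regions of each hit.
#'
#' @param hits a hit tibble (needs `loop1_seq`, `loop2_seq`).
#' @param rule a [tertiary_rule()].
#' @return A tibble with columns `tertiary_ok` and `tertiary_matches`.
#' @export
check_tertiary_contacts <- function(hits, rule) {
  stopifnot(inherits(rule, "tertiary_rule"))
  count_one <- function(loop, motif) {
    pc <- seq_chars(motif)
    pc <- pc[seq_len(min(length(pc), nchar(loop)))]
    if (!length(pc)) return(0L)
    lc <- seq_chars(loop)[seq_along(pc)]
    constrained <- pc != "N"
    ok <- (lc == pc) | (pc == "H" & lc %in% c("A", "C", "U"))
    sum(ok & constrained)
  }
  m <- vapply(seq_len(nrow(hits)), function(i) {
    count_one(hits$loop1_seq[i], rule$loop1_required_motif) +
      count_one(hits$loop2_seq[i], rule$loop2_required_motif)
  }, integer(1))
  tibble(tertiary_ok = m >= rule$min_matches, tertiary_matches = m)
}

#' Extract structural features from hits
#'
#' @param hits a hit tibble.
#' @param rule tertiary rule used for the contact count (defaults to the
#'   canonical rule).
#' @return A tibble with `helix3_bp`, `helix3_loop_is_palindromic_tetraloop`,
#'   `helix2_base_mismatch`, `tertiary_matches` and `tertiary_ok`.
#' @export
extract_features <- function(hits, rule = tertiary_rule()) {
  tc <- check_tertiary_contacts(hits, rule)
  tibble(
    helix3_bp = hits$helix3_bp,
    helix3_loop_is_palindromic_tetraloop =
      nchar(hits$loop3_seq) == 4L & hits$loop3_seq == revcomp(hits$loop3_seq),
    helix2_base_mismatch = hits$helix2_base_mismatch,
    tertiary_matches = tc$tertiary_matches,
    tertiary_ok = tc$tertiary_ok
  )
}

#' Predict the self-cleavage mode from structural features
#'
#' Encodes the observation that motifs with a vestigial helix III (a single
#' base pair) barely cleave as monomers and need to pair up as dimers, while
#' motifs with a stable helix III and intact loop-loop contacts cleave
#' efficiently as monomers.
#'
#' @param features a tibble from [extract_features()] (columns `helix3_bp`,
#'   `tertiary_ok`; `helix2_base_mismatch` is carried but not used by the
#'   default rule).
#' @param dimer_max_helix3 helix III size at or below which a dimer is
#'   required (default 1 bp).
#' @param monomer_min_helix3 minimum helix III size for monomer competence
#'   (default 3 bp).
#' @return Character vector of "dimer_required", "weak" or
#'   "monomer_competent".
#' @export
predict_cleavage_mode <- function(features, dimer_max_helix3 = 1L,
                                  monomer_min_helix3 = 3L) {
  dplyr::case_when(
    features$helix3_bp <= dimer_max_helix3 ~ "dimer_required",
    features$helix3_bp < monomer_min_helix3 | !features$tertiary_ok ~ "weak",
    TRUE ~ "monomer_competent"
  )
}

# Attach topology, variant, features and predicted mode to raw hits.
# A hit is labelled "canonical" when its loop-loop contact count satisfies
# the canonical threshold (the descriptor's own rule when non-trivial,
# otherwise the default canonical rule), and "minimal" otherwise.
annotate_hits <- function(hits, d) {
  if (nrow(hits) == 0L) {
    hits$variant <- character(0)
    hits$helix3_loop_is_palindromic_tetraloop <- logical(0)
    hits$tertiary_matches <- integer(0)
    hits$tertiary_ok <- logical(0)
    hits$predicted_mode <- character(0)
    return(hits)
  }
  label_rule <- if (d$tertiary_rule$min_matches > 0L) {
    d$tertiary_rule
  } else {
    tertiary_rule(d$tertiary_rule$loop1_required_motif,
                  d$tertiary_rule$loop2_required_motif,
                  min_matches = 3L)
  }
  feats <- extract_features(hits, label_rule)
  hits$topology <- classify_topology(hits)
  hits$variant <- ifelse(feats$tertiary_ok, "canonical", "minimal")
  hits$helix3_loop_is_palindromic_tetraloop <-
    feats$helix3_loop_is_palindromic_tetraloop
  hits$tertiary_matches <- feats$tertiary_matches
  hits$tertiary_ok <- feats$tertiary_ok
  hits$predicted_mode <- predict_cleavage_mode(feats)
  hits
}
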