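#' Tertiary (loop-loop) interaction rule
#'
#' Canonical type I hammerhead ribozymes are stabilised by contacts between
#' the internal loop of helix I (loop 1) and the terminal loop of helix II
#' (loop 2). The rule records a required motif for each loop region and the
#' minimum number of constrained positions that must match for the contact to
#' be considered present. The default motif identities are configurable
#' placeholders: the field literature depicts the interacting nucleotides
#' structurally rather than as a linear consensus.
#'
#' @param loop1_required_motif pattern over \{A,C,G,U,N,H\} anchored at the
#'   start of the loop 1 region.
#' @param loop2_required_motif pattern anchored at the start of loop 2.
#' @param min_matches minimum matched constrained positions for the rule to
#'   be satisfied.
#' @return An object of class `tertiary_rule`.
#' @export
tertiary_rule <- function(loop1_required_motif = "UG",
                          loop2_required_motif = "GUGA",
                          min_matches = 3L) {
  check_pattern_alphabet(loop1_required_motif, "loop1_required_motif")
  check_pattern_alphabet(loop2_required_motif, "loop2_required_motif")
  total <- n_constrained(loop1_required_motif) +
    n_constrained(loop2_required_motif)
  if (min_matches > total) {
    abort("min_matches exceeds the constrained positions of the two motifs")
  }
  structure(
    list(loop1_required_motif = loop1_required_motif,
         loop2_required_motif = loop2_required_motif,
         min_matches = as.integer(min_matches)),
    class = "tertiary_rule"
  )
}

#' Construct an HHR motif descriptor
#'
#' The descriptor is the declarative grammar the matcher enumerates: the two
#' conserved core boxes, the NUH cleavage triplet, per-helix base-pair ranges,
#' per-loop length ranges, the helix I internal loop, and the tertiary rule.
#' Most users want [default_descriptor()].
#'
#' @param topology "I", "II" or "III" (named for the open-ended helix).
#' @param box1,box2 core box patterns (between helix I/II and helix II/III).
#' @param cleavage_context cleavage triplet pattern; H is A, C or U, cleavage
#'   occurs 3' of the H.
#' @param helix_ranges named list `helix1`, `helix2`, `helix3` of
#'   `c(min_bp, max_bp)`.
#' @param loop_ranges named list `loop1`, `loop2`, `loop3` of
#'   `c(min_nt, max_nt)`; `loop1` is the terminal loop closing helix I in
#'   topologies where helix I is not the open helix.
#' @param helix1_internal_loop `c(min_nt, max_nt)` per strand for the helix I
#'   internal loop carrying the tertiary-contact nucleotides.
#' @param allow_gu_wobble allow G.U pairs inside helices.
#' @param allow_helix2_base_mismatch permit a non-complementary pair at the
#'   core-proximal position of helix II (seen in one axolotl ribozyme family).
#' @param max_core_mismatches mismatches tolerated across box1/box2/NUH.
#' @param tertiary_rule a [tertiary_rule()] object.
#' @param variant "canonical" or "minimal" (bookkeeping label; the matcher
#'   uses the tertiary rule itself).
#' @return An object of class `hhr_descriptor`.
#' @export
hhr_descriptor <- function(topology = "I",
                           box1 = "CUGANGA",
                           box2 = "GAAAC",
                           cleavage_context = "NUH",
                           helix_ranges = list(helix1 = c(3L, 11L),
                                               helix2 = c(3L, 6L),
                                               helix3 = c(1L, 6L)),
                           loop_ranges = list(loop1 = c(3L, 8L),
                                              loop2 = c(4L, 10L),
                                              loop3 = c(3L, 8L)),
                           helix1_internal_loop = c(0L, 4L),
                           allow_gu_wobble = TRUE,
                           allow_helix2_base_mismatch = TRUE,
                           max_core_mismatches = 0L,
                           tertiary_rule = retrozyme::tertiary_rule(),
                           variant = "canonical") {
  if (!topology %in% c("I", "II", "III")) {
    abort(sprintf("unknown topology '%s' (use I, II or III)", topology))
  }
  if (!variant %in% c("canonical", "minimal")) {
    abort(sprintf("unknown variant '%s' (use canonical or minimal)", variant))
  }
  check_pattern_alphabet(box1, "box1")
  check_pattern_alphabet(box2, "box2")
  check_pattern_alphabet(cleavage_context, "cleavage_context")
  for (nm in c("helix1", "helix2", "helix3")) {
    r <- helix_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      abort(sprintf("helix_ranges$%s must be c(min, max) with 1 <= min <= max", nm))
    }
  }
  for (nm in c("loop1", "loop2", "loop3")) {
    r <- loop_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || r[1] < 0L) {
      abort(sprintf("loop_ranges$%s must be c(min, max) with 0 <= min <= max", nm))
    }
  }
  il <- helix1_internal_loop
  if (length(il) != 2L || il[1] > il[2] || il[1] < 0L) {
    abort("helix1_internal_loop must be c(min, max) with 0 <= min <= max")
  }
  if (max_core_mismatches < 0L) abort("max_core_mismatches must be >= 0")
  stopifnot(inherits(tertiary_rule, "tertiary_rule"))
  structure(
    list(topology = topology,
         box1 = box1,
         box2 = box2,
         cleavage_context = cleavage_context,
         helix_ranges = lapply(helix_ranges, as.integer),
         loop_ranges = lapply(loop_ranges, as.integer),
         helix1_internal_loop = as.integer(il),
         allow_gu_wobble = isTRUE(allow_gu_wobble),
         allow_helix2_base_mismatch = isTRUE(allow_helix2_base_mismatch),
         max_core_mismatches = as.integer(max_core_mismatches),
         tertiary_rule = tertiary_rule,
         variant = variant),
    class = "hhr_descriptor"
  )
}

#' Default descriptor for a topology and variant
#'
#' The canonical variant carries a non-trivial tertiary rule (contacts
#' between the helix I internal loop and loop 2 required); the minimal
#' variant relaxes the rule to `min_matches = 0` and keeps helix III
#' admissible down to a single base pair.
#'
#' @param topology "I", "II" or "III".
#' @param variant "canonical" or "minimal".
#' @return An `hhr_descriptor`.
#' @examples
#' d <- default_descriptor("I", "canonical")
#' count_core_positions(d)  # 15
#' @export
default_descriptor <- function(topology = "I", variant = "canonical") {
  if (!is.character(topology) || !topology %in% c("I", "II", "III")) {
    abort(sprintf("unknown topology '%s' (use I, II or III)", as.character(topology)))
  }
  if (!variant %in% c("canonical", "minimal")) {
    abort(sprintf("unknown variant '%s' (use canonical or minimal)", variant))
  }
  rule <- if (variant == "canonical") {
    tertiary_rule()
  } else {
    tertiary_rule(min_matches = 0L)
  }
  hhr_descriptor(topology = topology, tertiary_rule = rule, variant = variant)
}

#' Number of constrained core positions of a descriptor
#'
#' Counts the positions of box1, box2 and the cleavage triplet. Degenerate
#' slots (N, H) count: they are core positions whose identity is free but
#' whose presence is structurally required.
#'
#' @param d an `hhr_descriptor`.
#' @return Integer count (15 for the default canonical descriptor).
#' @export
count_core_positions <- function(d) {
  stopifnot(inherits(d, "hhr_descriptor"))
  nchar(d$box1) + nchar(d$box2) + nchar(d$cleavage_context)
}

#' @export
print.hhr_descriptor <- function(x, ...) {
  cat(sprintf("<hhr_descriptor> type %s (%s variant)\n", x$topology, x$variant))
  cat(sprintf("  core: %s ... %s ... %s (%d positions)\n",
              x$box1, x$box2, x$cleavage_context, count_core_positions(x)))
  hr <- x$helix_ranges
  cat(sprintf("  helices (bp): I %d-%d, II %d-%d, III %d-%d; G.U %s\n",
              hr$helix1[1], hr$helix1[2], hr$helix2[1], hr$helix2[2],
              hr$helix3[1], hr$helix3[2],
              if (x$allow_gu_wobble) "allowed" else "disallowed"))
  cat(sprintf("  tertiary rule: loop1 '%s' / loop2 '%s', min %d matches\n",
              x$tertiary_rule$loop1_required_motif,
              x$tertiary_rule$loop2_required_motif,
              x$tertiary_rule$min_matches))
  invisible(x)
}

#' Write / read a descriptor as a YAML config
#'
#' Serialization uses the exact key names of the constructor so configs are
#' self-documenting and round-trip losslessly.
#'
#' @param d an `hhr_descriptor`.
#' @param path file path.
#' @return `write_descriptor` returns `path` invisibly; `read_descriptor`
#'   returns an `hhr_descriptor`.
#' @export
write_descriptor <- function(d, path) {
  stopifnot(inherits(d, "hhr_descriptor"))
  x <- unclass(d)
  x$tertiary_rule <- unclass(x$tertiary_rule)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_descriptor
#' @export
read_descriptor <- function(path) {
  x <- yaml::read_yaml(path)
  rule <- do.call(tertiary_rule, x$tertiary_rule)
  hhr_descriptor(
    topology = x$topology, box1 = x$box1, box2 = x$box2,
    cleavage_context = x$cleavage_context,
    helix_ranges = x$helix_ranges, loop_ranges = x$loop_ranges,
    helix1_internal_loop = unlist(x$helix1_internal_loop),
    allow_gu_wobble = x$allow_gu_wobble,
    allow_helix2_base_mismatch = x$allow_helix2_base_mismatch %||% TRUE,
    max_core_mismatches = x$max_core_mismatches,
    tertiary_rule = rule, variant = x$variant %||% "canonical"
  )
}
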