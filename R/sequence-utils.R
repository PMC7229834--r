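#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Internal sequence machinery. All sequences are handled as uppercase
# RNA-alphabet character scalars ({A,C,G,U,N}); DNA input (T, lowercase)
# is normalized on entry. N is carried through but never matched.

RZ_ALPHABET <- c("A", "C", "G", "U", "N")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases the input and converts T to U. Characters outside
#' \{A,C,G,T,U,N\} are rejected.
#'
#' @param x character vector of nucleotide strings.
#' @return Character vector over \{A,C,G,U,N\}.
#' @export
normalize_residues <- function(x) {
  if (!is.character(x)) abort("sequence must be a character vector")
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGUN]", "", out[bad]), "")))
    abort(sprintf("illegal sequence character(s): %s",
                  paste(ch, collapse = ", ")))
  }
  out
}

#' Reverse complement
#'
#' @param x character vector of normalized nucleotide strings.
#' @return Reverse complement(s), same alphabet.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector once; most internals work on these
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Watson-Crick (+ optional G.U wobble) pairing predicate, vectorized
can_pair <- function(a, b, gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (gu) wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  wc
}

# IUPAC-subset pattern match: pattern over {A,C,G,U,N,H}, vectorized over
# positions. Returns number of mismatches at constrained positions.
pattern_mismatches <- function(chars, pattern_chars) {
  stopifnot(length(chars) == length(pattern_chars))
  ok <- (pattern_chars == "N") |
    (chars == pattern_chars) |
    (pattern_chars == "H" & chars %in% c("A", "C", "U"))
  sum(!ok)
}

# constrained (non-N) positions of a pattern
n_constrained <- function(pattern) sum(seq_chars(pattern) != "N")

check_pattern_alphabet <- function(pattern, what = "pattern") {
  if (grepl("[^ACGUNH]", pattern)) {
    abort(sprintf("%s may only contain A, C, G, U, N, H: got '%s'",
                  what, pattern))
  }
  invisible(pattern)
}

#' GC content of a sequence
#'
#' @param x a normalized nucleotide string.
#' @return Fraction of G+C among non-N residues, in [0, 1].
#' @export
gc_fraction <- function(x) {
  ch <- seq_chars(normalize_residues(x))
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) abort("cannot compute GC of an empty/all-N sequence")
  mean(ch %in% c("G", "C"))
}

# i.i.d. random sequence at a given GC fraction (uses the session RNG)
random_seq <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  paste(sample(c("G", "C", "A", "U"), n, replace = TRUE, prob = p),
        collapse = "")
}

# draw a random base excluding some set
random_base_not <- function(exclude) {
  pool <- setdiff(c("A", "C", "G", "U"), exclude)
  sample(pool, 1L)
}

#' Dinucleotide shuffle
#'
#' Permutes a sequence while preserving its exact dinucleotide composition
#' (random Eulerian-path shuffle of the dinucleotide multigraph). Used to
#' build composition-matched controls for self-pairedness comparisons.
#'
#' @param x a normalized nucleotide string (length >= 2).
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(x) {
  ch <- seq_chars(normalize_residues(x))
  n <- length(ch)
  if (n < 3L) return(paste(ch, collapse = ""))
  # edge list of the dinucleotide multigraph
  from <- ch[-n]
  to <- ch[-1L]
  last <- ch[n]
  # For each vertex, shuffle its out-edges, but force a spanning arborescence
  # into the last vertex so the walk is Eulerian (Altschul-Erickson).
  verts <- unique(ch)
  repeat {
    out_edges <- lapply(verts, function(v) sample(to[from == v]))
    names(out_edges) <- verts
    # last out-edge of every non-terminal vertex must reach `last` via the
    # chain of last edges; test connectivity of the "last edge" subgraph
    lastedge <- vapply(verts, function(v) {
      e <- out_edges[[v]]
      if (length(e)) e[length(e)] else NA_character_
    }, character(1))
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v
      seen <- character(0)
      while (!is.na(lastedge[[cur]]) && !(cur %in% seen) && cur != last) {
        seen <- c(seen, cur)
        cur <- lastedge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # walk the graph
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  walk <- character(n)
  walk[1L] <- ch[1L]
  cur <- ch[1L]
  for (i in 2:n) {
    nxt <- out_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    walk[i] <- nxt
    cur <- nxt
  }
  paste(walk, collapse = "")
}
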