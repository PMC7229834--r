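# Maximum base-pairing secondary structure (Nussinov-style dynamic
# programming). Deliberately non-thermodynamic: it maximizes the number of
# nested Watson-Crick + G.U pairs, providing an exactly-solvable
# self-pairedness metric in place of free-energy folding.

nussinov_matrix <- function(ch, min_loop = 3L, gu = TRUE) {
  n <- length(ch)
  M <- matrix(0L, n + 1L, max(n, 1L))
  if (n < min_loop + 2L) return(M)
  for (d in seq(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- M[i + 1L, j]
      ks <- (i + min_loop + 1L):j
      pk <- ks[can_pair(rep(ch[i], length(ks)), ch[ks], gu)]
      if (length(pk)) {
        cand <- M[i + 1L, pk - 1L] + 1L + M[cbind(pk + 1L, j)]
        best <- max(best, cand)
      }
      M[i, j] <- best
    }
  }
  M
}

nussinov_traceback <- function(M, ch, min_loop, gu) {
  pairs <- list()
  stack <- list(c(1L, length(ch)))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    ks <- (i + min_loop + 1L):j
    pk <- ks[can_pair(rep(ch[i], length(ks)), ch[ks], gu)]
    for (k in pk) {
      if (M[i + 1L, k - 1L] + 1L + M[k + 1L, j] == M[i, j]) {
        pairs[[length(pairs) + 1L]] <- c(i, k)
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  pairs
}

#' Maximum base-pairing fold of a linear or circular RNA
#'
#' Computes a nested pair set of maximum cardinality under Watson-Crick
#' (plus optional G.U) pairing by dynamic programming. Circular sequences
#' are evaluated as the best linear fold over all cut points.
#'
#' @param seq nucleotide string (alphabet \{A,C,G,U\} after normalization).
#' @param circular treat the sequence as circular.
#' @param min_loop minimum unpaired nucleotides enclosed by a pair
#'   (default 3).
#' @param gu count G.U as a pair (default TRUE).
#' @return An object of class `pair_set`: list with `pairs` (tibble of
#'   1-based index pairs i < j), `n`, `circular`, `min_loop` and, for
#'   circular folds, the chosen `cut`.
#' @export
max_pairing_fold <- function(seq, circular = FALSE, min_loop = 3L,
                             gu = TRUE) {
  seq <- normalize_residues(seq)
  if (grepl("N", seq, fixed = TRUE)) {
    abort("max_pairing_fold requires an unambiguous {A,C,G,U} sequence")
  }
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n == 0L) abort("cannot fold an empty sequence")
  rotations <- if (circular) 0:(n - 1L) else 0L
  best_count <- -1L; best_rot <- 0L; best_M <- NULL; best_ch <- ch
  for (r in rotations) {
    chr <- if (r == 0L) ch else c(ch[(r + 1L):n], ch[1:r])
    M <- nussinov_matrix(chr, min_loop, gu)
    cnt <- M[1L, n]
    if (cnt > best_count) {
      best_count <- cnt; best_rot <- r; best_M <- M; best_ch <- chr
    }
  }
  raw <- nussinov_traceback(best_M, best_ch, min_loop, gu)
  if (length(raw)) {
    ij <- do.call(rbind, raw)
    # map rotated indices back to the original sequence
    orig <- ((ij - 1L + best_rot) %% n) + 1L
    pairs <- tibble(i = pmin(orig[, 1], orig[, 2]),
                    j = pmax(orig[, 1], orig[, 2]))
    pairs <- dplyr::arrange(pairs, .data$i)
  } else {
    pairs <- tibble(i = integer(), j = integer())
  }
  structure(list(pairs = pairs, n = n, circular = circular,
                 min_loop = as.integer(min_loop), gu = gu,
                 cut = best_rot),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs on %d nt (%s, min_loop %d)\n",
              nrow(x$pairs), x$n, if (x$circular) "circular" else "linear",
              x$min_loop))
  invisible(x)
}

#' Self-pairedness of a sequence
#'
#' Fraction of nucleotides engaged in the maximum base-pairing fold:
#' 2 |pairs| / n.
#'
#' @inheritParams max_pairing_fold
#' @return Fraction in [0, 1].
#' @export
self_pairedness <- function(seq, circular = FALSE, min_loop = 3L,
                            gu = TRUE) {
  fold <- max_pairing_fold(seq, circular = circular, min_loop = min_loop,
                           gu = gu)
  2 * nrow(fold$pairs) / fold$n
}

#' Dot-bracket string of a pair set
#'
#' @param fold a `pair_set` from [max_pairing_fold()].
#' @return A dot-bracket string (nested pairs only, so one bracket level
#'   suffices).
#' @export
dot_bracket <- function(fold) {
  stopifnot(inherits(fold, "pair_set"))
  db <- rep(".", fold$n)
  db[fold$pairs$i] <- "("
  db[fold$pairs$j] <- ")"
  paste(db, collapse = "")
}
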