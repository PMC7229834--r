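# Independent reference implementations used as oracles. Each is written as
# a direct transcription of the defining recurrence/enumeration, sharing no
# code path with the package internals it checks.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# ---- global alignment oracle (match +1, mismatch 0, gap -1) ----------------
# Full Needleman-Wunsch table; traceback counts matches and alignment columns.
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                             S[i, j + 1] - 1,
                             S[i + 1, j] - 1)
    }
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(identity = matches / cols, score = S[n + 1, m + 1])
}

# ---- max-pairing oracles ---------------------------------------------------
pair_ok_oracle <- function(x, y, gu = TRUE) {
  p <- paste0(x, y)
  p %in% c("AU", "UA", "GC", "CG", if (gu) c("GU", "UG"))
}

# top-down memoized maximum over "i unpaired / i paired with k"
max_pairs_memo_oracle <- function(seq, min_loop = 3L, gu = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pair_ok_oracle(ch[i], ch[k], gu)) {
        best <- max(best, f(i + 1L, k - 1L) + 1L + f(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  f(1L, length(ch))
}

# Explicit enumeration of every nested structure (no memoization): the
# recursion tree visits each nested pair set once. Tiny n only.
max_pairs_exhaustive_oracle <- function(seq, min_loop = 3L, gu = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pair_ok_oracle(ch[i], ch[k], gu)) {
        best <- max(best, f(i + 1L, k - 1L) + 1L + f(k + 1L, j))
      }
    }
    best
  }
  f(1L, length(ch))
}

# ---- kinetics grid oracle --------------------------------------------------
# dense 2-D grid search over (k, F_inf); no profiling, no 1-D reduction
kinetics_grid_oracle <- function(t, f, n_k = 2000L, n_F = 200L) {
  sweep_grid <- function(ks, Fs) {
    best <- c(rss = Inf, k = NA, F_inf = NA)
    G <- outer(ks, t, function(k, t) 1 - exp(-k * t))  # n_k x n_t
    for (Fi in Fs) {
      rss <- rowSums((matrix(f, length(ks), length(f), byrow = TRUE) -
                        Fi * G)^2)
      i <- which.min(rss)
      if (rss[i] < best["rss"]) best <- c(rss = rss[i], k = ks[i], F_inf = Fi)
    }
    best
  }
  ks <- exp(seq(log(1e-4), log(10), length.out = n_k))
  Fs <- seq(0.005, 1.05, length.out = n_F)
  best <- sweep_grid(ks, Fs)
  # refine around the coarse optimum (still pure grid search)
  dk <- log(10 / 1e-4) / (n_k - 1)
  dF <- (1.05 - 0.005) / (n_F - 1)
  for (rep in 1:3) {
    ks2 <- exp(seq(log(best[["k"]]) - 2 * dk, log(best[["k"]]) + 2 * dk,
                   length.out = 81L))
    Fs2 <- seq(max(0, best[["F_inf"]] - 2 * dF),
               min(1.05, best[["F_inf"]] + 2 * dF), length.out = 81L)
    best <- sweep_grid(ks2, Fs2)
    dk <- 4 * dk / 80
    dF <- 4 * dF / 80
  }
  best
}

# ---- independent matcher for a reduced descriptor --------------------------
# Straight expand.grid over all element lengths at every offset; each
# complete assignment is validated with plain string operations (strict
# Watson-Crick, no wobble). Only valid for type I descriptors with
# allow_gu_wobble = FALSE and allow_helix2_base_mismatch = FALSE.
reduced_descriptor <- function() {
  hhr_descriptor(
    topology = "I",
    helix_ranges = list(helix1 = c(3L, 4L), helix2 = c(3L, 3L),
                        helix3 = c(2L, 2L)),
    loop_ranges = list(loop1 = c(3L, 3L), loop2 = c(4L, 5L),
                       loop3 = c(3L, 3L)),
    helix1_internal_loop = c(0L, 1L),
    allow_gu_wobble = FALSE,
    allow_helix2_base_mismatch = FALSE
  )
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

match_spans_oracle <- function(seq, d) {
  n <- nchar(seq)
  sub <- function(s, len) if (len == 0) "" else substr(seq, s, s + len - 1)
  grid <- expand.grid(h1 = d$helix_ranges$helix1[1]:d$helix_ranges$helix1[2],
                      il1a = d$helix1_internal_loop[1]:d$helix1_internal_loop[2],
                      il1b = d$helix1_internal_loop[1]:d$helix1_internal_loop[2],
                      h2 = d$helix_ranges$helix2[1]:d$helix_ranges$helix2[2],
                      l2 = d$loop_ranges$loop2[1]:d$loop_ranges$loop2[2],
                      h3 = d$helix_ranges$helix3[1]:d$helix_ranges$helix3[2],
                      l3 = d$loop_ranges$loop3[1]:d$loop_ranges$loop3[2])
  box_match <- function(s, pattern) {
    if (nchar(s) != nchar(pattern)) return(FALSE)
    sc <- strsplit(s, "")[[1]]; pc <- strsplit(pattern, "")[[1]]
    all(pc == "N" | sc == pc | (pc == "H" & sc %in% c("A", "C", "U")))
  }
  out <- list()
  for (start in 1:n) {
    for (g in seq_len(nrow(grid))) {
      with(grid[g, ], {
        p <- start
        h1a <- sub(p, h1); p <- p + h1
        il1a_s <- sub(p, il1a); p <- p + il1a
        box1 <- sub(p, 7); p <- p + 7
        h2a <- sub(p, h2); p <- p + h2
        loop2 <- sub(p, l2); p <- p + l2
        h2b <- sub(p, h2); p <- p + h2
        box2 <- sub(p, 5); p <- p + 5
        h3a <- sub(p, h3); p <- p + h3
        loop3 <- sub(p, l3); p <- p + l3
        h3b <- sub(p, h3); p <- p + h3
        nuh <- sub(p, 3); p <- p + 3
        il1b_s <- sub(p, il1b); p <- p + il1b
        h1b <- sub(p, h1); p <- p + h1
        if (p - 1 <= n &&
            box_match(box1, d$box1) && box_match(box2, d$box2) &&
            box_match(nuh, d$cleavage_context) &&
            h1b == rc_oracle(h1a) && h2b == rc_oracle(h2a) &&
            h3b == rc_oracle(h3a)) {
          out[[length(out) + 1L]] <<- c(start = start - 1L, end = p - 1L)
        }
      })
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  unique(data.frame(
    start = vapply(out, function(x) as.integer(x[["start"]]), integer(1)),
    end = vapply(out, function(x) as.integer(x[["end"]]), integer(1))))
}
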