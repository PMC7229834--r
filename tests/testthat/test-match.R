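test_that("planted motifs are matched at the planted span for every topology", {
  for (topo in c("I", "II", "III")) {
    d <- default_descriptor(topo, "canonical")
    built <- build_hhr_sequence(d, hhr_variant_spec(), seed = 11)
    hits <- match_at(built$sequence, 0, d)
    expect_gt(nrow(hits), 0)
    expect_true(any(hits$start == 0 & hits$end == nchar(built$sequence)))
    expect_true(all(hits$topology == topo))
  }
})

test_that("a point mutation in box1 abolishes matching", {
  d <- default_descriptor("I", "canonical")
  built <- build_hhr_sequence(d, hhr_variant_spec(), seed = 3)
  seq <- built$sequence
  box1 <- built$annotation[built$annotation$element == "box1", ]
  # the invariant G at box1 position 3 (CUGANGA) -> C
  pos <- box1$start + 3L  # 1-based index of box1's 3rd residue
  expect_equal(substr(seq, pos, pos), "G")
  mutated <- seq
  substr(mutated, pos, pos) <- "C"
  expect_equal(nrow(match_at(mutated, 0, d)), 0L)
})

test_that("match_at equals an independent exhaustive validator on random sequences", {
  d <- reduced_descriptor()
  spec <- hhr_variant_spec(helix1_bp = 3L, helix2_bp = 3L, helix3_bp = 2L,
                           il1a_len = 1L, il1b_len = 1L, loop2_len = 4L,
                           loop3_len = 3L, tertiary_on = FALSE)
  for (s in 1:8) {
    set.seed(s)
    built <- build_hhr_sequence(d, spec)
    seq <- paste0(random_rna(40), built$sequence, random_rna(40))
    got <- purrr::map_dfr(0:(nchar(seq) - 1), function(o) {
      match_at(seq, o, d, annotate = FALSE)[, c("start", "end")]
    })
    got <- unique(as.data.frame(got))
    want <- match_spans_oracle(seq, d)
    expect_equal(got[order(got$start, got$end), ],
                 want[order(want$start, want$end), ],
                 ignore_attr = TRUE)
    expect_gt(nrow(want), 0)  # the planted motif is found by both routes
  }
})

test_that("tertiary contact checking counts constrained positions", {
  d <- default_descriptor("I", "canonical")
  built <- build_hhr_sequence(d, hhr_variant_spec(tertiary_on = TRUE),
                              seed = 5)
  hits <- match_at(built$sequence, 0, d)
  best <- hits[which.max(hits$total_bp), ]
  tc <- check_tertiary_contacts(best, d$tertiary_rule)
  expect_true(tc$tertiary_ok)
  expect_equal(tc$tertiary_matches, 6L)  # UG + GUGA fully planted

  built_off <- build_hhr_sequence(d, hhr_variant_spec(tertiary_on = FALSE),
                                  seed = 5)
  hits_off <- match_at(built_off$sequence, 0, d)
  best_off <- hits_off[which.max(hits_off$total_bp), ]
  tc_off <- check_tertiary_contacts(best_off, d$tertiary_rule)
  expect_false(tc_off$tertiary_ok)
  expect_equal(tc_off$tertiary_matches, 0L)  # actively avoided by generator

  relaxed <- tertiary_rule(min_matches = 0L)
  expect_true(check_tertiary_contacts(best_off, relaxed)$tertiary_ok)
})

test_that("feature extraction reads helix III, tetraloop and helix II base", {
  d <- default_descriptor("I", "canonical")
  amex1 <- build_hhr_sequence(
    d, hhr_variant_spec(helix3_bp = 1L, palindromic_tetraloop = TRUE),
    seed = 21)
  h <- match_at(amex1$sequence, 0, d)
  h <- h[which.max(h$total_bp), ]
  f <- extract_features(h)
  expect_equal(f$helix3_bp, 1L)
  expect_true(f$helix3_loop_is_palindromic_tetraloop)

  amex2 <- build_hhr_sequence(
    d, hhr_variant_spec(helix3_bp = 2L, helix2_mismatch = TRUE), seed = 22)
  h2 <- match_at(amex2$sequence, 0, d)
  h2 <- h2[which.max(h2$total_bp), ]
  f2 <- extract_features(h2)
  expect_equal(f2$helix3_bp, 2L)
  expect_true(f2$helix2_base_mismatch)

  plain <- build_hhr_sequence(
    d, hhr_variant_spec(helix3_bp = 3L, loop3_len = 6L), seed = 23)
  h3 <- match_at(plain$sequence, 0, d)
  h3 <- h3[which.max(h3$total_bp), ]
  f3 <- extract_features(h3)
  expect_equal(f3$helix3_bp, 3L)
  expect_false(f3$helix3_loop_is_palindromic_tetraloop)
})

test_that("cleavage mode prediction follows helix III strength and contacts", {
  feats <- tibble::tibble(
    helix3_bp = c(1L, 2L, 3L, 3L),
    tertiary_ok = c(TRUE, FALSE, TRUE, FALSE),
    helix2_base_mismatch = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(predict_cleavage_mode(feats),
               c("dimer_required", "weak", "monomer_competent", "weak"))
})

test_that("canonical-variant hits satisfy the descriptor's tertiary rule", {
  d <- default_descriptor("I", "canonical")
  set.seed(404)
  for (i in 1:5) {
    built <- build_hhr_sequence(d, hhr_variant_spec())
    hits <- match_at(built$sequence, 0, d)
    canon <- hits[hits$variant == "canonical", ]
    if (nrow(canon)) {
      expect_true(all(check_tertiary_contacts(canon, d$tertiary_rule)$tertiary_ok))
    }
  }
})

test_that("cleavage site sits immediately 3' of the NUH triplet", {
  d <- default_descriptor("I", "canonical")
  built <- build_hhr_sequence(d, hhr_variant_spec(), seed = 9)
  hits <- match_at(built$sequence, 0, d)
  best <- hits[which.max(hits$total_bp), ]
  nuh_span <- best$segments[[1]][["nuh"]]
  expect_equal(best$cleavage_site, nuh_span[2])
  expect_equal(substr(built$sequence, nuh_span[1] + 2L, nuh_span[1] + 2L),
               "U")
})
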