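test_that("species profiles encode the study organisms' repeat landscapes", {
  coral <- species_profile("coral")
  expect_equal(diff(sort(coral$monomer_lengths)), 20L)
  expect_equal(coral$indel_length, 20L)
  expect_equal(coral$copy_range, c(2L, 62L))
  expect_true(coral$hhr_variant_spec$tertiary_on)

  mussel <- species_profile("mussel")
  expect_equal(range(mussel$monomer_lengths), c(350L, 390L))
  expect_false(mussel$hhr_variant_spec$tertiary_on)

  ax1 <- species_profile("axolotl_1")
  ax2 <- species_profile("axolotl_2")
  expect_equal(c(ax1$monomer_lengths, ax2$monomer_lengths), c(330L, 350L))
  expect_equal(ax1$hhr_variant_spec$helix3_bp, 1L)
  expect_true(ax1$hhr_variant_spec$palindromic_tetraloop)
  expect_equal(ax2$hhr_variant_spec$helix3_bp, 2L)
  expect_true(ax2$hhr_variant_spec$helix2_mismatch)

  for (p in list(coral, mussel, ax1, ax2)) {
    expect_lt(p$gc_monomer, 0.45)
    expect_gte(p$copy_range[1], 2L)
    expect_true(all(p$monomer_lengths >= 150 & p$monomer_lengths <= 450))
  }
  expect_error(species_profile("salamander"), "unknown")
})

test_that("built HHR sequences are matcher-guaranteed and seed-deterministic", {
  d <- default_descriptor("I", "canonical")
  a <- build_hhr_sequence(d, hhr_variant_spec(), seed = 6)
  b <- build_hhr_sequence(d, hhr_variant_spec(), seed = 6)
  expect_identical(a, b)
  spec1 <- hhr_variant_spec(helix3_bp = 1L, palindromic_tetraloop = TRUE)
  built <- build_hhr_sequence(d, spec1, seed = 7)
  hits <- match_at(built$sequence, 0, d)
  best <- hits[which.max(hits$total_bp), ]
  expect_equal(classify_topology(best), "I")
  f <- extract_features(best)
  expect_equal(f$helix3_bp, 1L)
  expect_true(f$helix3_loop_is_palindromic_tetraloop)
  expect_error(
    build_hhr_sequence(d, hhr_variant_spec(helix3_bp = 9L)),
    "outside")
})

test_that("generated genomes are byte-identical under one seed", {
  p <- species_profile("coral")
  a <- generate_genome(p, n_loci = 3, background_length = 30000, seed = 123,
                       copy_range = c(2, 5))
  b <- generate_genome(p, n_loci = 3, background_length = 30000, seed = 123,
                       copy_range = c(2, 5))
  expect_identical(a$genome$residues, b$genome$residues)
  expect_identical(a$truth, b$truth)
  c2 <- generate_genome(p, n_loci = 3, background_length = 30000, seed = 124,
                        copy_range = c(2, 5))
  expect_false(identical(a$genome$residues, c2$genome$residues))
})

test_that("truth tables respect contig bounds and non-overlap", {
  g <- generate_genome(species_profile("mussel"), n_loci = 5,
                       background_length = 80000, seed = 3,
                       copy_range = c(2, 6))
  tr <- g$truth
  expect_equal(nrow(tr), 5L)
  expect_true(all(tr$start >= 0 & tr$end <= g$genome$length))
  expect_true(all(tr$end - tr$start == tr$monomer_length * tr$copies))
  o <- order(tr$start)
  expect_true(all(tr$start[o][-1] >= tr$end[o][-nrow(tr)]))
})

test_that("background GC converges to the profile parameter", {
  p <- species_profile("coral")
  g <- generate_genome(p, n_loci = 1, background_length = 100000, seed = 55,
                       copy_range = c(2, 2))
  tr <- g$truth
  bg <- paste0(substr(g$genome$residues, 1, tr$start - 10),
               substr(g$genome$residues, tr$end + 10, g$genome$length))
  expect_lt(abs(gc_fraction(bg) - p$gc_background), 0.02)
})

test_that("full pipeline on generator output has perfect recall and precision", {
  g <- generate_genome(list(species_profile("coral"),
                            species_profile("axolotl_2")),
                       n_loci = c(3, 2), background_length = 90000,
                       seed = 42, copy_range = c(2, 6))
  res <- call_loci(g$genome, scan_genome(g$genome, g$descriptor))
  rz <- res[res$classification == "retrozyme", ]
  expect_equal(nrow(rz), nrow(g$truth))                      # recall = 1
  expect_equal(nrow(res), nrow(g$truth))                     # precision = 1
  expect_equal(sort(rz$start), sort(g$truth$start))
  expect_equal(sort(rz$end), sort(g$truth$end))
  m <- match(rz$start, g$truth$start)
  expect_equal(rz$monomer_period, as.numeric(g$truth$monomer_length[m]))
  expect_equal(rz$copy_number, g$truth$copies[m])
  expect_equal(rz$strand, g$truth$strand[m])
  # family count equals number of distinct planted profiles
  expect_equal(length(unique(rz$family_id)),
               length(unique(g$truth$family_label)))
})

test_that("capacity errors fire when loci cannot be placed", {
  expect_error(generate_genome(species_profile("coral"), n_loci = 50,
                               background_length = 5000, seed = 1),
               "too small")
})

test_that("decoy kinds behave as designed", {
  d <- default_descriptor("I", "canonical")
  sh <- make_decoys("shuffled_core", 3, seed = 61)
  br <- make_decoys("broken_helix", 3, seed = 62)
  for (s in c(sh, br)) expect_equal(nrow(scan_genome(c(x = s), d)), 0L)
  iso <- make_decoys("isolated_hhr", 2, seed = 63)
  hits <- scan_genome(iso, d)
  expect_equal(nrow(hits), 2L)
  genome <- tibble::tibble(contig = names(iso), residues = unname(iso),
                           length = nchar(iso))
  loci <- call_loci(genome, hits)
  expect_true(all(loci$classification == "isolated_hhr"))
  expect_identical(make_decoys("shuffled_core", 3, seed = 61), sh)
  expect_error(make_decoys("shuffled_core", 0), "n must")
})
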