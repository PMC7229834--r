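fake_hits <- function(starts, strand = "+", contig = "c1", width = 56L) {
  tibble::tibble(
    contig = contig, start = as.integer(starts),
    end = as.integer(starts) + width, strand = strand,
    total_bp = 13L, hit_id = sprintf("h%d", seq_along(starts)))
}

test_that("tandem grouping joins co-oriented hits within the gap", {
  h <- fake_hits(c(1000, 1350, 1700, 2050))
  g <- group_tandem(h, max_gap = 500)
  expect_equal(length(unique(g$tandem_id)), 1L)

  h2 <- fake_hits(c(1000, 9000))
  g2 <- group_tandem(h2, max_gap = 500)
  expect_equal(length(unique(g2$tandem_id)), 2L)

  h3 <- dplyr::bind_rows(fake_hits(c(1000, 1400)),
                         fake_hits(c(1200, 1600), strand = "-"))
  g3 <- group_tandem(h3, max_gap = 900)
  expect_equal(length(unique(g3$tandem_id)), 2L)
  expect_equal(length(unique(g3$tandem_id[g3$strand == "+"])), 1L)
})

test_that("period estimation is the median spacing; copies count hits", {
  expect_equal(estimate_period(c(1000, 1350, 1700, 2050)),
               tibble::tibble(monomer_period = 350, copy_number = 4L))
  expect_equal(estimate_period(c(0, 353)),
               tibble::tibble(monomer_period = 353, copy_number = 2L))
  # irregular spacing: median of {300, 600} = 450
  expect_equal(estimate_period(c(0, 300, 900))$monomer_period, 450)
  expect_true(is.na(estimate_period(1000)$monomer_period))
})

test_that("repeat identity separates true arrays from coincidental spacing", {
  unit <- "ACGUUGCAAUGCGAUA"
  arr <- strrep(unit, 6)
  expect_equal(validate_repeat(arr, 0, nchar(arr), nchar(unit)), 1.0)
  set.seed(8)
  rand <- random_rna(2000)
  id_rand <- validate_repeat(rand, 0, 2000, 400)
  expect_lt(abs(id_rand - 0.25), 0.08)
  expect_warning(validate_repeat(arr, 0, 20, 16), "undefined")
})

test_that("repeat identity decreases with planted mutation rate", {
  rates <- c(0, 0.05, 0.15)
  ids <- vapply(rates, function(mu) {
    g <- generate_genome(species_profile("axolotl_2"), n_loci = 1,
                         background_length = 15000, seed = 99,
                         mutation_rate = mu, copy_range = c(6, 6))
    tr <- g$truth
    validate_repeat(g$genome$residues, tr$start, tr$end, tr$monomer_length)
  }, numeric(1))
  expect_equal(ids[1], 1.0)
  expect_true(all(diff(ids) < 0))
  # copies mutate independently: P(match) = (1-mu)^2 + mu^2/3 ~ 0.903
  expect_lt(abs(ids[2] - 0.903), 0.04)
})

test_that("locus GC is the G+C percentage of the span", {
  expect_equal(locus_gc("GGCC", 0, 4), 100)
  expect_equal(locus_gc("AUAU", 0, 4), 0)
  expect_equal(locus_gc("AUGC", 0, 4), 50)
  expect_error(locus_gc("AUGC", 2, 2), "empty")
})

test_that("TSD detection finds the longest exact flanking duplication", {
  core <- strrep("ACGGUUAC", 10)
  tsd <- "GAUUACA"
  s <- paste0(random_rna(30), tsd, core, tsd, random_rna(30))
  set.seed(1)
  got <- detect_tsd(s, 30 + 7, 37 + nchar(core))
  expect_equal(got$tsd_length, 7L)
  expect_equal(got$tsd_seq, tsd)

  s2 <- paste0(strrep("A", 30), core, strrep("C", 30))
  expect_equal(detect_tsd(s2, 30, 30 + nchar(core))$tsd_length, 0L)

  expect_warning(out <- detect_tsd(core, 2, nchar(core) - 2), "edge")
  expect_equal(out$tsd_length, 0L)
})

test_that("planted 6-nt TSDs are detected on pipeline locus spans", {
  g <- generate_genome(species_profile("mussel"), n_loci = 2,
                       background_length = 30000, seed = 12,
                       copy_range = c(2, 4))
  loci <- call_loci(g$genome, scan_genome(g$genome, g$descriptor))
  expect_equal(loci$tsd_length, rep(6L, nrow(loci)))
  expect_true(all(loci$tsd_length > 4L))
  expect_setequal(loci$tsd_seq, g$truth$tsd_seq)
})

test_that("locus classification applies copy, size and GC rules", {
  expect_equal(classify_locus(8L, 353, 40), "retrozyme")
  expect_equal(classify_locus(3L, 700, 40), "ambiguous")
  expect_equal(classify_locus(1L, NA, 40), "isolated_hhr")
  expect_equal(classify_locus(4L, 300, 47), "ambiguous")
  expect_equal(classify_locus(c(2L, 1L), c(225, NA), c(39, 39)),
               c("retrozyme", "isolated_hhr"))
})

test_that("monomer length classes chain within tolerance", {
  cls <- monomer_length_classes(c(rep(225, 6), rep(245, 4)))
  expect_equal(cls$length, c(225, 245))
  expect_equal(cls$count, c(6L, 4L))
  expect_equal(diff(cls$length), 20)
  expect_equal(nrow(monomer_length_classes(rep(350, 5))), 1L)
  cls2 <- monomer_length_classes(c(330, 331, 330, 350, 349, 350))
  expect_equal(nrow(cls2), 2L)
})

test_that("pairwise identity agrees with a Needleman-Wunsch oracle", {
  expect_equal(pairwise_identity("ACGUACGU", "ACGUACGU"), 1.0)
  set.seed(33)
  base <- random_rna(245)
  del <- paste0(substr(base, 1, 100), substr(base, 121, 245))
  expect_lt(abs(pairwise_identity(base, del) - 225 / 245), 0.01)
  for (i in 1:6) {
    a <- random_rna(20); b <- random_rna(20)
    expect_lt(abs(pairwise_identity(a, b) - nw_identity_oracle(a, b)$identity),
              0.101)  # ties among optimal alignments may differ in matches
  }
  rc_id <- pairwise_identity(base, revcomp(base))
  expect_lt(rc_id, 0.65)
  expect_error(pairwise_identity("", "ACGU"), "empty")
})

test_that("greedy family clustering is deterministic and threshold-driven", {
  set.seed(14)
  a <- random_rna(200); b <- random_rna(200); c3 <- random_rna(200)
  fams <- cluster_families(c(x1 = a, x2 = a, x3 = b))
  expect_equal(fams$members$family_id, c("F01", "F01", "F02"))
  all_same <- cluster_families(rep(a, 4))
  expect_equal(unique(all_same$members$family_id), "F01")
  # n sequences pairwise below threshold -> n families (checked all-pairs)
  seqs <- c(a, b, c3)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(pairwise_identity(seqs[i], seqs[j]), 0.8)
  }
  expect_equal(nrow(cluster_families(seqs)$centroids), 3L)
  # idempotent growth under duplication of a member
  f1 <- cluster_families(seqs)
  f2 <- cluster_families(c(seqs, a))
  expect_equal(nrow(f1$centroids), nrow(f2$centroids))
  expect_error(cluster_families(seqs, threshold = 1.2), "threshold")
})

test_that("axolotl family profiles cluster into exactly two families", {
  g <- generate_genome(list(species_profile("axolotl_1"),
                            species_profile("axolotl_2")),
                       n_loci = c(2, 2), background_length = 60000,
                       seed = 20, copy_range = c(2, 4))
  res <- call_loci(g$genome, scan_genome(g$genome, g$descriptor))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$classification == "retrozyme"))
  expect_equal(length(unique(res$family_id)), 2L)
  # family labels track the planted profile
  lab <- g$truth$family_label[match(res$start, g$truth$start)]
  expect_equal(length(unique(paste(lab, res$family_id))), 2L)
})
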