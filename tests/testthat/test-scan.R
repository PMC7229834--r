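write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

test_that("FASTA reading normalizes case and alphabet, preserves order", {
  path <- write_temp_fasta(c(">chr1 description", "ACGTac", "gtAC",
                             ">chr2", "UUUU"))
  g <- read_fasta(path)
  expect_equal(g$contig, c("chr1", "chr2"))
  expect_equal(g$residues, c("ACGUACGUAC", "UUUU"))
  expect_equal(g$length, c(10L, 4L))
  unlink(path)
})

test_that("FASTA format errors are reported", {
  bad <- write_temp_fasta(c(">chr1", "ACGXGT"))
  expect_error(read_fasta(bad), "illegal")
  unlink(bad)
  expect_error(read_fasta(tempfile()), "no such file")
  empty <- write_temp_fasta(character(0))
  expect_error(read_fasta(empty), "")
  unlink(empty)
})

test_that("scanning a synthetic genome recovers exactly the planted hits", {
  g <- generate_genome(species_profile("coral"), n_loci = 3,
                       background_length = 40000, seed = 7,
                       copy_range = c(2, 4))
  hits <- scan_genome(g$genome, g$descriptor)
  truth_starts <- sort(unlist(g$truth$hhr_starts))
  expect_equal(nrow(hits), sum(g$truth$copies))
  expect_equal(sort(hits$start), truth_starts)
  # strands agree with the planted orientation
  by_locus <- purrr::map2_chr(g$truth$hhr_starts, g$truth$strand,
                              function(st, sd) sd)
  expect_setequal(unique(hits$strand), unique(g$truth$strand))
})

test_that("decoys with shuffled cores or broken helices add no hits", {
  g <- generate_genome(species_profile("coral"), n_loci = 3,
                       background_length = 40000, seed = 7,
                       copy_range = c(2, 4))
  d <- g$descriptor
  n_true <- sum(g$truth$copies)
  decoys <- c(make_decoys("shuffled_core", 2, seed = 13),
              make_decoys("broken_helix", 1, seed = 14))
  # decoys verified unmatched by the exhaustive reference scanner
  for (dec in decoys) expect_equal(nrow(brute_force_scan(dec, d)), 0L)
  genome2 <- tibble::tibble(
    contig = c(g$genome$contig, names(decoys)),
    residues = c(g$genome$residues, unname(decoys)),
    length = nchar(c(g$genome$residues, unname(decoys))))
  hits2 <- scan_genome(genome2, d)
  expect_equal(nrow(hits2), n_true)
})

test_that("an empty genome yields an empty, well-formed hit table", {
  d <- default_descriptor("I", "canonical")
  empty <- tibble::tibble(contig = character(), residues = character(),
                          length = integer())
  hits <- scan_genome(empty, d)
  expect_equal(nrow(hits), 0L)
  expect_true(all(c("contig", "start", "end", "strand", "topology",
                    "variant", "predicted_mode") %in% names(hits)))
})

test_that("the reference scanner refuses long input and handles trivial ones", {
  d <- default_descriptor("I", "canonical")
  expect_error(brute_force_scan(strrep("A", 2000), d), "1000")
  expect_equal(nrow(brute_force_scan(strrep("A", 200), d)), 0L)
})

test_that("anchored scanning equals exhaustive enumeration, including N windows", {
  d <- default_descriptor("I", "canonical")
  set.seed(2024)
  for (i in 1:10) {
    s <- random_rna(300)
    if (i > 7) {
      # plant a motif so the equality is exercised on non-empty hit sets
      hhr <- build_hhr_sequence(d, hhr_variant_spec())$sequence
      s <- paste0(substr(s, 1, 100), hhr, substr(s, 101, 300 - nchar(hhr)))
    }
    if (i %% 3 == 0) substr(s, 150, 152) <- "NNN"
    a <- scan_genome(c(seq = s), d)
    b <- brute_force_scan(s, d, contig = "seq")
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("scanning is strand-symmetric", {
  d <- default_descriptor("I", "canonical")
  set.seed(5)
  hhr <- build_hhr_sequence(d, hhr_variant_spec())$sequence
  s <- paste0(random_rna(90), hhr, random_rna(110))
  L <- nchar(s)
  fwd <- scan_genome(c(x = s), d)
  rc <- scan_genome(c(x = revcomp(s)), d)
  expect_equal(nrow(fwd), nrow(rc))
  expect_setequal(L - fwd$end, rc$start)
  expect_setequal(L - fwd$start, rc$end)
  expect_setequal(rc$strand, chartr("+-", "-+", fwd$strand))
})

test_that("scan output is deterministic and sorted", {
  g <- generate_genome(species_profile("axolotl_1"), n_loci = 2,
                       background_length = 25000, seed = 31,
                       copy_range = c(2, 3))
  h1 <- scan_genome(g$genome, g$descriptor)
  h2 <- scan_genome(g$genome, g$descriptor)
  expect_identical(h1, h2)
  expect_false(is.unsorted(h1$start))
})

test_that("hit BED and GFF3 exports round-trip coordinates", {
  g <- generate_genome(species_profile("coral"), n_loci = 2,
                       background_length = 30000, seed = 17,
                       copy_range = c(2, 3))
  hits <- scan_genome(g$genome, g$descriptor)
  bed <- tempfile(fileext = ".bed"); gff <- tempfile(fileext = ".gff3")
  write_hits_bed(hits, bed)
  write_hits_gff3(hits, gff)
  bed_df <- utils::read.table(bed, sep = "\t")
  expect_equal(nrow(bed_df), nrow(hits))
  expect_equal(bed_df$V2, hits$start)
  expect_equal(bed_df$V3, hits$end)
  gr <- rtracklayer::import(gff)
  expect_equal(length(gr), nrow(hits))
  # GFF3 is 1-based closed
  expect_equal(BiocGenerics::start(gr), hits$start + 1L)
  expect_equal(BiocGenerics::end(gr), hits$end)
  expect_true(all(gr$variant %in% c("canonical", "minimal")))
  unlink(c(bed, gff))
})
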