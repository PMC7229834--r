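# End-to-end orchestration: scan -> tandem grouping -> locus statistics ->
# classification -> family clustering -> report bundle. These functions are
# the package's command surface; each is a thin, deterministic composition
# of the module functions.

#' Pipeline configuration
#'
#' @param descriptors list of `hhr_descriptor`s to scan with (default: the
#'   canonical type I descriptor).
#' @param max_gap tandem join distance, nt.
#' @param monomer_range admissible monomer period, nt.
#' @param gc_max GC cutoff for retrozyme classification, percent.
#' @param family_threshold identity threshold for family clustering.
#' @param tsd_k_max,tsd_min TSD search bounds, nt.
#' @param seed seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(descriptors = list(default_descriptor("I",
                                                                  "canonical")),
                            max_gap = 900L, monomer_range = c(150, 450),
                            gc_max = 45, family_threshold = 0.8,
                            tsd_k_max = 20L, tsd_min = 5L, seed = 1L) {
  if (!length(descriptors)) abort("need at least one descriptor")
  stopifnot(all(vapply(descriptors, inherits, logical(1), "hhr_descriptor")))
  if (max_gap <= 0 || any(monomer_range <= 0) || gc_max <= 0) {
    abort("numeric bounds must be positive")
  }
  structure(
    list(descriptors = descriptors, max_gap = as.integer(max_gap),
         monomer_range = monomer_range, gc_max = gc_max,
         family_threshold = family_threshold,
         tsd_k_max = as.integer(tsd_k_max), tsd_min = as.integer(tsd_min),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Annotate a genome: full scan-to-report pipeline
#'
#' Scans with every configured descriptor, merges and deduplicates hits,
#' groups them into tandem loci, computes period, copy number, GC,
#' repeat-identity QC and TSDs, classifies loci and clusters retrozyme
#' monomers into families. When `out_dir` is given, writes the report
#' bundle: hits (BED6 + GFF3), loci (GFF3 + TSV), family centroids (FASTA)
#' and a YAML run manifest echoing the configuration.
#'
#' @param genome a genome tibble from [read_fasta()] or a FASTA path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A list with `hits`, `loci`, `families` (centroid tibble or NULL)
#'   and `config`.
#' @export
run_annotate <- function(genome, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(genome)) genome <- read_fasta(genome)
  hits <- purrr::map_dfr(config$descriptors,
                         function(d) scan_genome(genome, d))
  if (nrow(hits)) {
    hits <- dplyr::distinct(hits, .data$contig, .data$start, .data$end,
                            .data$strand, .keep_all = TRUE)
    hits <- dplyr::arrange(hits, .data$contig, .data$start, .data$strand)
  }
  loci <- call_loci(genome, hits,
                    max_gap = config$max_gap,
                    monomer_range = config$monomer_range,
                    gc_max = config$gc_max,
                    tsd_k_max = config$tsd_k_max, tsd_min = config$tsd_min,
                    family_threshold = config$family_threshold)
  if (nrow(loci) == 0L) warn("no HHR hits: reports will be empty")
  families <- attr(loci, "family_centroids")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_bed(hits, file.path(out_dir, "hhr_hits.bed"))
    write_hits_gff3(hits, file.path(out_dir, "hhr_hits.gff3"))
    write_loci_gff3(loci, file.path(out_dir, "retrozyme_loci.gff3"))
    write_loci_tsv(loci, file.path(out_dir, "retrozyme_loci.tsv"))
    if (!is.null(families)) {
      write_family_fasta(families, file.path(out_dir, "family_centroids.fasta"))
    }
    manifest <- list(
      package = "retrozyme",
      version = as.character(utils::packageVersion("retrozyme")),
      seed = config$seed,
      n_descriptors = length(config$descriptors),
      max_gap = config$max_gap,
      monomer_range = config$monomer_range,
      gc_max = config$gc_max,
      family_threshold = config$family_threshold,
      n_hits = nrow(hits), n_loci = nrow(loci))
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  list(hits = hits, loci = loci, families = families, config = config)
}

#' Kinetics command wrapper
#'
#' `command = "fit"` reads a time-course TSV, fits the first-order model and
#' (optionally) writes a one-row fit TSV; `command = "simulate"` simulates a
#' seeded time course and writes it as TSV.
#'
#' @param command "fit" or "simulate".
#' @param input input TSV path (fit) or NULL.
#' @param output optional output TSV path.
#' @param k,F_inf,times,noise_sd,seed simulation parameters.
#' @return The fit (`kinetic_fit`) or the simulated time-course tibble.
#' @export
run_kinetics <- function(command = c("fit", "simulate"), input = NULL,
                         output = NULL, k = 0.8, F_inf = 0.95,
                         times = c(0.5, 1, 2, 5, 10, 15, 20, 30),
                         noise_sd = 0, seed = 1L) {
  command <- match.arg(command)
  if (command == "fit") {
    if (is.null(input)) abort("fit needs an input time-course TSV")
    fit <- fit_time_course(read_time_course(input))
    if (!is.null(output)) {
      readr::write_tsv(glance(fit), output)
    }
    fit
  } else {
    tc <- simulate_time_course(k, F_inf, times, noise_sd, seed)
    if (!is.null(output)) write_time_course(tc, output)
    tc
  }
}

#' Plot annotated loci along a contig
#'
#' Simple locus map: one segment per locus, coloured by classification,
#' labelled with period and copy number.
#'
#' @param loci a locus tibble from [call_loci()] or [run_annotate()].
#' @return A ggplot object.
#' @export
plot_locus_map <- function(loci) {
  ggplot2::ggplot(loci) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$contig, yend = .data$contig,
                   colour = .data$classification),
      linewidth = 4) +
    ggplot2::labs(x = "position (nt)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
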