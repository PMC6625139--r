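# accept a file path or an already-loaded object for pipeline inputs
load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) loader(x) else x
}

#' Run the per-sample somatic pipeline
#'
#' End-to-end per-sample analysis: caller intersection and filtering,
#' trinucleotide catalog and signature refit, microsatellite scan and MSI
#' scoring, LOH segmentation, second-hit classification and optional
#' hotspot driver flagging, assembled into a [build_sample_report()].
#'
#' All variant/interval inputs accept either a loaded data frame or a
#' file path (VCF for variants, BED for intervals, FASTA for the
#' reference).
#'
#' @param sample_id,group Sample identifier and declared group label
#'   (`"MMR-deficient"` / `"MMR-proficient"`).
#' @param germline Germline variant table or VCF path.
#' @param tumor_a,tumor_b The two tumor callers' variant tables or VCF
#'   paths (B is the indel-capable caller).
#' @param reference Reference sequences (named character vector,
#'   [generate_reference()] list, or FASTA path).
#' @param capture Capture intervals (data frame or BED path).
#' @param exons Exon intervals (data frame or BED path).
#' @param signatures Signature matrix (or TSV path).
#' @param mmr_gene Optional one-row interval (`chrom`, `start`, `end`)
#'   of the germline-mutated MMR gene, for second-hit classification.
#' @param hotspots Optional hotspot table (data frame or TSV path with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene`, `recurrence_count`).
#' @param ms_loci Optional precomputed microsatellite loci; scanned from
#'   the reference when `NULL`.
#' @param min_depth,min_vaf Filter thresholds.
#' @return List with the `report` plus every intermediate: `filtered`,
#'   `catalog`, `exposures`, `loh_sites`, `loh_regions`, `msi`,
#'   `drivers`.
#' @export
run_sample_pipeline <- function(sample_id, group, germline, tumor_a,
                                tumor_b, reference, capture, exons,
                                signatures, mmr_gene = NULL,
                                hotspots = NULL, ms_loci = NULL,
                                min_depth = 40, min_vaf = 0.10) {
  germline <- load_input(germline, read_vcf)
  tumor_a <- load_input(tumor_a, read_vcf)
  tumor_b <- load_input(tumor_b, read_vcf)
  reference <- load_input(reference, read_reference_fasta)
  capture <- as_capture(load_input(capture, read_bed))
  exons <- load_input(exons, read_bed)
  signatures <- load_input(signatures, read_signature_matrix)
  if (is.character(hotspots)) {
    hotspots <- utils::read.table(hotspots, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }

  filtered <- filter_somatic_variants(tumor_a, tumor_b, capture,
                                      min_depth = min_depth,
                                      min_vaf = min_vaf)
  catalog <- build_catalog(filtered$snvs, reference)
  exposures <- if (sum(catalog) > 0) {
    refit_signatures(catalog, signatures)
  } else {
    # nothing to refit: an explicit empty composition, not an error,
    # so that empty tumor inputs still yield a complete report
    structure(list(weights = stats::setNames(rep(0, nrow(signatures)),
                                             rownames(signatures)),
                   cosine = NA_real_, n_iterations = 0L,
                   history = numeric(0)),
              class = "exposure_vector")
  }
  if (is.null(ms_loci)) ms_loci <- find_microsatellites(reference)
  msi <- msi_summary(filtered$indels, ms_loci, exons)
  loh_sites <- suppressWarnings(
    select_informative_sites(germline, tumor_a))
  loh_regions <- if (nrow(loh_sites) > 0) {
    segment_loh_regions(loh_sites)
  } else NULL
  somatic_all <- rbind(filtered$snvs, filtered$indels)
  second_hit <- if (!is.null(mmr_gene)) {
    gene_second_hit(loh_regions, somatic_all, mmr_gene)
  } else "none"
  drivers <- if (!is.null(hotspots)) {
    flag_hotspot_drivers(somatic_all, hotspots)
  } else NULL
  report <- build_sample_report(sample_id, group, filtered$summary,
                                exposures, msi, second_hit, drivers)
  list(report = report, filtered = filtered, catalog = catalog,
       exposures = exposures, loh_sites = loh_sites,
       loh_regions = loh_regions, msi = msi, drivers = drivers)
}

#' Bundled per-sample cohort metrics table
#'
#' Loads `inst/extdata/cohort_metrics.tsv`, the six-lesion per-sample
#' metric table (three MMR-deficient sebaceous lesions from MSH2 carriers,
#' three MMR-proficient lesions) used by the worked examples and the
#' reproduction script: mutational load, TMB, exonic microsatellite indel
#' count, MSI score, and — for the MMR-deficient lesions — the combined
#' signature 6 + 15 contribution. The MMR-proficient combined contribution
#' is available only as a published group summary (mean 2.3, SD 4.0,
#' n = 3), not per sample, and is therefore not a column here.
#'
#' @return Data frame, one row per lesion.
#' @export
cohort_metrics <- function() {
  path <- system.file("extdata", "cohort_metrics.tsv",
                      package = "mmrsig", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
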