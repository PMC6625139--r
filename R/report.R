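#' Flag hotspot driver mutations
#'
#' A variant is flagged as a candidate driver when its predicted impact is
#' moderate or high and it matches a hotspot table entry — exactly on
#' `(chrom, pos, ref, alt)`, or on `(chrom, pos, ref)` for entries whose
#' `alt` is `"*"` (any alternate). Entries below `min_recurrence` are
#' ignored. Variants with no impact annotation are skipped and tallied in
#' the `n_missing_impact` attribute, with a warning.
#'
#' @param variants Variant data frame with an `impact` column (annotation
#'   from the VCF, or [infer_impact()] for synthetic data).
#' @param hotspots Data frame `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `recurrence_count`.
#' @param min_recurrence Minimum recurrence count for a usable hotspot
#'   entry (default 3).
#' @return The flagged subset of `variants` with a `gene` column added.
#' @export
flag_hotspot_drivers <- function(variants, hotspots, min_recurrence = 3) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gene") %in%
                  names(hotspots)))
  if (!is.null(hotspots$recurrence_count)) {
    hotspots <- hotspots[hotspots$recurrence_count >= min_recurrence, ,
                         drop = FALSE]
  }
  n_missing <- sum(is.na(variants$impact))
  if (n_missing > 0) {
    warning(n_missing, " variant(s) without impact annotation skipped")
  }
  v <- variants[!is.na(variants$impact) &
                  variants$impact %in% c("moderate", "high"), ,
                drop = FALSE]
  key4 <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  key3 <- function(d) paste(d$chrom, d$pos, d$ref, sep = ":")
  exact <- hotspots[hotspots$alt != "*", , drop = FALSE]
  anyalt <- hotspots[hotspots$alt == "*", , drop = FALSE]
  m_exact <- match(key4(v), key4(exact))
  m_any <- match(key3(v), key3(anyalt))
  hit <- !is.na(m_exact) | !is.na(m_any)
  out <- v[hit, , drop = FALSE]
  out$gene <- ifelse(!is.na(m_exact[hit]), exact$gene[m_exact[hit]],
                     anyalt$gene[m_any[hit]])
  rownames(out) <- NULL
  structure(out, n_missing_impact = n_missing)
}

#' Simple consequence-based impact rule for synthetic data
#'
#' Assigns `high` to stop-gain-like SNVs and frameshift indels, `moderate`
#' to other coding SNVs (missense-like), `modifier` otherwise — a built-in
#' stand-in for an external effect predictor, sufficient for synthetic
#' cohorts where true consequences are constructed, not predicted.
#'
#' @param variants Variant data frame.
#' @param high_keys Optional `(chrom:pos:ref:alt)` keys to force to
#'   `high` (how synthetic truth sets mark constructed truncating
#'   variants).
#' @return The data frame with its `impact` column filled where missing.
#' @export
infer_impact <- function(variants, high_keys = character(0)) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  frameshift <- variants$var_class %in% c("insertion", "deletion") &
    abs(nchar(variants$alt) - nchar(variants$ref)) %% 3 != 0
  filled <- ifelse(key %in% high_keys | frameshift, "high",
                   ifelse(variants$var_class == "SNV", "moderate",
                          "modifier"))
  variants$impact <- ifelse(is.na(variants$impact), filled,
                            variants$impact)
  variants
}

#' Assemble the per-sample somatic report
#'
#' Collects the outputs of every pipeline stage into one record mirroring
#' a per-sample summary table row: mutational load, TMB, exonic
#' microsatellite indels, MSI score, signature exposures and the
#' second-hit call. Every numeric field is taken verbatim from its stage.
#'
#' @param sample_id Sample identifier.
#' @param group Declared group label, `"MMR-deficient"` or
#'   `"MMR-proficient"` — user metadata, never inferred from the data.
#' @param filter_summary `"filter_summary"` from
#'   [filter_somatic_variants()].
#' @param exposures `"exposure_vector"` from [refit_signatures()].
#' @param msi `"msi_summary"` from [msi_summary()].
#' @param second_hit Character vector from [gene_second_hit()].
#' @param drivers Optional flagged driver table from
#'   [flag_hotspot_drivers()].
#' @return List of class `"sample_report"`.
#' @export
build_sample_report <- function(sample_id, group, filter_summary,
                                exposures, msi, second_hit,
                                drivers = NULL) {
  stopifnot(group %in% c("MMR-deficient", "MMR-proficient"))
  for (stage in c("filter_summary", "exposures", "msi", "second_hit")) {
    if (is.null(get(stage))) {
      stop("incomplete report: missing stage '", stage, "'")
    }
  }
  structure(list(
    sample_id = sample_id,
    group = group,
    mutational_load = filter_summary$n_in_capture,
    tmb = filter_summary$tmb,
    exonic_ms_indels = msi$n_exonic_ms_indels,
    msi_score = msi$score,
    second_hit = second_hit,
    exposures = as.list(exposures$weights[exposures$weights > 0]),
    cosine = exposures$cosine,
    drivers = if (is.null(drivers)) list() else
      as.list(paste(drivers$gene, drivers$chrom, drivers$pos, drivers$ref,
                    drivers$alt, sep = ":"))),
    class = "sample_report")
}

#' Serialize / deserialize a sample report as JSON
#'
#' The round trip is lossless for all report fields.
#'
#' @param report `"sample_report"` object.
#' @param path JSON path.
#' @return `read_sample_report()` returns the `"sample_report"`.
#' @export
write_sample_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sample_report
#' @export
read_sample_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$exposures <- as.list(unlist(x$exposures))
  x$drivers <- as.list(unlist(x$drivers))
  if (length(x$drivers) == 0) x$drivers <- list()
  structure(x, class = "sample_report")
}

report_metric <- function(report, metric) {
  if (metric == "combined_sig6_15") {
    w <- unlist(report$exposures)
    sum(w[names(w) %in% c("Signature.6", "Signature.15")]) * 100
  } else {
    report[[metric]]
  }
}

#' Cohort comparison of MMR-deficient vs MMR-proficient samples
#'
#' For each metric (TMB, exonic microsatellite indel count, MSI score and
#' combined signature 6 + 15 contribution), computes both group summaries
#' and the pooled two-tailed Student's t test. Groups with fewer than two
#' samples are skipped with a warning.
#'
#' @param reports List of `"sample_report"` objects carrying their group
#'   labels.
#' @param metrics Metrics to compare.
#' @return Data frame with one row per metric: group means and SDs, t
#'   statistic, degrees of freedom, and two-tailed p.
#' @export
build_cohort_report <- function(reports,
                                metrics = c("tmb", "exonic_ms_indels",
                                            "msi_score",
                                            "combined_sig6_15")) {
  groups <- vapply(reports, `[[`, "", "group")
  out <- list()
  for (metric in metrics) {
    vals <- vapply(reports, report_metric, numeric(1), metric = metric)
    def <- vals[groups == "MMR-deficient"]
    pro <- vals[groups == "MMR-proficient"]
    if (length(def) < 2 || length(pro) < 2) {
      warning("metric '", metric, "' skipped: a group has fewer than ",
              "two samples")
      next
    }
    tt <- students_t_test(def, pro)
    out[[metric]] <- data.frame(
      metric = metric,
      n_deficient = length(def), mean_deficient = mean(def),
      sd_deficient = stats::sd(def),
      n_proficient = length(pro), mean_proficient = mean(pro),
      sd_proficient = stats::sd(pro),
      t_statistic = tt$t_statistic, df = tt$df,
      p_two_tailed = tt$p_two_tailed,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stacked signature-composition plot for a cohort
#'
#' One stacked bar per sample showing each signature's percentage
#' contribution to the refitted composition.
#'
#' @param exposure_list Named list of `"exposure_vector"` objects (names
#'   are sample ids).
#' @param file Optional PDF path.
#' @export
plot_signature_composition <- function(exposure_list, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  mat <- vapply(exposure_list, function(e) e$weights,
                numeric(length(exposure_list[[1]]$weights)))
  mat <- mat[rowSums(mat) > 0, , drop = FALSE] * 100
  cols <- grDevices::hcl.colors(nrow(mat), "Spectral")
  graphics::barplot(mat, col = cols, ylab = "contribution (%)",
                    las = 2, border = NA)
  graphics::legend("topright", legend = rownames(mat), fill = cols,
                   cex = 0.6, bty = "n")
  invisible(NULL)
}
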