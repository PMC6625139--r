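hotspot_table <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2"),
             pos = c(100, 200, 300),
             ref = c("G", "A", "C"), alt = c("T", "*", "A"),
             gene = c("HRAS", "EGFR", "MET"),
             recurrence_count = c(10, 5, 3), stringsAsFactors = FALSE)
}

variant_at <- function(chrom, pos, ref, alt, impact) {
  mmrsig:::new_variant_df(chrom, pos, ref, alt, 100, 40, "PASS",
                          variant_class(ref, alt), impact = impact)
}

test_that("hotspot flagging needs both impact and a table match", {
  hs <- hotspot_table()
  expect_equal(flag_hotspot_drivers(variant_at("chr1", 100, "G", "T",
                                               "high"), hs)$gene, "HRAS")
  # modifier impact at a hotspot: not flagged
  expect_equal(nrow(flag_hotspot_drivers(
    variant_at("chr1", 100, "G", "T", "modifier"), hs)), 0)
  # any-alt entries match on (chrom, pos, ref)
  expect_equal(flag_hotspot_drivers(variant_at("chr1", 200, "A", "C",
                                               "moderate"), hs)$gene,
               "EGFR")
  # exact entries do not match a different alt
  expect_equal(nrow(flag_hotspot_drivers(
    variant_at("chr1", 100, "G", "C", "high"), hs)), 0)
  # below the recurrence cutoff the entry is ignored
  expect_equal(nrow(flag_hotspot_drivers(
    variant_at("chr2", 300, "C", "A", "high"), hs,
    min_recurrence = 5)), 0)
})

test_that("variants without impact are skipped with a tally", {
  hs <- hotspot_table()
  v <- rbind(variant_at("chr1", 100, "G", "T", "high"),
             variant_at("chr1", 100, "G", "T", NA_character_))
  expect_warning(out <- flag_hotspot_drivers(v, hs), "without impact")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_missing_impact"), 1L)
})

test_that("a cohort seeded with three hotspot drivers flags exactly three", {
  hs <- hotspot_table()
  drivers <- rbind(variant_at("chr1", 100, "G", "T", "high"),
                   variant_at("chr1", 200, "A", "G", "moderate"),
                   variant_at("chr2", 300, "C", "A", "high"))
  bystanders <- rbind(variant_at("chr1", 150, "C", "T", "high"),
                      variant_at("chr2", 400, "G", "A", "moderate"))
  out <- flag_hotspot_drivers(rbind(drivers, bystanders), hs)
  expect_equal(nrow(out), 3)
  expect_setequal(out$gene, c("HRAS", "EGFR", "MET"))
})

test_that("sample reports round-trip losslessly through JSON", {
  fs <- data.frame(n_input_a = 10, n_input_b = 10, n_intersect = 8,
                   n_pass_depth_vaf = 8, n_in_capture = 7, tmb = 14.0)
  exp <- structure(list(weights = c(Signature.1 = 0.6, Signature.6 = 0.4),
                        cosine = 0.98, n_iterations = 2L,
                        history = c(0.9, 0.98)),
                   class = "exposure_vector")
  msi <- structure(list(n_loci = 100L, n_affected = 5L, score = 5,
                        n_exonic_ms_indels = 12L), class = "msi_summary")
  rep1 <- build_sample_report("S1", "MMR-deficient", fs, exp, msi,
                              second_hit = c("somatic_mutation", "LOH"))
  f <- tempfile(fileext = ".json")
  write_sample_report(rep1, f)
  rep2 <- read_sample_report(f)
  for (field in c("sample_id", "group", "mutational_load", "tmb",
                  "exonic_ms_indels", "msi_score", "second_hit")) {
    expect_equal(rep2[[field]], rep1[[field]], ignore_attr = TRUE)
  }
  expect_equal(unlist(rep2$exposures), unlist(rep1$exposures))
})

test_that("an incomplete report names its missing stage", {
  expect_error(build_sample_report("S1", "MMR-deficient", NULL,
                                   list(weights = 1), list(score = 0),
                                   "none"),
               "missing stage 'filter_summary'")
  expect_error(build_sample_report("S1", "unknown-group",
                                   data.frame(), list(), list(), "none"))
})

test_that("empty tumor input yields a zeroed report, not an error", {
  ref <- make_test_reference(seed = 61)
  empty <- mmrsig:::new_variant_df()
  germ <- mmrsig:::new_variant_df("chr1", c(5000, 6000), "A", "G",
                                  80, 40, "PASS", "SNV")
  out <- run_sample_pipeline(
    "EMPTY", "MMR-proficient", germ, empty, empty, ref,
    capture = whole_interval(ref), exons = whole_interval(ref),
    signatures = sig_panel)
  expect_equal(out$report$mutational_load, 0)
  expect_equal(out$report$tmb, 0.0)
  expect_equal(out$report$msi_score, 0.0)
  expect_equal(out$report$second_hit, "none")
})

test_that("fixture cohort reports reproduce the headline comparisons", {
  metrics <- cohort_metrics()
  reports <- lapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    comb <- if (is.na(m$combined_sig6_15)) 0 else m$combined_sig6_15 / 100
    structure(list(sample_id = m$sample_id, group = m$group,
                   mutational_load = m$mutational_load, tmb = m$tmb,
                   exonic_ms_indels = m$exonic_ms_indels,
                   msi_score = m$msi_score, second_hit = "none",
                   exposures = list(Signature.6 = comb),
                   drivers = list()),
              class = "sample_report")
  })
  tab <- build_cohort_report(reports)
  tmb_row <- tab[tab$metric == "tmb", ]
  expect_equal(round(tmb_row$mean_deficient, 1), 23.3)
  expect_equal(round(tmb_row$sd_deficient, 1), 11.4)
  expect_equal(round(tmb_row$p_two_tailed, 2), 0.03)
  ms_row <- tab[tab$metric == "exonic_ms_indels", ]
  expect_equal(round(ms_row$mean_deficient, 0), 456)
  expect_equal(round(ms_row$p_two_tailed, 3), 0.052)
  msi_row <- tab[tab$metric == "msi_score", ]
  expect_equal(round(msi_row$mean_deficient, 1), 15.7)
  expect_equal(round(msi_row$p_two_tailed, 2), 0.08)
})

test_that("cohort tables byte-match a regeneration from group stats", {
  metrics <- cohort_metrics()
  reports <- lapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    structure(list(sample_id = m$sample_id, group = m$group,
                   mutational_load = m$mutational_load, tmb = m$tmb,
                   exonic_ms_indels = m$exonic_ms_indels,
                   msi_score = m$msi_score, second_hit = "none",
                   exposures = list(), drivers = list()),
              class = "sample_report")
  })
  tab <- build_cohort_report(reports, metrics = c("tmb", "msi_score"))
  golden <- do.call(rbind, lapply(c("tmb", "msi_score"), function(met) {
    def <- metrics[metrics$group == "MMR-deficient", met]
    pro <- metrics[metrics$group == "MMR-proficient", met]
    tt <- students_t_test(def, pro)
    data.frame(metric = met, n_deficient = 3L,
               mean_deficient = mean(def), sd_deficient = sd(def),
               n_proficient = 3L, mean_proficient = mean(pro),
               sd_proficient = sd(pro), t_statistic = tt$t_statistic,
               df = tt$df, p_two_tailed = tt$p_two_tailed,
               stringsAsFactors = FALSE)
  }))
  f1 <- tempfile(); f2 <- tempfile()
  write.table(tab, f1, sep = "\t", row.names = FALSE)
  write.table(golden, f2, sep = "\t", row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("one group's summary is unaffected by the other's membership", {
  mk <- function(id, group, tmb) {
    structure(list(sample_id = id, group = group, mutational_load = 1,
                   tmb = tmb, exonic_ms_indels = 0, msi_score = 0,
                   second_hit = "none", exposures = list(),
                   drivers = list()), class = "sample_report")
  }
  base_reports <- list(mk("d1", "MMR-deficient", 20),
                       mk("d2", "MMR-deficient", 26),
                       mk("p1", "MMR-proficient", 1),
                       mk("p2", "MMR-proficient", 2))
  extra <- c(base_reports, list(mk("p3", "MMR-proficient", 3)))
  t1 <- build_cohort_report(base_reports, metrics = "tmb")
  t2 <- build_cohort_report(extra, metrics = "tmb")
  expect_equal(t2$mean_deficient, t1$mean_deficient)
  expect_equal(t2$sd_deficient, t1$sd_deficient)
})

test_that("groups below two samples are skipped with a warning", {
  mk <- function(id, group) {
    structure(list(sample_id = id, group = group, mutational_load = 1,
                   tmb = 1, exonic_ms_indels = 0, msi_score = 0,
                   second_hit = "none", exposures = list(),
                   drivers = list()), class = "sample_report")
  }
  expect_warning(
    out <- build_cohort_report(list(mk("a", "MMR-deficient"),
                                    mk("b", "MMR-proficient"),
                                    mk("c", "MMR-proficient")),
                               metrics = "tmb"),
    "fewer than")
  expect_null(out)
})
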