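ref1 <- function(seq) list(sequence = c(chr1 = seq))

indel_df <- function(pos, ref, alt, chrom = "chr1") {
  mmrsig:::new_variant_df(chrom, pos, ref, alt, 80, 30, "PASS",
                          variant_class(ref, alt))
}

test_that("homopolymer and multimer runs are detected at thresholds", {
  # pad to satisfy the scan's minimum-reference assumptions trivially
  loci <- find_microsatellites(ref1("CCGAAAAACCG"))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$unit, "A")
  expect_equal(loci$n_repeats, 5)
  expect_equal(c(loci$start, loci$end), c(3, 8))

  loci2 <- find_microsatellites(ref1("GGTACACACTGG"))
  expect_equal(loci2$unit, "AC")
  expect_equal(loci2$n_repeats, 3)

  # below-threshold runs are not loci
  expect_equal(nrow(find_microsatellites(ref1("CCGAAAACCG"))), 0)
})

test_that("periodic motifs reduce to their smallest unit", {
  loci <- find_microsatellites(ref1(paste0("GGC", strrep("A", 8), "CGG")))
  expect_equal(loci$unit, "A")               # never reported as AA x 4
  expect_equal(loci$n_repeats, 8)
})

test_that("the scan matches an independent per-position oracle", {
  for (seed in c(1, 2, 3)) {
    seq <- mmrsig:::with_seed(seed, paste(
      sample(c("A", "C", "G", "T"), 5000, replace = TRUE,
             prob = c(0.35, 0.15, 0.15, 0.35)), collapse = ""))
    got <- find_microsatellites(ref1(seq))
    want <- ms_scan_oracle(seq)
    expect_equal(got[c("start", "end", "unit", "n_repeats")], want,
                 ignore_attr = TRUE)
    expect_gt(nrow(got), 0)                  # the comparison is non-vacuous
  }
})

test_that("exonic microsatellite indel counting needs both overlaps", {
  # repeat-free 10-mer padding so the poly-A run is the only locus
  seq <- paste0(strrep("GCATTCGGAT", 12), strrep("A", 8),
                strrep("CGTAACTGGC", 12))
  loci <- find_microsatellites(ref1(seq))
  expect_equal(nrow(loci), 1)
  exons <- data.frame(chrom = "chr1", start = 100, end = 200)
  ins <- indel_df(120, "T", "TA")            # anchor just before the run
  expect_equal(count_exonic_ms_indels(ins, loci, exons), 1)
  # same indel, exon elsewhere: no count
  expect_equal(count_exonic_ms_indels(
    ins, loci, data.frame(chrom = "chr1", start = 300, end = 350)), 0)
  # indel outside any locus: no count
  expect_equal(count_exonic_ms_indels(indel_df(110, "C", "CA"), loci,
                                      exons), 0)
  expect_equal(count_exonic_ms_indels(indel_df(integer(0), character(0),
                                               character(0)), loci,
                                      exons), 0)
})

test_that("msi_score counts affected loci once regardless of indel count", {
  loci <- data.frame(chrom = "chr1", start = c(100, 300, 500),
                     end = c(110, 310, 510), unit = "A", n_repeats = 10)
  expect_equal(msi_score(indel_df(integer(0), character(0),
                                  character(0)), loci), 0)
  one <- indel_df(105, "AA", "A")
  expect_equal(msi_score(one, loci), 100 * 1 / 3)
  # two indels in the same locus still affect one locus
  two_same <- rbind(one, indel_df(107, "A", "AA"))
  expect_equal(msi_score(two_same, loci), 100 * 1 / 3)
  expect_error(msi_score(one, loci[0, ]), "zero loci")
})

test_that("msi_score grows monotonically as indels accumulate", {
  loci <- data.frame(chrom = "chr1", start = seq(0, 1900, 100),
                     end = seq(10, 1910, 100))
  hits <- indel_df(seq(5, 1905, 100), "AA", "A")
  scores <- vapply(seq_len(nrow(hits)), function(k) {
    msi_score(hits[seq_len(k), ], loci)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_equal(scores[length(scores)], 100)
})

test_that("synthetic indel counts match the truth set exactly", {
  ref <- make_test_reference(seed = 59)
  spec <- synthetic_sample_spec(mmrd_mixture(50), n_germline_hets = 20,
                                ms_indel_rate = 0.1, seed = 41)
  s <- simulate_sample(ref, spec, sig_panel)
  n_true <- sum(s$truth$ms_status$mutated)
  exons <- whole_interval(ref)
  indels <- s$tumor_b[s$tumor_b$var_class %in%
                        c("insertion", "deletion"), ]
  expect_equal(count_exonic_ms_indels(indels, ref$ms_loci, exons), n_true)
  # rate 0.1 over ~490 loci: the draw sits inside the binomial 95% band
  n_loci <- nrow(ref$ms_loci)
  band <- stats::qbinom(c(0.025, 0.975), n_loci, 0.1)
  expect_gte(n_true, band[1]); expect_lte(n_true, band[2])
  expect_equal(msi_score(indels, ref$ms_loci), 100 * n_true / n_loci)
})

test_that("frameshift report flags out-of-frame indels per panel gene", {
  panel <- data.frame(gene = c("TGFBR2", "ASTE1"), chrom = "chr1",
                      start = c(100, 500), end = c(200, 600))
  none <- coding_ms_frameshift_report(
    indel_df(integer(0), character(0), character(0)), panel)
  expect_equal(none$call, c("None", "None"))
  plus1 <- coding_ms_frameshift_report(indel_df(150, "A", "AT"), panel)
  expect_equal(plus1$call, c("Frameshift", "None"))
  inframe <- coding_ms_frameshift_report(indel_df(150, "A", "ATTT"),
                                         panel)
  expect_equal(inframe$call, c("None", "None"))
})

test_that("the default panel lists the 14 coding-microsatellite genes", {
  expect_length(default_ms_gene_panel(), 14)
  expect_true(all(c("TGFBR2", "MSH3", "ACVR2") %in%
                    default_ms_gene_panel()))
})
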