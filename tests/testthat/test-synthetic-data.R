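test_that("generate_reference places planned microsatellites verbatim", {
  ref <- generate_reference(
    10000, microsatellite_plan = list(list(unit = "A", n_repeats = 10,
                                           pos = 500)),
    seed = 1)
  seq <- ref$sequence[["chr1"]]
  expect_identical(substr(seq, 501, 510), strrep("A", 10))
  expect_equal(ref$ms_loci$start, 500)
  expect_equal(ref$ms_loci$end, 510)
  # half-open truth coordinates: end - start = unit length * repeats
  expect_equal(ref$ms_loci$end - ref$ms_loci$start,
               nchar(ref$ms_loci$unit) * ref$ms_loci$n_repeats)
})

test_that("generate_reference handles empty plans and refuses bad ones", {
  ref <- generate_reference(10000, seed = 2)
  expect_equal(nrow(ref$ms_loci), 0)
  expect_error(
    generate_reference(10000, microsatellite_plan = list(
      list(unit = "A", n_repeats = 10, pos = 9995)), seed = 1),
    "cannot place")
  expect_error(
    generate_reference(10000, microsatellite_plan = list(
      list(unit = "AC", n_repeats = 5, pos = 100),
      list(unit = "T", n_repeats = 6, pos = 105)), seed = 1),
    "overlap")
})

test_that("reference generation is deterministic and GC-controlled", {
  r1 <- generate_reference(20000, gc_fraction = 0.6, seed = 9)
  r2 <- generate_reference(20000, gc_fraction = 0.6, seed = 9)
  expect_identical(r1$sequence, r2$sequence)
  gc <- mean(strsplit(r1$sequence[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.6), 0.02)
})

test_that("simulate_catalog conserves counts and matches the mixture", {
  m1 <- signature_mixture(c(Signature.1 = 1), 1000)
  counts <- simulate_catalog(m1, sig_panel, seed = 1)
  expect_equal(sum(counts), 1000)
  # expected-count mode reproduces the signature row exactly
  m6 <- signature_mixture(c(Signature.6 = 1), 5000)
  expect_equal(as.numeric(simulate_catalog(m6, sig_panel, expected = TRUE)),
               5000 * as.numeric(sig_panel["Signature.6", ]))
  expect_error(
    simulate_catalog(signature_mixture(c(SignatureX = 1), 10), sig_panel),
    "unknown signature")
})

test_that("large multinomial draws match the analytic mixture", {
  mix <- signature_mixture(c(Signature.1 = 0.6, Signature.6 = 0.4), 50000)
  counts <- simulate_catalog(mix, sig_panel, seed = 42)
  # independent oracle: direct mixture arithmetic on the rows
  p_oracle <- 0.6 * sig_panel["Signature.1", ] +
    0.4 * sig_panel["Signature.6", ]
  expect_lt(max(abs(counts / 50000 - p_oracle)), 0.01)
})

test_that("signature_mixture validates its invariants", {
  expect_error(signature_mixture(c(Signature.1 = 0.7), 10), "sum to 1")
  expect_error(signature_mixture(c(Signature.1 = 1.5, Signature.2 = -0.5),
                                 10), "non-negative")
})

test_that("simulated samples honour caller overlap and conserve truth", {
  ref <- make_test_reference()
  spec <- synthetic_sample_spec(mmrd_mixture(500), n_germline_hets = 100,
                                caller_overlap = 1, seed = 5)
  s <- simulate_sample(ref, spec, sig_panel)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  pass_a <- s$tumor_a[s$tumor_a$filter == "PASS" &
                        s$tumor_a$var_class == "SNV", ]
  pass_b <- s$tumor_b[s$tumor_b$filter == "PASS" &
                        s$tumor_b$var_class == "SNV", ]
  expect_setequal(key(pass_a), key(pass_b))     # overlap 1: identical keys

  spec2 <- synthetic_sample_spec(mmrd_mixture(500), n_germline_hets = 100,
                                 caller_overlap = 0.6, seed = 5)
  s2 <- simulate_sample(ref, spec2, sig_panel)
  pa <- s2$tumor_a[s2$tumor_a$filter == "PASS" &
                     s2$tumor_a$var_class == "SNV", ]
  pb <- s2$tumor_b[s2$tumor_b$filter == "PASS" &
                     s2$tumor_b$var_class == "SNV", ]
  expect_equal(length(union(key(pa), key(pb))), nrow(s2$truth$snvs))
  expect_equal(length(intersect(key(pa), key(pb))), s2$truth$n_shared)
  expect_equal(s2$truth$n_shared, round(0.6 * 500))
})

test_that("placed SNV contexts match the reference (context fidelity)", {
  ref <- make_test_reference()
  spec <- synthetic_sample_spec(mmrd_mixture(400), n_germline_hets = 50,
                                seed = 7)
  s <- simulate_sample(ref, spec, sig_panel)
  reread <- classify_context(ref, s$truth$snvs$chrom, s$truth$snvs$pos,
                             s$truth$snvs$ref, s$truth$snvs$alt)
  expect_equal(reread, s$truth$snvs$context)
})

test_that("without LOH segments no het site is shifted by construction", {
  ref <- make_test_reference()
  spec <- synthetic_sample_spec(mmrd_mixture(100), n_germline_hets = 300,
                                loh_segments = NULL, depth_mean = 80,
                                seed = 13)
  s <- simulate_sample(ref, spec, sig_panel)
  expect_false(any(s$truth$germline_sites$in_loh))
  sites <- select_informative_sites(s$germline, s$tumor_a)
  # only binomial noise remains: shifts beyond 0.3 are very rare at depth 80
  expect_lt(mean(sites$supports_loh), 0.02)
})

test_that("germline hets are binomial around VAF 0.5", {
  ref <- make_test_reference()
  spec <- synthetic_sample_spec(mmrd_mixture(100), n_germline_hets = 500,
                                depth_mean = 80, seed = 17)
  s <- simulate_sample(ref, spec, sig_panel)
  expect_lt(abs(mean(s$germline$vaf) - 0.5), 0.01)
  expect_gt(stats::sd(s$germline$vaf), 0.03)
})

test_that("identical spec and seed give byte-identical VCFs", {
  ref <- make_test_reference()
  spec <- synthetic_sample_spec(mmrd_mixture(200), n_germline_hets = 50,
                                ms_indel_rate = 0.1, caller_overlap = 0.8,
                                seed = 23)
  s1 <- simulate_sample(ref, spec, sig_panel)
  s2 <- simulate_sample(ref, spec, sig_panel)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(s1$tumor_b, f1, contig_lengths = c(chr1 = 100000))
  write_vcf(s2$tumor_b, f2, contig_lengths = c(chr1 = 100000))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("exhausting a context's reference positions is an explicit error", {
  ref <- generate_reference(10000, seed = 1)
  big <- signature_mixture(c(Signature.1 = 1), 50000)
  spec <- synthetic_sample_spec(big, n_germline_hets = 0, seed = 1)
  expect_error(simulate_sample(ref, spec, sig_panel), "context exhausted")
})
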