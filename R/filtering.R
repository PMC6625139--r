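#' Build merged capture regions from a BED-style interval table
#'
#' Overlapping intervals are merged; the total size (the TMB denominator)
#' is the sum of merged interval lengths.
#'
#' @param intervals Data frame `chrom`, `start`, `end` in 0-based
#'   half-open coordinates (as from [read_bed()]).
#' @return Object of class `"capture_regions"` with merged `intervals`
#'   and `total_size` in bases.
#' @export
capture_regions <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) stop("capture region set is empty")
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  df <- as.data.frame(gr)
  merged <- data.frame(
    chrom = as.character(df$seqnames),
    start = df$start - 1,
    end = df$end,
    stringsAsFactors = FALSE)
  structure(list(intervals = merged,
                 total_size = sum(merged$end - merged$start)),
            class = "capture_regions")
}

as_capture <- function(capture) {
  if (inherits(capture, "capture_regions")) capture
  else capture_regions(capture)
}

#' Intersect the somatic calls of two callers
#'
#' A variant passes if its `(chrom, pos, ref, alt)` key is present in both
#' call sets; per-record depth, alt count and VAF are taken from one
#' declared caller (default A). Records not tagged `PASS` (e.g. caller
#' germline tags) are excluded from both sides first.
#'
#' @param variants_a,variants_b Normalized variant data frames
#'   (multi-allelics already split).
#' @param stats_from Which caller's depth/VAF fields to report for
#'   intersected records: `"a"` (default) or `"b"`.
#' @return The intersected variant data frame.
#' @export
intersect_callers <- function(variants_a, variants_b,
                              stats_from = c("a", "b")) {
  stats_from <- match.arg(stats_from)
  pass <- function(v) {
    if (is.null(v$filter)) v else v[v$filter %in% c("PASS", "."), ,
                                    drop = FALSE]
  }
  a <- pass(variants_a); b <- pass(variants_b)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  if (stats_from == "b") { tmp <- a; a <- b; b <- tmp }
  out <- a[key(a) %in% key(b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply depth, VAF and capture-region filters
#'
#' A variant is kept iff `depth >= min_depth`, `vaf >= min_vaf` (both
#' thresholds inclusive, reading "minimum" as at-least) and its position
#' falls inside the capture region (a 1-based position `p` lies in the
#' half-open 0-based interval `[s, e)` iff `s < p <= e`).
#'
#' @param variants Variant data frame.
#' @param capture [capture_regions()] object or interval data frame; must
#'   be non-empty (TMB is undefined otherwise).
#' @param min_depth Minimum read depth (default 40).
#' @param min_vaf Minimum variant allele frequency (default 0.10).
#' @return Filtered variant data frame.
#' @export
apply_filters <- function(variants, capture, min_depth = 40,
                          min_vaf = 0.10) {
  stopifnot(min_depth > 0, min_vaf > 0)
  capture <- as_capture(capture)
  keep <- variants$depth >= min_depth & variants$vaf >= min_vaf
  v <- variants[keep & !is.na(keep), , drop = FALSE]
  if (nrow(v) > 0) {
    gr <- GenomicRanges::GRanges(v$chrom,
                                 IRanges::IRanges(v$pos, v$pos))
    hits <- GenomicRanges::countOverlaps(
      gr, intervals_to_granges(capture$intervals))
    v <- v[hits > 0, , drop = FALSE]
  }
  rownames(v) <- NULL
  v
}

#' Tumor mutational burden
#'
#' Filtered somatic SNVs per megabase of merged capture region.
#'
#' @param n_variants Number of filtered SSNVs.
#' @param capture [capture_regions()] object or interval data frame with
#'   positive total size.
#' @return Mutations per megabase (full precision; tables conventionally
#'   round to 1 decimal place).
#' @export
compute_tmb <- function(n_variants, capture) {
  capture <- as_capture(capture)
  if (capture$total_size <= 0) stop("capture size must be positive")
  n_variants / (capture$total_size / 1e6)
}

#' Run the full somatic SNV selection chain
#'
#' Caller intersection (SNVs only), then depth/VAF thresholds, then the
#' capture-region restriction, then TMB. Indels, which a single caller
#' provides, bypass the intersection but pass the same depth/VAF/capture
#' filters (set `intersect_indels = TRUE` to intersect them too).
#'
#' @param variants_a,variants_b Variant data frames from the two callers
#'   (caller B is the indel-capable one).
#' @param capture Capture regions.
#' @param min_depth,min_vaf Filter thresholds, see [apply_filters()].
#' @param stats_from See [intersect_callers()].
#' @param intersect_indels Whether indels must also be called by both
#'   callers (default `FALSE`).
#' @return List with `snvs` and `indels` (filtered data frames) and
#'   `summary`, a `"filter_summary"` row of counts along the chain:
#'   `n_input_a`, `n_input_b`, `n_intersect`, `n_pass_depth_vaf`,
#'   `n_in_capture`, `tmb`. Counts are monotone non-increasing.
#' @export
filter_somatic_variants <- function(variants_a, variants_b, capture,
                                    min_depth = 40, min_vaf = 0.10,
                                    stats_from = "a",
                                    intersect_indels = FALSE) {
  capture <- as_capture(capture)
  is_pass <- function(v) if (is.null(v$filter)) rep(TRUE, nrow(v))
                         else v$filter %in% c("PASS", ".")
  snv_a <- variants_a[variants_a$var_class == "SNV" & is_pass(variants_a), ,
                      drop = FALSE]
  snv_b <- variants_b[variants_b$var_class == "SNV" & is_pass(variants_b), ,
                      drop = FALSE]
  ind_b <- variants_b[variants_b$var_class %in% c("insertion", "deletion") &
                        is_pass(variants_b), , drop = FALSE]
  inter <- intersect_callers(snv_a, snv_b, stats_from = stats_from)
  pass_dv <- inter[inter$depth >= min_depth & inter$vaf >= min_vaf, ,
                   drop = FALSE]
  snvs <- apply_filters(inter, capture, min_depth, min_vaf)
  if (intersect_indels) {
    ind_a <- variants_a[variants_a$var_class %in%
                          c("insertion", "deletion") & is_pass(variants_a), ,
                        drop = FALSE]
    ind_b <- intersect_callers(ind_b, ind_a, stats_from = "a")
  }
  indels <- apply_filters(ind_b, capture, min_depth, min_vaf)
  summary <- data.frame(
    n_input_a = nrow(snv_a), n_input_b = nrow(snv_b),
    n_intersect = nrow(inter), n_pass_depth_vaf = nrow(pass_dv),
    n_in_capture = nrow(snvs),
    tmb = compute_tmb(nrow(snvs), capture))
  class(summary) <- c("filter_summary", "data.frame")
  list(snvs = snvs, indels = indels, summary = summary)
}
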