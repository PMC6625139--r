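#' Select informative heterozygous sites for LOH analysis
#'
#' An informative site is a germline variant with VAF between `vaf_window`
#' bounds (inclusive; default 0.3-0.7, the classic heterozygous band) that
#' is also re-observed in the tumor caller's records, where the somatic
#' VAF is read. Germline-het sites with no tumor record are dropped and
#' tallied (without read-level data, absence is indistinguishable from no
#' coverage).
#'
#' @param germline Germline variant data frame.
#' @param tumor Tumor variant data frame (any `filter` value; the tumor
#'   caller's germline-tagged re-observations are exactly the records
#'   sought here).
#' @param vaf_window Germline VAF window, inclusive bounds.
#' @param min_shift,require_homozygous Passed to [call_site_loh()] to fill
#'   the `supports_loh` column.
#' @return Data frame of class `"het_sites"`: `chrom`, `pos`,
#'   `germline_vaf`, `somatic_vaf`, `supports_loh`, sorted by position,
#'   with attribute `n_dropped_no_tumor_record`. Empty (with a warning)
#'   when no informative site exists.
#' @export
select_informative_sites <- function(germline, tumor,
                                     vaf_window = c(0.3, 0.7),
                                     min_shift = 0.3,
                                     require_homozygous = FALSE) {
  het <- germline[!is.na(germline$vaf) &
                    germline$vaf >= vaf_window[1] &
                    germline$vaf <= vaf_window[2], , drop = FALSE]
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  m <- match(key(het), key(tumor))
  dropped <- sum(is.na(m))
  het <- het[!is.na(m), , drop = FALSE]
  som_vaf <- tumor$vaf[m[!is.na(m)]]
  sites <- data.frame(chrom = het$chrom, pos = het$pos,
                      germline_vaf = het$vaf, somatic_vaf = som_vaf,
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites$supports_loh <- call_site_loh(sites$germline_vaf,
                                      sites$somatic_vaf,
                                      min_shift = min_shift,
                                      require_homozygous = require_homozygous)
  rownames(sites) <- NULL
  if (nrow(sites) == 0) {
    warning("no informative heterozygous sites; ",
            "downstream region calls will be 'insufficient_data'")
  }
  structure(sites, n_dropped_no_tumor_record = dropped,
            class = c("het_sites", "data.frame"))
}

#' Site-level LOH test
#'
#' A site supports LOH when the somatic VAF has shifted by strictly more
#' than `min_shift` from the germline VAF (default 0.3; a shift of exactly
#' 0.3 does not qualify). With a single VAF axis, a shift toward
#' homozygous reference (somatic below germline) and a shift toward
#' homozygous alternate (somatic above germline) are together equivalent
#' to the absolute-difference test, which is what is computed. Optionally
#' the somatic VAF may additionally be required to leave the heterozygous
#' band itself (`require_homozygous`), i.e. fall below 0.3 or above 0.7.
#'
#' @param germline_vaf,somatic_vaf Numeric vectors in `[0, 1]`.
#' @param min_shift Strict shift threshold.
#' @param require_homozygous Also require `somatic_vaf < 0.3` or
#'   `> 0.7`. Default `FALSE` (shift-only).
#' @return Logical vector.
#' @export
call_site_loh <- function(germline_vaf, somatic_vaf, min_shift = 0.3,
                          require_homozygous = FALSE) {
  # strict inequality with a guard against floating-point residue, so a
  # shift of exactly 0.30 (e.g. 0.8 - 0.5) never qualifies
  shift <- abs(somatic_vaf - germline_vaf) - min_shift > 1e-9
  if (require_homozygous) {
    shift <- shift & (somatic_vaf < 0.3 | somatic_vaf > 0.7)
  }
  shift
}

#' Segment informative sites into LOH regions
#'
#' Slides a window of `window_sites` consecutive informative sites along
#' each chromosome; a window qualifies when its supporting fraction is at
#' least `min_support_fraction`. Overlapping qualifying windows are merged
#' into one region spanning the first to last member site. Chromosomes
#' with enough sites but no qualifying window yield a single `no-LOH`
#' region; chromosomes with fewer sites than one window yield
#' `insufficient_data`.
#'
#' @param sites Sites from [select_informative_sites()] (or any data frame
#'   with `chrom`, `pos`, `supports_loh`), sorted by position. Duplicate
#'   `(chrom, pos)` records are collapsed first.
#' @param window_sites Number of consecutive sites per window (default
#'   10).
#' @param min_support_fraction Minimum supporting fraction per window
#'   (default 0.5).
#' @return Data frame of regions: `chrom`, `start`, `end` (positions of
#'   the first/last member site), `n_sites`, `n_supporting`, `status`
#'   (`"LOH"`, `"no-LOH"` or `"insufficient_data"`).
#' @export
segment_loh_regions <- function(sites, window_sites = 10,
                                min_support_fraction = 0.5) {
  stopifnot(window_sites >= 1, min_support_fraction >= 0,
            min_support_fraction <= 1)
  sites <- as.data.frame(sites)
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    region_row <- function(i1, i2, status) {
      data.frame(chrom = ch, start = s$pos[i1], end = s$pos[i2],
                 n_sites = i2 - i1 + 1L,
                 n_supporting = sum(s$supports_loh[i1:i2]),
                 status = status, stringsAsFactors = FALSE)
    }
    if (n < window_sites) {
      out[[length(out) + 1]] <- region_row(1L, n, "insufficient_data")
      next
    }
    # supporting count per window via cumulative sums
    cs <- cumsum(c(0, s$supports_loh))
    starts <- seq_len(n - window_sites + 1L)
    frac <- (cs[starts + window_sites] - cs[starts]) / window_sites
    qualifying <- starts[frac >= min_support_fraction]
    if (length(qualifying) == 0) {
      out[[length(out) + 1]] <- region_row(1L, n, "no-LOH")
      next
    }
    # merge windows that overlap in site-index space
    w_end <- qualifying + window_sites - 1L
    run_id <- cumsum(c(TRUE, qualifying[-1] > w_end[-length(w_end)] + 1L))
    for (r in unique(run_id)) {
      i1 <- min(qualifying[run_id == r])
      i2 <- max(w_end[run_id == r])
      out[[length(out) + 1]] <- region_row(i1, i2, "LOH")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the somatic second hit affecting a gene
#'
#' In a germline carrier, the wild-type allele can be lost either by a
#' somatic point mutation in the gene or by LOH across it. Returns
#' `"somatic_mutation"` when a high- or moderate-impact somatic variant
#' falls inside the gene interval, `"LOH"` when an LOH region overlaps it,
#' both (somatic mutation first) when both occur, and `"none"` otherwise.
#'
#' @param regions Region table from [segment_loh_regions()] (may be
#'   `NULL`).
#' @param somatic_variants Filtered somatic variant data frame with an
#'   `impact` column.
#' @param gene_interval One-row data frame `chrom`, `start`, `end`
#'   (half-open 0-based) locating the gene.
#' @return Character vector of second-hit calls (`"none"` if empty).
#' @export
gene_second_hit <- function(regions, somatic_variants, gene_interval) {
  stopifnot(nrow(gene_interval) == 1)
  calls <- character(0)
  if (!is.null(somatic_variants) && nrow(somatic_variants) > 0) {
    in_gene <- somatic_variants$chrom == gene_interval$chrom &
      somatic_variants$pos > gene_interval$start &
      somatic_variants$pos <= gene_interval$end
    impact <- somatic_variants$impact
    hit <- in_gene & !is.na(impact) & impact %in% c("high", "moderate")
    if (any(hit)) calls <- c(calls, "somatic_mutation")
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    loh <- regions[regions$status == "LOH", , drop = FALSE]
    overlap <- loh$chrom == gene_interval$chrom &
      loh$start <= gene_interval$end &       # region positions are 1-based
      loh$end > gene_interval$start
    if (any(overlap)) calls <- c(calls, "LOH")
  }
  if (length(calls) == 0) "none" else calls
}

#' Per-chromosome LOH evidence plot
#'
#' Scatter of somatic VAF against position at informative germline-het
#' sites, supporting sites highlighted and called LOH regions shaded —
#' one panel per chromosome.
#'
#' @param sites Sites from [select_informative_sites()].
#' @param regions Optional region table from [segment_loh_regions()].
#' @param file Optional output file (PDF); plots to the active device
#'   when `NULL`.
#' @export
plot_loh_sites <- function(sites, regions = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 3)
    on.exit(grDevices::dev.off())
  }
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    graphics::plot(s$pos, s$somatic_vaf, ylim = c(0, 1),
                   pch = 19, cex = 0.5,
                   col = ifelse(s$supports_loh, "firebrick", "grey50"),
                   xlab = paste("position on", ch),
                   ylab = "somatic VAF at germline het sites",
                   main = paste0(ch, ": LOH evidence"))
    graphics::abline(h = c(0.3, 0.7), lty = 3, col = "grey70")
    if (!is.null(regions)) {
      r <- regions[regions$chrom == ch & regions$status == "LOH", ]
      if (nrow(r) > 0) {
        graphics::rect(r$start, -0.04, r$end, 1.04,
                       col = grDevices::adjustcolor("firebrick", 0.1),
                       border = NA)
      }
    }
  }
  invisible(NULL)
}
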