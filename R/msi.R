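#' Scan a reference for microsatellite loci
#'
#' Finds maximal, non-extendable tandem repeats with unit size 1-5 bp:
#' homopolymers of at least `min_homopolymer` repeats and multimers of at
#' least `min_multimer` repeats. Periodic motifs (e.g. "AA", "ACAC")
#' reduce to their smallest unit, and overlapping candidates are resolved
#' in favour of the smaller unit. The scan order is deterministic.
#'
#' @param reference Named character vector of sequences, `DNAStringSet`,
#'   or a [generate_reference()] list.
#' @param min_homopolymer Minimum repeats for 1 bp units (default 5).
#' @param min_multimer Minimum repeats for 2-5 bp units (default 3).
#' @return Data frame `chrom`, `start`, `end` (half-open 0-based),
#'   `unit`, `n_repeats`, sorted by position; `end - start` equals
#'   `nchar(unit) * n_repeats` (trailing partial units are not counted).
#' @export
find_microsatellites <- function(reference, min_homopolymer = 5,
                                 min_multimer = 3) {
  stopifnot(min_homopolymer >= 2, min_multimer >= 2)
  seqs <- ref_as_character(reference)
  out <- list()
  for (ch in names(seqs)) {
    seq <- seqs[[ch]]
    cand <- list()
    for (k in 1:5) {
      min_rep <- if (k == 1) min_homopolymer else min_multimer
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_rep - 1)
      m <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      n_rep <- len %/% k
      unit <- substr(rep(seq, length(m)), m, m + k - 1)
      periodic <- vapply(unit, is_periodic_unit, logical(1))
      keep <- !periodic
      if (!any(keep)) next
      cand[[k]] <- data.frame(
        chrom = ch, start = as.integer(m[keep] - 1),
        end = as.integer(m[keep] - 1 + k * n_rep[keep]),
        unit = unname(unit[keep]), n_repeats = n_rep[keep],
        stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0) next
    # smaller units win overlaps; scan in (unit size, position) order
    cand <- cand[order(nchar(cand$unit), cand$start), , drop = FALSE]
    accepted <- logical(nrow(cand))
    occ_start <- integer(0); occ_end <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!any(cand$start[i] < occ_end & cand$end[i] > occ_start)) {
        accepted[i] <- TRUE
        occ_start <- c(occ_start, cand$start[i])
        occ_end <- c(occ_end, cand$end[i])
      }
    }
    out[[ch]] <- cand[accepted, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      n_repeats = integer(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# TRUE when a motif is a whole-number repetition of a shorter motif
is_periodic_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1) return(FALSE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit) {
      return(TRUE)
    }
  }
  FALSE
}

#' Count somatic indels at exonic microsatellites
#'
#' Counts indels whose reference-affected span (the deleted bases for a
#' deletion, the single anchor base for an insertion) overlaps both a
#' microsatellite locus and an exon interval. Each indel is counted once.
#'
#' @param indels Variant data frame of normalized indels.
#' @param loci Microsatellite loci (`chrom`, `start`, `end`, half-open
#'   0-based).
#' @param exon_regions Exon intervals (`chrom`, `start`, `end`, half-open
#'   0-based).
#' @return Integer count.
#' @export
count_exonic_ms_indels <- function(indels, loci, exon_regions) {
  indels <- indels[indels$var_class %in% c("insertion", "deletion"), ,
                   drop = FALSE]
  if (nrow(indels) == 0 || nrow(loci) == 0 || nrow(exon_regions) == 0) {
    return(0L)
  }
  spans <- variant_spans(indels)
  in_ms <- GenomicRanges::countOverlaps(spans,
                                        intervals_to_granges(loci)) > 0
  in_ex <- GenomicRanges::countOverlaps(
    spans, intervals_to_granges(exon_regions)) > 0
  sum(in_ms & in_ex)
}

#' Microsatellite instability score
#'
#' Percentage of microsatellite loci affected by at least one somatic
#' indel. This is a locus-overlap score over called indels — a declared
#' proxy for read-level MSI callers, faithful to the "percentage of
#' microsatellites affected by indels" definition but not comparable in
#' absolute value to tools that model per-read repeat-length
#' distributions.
#'
#' @param indels Variant data frame of somatic indels.
#' @param loci Microsatellite loci; must be non-empty.
#' @return Percentage in `[0, 100]`; multiple indels at one locus count
#'   that locus once.
#' @export
msi_score <- function(indels, loci) {
  if (nrow(loci) == 0) stop("msi_score undefined with zero loci")
  indels <- indels[indels$var_class %in% c("insertion", "deletion"), ,
                   drop = FALSE]
  if (nrow(indels) == 0) return(0)
  hit <- GenomicRanges::countOverlaps(intervals_to_granges(loci),
                                      variant_spans(indels)) > 0
  100 * sum(hit) / nrow(loci)
}

#' Coding-microsatellite frameshift report
#'
#' For each gene in a panel of coding-microsatellite intervals, reports
#' `"Frameshift"` when a somatic indel whose length is not divisible by 3
#' overlaps the gene's coding-microsatellite interval, else `"None"`.
#'
#' @param indels Variant data frame of somatic indels.
#' @param gene_panel Data frame `gene`, `chrom`, `start`, `end` (half-open
#'   0-based), one row per panel gene.
#' @return Data frame `gene`, `call` in panel order.
#' @export
coding_ms_frameshift_report <- function(indels, gene_panel) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_panel)))
  indels <- indels[indels$var_class %in% c("insertion", "deletion"), ,
                   drop = FALSE]
  fs <- indels[abs(nchar(indels$alt) - nchar(indels$ref)) %% 3 != 0, ,
               drop = FALSE]
  call <- rep("None", nrow(gene_panel))
  if (nrow(fs) > 0 && nrow(gene_panel) > 0) {
    hit <- GenomicRanges::countOverlaps(intervals_to_granges(gene_panel),
                                        variant_spans(fs)) > 0
    call[hit] <- "Frameshift"
  }
  data.frame(gene = gene_panel$gene, call = call, stringsAsFactors = FALSE)
}

#' Default coding-microsatellite gene panel names
#'
#' The 14 genes whose coding microsatellite regions are recurrently hit by
#' somatic indels in MMR-deficient colorectal and endometrial cancer, used
#' as the default frameshift report panel. Interval coordinates must be
#' supplied by the user's gene-model BED for real genomes.
#'
#' @return Character vector of 14 gene symbols.
#' @export
default_ms_gene_panel <- function() {
  c("TGFBR2", "TAF1B", "AIM2", "ASTE1", "ACVR2", "CASP5", "NDUFC2",
    "SLC2289", "MSH3", "SMAP1", "OR7E24", "KIAA2018", "JAK1", "C18ORF34")
}

#' Summarize microsatellite instability for one sample
#'
#' @param indels Somatic indels (filtered).
#' @param loci Microsatellite loci.
#' @param exon_regions Exon intervals.
#' @return List of class `"msi_summary"`: `n_loci`, `n_affected`,
#'   `score` (percent), `n_exonic_ms_indels`.
#' @export
msi_summary <- function(indels, loci, exon_regions) {
  score <- msi_score(indels, loci)
  structure(list(n_loci = nrow(loci),
                 n_affected = as.integer(round(score * nrow(loci) / 100)),
                 score = score,
                 n_exonic_ms_indels = count_exonic_ms_indels(indels, loci,
                                                             exon_regions)),
            class = "msi_summary")
}
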