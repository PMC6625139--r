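#' Write a variant table as VCF 4.2
#'
#' Emits one single-sample VCF with `GT:DP:AD` FORMAT fields (AD as
#' ref,alt counts) and the variant's `filter` and `impact` columns in the
#' FILTER and INFO fields. Output is deterministic for a given table.
#'
#' @param variants Variant data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, optional `filter`, `impact`).
#' @param path Output path (plain text).
#' @param sample_name Sample column name.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(variants, path, sample_name = "SAMPLE",
                      contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  hdr <- c(
    hdr,
    "##FILTER=<ID=germline,Description=\"Evidence of a germline origin\">",
    paste0("##INFO=<ID=IMPACT,Number=1,Type=String,",
           "Description=\"Predicted impact\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  filt <- if (is.null(variants$filter)) rep("PASS", nrow(variants))
          else variants$filter
  info <- if (is.null(variants$impact)) rep(".", nrow(variants))
          else ifelse(is.na(variants$impact), ".",
                      paste0("IMPACT=", variants$impact))
  body <- if (nrow(variants) > 0) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    v <- variants[ord, , drop = FALSE]
    filt <- filt[ord]; info <- info[ord]
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", filt, info, "GT:DP:AD",
          sprintf("0/1:%d:%d,%d", v$depth, v$depth - v$alt_count,
                  v$alt_count),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a normalized variant table
#'
#' Multi-allelic records are split into one row per alternate allele (with
#' the matching AD entry). VAF is taken from AD when present, else from an
#' AF INFO field; a record with neither is an error. The variant class is
#' derived from allele lengths (`SNV`, `insertion`, `deletion`, or
#' `other` for balanced multi-base substitutions, which downstream catalog
#' construction skips).
#'
#' @param path VCF path (plain or bgzipped).
#' @return Variant data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `vaf`, `filter`, `var_class`, `impact`.
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(v@fix) == 0) return(new_variant_df())
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)          # vcfR drops dims at 1 record
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt_field <- function(tag) {
    tryCatch(as.character(vcfR::extract.gt(v, tag))[seq_len(nrow(fix))],
             error = function(e) rep(NA_character_, nrow(fix)))
  }
  dp <- suppressWarnings(as.integer(gt_field("DP")))
  ad <- gt_field("AD")
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  impact <- vcfR::extract.info(v, "IMPACT")
  if (is.null(impact)) impact <- rep(NA_character_, nrow(fix))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.na(ad[i])) {
      suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    } else NULL
    depth_i <- if (!is.na(dp[i])) dp[i]
               else if (!is.null(ads)) sum(ads) else NA_integer_
    lapply(seq_along(alts), function(j) {
      alt_count <- if (!is.null(ads) && length(ads) >= j + 1) ads[j + 1]
                   else NA_integer_
      vaf <- if (!is.na(alt_count) && !is.na(depth_i) && depth_i > 0) {
        alt_count / depth_i
      } else if (length(af) >= i && !is.na(af[i])) {
        af[i]
      } else {
        stop("record ", fix$CHROM[i], ":", fix$POS[i],
             " has neither AD nor AF; cannot compute VAF")
      }
      data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts[j],
                 depth = depth_i, alt_count = alt_count, vaf = vaf,
                 filter = ifelse(is.na(fix$FILTER[i]), "PASS",
                                 fix$FILTER[i]),
                 var_class = variant_class(fix$REF[i], alts[j]),
                 impact = impact[i], stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Variant class from allele lengths
#'
#' @param ref,alt Allele strings.
#' @return `"SNV"`, `"insertion"`, `"deletion"`, or `"other"`.
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1 & na == 1, "SNV",
         ifelse(na > nr, "insertion",
                ifelse(nr > na, "deletion", "other")))
}

#' Write / read a reference as FASTA
#'
#' @param reference Named character vector of sequences or a
#'   [generate_reference()] list.
#' @param path FASTA path.
#' @param width Line width for wrapping.
#' @return `read_reference_fasta()`: named character vector.
#' @export
write_reference_fasta <- function(reference, path, width = 70L) {
  seqs <- ref_as_character(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open; columns chrom, start, end and
#'   optionally name).
#' @return Data frame `chrom`, `start`, `end` (and `name` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[, seq_len(min(4, ncol(df))), drop = FALSE]
}

# intervals data frame (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = df$end))
}

# variant table -> GRanges of reference-affected spans:
# SNV = the site; deletion = the deleted bases; insertion = the anchor
# base plus the base after it (a left-aligned insertion's anchor sits one
# base before the run it extends, so the anchor alone would miss the run)
variant_spans <- function(variants) {
  len <- nchar(variants$ref)
  start <- ifelse(variants$var_class == "deletion",
                  variants$pos + 1, variants$pos)
  end <- ifelse(variants$var_class == "deletion", variants$pos + len - 1,
                ifelse(variants$var_class == "insertion",
                       variants$pos + 1, variants$pos))
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = start, end = end))
}
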