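#' The 96 trinucleotide substitution context labels
#'
#' Labels follow the pyrimidine-reference convention used by the standard
#' 30-signature tables: six substitution classes in the fixed order
#' C>A, C>G, C>T, T>A, T>C, T>G, and within each class the 16 flank pairs in
#' alphabetical order (`A[.]A`, `A[.]C`, ..., `T[.]T`).
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
context_labels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f5, f3) {
      paste0(f5, "[", s, "]", f3)
    })))
  }))
}

# substitution class and flanks for each of the 96 bins, as a data.frame
context_table <- function() {
  lab <- context_labels()
  data.frame(
    label = lab,
    five = substr(lab, 1, 1),
    ref = substr(lab, 3, 3),
    alt = substr(lab, 5, 5),
    three = substr(lab, 7, 7),
    stringsAsFactors = FALSE
  )
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# reverse complement of trinucleotide strings, vectorized
revcomp3 <- function(x) {
  paste0(comp_base(substr(x, 3, 3)), comp_base(substr(x, 2, 2)),
         comp_base(substr(x, 1, 1)))
}

# normalize a reference to a named character vector of uppercase sequences
ref_as_character <- function(reference) {
  if (is.list(reference) && !is.null(reference$sequence)) {
    reference <- reference$sequence
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- as.character(reference)
  }
  if (!is.character(reference) || is.null(names(reference))) {
    stop("reference must be a named character vector, DNAStringSet, ",
         "or a synthetic reference list")
  }
  toupper(reference)
}

#' Classify SNVs into the 96 trinucleotide contexts
#'
#' Looks up the 5' and 3' flanking bases in the reference and assigns each
#' single-nucleotide variant to one of the 96 substitution-context bins.
#' Purine-reference variants (A or G) are reverse-complemented, substitution
#' and flanks together, before binning, so the returned bin always has a
#' pyrimidine reference base.
#'
#' @param reference Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or the list returned by [generate_reference()].
#' @param chrom,pos,ref,alt Vectors describing the variants (`pos` 1-based).
#' @return Integer vector of 1-based bin indices into [context_labels()];
#'   `NA` where the variant is unclassifiable (non-ACGT flank or reference
#'   mismatch). Unclassifiable variants are a tally for the caller, not an
#'   error.
#' @export
classify_context <- function(reference, chrom, pos, ref, alt) {
  seqs <- ref_as_character(reference)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (n == 0) return(integer(0))
  if (!all(chrom %in% names(seqs))) {
    stop("variant chromosome(s) not present in reference: ",
         paste(unique(setdiff(chrom, names(seqs))), collapse = ", "))
  }
  lens <- nchar(seqs)[chrom]
  ok <- pos >= 2 & pos <= lens - 1 & nchar(ref) == 1 & nchar(alt) == 1
  tri <- rep(NA_character_, n)
  tri[ok] <- substr(seqs[chrom[ok]], pos[ok] - 1, pos[ok] + 1)
  # reference allele must match the sequence; flanks must be plain ACGT
  ok <- ok & !is.na(tri) & substr(tri, 2, 2) == ref &
    !grepl("[^ACGT]", paste0(tri, alt))
  tri[!ok] <- NA_character_
  sub <- paste0(ref, ">", alt)
  purine <- ref %in% c("A", "G")
  tri[ok & purine] <- revcomp3(tri[ok & purine])
  sub[purine] <- paste0(comp_base(ref[purine]), ">", comp_base(alt[purine]))
  lab <- paste0(substr(tri, 1, 1), "[", sub, "]", substr(tri, 3, 3))
  idx <- match(lab, context_labels())
  idx[!ok] <- NA_integer_
  idx
}

#' Build a 96-bin trinucleotide catalog from somatic variants
#'
#' Only single-nucleotide variants contribute; indels and other classes are
#' ignored. Variants whose context cannot be determined are excluded and
#' reported in the `"unclassifiable"` attribute, so that
#' `sum(catalog) + unclassifiable` equals the number of input SNVs.
#'
#' @param variants Data frame of somatic variants with columns `chrom`,
#'   `pos`, `ref`, `alt` and (optionally) `var_class`.
#' @param reference Reference accepted by [classify_context()].
#' @return Named integer vector of length 96 (class
#'   `"trinucleotide_catalog"`), names as in [context_labels()], with
#'   attribute `unclassifiable`.
#' @export
build_catalog <- function(variants, reference) {
  if (!is.null(variants$var_class)) {
    variants <- variants[variants$var_class == "SNV", , drop = FALSE]
  } else {
    variants <- variants[nchar(variants$ref) == 1 &
                           nchar(variants$alt) == 1, , drop = FALSE]
  }
  counts <- integer(96)
  unclassifiable <- 0L
  if (nrow(variants) > 0) {
    idx <- classify_context(reference, variants$chrom, variants$pos,
                            variants$ref, variants$alt)
    unclassifiable <- sum(is.na(idx))
    counts <- tabulate(idx, nbins = 96)
  }
  names(counts) <- context_labels()
  structure(counts, unclassifiable = unclassifiable,
            class = c("trinucleotide_catalog", "integer"))
}

#' Write or read a 96-bin catalog as TSV
#'
#' Two-column table: context label and count, in canonical bin order.
#'
#' @param catalog Named 96-vector of counts.
#' @param path File path.
#' @return `read_catalog()` returns the named integer vector.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(length(catalog) == 96)
  utils::write.table(
    data.frame(context = context_labels(), count = as.integer(catalog)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- as.integer(df$count[match(context_labels(), df$context)])
  if (anyNA(counts)) stop("catalog file does not cover all 96 contexts")
  names(counts) <- context_labels()
  counts
}
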