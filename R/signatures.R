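# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Synthetic 30-signature probability matrix
#'
#' A deterministic stand-in for the standard panel of 30 single-base
#' substitution signatures (the real panel is distributed by COSMIC and is
#' not bundled here). Each row is a probability distribution over the 96
#' trinucleotide contexts. A few rows are shaped after well-known
#' aetiologies so that synthetic cohorts resemble real ones:
#' \itemize{
#'   \item `Signature.1` — C>T concentrated at NpCpG (5-methylcytosine
#'     deamination-like);
#'   \item `Signature.4` / `Signature.29` — C>A dominated (tobacco-like);
#'   \item `Signature.6` / `Signature.15` — C>T rich with distinct flank
#'     preferences plus small indel-free C>A / T>C components
#'     (mismatch-repair-deficiency-like);
#'   \item `Signature.7` — C>T at dipyrimidines, 5' C or T (ultraviolet-like).
#' }
#' The remaining rows are sparse Dirichlet draws under a fixed internal
#' seed, so the matrix is identical in every session. The same table ships
#' as `inst/extdata/signatures_synthetic_30x96.tsv`.
#'
#' @return Numeric matrix, 30 rows (named `Signature.1` ... `Signature.30`)
#'   by 96 columns (named as [context_labels()]); rows sum to 1.
#' @export
synthetic_signature_matrix <- function() {
  ctx <- context_table()
  n_sig <- 30L
  with_seed(780219L, {
    # sparse random baseline: gamma draws ~ Dirichlet(0.12)
    mat <- matrix(stats::rgamma(n_sig * 96, shape = 0.12), nrow = n_sig)
    shaped <- function(base_mask, base_w, noise = 0.02) {
      w <- ifelse(base_mask, base_w, 0) + stats::rgamma(96, shape = 0.5) * noise
      w / sum(w)
    }
    is_ct <- ctx$ref == "C" & ctx$alt == "T"
    is_ca <- ctx$ref == "C" & ctx$alt == "A"
    is_tc <- ctx$ref == "T" & ctx$alt == "C"
    mat[1, ] <- shaped(is_ct & ctx$three == "G", 1.0, noise = 0.01)
    mat[4, ] <- shaped(is_ca, 0.6 + 0.4 * (ctx$five == "C"), noise = 0.02)
    mat[6, ] <- shaped(is_ct & ctx$five %in% c("A", "G"),
                       0.8 + 0.4 * (ctx$three == "C"), noise = 0.03)
    mat[7, ] <- shaped(is_ct & ctx$five %in% c("C", "T"),
                       0.7 + 0.6 * (ctx$five == "T"), noise = 0.01)
    mat[15, ] <- shaped((is_ct & ctx$five == "T") | (is_tc & ctx$five == "G"),
                        0.9, noise = 0.03)
    mat[29, ] <- shaped(is_ca & ctx$three %in% c("A", "T"), 0.8, noise = 0.02)
    mat <- mat / rowSums(mat)
    dimnames(mat) <- list(paste0("Signature.", seq_len(n_sig)),
                          context_labels())
    mat
  })
}

validate_signature_matrix <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) != 96) {
    stop("signature matrix must have 96 context columns")
  }
  if (any(mat < 0)) stop("signature matrix entries must be non-negative")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("signature matrix rows must each sum to 1 (tolerance 1e-6)")
  }
  if (!identical(colnames(mat), context_labels())) {
    stop("signature matrix columns must follow the canonical context order")
  }
  invisible(mat)
}

#' Read / write a signature probability matrix TSV
#'
#' The file dialect is the one used by the public signature tables: a header
#' row of signature ids preceded by a `context` column, then 96 data rows
#' keyed by context label (e.g. `A[C>A]A`). Rows may appear in any order in
#' the file; they are returned in canonical context order.
#'
#' @param path File path.
#' @param renormalize Renormalize rows to sum exactly to 1 after reading
#'   (guards against decimal truncation in the file). Default `TRUE`.
#' @return `read_signature_matrix()`: matrix of signatures (rows) by the 96
#'   contexts (columns), rows summing to 1.
#' @export
read_signature_matrix <- function(path, renormalize = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"context" %in% names(df)) stop("missing 'context' column")
  ord <- match(context_labels(), df$context)
  if (anyNA(ord)) stop("signature file does not cover all 96 contexts")
  mat <- t(as.matrix(df[ord, setdiff(names(df), "context"), drop = FALSE]))
  colnames(mat) <- context_labels()
  if (renormalize) mat <- mat / rowSums(mat)
  validate_signature_matrix(mat)
  mat
}

#' @rdname read_signature_matrix
#' @param mat Signature matrix (signatures in rows, 96 context columns).
#' @export
write_signature_matrix <- function(mat, path) {
  validate_signature_matrix(mat)
  df <- data.frame(context = context_labels(), t(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled synthetic signature panel
#'
#' Reads `signatures_synthetic_30x96.tsv` from the installed package. This
#' is the synthetic panel of [synthetic_signature_matrix()]; analyses of
#' real data should pass the genuine 30-signature table through
#' [read_signature_matrix()] instead.
#'
#' @return 30 x 96 signature matrix.
#' @export
example_signature_matrix <- function() {
  path <- system.file("extdata", "signatures_synthetic_30x96.tsv",
                      package = "mmrsig", mustWork = TRUE)
  read_signature_matrix(path)
}
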