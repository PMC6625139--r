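#' Cosine similarity between two non-negative 96-bin vectors
#'
#' @param a,b Non-negative numeric vectors of equal length, neither all
#'   zero.
#' @return Similarity in `[0, 1]`; scale-invariant in each argument.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("vectors must be non-negative")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Refit a trinucleotide catalog against a signature panel
#'
#' Decomposes a 96-bin mutation catalog into non-negative exposures over a
#' panel of predefined signatures by maximizing the cosine similarity
#' between the normalized catalog and the reconstructed linear combination
#' (the approach popularized by deconstructSigs-style refitting tools).
#'
#' The algorithm is greedy forward selection. Starting from the empty
#' model, each iteration considers every signature in the panel: the
#' candidate's mixing weight `w` in `[0, 1]` (the fraction of the
#' reconstruction handed to the candidate, the remainder rescaling the
#' current exposures) is chosen by a bounded scalar search, and the best
#' candidate is accepted only if it improves the objective by more than
#' `improvement_tol`. Ties are broken in favour of the lowest signature
#' index. After convergence, exposures below `weight_floor` are zeroed and
#' the remainder renormalized to sum to 1. The achieved objective is
#' non-decreasing across accepted iterations.
#'
#' @param catalog Numeric 96-vector of context counts (or frequencies);
#'   must not be all zero.
#' @param signatures Signature matrix (rows = signatures, 96 columns), as
#'   from [read_signature_matrix()] or [synthetic_signature_matrix()].
#' @param weight_floor Exposures below this fraction are discarded after
#'   convergence (default 0.06, the discard rule of the reference tool).
#' @param improvement_tol Minimum objective improvement to accept another
#'   iteration (default 1e-4).
#' @param max_iterations Hard cap on accepted iterations.
#' @param objective `"cosine"` (default) maximizes cosine similarity;
#'   `"sse"` minimizes the sum of squared frequency errors instead. The
#'   two agree closely on clean mixtures.
#' @return List of class `"exposure_vector"`: `weights` (named, sums to 1),
#'   `cosine` (achieved similarity of the final reconstruction),
#'   `n_iterations`, and `history` (objective after each accepted
#'   iteration).
#' @export
refit_signatures <- function(catalog, signatures,
                             weight_floor = 0.06,
                             improvement_tol = 1e-4,
                             max_iterations = 100L,
                             objective = c("cosine", "sse")) {
  objective <- match.arg(objective)
  validate_signature_matrix(signatures)
  stopifnot(length(catalog) == 96, weight_floor >= 0, weight_floor < 0.5,
            improvement_tol > 0)
  if (any(catalog < 0)) stop("catalog counts must be non-negative")
  total <- sum(catalog)
  if (total <= 0) stop("cannot refit an all-zero catalog")
  m <- as.numeric(catalog) / total
  n_sig <- nrow(signatures)

  obj <- if (objective == "cosine") {
    function(recon) cosine_similarity(m, recon)
  } else {
    function(recon) -sum((m - recon)^2)
  }

  # iteration 1: best single signature (also the degenerate fallback)
  start_vals <- vapply(seq_len(n_sig), function(j) obj(signatures[j, ]),
                       numeric(1))
  best_j <- which.max(start_vals)            # which.max takes lowest index on ties
  x <- numeric(n_sig)
  x[best_j] <- 1
  current <- start_vals[best_j]
  history <- current
  n_iter <- 1L

  while (n_iter < max_iterations) {
    recon <- as.numeric(x %*% signatures)
    step_best <- list(val = current, j = NA_integer_, w = NA_real_)
    for (j in seq_len(n_sig)) {
      f <- function(w) obj((1 - w) * recon + w * signatures[j, ])
      opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-4)
      if (opt$objective > step_best$val + 1e-15) {
        step_best <- list(val = opt$objective, j = j, w = opt$maximum)
      }
    }
    if (is.na(step_best$j) || step_best$val - current <= improvement_tol) {
      break
    }
    x <- (1 - step_best$w) * x
    x[step_best$j] <- x[step_best$j] + step_best$w
    current <- step_best$val
    history <- c(history, current)
    n_iter <- n_iter + 1L
  }

  x[x < weight_floor] <- 0
  if (sum(x) == 0) {                         # floor removed everything: keep the best single
    x[best_j] <- 1
  }
  x <- x / sum(x)
  names(x) <- rownames(signatures)
  final_cos <- cosine_similarity(m, as.numeric(x %*% signatures))
  structure(list(weights = x, cosine = final_cos, n_iterations = n_iter,
                 history = history),
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat("Signature exposures (cosine similarity ",
      formatC(x$cosine, digits = 4, format = "f"), ", ",
      x$n_iterations, " iterations)\n", sep = "")
  w <- x$weights[x$weights > 0]
  w <- w[order(-w)]
  for (id in names(w)) {
    cat(sprintf("  %-14s %5.1f%%\n", id, 100 * w[[id]]))
  }
  invisible(x)
}

#' Combined percentage contribution of a set of signatures
#'
#' @param exposures An `"exposure_vector"` from [refit_signatures()], or a
#'   named weight vector summing to 1.
#' @param ids Signature ids to combine, e.g.
#'   `c("Signature.6", "Signature.15")`.
#' @return Combined contribution as a percentage (0-100).
#' @export
combined_contribution <- function(exposures, ids) {
  w <- if (inherits(exposures, "exposure_vector")) exposures$weights
       else exposures
  if (length(ids) == 0) return(0)
  missing_ids <- setdiff(ids, names(w))
  if (length(missing_ids) > 0) {
    stop("unknown signature id(s): ", paste(missing_ids, collapse = ", "))
  }
  100 * sum(w[ids])
}

#' Write refitted exposures as TSV
#'
#' Three columns: signature, weight (fraction), percent.
#'
#' @param exposures `"exposure_vector"` object.
#' @param path File path.
#' @export
write_exposures <- function(exposures, path) {
  w <- exposures$weights
  utils::write.table(
    data.frame(signature = names(w), weight = as.numeric(w),
               percent = 100 * as.numeric(w)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
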