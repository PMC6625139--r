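# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive re-derivations (grid search, per-position
# scans, quadrature) that never call the code paths they check.

sig_panel <- example_signature_matrix()

# exhaustive simplex grid search over <= 3 signatures: the refit oracle
grid_refit_oracle <- function(catalog, signatures, ids, step = 0.005) {
  m <- catalog / sum(catalog)
  P <- signatures[ids, , drop = FALSE]
  ws <- seq(0, 1, by = step)
  grids <- switch(as.character(length(ids)),
    "1" = matrix(1, 1, 1),
    "2" = cbind(ws, 1 - ws),
    "3" = {
      g <- expand.grid(w1 = ws, w2 = ws)
      g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
      cbind(g$w1, g$w2, pmax(0, 1 - g$w1 - g$w2))
    },
    stop("oracle supports at most 3 signatures"))
  recon <- grids %*% P
  cosines <- as.numeric(recon %*% m) /
    (sqrt(rowSums(recon^2)) * sqrt(sum(m^2)))
  best <- which.max(cosines)
  list(cosine = cosines[best],
       weights = stats::setNames(grids[best, ], ids))
}

# naive per-position microsatellite scan (candidate at every start, then
# the same smaller-unit-first overlap resolution)
ms_scan_oracle <- function(seq, min_homopolymer = 5, min_multimer = 3) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  is_per <- function(u) {
    k <- nchar(u)
    if (k == 1) return(FALSE)
    any(vapply(seq_len(k - 1), function(d) {
      k %% d == 0 && strrep(substr(u, 1, d), k / d) == u
    }, logical(1)))
  }
  cand <- list()
  for (k in 1:5) {
    minr <- if (k == 1) min_homopolymer else min_multimer
    for (i in seq_len(n - k * minr + 1)) {
      unit <- paste(chars[i:(i + k - 1)], collapse = "")
      if (is_per(unit)) next
      if (i - k >= 1 &&
          paste(chars[(i - k):(i - 1)], collapse = "") == unit) next
      r <- 1
      while (i + (r + 1) * k - 1 <= n &&
             paste(chars[(i + r * k):(i + (r + 1) * k - 1)],
                   collapse = "") == unit) {
        r <- r + 1
      }
      if (r >= minr) {
        cand[[length(cand) + 1]] <-
          data.frame(start = i - 1, end = i - 1 + r * k, unit = unit,
                     n_repeats = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), n_repeats = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(nchar(cand$unit), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  occ <- cbind(integer(0), integer(0))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < occ[, 2] & cand$end[i] > occ[, 1])) {
      keep[i] <- TRUE
      occ <- rbind(occ, c(cand$start[i], cand$end[i]))
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# two-tailed t probability by quadrature over the t density
t_p_quadrature <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-13, abs.tol = 0)$value
}

# small standard fixture: 100 kb reference with a poly-A microsatellite
# every 200 bases, whole sequence as capture/exon region
make_test_reference <- function(seed = 3, length = 100000,
                                ms_every = 200) {
  plan <- lapply(seq(1000, length - 1000, by = ms_every),
                 function(p) list(unit = "A", n_repeats = 8, pos = p))
  generate_reference(length, microsatellite_plan = plan, seed = seed)
}

whole_interval <- function(ref) {
  ch <- names(ref$sequence)
  data.frame(chrom = ch, start = 0, end = nchar(ref$sequence[[ch]]),
             stringsAsFactors = FALSE)
}

mmrd_mixture <- function(total = 1000) {
  signature_mixture(c(Signature.6 = 0.31, Signature.15 = 0.10,
                      Signature.1 = 0.59), total)
}
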