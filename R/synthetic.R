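#' Define a signature mixture for simulation
#'
#' @param weights Named numeric vector of per-signature fractions; must be
#'   non-negative and sum to 1 (tolerance 1e-9). Names must match rows of
#'   the signature matrix used downstream (e.g. `"Signature.6"`).
#' @param total_snvs Number of somatic SNVs to draw from the mixture.
#' @return Object of class `"signature_mixture"`.
#' @export
signature_mixture <- function(weights, total_snvs) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (total_snvs < 0) stop("total_snvs must be non-negative")
  structure(list(weights = weights, total_snvs = as.integer(total_snvs)),
            class = "signature_mixture")
}

#' Generate a synthetic reference sequence with planned microsatellites
#'
#' Builds a random sequence with the requested GC fraction and embeds each
#' planned microsatellite verbatim at its stated position (0-based start).
#' The planned loci are returned as a truth table in half-open 0-based
#' coordinates.
#'
#' @param length Sequence length in bases (minimum 10,000).
#' @param gc_fraction Fraction of G+C in the random background.
#' @param microsatellite_plan List of `list(unit, n_repeats, pos)` entries:
#'   `unit` is a 1-5 bp motif over ACGT, `pos` the 0-based start of the
#'   run. Loci must fit inside the sequence without overlapping; a plan
#'   that cannot be placed raises an error rather than being truncated.
#' @param seed Integer seed; the same plan and seed give a byte-identical
#'   sequence.
#' @param chrom Chromosome name for the single generated sequence.
#' @return List with `sequence` (named character vector of one sequence)
#'   and `ms_loci` (data frame `chrom`, `start`, `end`, `unit`,
#'   `n_repeats`).
#' @export
generate_reference <- function(length, gc_fraction = 0.41,
                               microsatellite_plan = list(),
                               seed = 1L, chrom = "chr1") {
  stopifnot(length >= 10000, gc_fraction >= 0, gc_fraction <= 1)
  plan <- lapply(microsatellite_plan, function(p) {
    if (!grepl("^[ACGT]{1,5}$", p$unit)) {
      stop("microsatellite unit must be 1-5 bp over ACGT: ", p$unit)
    }
    if (p$n_repeats < 2) stop("n_repeats must be at least 2")
    list(unit = p$unit, n_repeats = as.integer(p$n_repeats),
         start = as.integer(p$pos),
         end = as.integer(p$pos) + nchar(p$unit) * as.integer(p$n_repeats))
  })
  if (length(plan) > 0) {
    starts <- vapply(plan, `[[`, integer(1), "start")
    ends <- vapply(plan, `[[`, integer(1), "end")
    if (any(starts < 1) || any(ends > length)) {
      stop("cannot place microsatellite plan: locus outside the sequence")
    }
    ord <- order(starts)
    if (any(starts[ord][-1] < ends[ord][-length(ends)])) {
      stop("cannot place microsatellite plan: loci overlap")
    }
  }
  seq <- with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  })
  for (p in plan) {
    substr(seq, p$start + 1, p$end) <- strrep(p$unit, p$n_repeats)
  }
  loci <- if (length(plan) > 0) {
    data.frame(chrom = chrom,
               start = vapply(plan, `[[`, integer(1), "start"),
               end = vapply(plan, `[[`, integer(1), "end"),
               unit = vapply(plan, `[[`, character(1), "unit"),
               n_repeats = vapply(plan, `[[`, integer(1), "n_repeats"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), n_repeats = integer(0),
               stringsAsFactors = FALSE)
  }
  stats::setNames(list(stats::setNames(seq, chrom), loci),
                  c("sequence", "ms_loci"))
}

#' Draw a 96-bin catalog from a signature mixture
#'
#' The analytic bin distribution is the mixture-weighted combination of the
#' signature rows; counts are drawn from a multinomial over that
#' distribution (or returned as exact expected counts).
#'
#' @param mixture A [signature_mixture()].
#' @param signatures Signature matrix (rows summing to 1).
#' @param seed Integer seed for the multinomial draw.
#' @param expected If `TRUE`, return the exact expected counts
#'   `total_snvs * p` instead of sampling.
#' @return Named numeric 96-vector of counts.
#' @export
simulate_catalog <- function(mixture, signatures, seed = 1L,
                             expected = FALSE) {
  validate_signature_matrix(signatures)
  unknown <- setdiff(names(mixture$weights), rownames(signatures))
  if (length(unknown) > 0) {
    stop("unknown signature id(s) in mixture: ",
         paste(unknown, collapse = ", "))
  }
  p <- as.numeric(mixture$weights %*%
                    signatures[names(mixture$weights), , drop = FALSE])
  counts <- if (expected) {
    mixture$total_snvs * p
  } else {
    with_seed(seed,
              as.numeric(stats::rmultinom(1, mixture$total_snvs, p)))
  }
  stats::setNames(counts, context_labels())
}

#' Specify one synthetic tumor/germline sample
#'
#' @param mixture [signature_mixture()] for the somatic SNVs.
#' @param n_germline_hets Number of germline heterozygous SNPs.
#' @param loh_segments Data frame `chrom`, `start`, `end` (half-open
#'   0-based), `retained` (`"ref"` or `"alt"`, the allele kept by the
#'   somatic loss); segments must not overlap within a chromosome. `NULL`
#'   for none.
#' @param ms_indel_rate Fraction of planned microsatellite loci receiving a
#'   somatic +/- 1-unit indel.
#' @param depth_mean Mean sequencing depth (reads) for simulated records.
#' @param caller_overlap Fraction of somatic SNVs emitted by both
#'   pseudo-callers; the remainder are split between them.
#' @param seed Integer seed; the full sample is deterministic given the
#'   spec.
#' @return Object of class `"synthetic_sample_spec"`.
#' @export
synthetic_sample_spec <- function(mixture, n_germline_hets = 200L,
                                  loh_segments = NULL,
                                  ms_indel_rate = 0,
                                  depth_mean = 80,
                                  caller_overlap = 1,
                                  seed = 1L) {
  stopifnot(inherits(mixture, "signature_mixture"),
            n_germline_hets >= 0,
            ms_indel_rate >= 0, ms_indel_rate <= 1,
            caller_overlap >= 0, caller_overlap <= 1,
            depth_mean > 0)
  if (!is.null(loh_segments) && nrow(loh_segments) > 0) {
    stopifnot(all(c("chrom", "start", "end", "retained") %in%
                    names(loh_segments)),
              all(loh_segments$retained %in% c("ref", "alt")))
    for (ch in unique(loh_segments$chrom)) {
      s <- loh_segments[loh_segments$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("loh_segments overlap on ", ch)
      }
    }
  }
  structure(list(mixture = mixture,
                 n_germline_hets = as.integer(n_germline_hets),
                 loh_segments = loh_segments,
                 ms_indel_rate = ms_indel_rate,
                 depth_mean = depth_mean,
                 caller_overlap = caller_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_sample_spec")
}

# sample alt counts at given success probability, resampling rows until
# `accept(alt, depth)` holds (used to enforce VAF floors/shifts)
rbinom_accept <- function(depth, prob, accept, max_tries = 1000L) {
  alt <- stats::rbinom(length(depth), depth, prob)
  for (i in seq_len(max_tries)) {
    bad <- !accept(alt, depth)
    if (!any(bad)) break
    alt[bad] <- stats::rbinom(sum(bad), depth[bad], prob)
  }
  alt
}

pos_in_segments <- function(chrom, pos, segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(NA_integer_, length(pos)))
  }
  hit <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(segments))) {
    in_seg <- chrom == segments$chrom[i] &
      pos > segments$start[i] & pos <= segments$end[i]
    hit[in_seg] <- i
  }
  hit
}

new_variant_df <- function(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           depth = integer(0), alt_count = integer(0),
                           filter = "PASS", var_class = "SNV",
                           impact = NA_character_) {
  n <- length(pos)
  depth <- rep_len(as.integer(depth), n)
  alt_count <- rep_len(as.integer(alt_count), n)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   depth = depth, alt_count = alt_count,
                   vaf = ifelse(depth > 0, alt_count / depth, NA_real_),
                   filter = rep_len(filter, n),
                   var_class = rep_len(var_class, n),
                   impact = rep_len(impact, n), stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
}

#' Simulate a germline + dual-caller tumor sample with known truth
#'
#' Produces the inputs the somatic pipeline consumes — a germline variant
#' table and two "pseudo-caller" tumor variant tables — together with the
#' truth needed to verify every downstream stage:
#' \itemize{
#'   \item somatic SNVs are placed at reference positions whose
#'     trinucleotide matches the sampled 96-bin context (searched on either
#'     strand; the reference is never mutated to fit), with depth at least
#'     40 and VAF at least 0.2 so they survive default filtering;
#'   \item germline heterozygous SNPs have alt counts binomial around VAF
#'     0.5; their somatic re-observations appear in both tumor tables with
#'     `filter = "germline"` (as real somatic callers tag them), shifted to
#'     VAF >= 0.85 or <= 0.15 inside LOH segments and re-drawn around 0.5
#'     outside;
#'   \item a fraction `caller_overlap` of somatic SNVs is emitted by both
#'     callers, the rest alternating between them; microsatellite indels
#'     (one repeat unit inserted or deleted, left-aligned) occur at rate
#'     `ms_indel_rate` and are emitted by caller B only, mirroring an
#'     indel-capable second caller.
#' }
#'
#' @param reference A reference from [generate_reference()] (its `ms_loci`
#'   are the candidate microsatellite loci).
#' @param spec A [synthetic_sample_spec()].
#' @param signatures Signature matrix for the mixture.
#' @return List with `germline`, `tumor_a`, `tumor_b` (variant data
#'   frames) and `truth`: `snvs` (with 1-based context bin and caller
#'   assignment), `exposures`, `n_shared`, `loh_segments`, `ms_status`
#'   (loci with `mutated` flag), `germline_sites` (with `in_loh` flag).
#' @export
simulate_sample <- function(reference, spec, signatures) {
  stopifnot(inherits(spec, "synthetic_sample_spec"))
  seqs <- ref_as_character(reference)
  ms_loci <- reference$ms_loci
  if (is.null(ms_loci)) {
    ms_loci <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), unit = character(0),
                          n_repeats = integer(0), stringsAsFactors = FALSE)
  }
  with_seed(spec$seed, {
    # --- candidate positions indexed by pyrimidine-centred trinucleotide
    cand_chrom <- character(0); cand_pos <- integer(0); cand_key <- character(0)
    for (ch in names(seqs)) {
      L <- nchar(seqs[[ch]])
      p <- 2:(L - 1)
      excl <- ms_loci[ms_loci$chrom == ch, , drop = FALSE]
      if (nrow(excl) > 0) {
        bad <- rep(FALSE, length(p))
        for (i in seq_len(nrow(excl))) {
          bad <- bad | (p > excl$start[i] - 1 & p <= excl$end[i] + 1)
        }
        p <- p[!bad]
      }
      tri <- substring(seqs[[ch]], p - 1, p + 1)
      centre <- substr(tri, 2, 2)
      pur <- centre %in% c("A", "G")
      tri[pur] <- revcomp3(tri[pur])
      cand_chrom <- c(cand_chrom, rep(ch, length(p)))
      cand_pos <- c(cand_pos, p)
      cand_key <- c(cand_key, tri)
    }
    used <- rep(FALSE, length(cand_pos))
    pool <- split(seq_along(cand_pos), cand_key)

    # --- somatic SNVs from the mixture
    counts <- as.numeric(stats::rmultinom(
      1, spec$mixture$total_snvs,
      as.numeric(spec$mixture$weights %*%
                   signatures[names(spec$mixture$weights), , drop = FALSE])))
    ctx <- context_table()
    pick_ix <- integer(0); pick_bin <- integer(0)
    for (b in which(counts > 0)) {
      key <- paste0(ctx$five[b], ctx$ref[b], ctx$three[b])
      avail <- pool[[key]]
      avail <- avail[!used[avail]]
      if (length(avail) < counts[b]) {
        stop("context exhausted: no unused reference position matches ",
             ctx$label[b])
      }
      sel <- avail[sample.int(length(avail), counts[b])]
      used[sel] <- TRUE
      pick_ix <- c(pick_ix, sel)
      pick_bin <- c(pick_bin, rep(b, counts[b]))
    }
    n_snv <- length(pick_ix)
    snv_chrom <- cand_chrom[pick_ix]
    snv_pos <- cand_pos[pick_ix]
    centre <- substr(seqs[snv_chrom], snv_pos, snv_pos)
    on_pyr <- centre == ctx$ref[pick_bin]
    snv_ref <- centre
    snv_alt <- ifelse(on_pyr, ctx$alt[pick_bin],
                      comp_base(ctx$alt[pick_bin]))
    snv_depth <- pmax(40L, stats::rpois(n_snv, spec$depth_mean))
    snv_altc <- rbinom_accept(snv_depth, 0.45,
                              function(a, d) a >= 1 & a / d >= 0.2)

    # caller assignment: shared fraction in both, remainder alternating
    callers <- character(n_snv)
    if (n_snv > 0) {
      ord <- sample.int(n_snv)
      n_shared <- round(spec$caller_overlap * n_snv)
      callers[ord[seq_len(n_shared)]] <- "AB"
      solo <- ord[setdiff(seq_len(n_snv), seq_len(n_shared))]
      callers[solo] <- rep_len(c("A", "B"), length(solo))
    } else {
      n_shared <- 0L
    }

    # --- germline heterozygous SNPs
    avail <- which(!used)
    if (length(avail) < spec$n_germline_hets) {
      stop("reference too short to host the requested germline hets")
    }
    gsel <- avail[sample.int(length(avail), spec$n_germline_hets)]
    used[gsel] <- TRUE
    g_chrom <- cand_chrom[gsel]; g_pos <- cand_pos[gsel]
    g_ref <- substr(seqs[g_chrom], g_pos, g_pos)
    bases <- c("A", "C", "G", "T")
    g_alt <- vapply(g_ref, function(r) sample(setdiff(bases, r), 1), "")
    g_depth <- pmax(1L, stats::rpois(spec$n_germline_hets, spec$depth_mean))
    g_altc <- stats::rbinom(spec$n_germline_hets, g_depth, 0.5)

    # somatic re-observation of germline sites (LOH shift inside segments)
    seg_hit <- pos_in_segments(g_chrom, g_pos, spec$loh_segments)
    in_loh <- !is.na(seg_hit)
    retained <- ifelse(in_loh, spec$loh_segments$retained[seg_hit], NA)
    s_depth <- pmax(1L, stats::rpois(spec$n_germline_hets, spec$depth_mean))
    s_prob <- ifelse(!in_loh, 0.5, ifelse(retained == "ref", 0.1, 0.9))
    s_altc <- stats::rbinom(spec$n_germline_hets, s_depth, s_prob)
    fix <- which(in_loh)
    if (length(fix) > 0) {
      hi <- retained[fix] == "alt"
      s_altc[fix] <- rbinom_accept(
        s_depth[fix], s_prob[fix],
        function(a, d) ifelse(hi, a / d >= 0.85, a / d <= 0.15))
    }

    # --- microsatellite indels at truth loci (caller B only)
    ms_status <- ms_loci
    ms_status$mutated <- if (nrow(ms_loci) > 0) {
      stats::runif(nrow(ms_loci)) < spec$ms_indel_rate
    } else logical(0)
    mut <- which(ms_status$mutated)
    ind_chrom <- character(0); ind_pos <- integer(0)
    ind_ref <- character(0); ind_alt <- character(0)
    for (i in mut) {
      ch <- ms_loci$chrom[i]; s <- ms_loci$start[i]  # 1-based anchor = s
      unit <- substr(seqs[[ch]], s + 1, s + nchar(ms_loci$unit[i]))
      anchor <- substr(seqs[[ch]], s, s)
      if (stats::runif(1) < 0.5) {                    # insertion of one unit
        ind_ref <- c(ind_ref, anchor)
        ind_alt <- c(ind_alt, paste0(anchor, unit))
      } else {                                        # deletion of one unit
        ind_ref <- c(ind_ref, paste0(anchor, unit))
        ind_alt <- c(ind_alt, anchor)
      }
      ind_chrom <- c(ind_chrom, ch); ind_pos <- c(ind_pos, s)
    }
    n_ind <- length(ind_pos)
    ind_depth <- pmax(40L, stats::rpois(n_ind, spec$depth_mean))
    ind_altc <- rbinom_accept(ind_depth, 0.45,
                              function(a, d) a >= 1 & a / d >= 0.2)

    # --- assemble tables
    germline <- new_variant_df(g_chrom, g_pos, g_ref, g_alt,
                               g_depth, g_altc, "PASS", "SNV")
    som_g <- new_variant_df(g_chrom, g_pos, g_ref, g_alt,
                            s_depth, s_altc, "germline", "SNV")
    tum_snv <- function(which_callers) {
      keep <- callers %in% which_callers
      new_variant_df(snv_chrom[keep], snv_pos[keep], snv_ref[keep],
                     snv_alt[keep], snv_depth[keep], snv_altc[keep],
                     "PASS", "SNV")
    }
    indels <- new_variant_df(ind_chrom, ind_pos, ind_ref, ind_alt,
                             ind_depth, ind_altc, "PASS",
                             ifelse(nchar(ind_alt) > nchar(ind_ref),
                                    "insertion", "deletion"))
    tumor_a <- rbind(tum_snv(c("AB", "A")), som_g)
    tumor_b <- rbind(tum_snv(c("AB", "B")), indels, som_g)
    tumor_a <- tumor_a[order(tumor_a$chrom, tumor_a$pos), ]
    tumor_b <- tumor_b[order(tumor_b$chrom, tumor_b$pos), ]
    rownames(tumor_a) <- rownames(tumor_b) <- rownames(germline) <- NULL

    truth_snvs <- data.frame(chrom = snv_chrom, pos = snv_pos,
                             ref = snv_ref, alt = snv_alt,
                             context = pick_bin, caller = callers,
                             stringsAsFactors = FALSE)
    list(germline = germline, tumor_a = tumor_a, tumor_b = tumor_b,
         truth = list(snvs = truth_snvs,
                      exposures = spec$mixture$weights,
                      n_shared = n_shared,
                      loh_segments = spec$loh_segments,
                      ms_status = ms_status,
                      germline_sites = data.frame(
                        chrom = g_chrom, pos = g_pos, ref = g_ref,
                        alt = g_alt, in_loh = in_loh,
                        stringsAsFactors = FALSE)))
  })
}
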