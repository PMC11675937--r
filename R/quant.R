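# tRNA-seq quantification: TMM between-sample normalization of isodecoder
# count tables, aggregation to isoacceptor (anticodon) abundances, and
# condition fold changes.

# Single-pair TMM factor (Robinson & Oshlack): doubly trimmed,
# precision-weighted mean of log ratios of library-size-scaled counts.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim, abs_trim, weighted = TRUE) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (n == 0) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  f <- if (weighted) sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
       else mean(m[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM scaling factors for a count matrix
#'
#' Trimmed mean of M-values: for each sample versus a reference sample,
#' log-ratios (M) and average log-abundances (A) of library-size-scaled
#' counts are computed over features nonzero in both samples, doubly trimmed
#' (`logratio_trim` on M, `abs_trim` on A), and combined as a
#' precision-weighted mean. Factors are rescaled so their geometric mean
#' is 1.
#'
#' @param counts nonnegative integer matrix, features x samples.
#' @param logratio_trim fraction trimmed from each tail of M (default 0.3).
#' @param abs_trim fraction trimmed from each tail of A (default 0.05).
#' @param reference_sample column index/name, or `NULL` to pick the sample
#'   whose upper-quartile of scaled counts is closest to the mean
#'   upper-quartile.
#' @param weighted use asymptotic-variance precision weights (default TRUE).
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05,
                        reference_sample = NULL, weighted = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need >= 2 features for TMM")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (is.null(reference_sample)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    reference_sample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference_sample)) {
    reference_sample <- match(reference_sample, colnames(counts))
    if (is.na(reference_sample)) stop("reference sample not found")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, reference_sample],
                    lib[j], lib[reference_sample],
                    logratio_trim, abs_trim, weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalize a count matrix with TMM factors
#'
#' @param counts features x samples count matrix.
#' @param factors positive factors aligned with the columns of `counts`
#'   (named vectors are matched by name).
#' @param scale multiplier applied after dividing by effective library size
#'   (default 1e6, CPM-style).
#' @return Matrix of normalized abundances, same shape as `counts`.
#' @export
normalize_counts <- function(counts, factors, scale = 1e6) {
  counts <- as.matrix(counts)
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    if (!setequal(names(factors), colnames(counts))) {
      stop("factor names do not match sample ids")
    }
    factors <- factors[colnames(counts)]
  } else if (length(factors) != ncol(counts)) {
    stop("one factor per sample required")
  }
  if (any(factors <= 0)) stop("factors must be positive")
  lib <- colSums(counts)
  sweep(counts, 2, lib * factors, "/") * scale
}

#' Aggregate isodecoder abundances to isoacceptor abundances
#'
#' The isoacceptor value in each sample is the arithmetic mean of its member
#' isodecoder values (optionally weighted by gene copy number).
#'
#' @param abundance normalized matrix, isodecoder group ids x samples.
#' @param isoacceptors data.frame from [build_isoacceptor_map()].
#' @param copy_weights optional named vector of isodecoder copy numbers for a
#'   copy-number-weighted mean; default unweighted.
#' @return Matrix, isoacceptor ids x samples.
#' @export
aggregate_isoacceptors <- function(abundance, isoacceptors, copy_weights = NULL) {
  members <- strsplit(isoacceptors$isodecoder_group_ids, ",", fixed = TRUE)
  missing <- setdiff(unlist(members), rownames(abundance))
  if (length(missing)) {
    stop("isodecoder(s) absent from abundance table: ",
         paste(missing, collapse = ", "))
  }
  out <- t(vapply(members, function(ids) {
    sub <- abundance[ids, , drop = FALSE]
    if (is.null(copy_weights)) colMeans(sub)
    else {
      w <- copy_weights[ids]
      colSums(sub * w) / sum(w)
    }
  }, numeric(ncol(abundance))))
  rownames(out) <- isoacceptors$isoacceptor_id
  colnames(out) <- colnames(abundance)
  out
}

#' Per-condition mean abundance
#'
#' @param abundance features x samples matrix.
#' @param samples data.frame with `sample_id`, `condition` (replicates are
#'   the samples sharing a condition).
#' @return Matrix, features x conditions, of replicate means.
#' @export
condition_means <- function(abundance, samples) {
  miss <- setdiff(samples$sample_id, colnames(abundance))
  if (length(miss)) stop("samples absent from abundance table: ",
                         paste(miss, collapse = ", "))
  conds <- unique(samples$condition)
  out <- vapply(conds, function(cc) {
    rowMeans(abundance[, samples$sample_id[samples$condition == cc], drop = FALSE])
  }, numeric(nrow(abundance)))
  colnames(out) <- conds
  out
}

#' Condition log2 fold changes with threshold flags
#'
#' log2FC = log2(mean(condition_a) / mean(condition_b)); features with
#' |log2FC| >= `lfc_threshold` are flagged (boundary inclusive). When either
#' condition mean is zero, `pseudocount` is added to both. An optional
#' externally computed q-value column can be joined for combined filtering.
#'
#' @param abundance features x samples normalized matrix.
#' @param samples data.frame with `sample_id`, `condition`.
#' @param condition_a,condition_b condition labels (numerator, denominator).
#' @param lfc_threshold absolute log2FC flag threshold (default 0.5).
#' @param pseudocount added to both means when either is zero (default 0.5).
#' @param q_values optional named vector of q-values; features pass the
#'   combined filter when flagged and q <= `q_threshold`.
#' @param q_threshold default 0.1.
#' @return data.frame: `feature_id`, `mean_a`, `mean_b`, `log2fc`, `flagged`,
#'   and `q_value`/`significant` when q-values are supplied.
#' @export
condition_fold_change <- function(abundance, samples, condition_a, condition_b,
                                  lfc_threshold = 0.5, pseudocount = 0.5,
                                  q_values = NULL, q_threshold = 0.1) {
  for (cc in c(condition_a, condition_b)) {
    if (!cc %in% samples$condition) stop("condition absent: ", cc)
  }
  cm <- condition_means(abundance, samples)
  ma <- cm[, condition_a]
  mb <- cm[, condition_b]
  zero <- ma == 0 | mb == 0
  ma[zero] <- ma[zero] + pseudocount
  mb[zero] <- mb[zero] + pseudocount
  lfc <- log2(ma / mb)
  out <- data.frame(
    feature_id = rownames(abundance),
    mean_a = cm[, condition_a],
    mean_b = cm[, condition_b],
    log2fc = unname(lfc),
    flagged = unname(abs(lfc) >= lfc_threshold),
    stringsAsFactors = FALSE
  )
  if (!is.null(q_values)) {
    out$q_value <- unname(q_values[out$feature_id])
    out$significant <- out$flagged & !is.na(out$q_value) & out$q_value <= q_threshold
  }
  out
}

#' Anticodon-keyed decoding supply from isoacceptor abundances
#'
#' Collapses an isoacceptor abundance vector/matrix to an anticodon-keyed
#' supply vector for tAI, excluding initiator Met (`iMet`) which does not
#' participate in elongation.
#'
#' @param iso_abundance named vector or single-column matrix keyed by
#'   isoacceptor id (`<AA>-<anticodon>`).
#' @param isoacceptors data.frame from [build_isoacceptor_map()].
#' @return Named numeric vector keyed by anticodon.
#' @export
anticodon_supply <- function(iso_abundance, isoacceptors) {
  if (is.matrix(iso_abundance)) iso_abundance <- iso_abundance[, 1]
  keep <- isoacceptors$amino_acid != "iMet"
  ids <- isoacceptors$isoacceptor_id[keep]
  miss <- setdiff(ids, names(iso_abundance))
  if (length(miss)) stop("isoacceptor(s) missing from abundance: ",
                         paste(miss, collapse = ", "))
  vals <- iso_abundance[ids]
  acs <- isoacceptors$anticodon[keep]
  out <- tapply(vals, acs, sum)
  stats::setNames(as.numeric(out), names(out))
}
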