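# Per-codon and per-gene optimality and translation-efficiency metrics:
# codon stabilization coefficient (CSC), codon classes, tAI / tAI_gene,
# CAI, expression-weighted codon demand, supply/demand ratios (SDR) and the
# cross-condition comparisons built on them.

#' Codon stabilization coefficients
#'
#' CSC of a codon is the Pearson correlation, across genes, between the
#' codon's length-normalized frequency and mRNA half-life. Codons whose
#' frequency has zero variance get `NA` with a message. Half-lives are used
#' on their natural scale (hours) by default.
#'
#' @param freq genes x 61 frequency matrix.
#' @param half_lives named numeric vector of half-lives (hours > 0); genes
#'   missing from either input are dropped with a message.
#' @param log_halflife correlate against log(half-life) instead.
#' @return Named 61-vector of CSC values in \[-1, 1\] (NA where undefined).
#' @export
compute_csc <- function(freq, half_lives, log_halflife = FALSE) {
  common <- intersect(rownames(freq), names(half_lives))
  dropped <- nrow(freq) - length(common)
  if (dropped > 0) message(dropped, " gene(s) without half-life dropped from CSC")
  if (length(common) < 3) stop("need >= 3 genes with both frequency and half-life")
  hl <- half_lives[common]
  if (any(hl <= 0)) stop("half-lives must be positive")
  if (log_halflife) hl <- log(hl)
  if (stats::sd(hl) == 0) stop("constant half-life vector: correlation undefined")
  f <- freq[common, , drop = FALSE]
  csc <- suppressWarnings(as.numeric(stats::cor(f, hl)))
  names(csc) <- colnames(freq)
  const <- apply(f, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    message(sum(const), " codon(s) with constant frequency: CSC undefined")
    csc[const] <- NA_real_
  }
  csc
}

#' Classify codons as optimal / neutral / non-optimal
#'
#' optimal: CSC >= `pos_threshold`; non-optimal: CSC <= `neg_threshold`;
#' strictly between: neutral (both boundaries inclusive of their class).
#'
#' @param csc named CSC vector.
#' @param pos_threshold default 0.01.
#' @param neg_threshold default -0.01.
#' @return Named character vector in {optimal, neutral, non_optimal}, NA
#'   propagated.
#' @export
classify_codons <- function(csc, pos_threshold = 0.01, neg_threshold = -0.01) {
  out <- ifelse(is.na(csc), NA_character_,
         ifelse(csc >= pos_threshold, "optimal",
         ifelse(csc <= neg_threshold, "non_optimal", "neutral")))
  stats::setNames(out, names(csc))
}

#' Per-codon tAI from measured tRNA abundance
#'
#' The raw weight of a codon is the penalty-weighted sum of its cognate
#' anticodon abundances, W_c = sum_j (1 - s_cj) * abundance_j, over the
#' Watson-Crick and wobble cognates given by the rule set. tAI is W_c
#' divided by the maximum weight among synonymous codons of the same amino
#' acid family, so the best-decoded codon of each family has tAI = 1.
#'
#' @param supply named abundance vector keyed by anticodon (see
#'   [anticodon_supply()]).
#' @param rules a `wobble_rules` object.
#' @return data.frame with `codon`, `amino_acid`, `W` (raw weight), `tai`.
#' @export
codon_tai <- function(supply, rules = default_wobble_rules()) {
  if (any(supply < 0)) stop("abundances must be nonnegative")
  tab <- codon_table()
  W <- vapply(tab$codon, function(cd) {
    cg <- cognate_trnas(cd, supply, rules)
    sum((1 - cg$s) * cg$abundance)
  }, numeric(1))
  fam_max <- tapply(W, tab$aa, max)[tab$aa]
  dead <- unique(tab$amino_acid[fam_max == 0])
  if (length(dead)) {
    stop("no decoding capacity for amino acid family: ",
         paste(dead, collapse = ", "))
  }
  data.frame(codon = tab$codon, amino_acid = tab$amino_acid,
             W = unname(W), tai = unname(W / fam_max),
             stringsAsFactors = FALSE)
}

#' Gene-level tAI (geometric mean over codon positions)
#'
#' tAI_gene = (prod tAI_c)^(1/L), computed as exp of the count-weighted mean
#' log tAI. Codons with tAI = 0 are an error in strict mode; lenient mode
#' substitutes the smallest positive tAI (or `floor`) with a message.
#'
#' @param counts named 61-vector of the gene's codon counts, or a genes x 61
#'   matrix for vectorized computation.
#' @param tai named per-codon tAI vector (or `codon_tai()` data.frame).
#' @param zero `"error"` (default) or `"floor"`.
#' @param floor replacement for zero tAI in lenient mode; default smallest
#'   positive tAI.
#' @return tAI_gene value(s) in (0, 1\].
#' @export
gene_tai <- function(counts, tai, zero = c("error", "floor"), floor = NULL) {
  zero <- match.arg(zero)
  if (is.data.frame(tai)) tai <- stats::setNames(tai$tai, tai$codon)
  if (is.matrix(counts)) {
    tai_v <- tai[colnames(counts)]
  } else {
    tai_v <- tai[names(counts)]
  }
  if (anyNA(tai_v)) stop("tAI undefined for some codons")
  zero_used <- if (is.matrix(counts)) any(counts[, tai_v == 0] > 0)
               else any(counts[tai_v == 0] > 0)
  if (any(tai_v == 0) && zero_used) {
    if (zero == "error") stop("codon(s) with tAI = 0 occur in scored gene(s)")
    repl <- floor %||% min(tai_v[tai_v > 0])
    message("substituting tAI floor ", signif(repl, 4), " for zero-tAI codons")
    tai_v[tai_v == 0] <- repl
  }
  lt <- log(tai_v)
  lt[tai_v == 0] <- 0  # unused codons only
  if (is.matrix(counts)) {
    L <- rowSums(counts)
    if (any(L < 1)) stop("gene(s) with no codons")
    return(exp(as.numeric(counts %*% lt) / L))
  }
  L <- sum(counts)
  if (L < 1) stop("gene with no codons")
  exp(sum(counts * lt) / L)
}

#' Codon adaptation index against a reference gene set
#'
#' Relative adaptiveness w_c is the codon's count in the pooled reference
#' divided by the count of the most-used synonymous codon of the same family
#' (equivalently RSCU / max family RSCU). Codons unused in the reference get
#' a 0.5 pseudo-count. CAI of a gene is the geometric mean of w over its
#' codons, excluding the single-codon families ATG and TGG.
#'
#' @param counts genes x 61 count matrix of query genes.
#' @param reference_counts pooled 61-vector of reference codon counts (e.g.
#'   summed over ribosomal protein genes), or a genes x 61 matrix to pool.
#' @return List with `cai` (named per-gene vector) and `w` (named 61-vector
#'   of relative adaptiveness).
#' @export
compute_cai <- function(counts, reference_counts) {
  if (is.matrix(reference_counts)) reference_counts <- colSums(reference_counts)
  tab <- codon_table()
  ref <- reference_counts[tab$codon]
  if (all(ref == 0)) stop("empty reference set")
  fam_tot <- tapply(ref, tab$aa, sum)
  absent <- names(fam_tot)[fam_tot == 0]
  if (length(absent)) {
    message("amino acid family absent from reference (w = 1 for all members): ",
            paste(absent, collapse = ", "))
  }
  ref_adj <- ifelse(ref == 0, 0.5, ref)
  fam_max <- tapply(ref_adj, tab$aa, max)[tab$aa]
  w <- stats::setNames(as.numeric(ref_adj / fam_max), tab$codon)
  use <- tab$codon[!tab$single_codon_family]
  m <- counts[, use, drop = FALSE]
  L <- rowSums(m)
  if (any(L < 1)) stop("gene(s) with no multi-codon-family codons")
  cai <- exp(as.numeric(m %*% log(w[use])) / L)
  list(cai = stats::setNames(cai, rownames(counts)), w = w)
}

#' Expression-weighted codon demand
#'
#' Raw demand of a codon is the expression-weighted sum of its normalized
#' frequency across genes; the demand vector is renormalized to sum 1 over
#' the 61 sense codons, making downstream SDR values invariant to expression
#' units.
#'
#' @param freq genes x 61 frequency matrix.
#' @param expression named nonnegative expression vector; genes missing from
#'   either input are dropped with a message.
#' @param renormalize divide by the total so demand sums to 1 (default TRUE).
#' @return Named 61-vector of demand values.
#' @export
codon_demand <- function(freq, expression, renormalize = TRUE) {
  common <- intersect(rownames(freq), names(expression))
  dropped <- nrow(freq) - length(common)
  if (dropped > 0) message(dropped, " gene(s) without expression dropped from demand")
  if (!length(common)) stop("no genes with expression")
  e <- expression[common]
  if (any(e < 0)) stop("expression must be nonnegative")
  if (sum(e) == 0) stop("all-zero expression")
  d <- as.numeric(t(freq[common, , drop = FALSE]) %*% e)
  names(d) <- colnames(freq)
  if (renormalize) d <- d / sum(d)
  d
}

#' Supply/demand ratios per codon and per gene
#'
#' SDR_c = tAI_c / demand_c; the gene-level SDR is the geometric mean of
#' SDR_c over the gene's codon positions.
#'
#' @param tai named per-codon tAI vector (or `codon_tai()` data.frame).
#' @param demand named per-codon demand vector.
#' @param counts genes x 61 codon count matrix of the scored genes.
#' @return List with `sdr_codon` (61-vector) and `sdr_gene` (named vector).
#' @export
compute_sdr <- function(tai, demand, counts) {
  if (is.data.frame(tai)) tai <- stats::setNames(tai$tai, tai$codon)
  codons <- colnames(counts)
  tai <- tai[codons]; demand <- demand[codons]
  if (anyNA(tai) || anyNA(demand)) stop("tAI/demand undefined for some codons")
  occurring <- colSums(counts) > 0
  zero_dem <- occurring & demand == 0
  if (any(zero_dem)) {
    stop("zero demand for occurring codon(s): ",
         paste(codons[zero_dem], collapse = ", "))
  }
  zero_tai <- occurring & tai == 0
  if (any(zero_tai)) stop("tAI = 0 for occurring codon(s): ",
                          paste(codons[zero_tai], collapse = ", "))
  sdr_c <- tai / demand
  lsdr <- log(sdr_c)
  lsdr[!occurring & !is.finite(lsdr)] <- 0
  L <- rowSums(counts)
  sdr_g <- exp(as.numeric(counts %*% lsdr) / L)
  list(sdr_codon = sdr_c, sdr_gene = stats::setNames(sdr_g, rownames(counts)))
}

#' Cross-condition SDR difference with top/bottom selection
#'
#' delta SDR = SDR(condition_b) - SDR(condition_a) per gene; genes are ranked
#' by delta and the top and bottom `fraction` selected.
#'
#' @param sdr_a,sdr_b named per-gene SDR vectors for the two conditions.
#' @param fraction tail fraction for top/bottom selection (default 0.1).
#' @return List: `table` (ranked data.frame `gene_id`, `sdr_a`, `sdr_b`,
#'   `delta_sdr`), `top`, `bottom` (gene id vectors).
#' @export
delta_sdr <- function(sdr_a, sdr_b, fraction = 0.1) {
  common <- intersect(names(sdr_a), names(sdr_b))
  d <- sdr_b[common] - sdr_a[common]
  ord <- order(-d, common)
  tab <- data.frame(gene_id = common[ord], sdr_a = unname(sdr_a[common][ord]),
                    sdr_b = unname(sdr_b[common][ord]),
                    delta_sdr = unname(d[ord]), stringsAsFactors = FALSE)
  n <- ceiling(fraction * nrow(tab))
  list(table = tab, top = tab$gene_id[seq_len(n)],
       bottom = rev(tab$gene_id)[seq_len(n)])
}

#' Watson-Crick cognate abundance per codon
#'
#' Abundance of the anticodon that is the codon's reverse complement; 0 when
#' no such tRNA exists in the pool.
#'
#' @param supply named abundance vector keyed by anticodon.
#' @param codons codons to map (default all 61 sense codons).
#' @return Named vector of abundances per codon.
#' @export
wc_abundance_map <- function(supply, codons = sense_codons()) {
  ac <- wc_anticodon(codons)
  ab <- supply[ac]
  ab[is.na(ab)] <- 0
  stats::setNames(unname(ab), codons)
}

#' Effect size of tAI between stabilizing and destabilizing codons
#'
#' Cohen's d (pooled-SD) and Welch's t-test comparing tAI of stabilizing
#' versus destabilizing codons, grouped either by CSC sign (default) or by
#' the optimal/non-optimal classes.
#'
#' @param tai named per-codon tAI vector.
#' @param csc named per-codon CSC vector (sign grouping) or class vector
#'   from [classify_codons()] (class grouping).
#' @param grouping `"sign"` or `"class"`.
#' @return List: `cohens_d`, `t`, `df`, `p_value`, `n_stabilizing`,
#'   `n_destabilizing`.
#' @export
tai_csc_effect <- function(tai, csc, grouping = c("sign", "class")) {
  grouping <- match.arg(grouping)
  common <- intersect(names(tai), names(csc))
  tai <- tai[common]; csc <- csc[common]
  ok <- !is.na(csc) & !is.na(tai)
  tai <- tai[ok]; csc <- csc[ok]
  if (grouping == "sign") {
    g1 <- tai[as.numeric(csc) > 0]
    g2 <- tai[as.numeric(csc) < 0]
  } else {
    g1 <- tai[csc == "optimal"]
    g2 <- tai[csc == "non_optimal"]
  }
  if (length(g1) < 2 || length(g2) < 2) stop("need >= 2 codons per group")
  sp2 <- ((length(g1) - 1) * stats::var(g1) + (length(g2) - 1) * stats::var(g2)) /
    (length(g1) + length(g2) - 2)
  if (sp2 == 0) {
    if (mean(g1) == mean(g2)) {
      return(list(cohens_d = 0, t = 0, df = length(g1) + length(g2) - 2,
                  p_value = 1, n_stabilizing = length(g1),
                  n_destabilizing = length(g2)))
    }
    stop("zero pooled variance with unequal means: Cohen's d undefined")
  }
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  list(cohens_d = (mean(g1) - mean(g2)) / sqrt(sp2),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       n_stabilizing = length(g1), n_destabilizing = length(g2))
}

#' Joint differential tAI / differential CSC categories
#'
#' Codons are labeled by whether tAI differs between conditions
#' (|tAI_b - tAI_a| >= `delta_tai_threshold`) and whether the CSC class
#' changed: `concordant` (both, same direction), `discordant` (both,
#' opposite direction), `tai_only`, `csc_only`, `no_difference`.
#'
#' @param tai_a,tai_b named per-codon tAI vectors per condition.
#' @param class_a,class_b per-codon class vectors from [classify_codons()].
#' @param delta_tai_threshold default 0.2 (boundary inclusive).
#' @return data.frame: `codon`, `delta_tai`, `class_a`, `class_b`,
#'   `category`.
#' @export
differential_tai_csc <- function(tai_a, tai_b, class_a, class_b,
                                 delta_tai_threshold = 0.2) {
  codons <- Reduce(intersect, list(names(tai_a), names(tai_b),
                                   names(class_a), names(class_b)))
  dt <- tai_b[codons] - tai_a[codons]
  rank_of <- c(non_optimal = -1, neutral = 0, optimal = 1)
  dc <- rank_of[class_b[codons]] - rank_of[class_a[codons]]
  tai_diff <- abs(dt) >= delta_tai_threshold
  csc_diff <- !is.na(dc) & dc != 0
  category <- ifelse(tai_diff & csc_diff,
                     ifelse(sign(dt) == sign(dc), "concordant", "discordant"),
              ifelse(tai_diff, "tai_only",
              ifelse(csc_diff, "csc_only", "no_difference")))
  data.frame(codon = codons, delta_tai = unname(dt),
             class_a = unname(class_a[codons]), class_b = unname(class_b[codons]),
             category = unname(category), stringsAsFactors = FALSE)
}

#' Half-life summary for a gene set
#'
#' Arithmetic mean, standard error of the mean and n per condition, over the
#' genes of a set with half-life coverage.
#'
#' @param gene_set character vector of gene ids.
#' @param half_lives named vector, or genes x conditions matrix/data.frame.
#' @return data.frame: `condition`, `mean`, `sem`, `n` (SEM is `NA` when
#'   n = 1).
#' @export
geneset_halflife_summary <- function(gene_set, half_lives) {
  if (is.null(dim(half_lives))) {
    half_lives <- matrix(half_lives, ncol = 1,
                         dimnames = list(names(half_lives), "half_life"))
  }
  half_lives <- as.matrix(half_lives)
  common <- intersect(gene_set, rownames(half_lives))
  if (!length(common)) stop("no genes in set have half-life coverage")
  out <- do.call(rbind, lapply(colnames(half_lives), function(cc) {
    x <- half_lives[common, cc]
    x <- x[!is.na(x)]
    data.frame(condition = cc, mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
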