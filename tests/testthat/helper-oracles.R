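`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles: deliberately naive re-implementations used to verify
# the package's computations, kept structurally different from the code
# under test.

# Brute-force TMM factor between two columns, following the published
# weighted trimmed-mean-of-M-values definition with sort-based trimming.
oracle_tmm_pair <- function(y1, y2, trim_m = 0.3, trim_a = 0.05) {
  n1 <- sum(y1); n2 <- sum(y2)
  use <- y1 > 0 & y2 > 0
  p1 <- y1[use] / n1
  p2 <- y2[use] / n2
  M <- log2(p1 / p2)
  A <- 0.5 * log2(p1 * p2)
  w <- 1 / ((n1 - y1[use]) / (n1 * y1[use]) + (n2 - y2[use]) / (n2 * y2[use]))
  if (max(abs(M)) < 1e-6) return(1)
  k <- length(M)
  keep_m <- rank(M) >= floor(k * trim_m) + 1 & rank(M) <= k - floor(k * trim_m)
  keep_a <- rank(A) >= floor(k * trim_a) + 1 & rank(A) <= k - floor(k * trim_a)
  keep <- keep_m & keep_a
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

oracle_tmm_factors <- function(counts, ref) {
  f <- sapply(seq_len(ncol(counts)), function(j) {
    oracle_tmm_pair(counts[, j], counts[, ref])
  })
  f / exp(mean(log(f)))
}

# product-then-root geometric mean
oracle_geomean <- function(x) prod(x)^(1 / length(x))

# naive triplet scan of a CDS (no validation; stops included)
oracle_codon_scan <- function(seq) {
  seq <- toupper(seq)
  starts <- seq(1, nchar(seq) - 2, by = 3)
  table(substring(seq, starts, starts + 2))
}

# brute-force average-linkage agglomeration on a small matrix; returns the
# merge heights in order
oracle_average_linkage_heights <- function(m) {
  clusters <- as.list(seq_len(nrow(m)))
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- mean(d[clusters[[i]], clusters[[j]]])
          if (h < best[1]) best <- c(h, i, j)
        }
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# adjusted Rand index (contingency-table closed form)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# rank-based AUC for a score separating two groups
oracle_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# hand-built codon -> Watson-Crick anticodon table, independent of the
# package's reverse_complement
oracle_wc_table <- function() {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  codons <- sense_codons()
  setNames(vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    paste0(comp[b[3]], comp[b[2]], comp[b[1]])
  }, character(1)), codons)
}

# small tRNA gene fixture writer
write_fixture_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(h) c(paste0(">", h), records[[h]]))),
             path)
  path
}
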