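freq_toy <- function() {
  # 5 genes, AAA frequency perfectly linear in half-life, GGC the complement
  f <- matrix(0, 5, 61, dimnames = list(paste0("g", 1:5), sense_codons()))
  f[, "AAA"] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  f[, "GGC"] <- 1 - f[, "AAA"]
  f
}

test_that("CSC is the Pearson correlation of codon frequency with half-life", {
  f <- freq_toy()
  hl <- setNames(c(1, 2, 3, 4, 5), rownames(f))
  csc <- suppressMessages(compute_csc(f, hl))
  expect_equal(csc[["AAA"]], 1)
  expect_equal(csc[["GGC"]], -1)
  # direct formula oracle on a non-degenerate column
  f2 <- f
  set.seed(2)
  f2[, "TTT"] <- runif(5, 0, 0.05)
  csc2 <- suppressMessages(compute_csc(f2, hl))
  expect_equal(csc2[["TTT"]],
               sum((f2[, "TTT"] - mean(f2[, "TTT"])) * (hl - mean(hl))) /
                 sqrt(sum((f2[, "TTT"] - mean(f2[, "TTT"]))^2) * sum((hl - mean(hl))^2)),
               tolerance = 1e-12)
  # constant-frequency codons are undefined
  expect_true(is.na(csc[["ATG"]]))
  expect_error(compute_csc(f, setNames(rep(2, 5), rownames(f))), "constant")
  expect_error(compute_csc(f[1:2, ], hl[1:2]), ">= 3")
})

test_that("CSC is invariant to gene order and half-life shifts", {
  f <- freq_toy()
  set.seed(3)
  f[, "TTT"] <- runif(5, 0, 0.05)
  hl <- setNames(c(2, 4, 1, 5, 3), rownames(f))
  c1 <- suppressMessages(compute_csc(f, hl))
  perm <- sample(rownames(f))
  c2 <- suppressMessages(compute_csc(f[perm, ], hl[perm]))
  expect_equal(c1, c2)
  c3 <- suppressMessages(compute_csc(f, hl + 10))
  expect_equal(c1, c3)
  expect_true(all(abs(c1) <= 1, na.rm = TRUE))
})

test_that("codon classes use inclusive +/-0.01 boundaries", {
  csc <- c(a = 0.01, b = 0.009, c = -0.01, d = -0.009, e = 0.5, f = NA)
  cls <- classify_codons(csc)
  expect_equal(unname(cls[c("a", "b", "c", "d", "e")]),
               c("optimal", "neutral", "non_optimal", "neutral", "optimal"))
  expect_true(is.na(cls[["f"]]))
})

covering_supply <- function(level = 10) {
  acs <- covering_anticodon_set()
  setNames(rep(level, length(acs)), acs)
}

test_that("tAI weights follow the penalty-weighted cognate sum", {
  supply <- covering_supply()
  supply["GAA"] <- 100
  supply["AAA"] <- 0
  ct <- codon_tai(supply)
  w <- setNames(ct$W, ct$codon)
  tai <- setNames(ct$tai, ct$codon)
  expect_equal(w[["TTC"]], 100)
  expect_equal(w[["TTT"]], 59) # (1 - 0.41) * 100
  expect_equal(tai[["TTC"]], 1)
  expect_equal(tai[["TTT"]], 0.59)
  # single-codon families self-normalize to 1
  expect_equal(tai[["ATG"]], 1)
  expect_equal(tai[["TGG"]], 1)
})

test_that("tAI is invariant to abundance scaling and one codon per family hits 1", {
  supply <- covering_supply()
  set.seed(6)
  supply[] <- runif(length(supply), 1, 1000)
  t1 <- codon_tai(supply)
  t10 <- codon_tai(supply * 10)
  expect_equal(t1$tai, t10$tai, tolerance = 1e-12)
  tab <- codon_table()
  for (f in unique(tab$aa)) {
    expect_equal(max(t1$tai[tab$aa[match(t1$codon, tab$codon)] == f]), 1)
  }
  dead <- supply
  dead[c("GAA", "AAA")] <- 0 # no Phe decoding capacity at all
  expect_error(codon_tai(dead), "Phe")
})

test_that("gene tAI is the geometric mean over codon positions", {
  tai <- setNames(rep(1, 61), sense_codons())
  counts <- setNames(rep(0L, 61), sense_codons())
  counts[c("AAA", "GGC")] <- c(3L, 2L)
  expect_equal(gene_tai(counts, tai), 1)
  tai2 <- tai
  tai2["GGC"] <- 0.25
  counts2 <- setNames(rep(0L, 61), sense_codons())
  counts2[c("AAA", "GGC")] <- c(1L, 1L)
  expect_equal(gene_tai(counts2, tai2), 0.5)
  # 50-codon gene against a product-then-root oracle
  set.seed(10)
  tai3 <- setNames(runif(61, 0.05, 1), sense_codons())
  codons <- sample(sense_codons(), 50, replace = TRUE)
  counts3 <- table(factor(codons, levels = sense_codons()))
  counts3 <- setNames(as.integer(counts3), names(counts3))
  expect_equal(gene_tai(counts3, tai3), oracle_geomean(tai3[codons]),
               tolerance = 1e-12)
  # geometric mean never exceeds arithmetic mean
  expect_lte(gene_tai(counts3, tai3), mean(tai3[codons]))
  # zero-tAI codons in use: strict error, lenient floor
  tai0 <- tai3
  tai0[codons[1]] <- 0
  expect_error(gene_tai(counts3, tai0), "tAI = 0")
  lenient <- suppressMessages(gene_tai(counts3, tai0, zero = "floor"))
  expect_true(lenient > 0 && lenient <= 1)
})

test_that("CAI follows reference relative adaptiveness", {
  ref <- setNames(rep(0L, 61), sense_codons())
  ref[c("TTT", "TTC")] <- c(75L, 25L)
  ref[c("AAA", "AAG")] <- c(10L, 30L)
  gene <- matrix(0L, 1, 61, dimnames = list("g1", sense_codons()))
  gene[1, "TTC"] <- 1L
  r <- compute_cai(gene, ref)
  expect_equal(unname(r$cai), 1 / 3)
  expect_equal(r$w[["TTT"]], 1)
  expect_equal(r$w[["TTC"]], 1 / 3)
  # gene using only family-maximal codons scores exactly 1
  best <- matrix(0L, 1, 61, dimnames = list("g2", sense_codons()))
  best[1, c("TTT", "AAG")] <- c(5L, 7L)
  expect_equal(unname(suppressMessages(compute_cai(best, ref))$cai), 1)
  # duplication invariance
  dup <- gene * 2L
  rownames(dup) <- "g1x2"
  expect_equal(unname(compute_cai(dup, ref)$cai), 1 / 3)
  # ATG/TGG are excluded from the geometric mean
  withm <- gene
  withm[1, "ATG"] <- 5L
  expect_equal(unname(compute_cai(withm, ref)$cai), 1 / 3)
})

test_that("codon demand is the expression-weighted frequency average", {
  f <- freq_toy()
  d1 <- codon_demand(f[1, , drop = FALSE], c(g1 = 1), renormalize = FALSE)
  expect_equal(unname(d1), unname(f[1, ]))
  d2 <- codon_demand(f[1:2, ], c(g1 = 1, g2 = 1))
  expect_equal(unname(d2), unname(colMeans(f[1:2, ]) / sum(colMeans(f[1:2, ]))))
  # 10-gene brute-force oracle
  set.seed(12)
  tx <- gen_transcriptome(n_genes = 10, n_profiles = 1, seed = 5,
                          length_range = c(40, 60))
  cfm <- codon_frequency_matrix(tx$cds)
  e <- setNames(runif(10, 1, 100), rownames(cfm$freq))
  d <- codon_demand(cfm$freq, e, renormalize = FALSE)
  brute <- sapply(colnames(cfm$freq), function(cd) sum(e * cfm$freq[, cd]))
  expect_equal(unname(d), unname(brute), tolerance = 1e-12)
  expect_equal(sum(codon_demand(cfm$freq, e)), 1, tolerance = 1e-12)
  expect_error(codon_demand(cfm$freq, e * 0), "all-zero")
})

test_that("SDR is tAI over demand with geometric-mean gene summaries", {
  tai <- setNames(rep(1, 61), sense_codons())
  demand <- setNames(rep(1 / 61, 61), sense_codons())
  counts <- matrix(0L, 2, 61, dimnames = list(c("g1", "g2"), sense_codons()))
  counts[1, c("AAA", "GGC")] <- c(2L, 3L)
  counts[2, "TTT"] <- 4L
  s <- compute_sdr(tai, demand, counts)
  expect_true(all(s$sdr_codon == 61))
  expect_equal(unname(s$sdr_gene), c(61, 61))
  # identical conditions give delta SDR 0 everywhere
  d <- delta_sdr(s$sdr_gene, s$sdr_gene)
  expect_true(all(d$table$delta_sdr == 0))
  bad <- demand
  bad["AAA"] <- 0
  expect_error(compute_sdr(tai, bad, counts), "AAA")
  # gene SDR equals the oracle geometric mean of per-position SDR values
  set.seed(14)
  tai2 <- setNames(runif(61, 0.1, 1), sense_codons())
  dem2 <- setNames(runif(61, 0.5, 2), sense_codons())
  dem2 <- dem2 / sum(dem2)
  s2 <- compute_sdr(tai2, dem2, counts)
  pos <- rep(c("AAA", "GGC"), c(2, 3))
  expect_equal(unname(s2$sdr_gene[1]),
               oracle_geomean((tai2 / dem2)[pos]), tolerance = 1e-12)
})

test_that("delta SDR ranking selects top and bottom tails deterministically", {
  a <- setNames(rep(1, 10), paste0("g", 1:10))
  b <- setNames(seq(0.5, 1.5, length.out = 10), paste0("g", 1:10))
  d <- delta_sdr(a, b, fraction = 0.1)
  expect_equal(d$top, "g10")
  expect_equal(d$bottom, "g1")
  expect_equal(d$table$delta_sdr, unname(sort(b - a, decreasing = TRUE)))
})

test_that("Watson-Crick abundance mapping uses the reverse complement", {
  supply <- c(GAA = 42, TTT = 7)
  m <- wc_abundance_map(supply)
  expect_equal(m[["TTC"]], 42)
  expect_equal(m[["AAA"]], 7)
  expect_equal(m[["GGG"]], 0) # no CCC tRNA in the pool
  tab <- oracle_wc_table()
  full <- setNames(seq_along(tab), unname(tab))
  m2 <- wc_abundance_map(full)
  expect_equal(unname(m2[names(tab)]), unname(full[tab]))
})

test_that("tAI effect sizes match the Cohen's d formula oracle", {
  tai <- setNames(c(1, 1, 1, 0.9, 0.95, 1, 0.2, 0.3, 0.25, 0.4, 0.35, 0.3),
                  paste0("c", 1:12))
  csc <- setNames(c(rep(0.1, 6), rep(-0.1, 6)), paste0("c", 1:12))
  r <- tai_csc_effect(tai, csc)
  g1 <- tai[1:6]; g2 <- tai[7:12]
  sp <- sqrt(((5) * var(g1) + (5) * var(g2)) / 10)
  expect_equal(r$cohens_d, (mean(g1) - mean(g2)) / sp, tolerance = 1e-12)
  expect_equal(r$p_value, t.test(g1, g2)$p.value, tolerance = 1e-12)
  # identical groups: d = 0, p = 1
  same <- setNames(rep(0.5, 8), paste0("s", 1:8))
  csc2 <- setNames(c(rep(1, 4), rep(-1, 4)), paste0("s", 1:8))
  r2 <- tai_csc_effect(same, csc2)
  expect_equal(r2$cohens_d, 0)
  expect_equal(r2$p_value, 1)
  # degenerate: zero variance with unequal means
  deg <- setNames(c(1, 1, 1, 0, 0, 0), paste0("d", 1:6))
  csc3 <- setNames(c(rep(1, 3), rep(-1, 3)), paste0("d", 1:6))
  expect_error(tai_csc_effect(deg, csc3), "undefined")
  expect_error(tai_csc_effect(same[1:3], csc2[c(1, 2, 5)]), ">= 2")
})

test_that("differential tAI/CSC categories respect the 0.2 threshold", {
  tai_a <- c(x = 0.5, y = 0.5, z = 0.5, w = 0.5)
  tai_b <- c(x = 0.75, y = 0.6, z = 0.5, w = 0.71)
  cls_a <- c(x = "neutral", y = "optimal", z = "optimal", w = "optimal")
  cls_b <- c(x = "optimal", y = "neutral", z = "optimal", w = "neutral")
  d <- differential_tai_csc(tai_a, tai_b, cls_a, cls_b)
  cat_of <- setNames(d$category, d$codon)
  expect_equal(cat_of[["x"]], "concordant")   # tAI up, class up
  expect_equal(cat_of[["y"]], "csc_only")     # |dtAI| = 0.1 < 0.2
  expect_equal(cat_of[["z"]], "no_difference")
  expect_equal(cat_of[["w"]], "discordant")   # tAI up but class down
})

test_that("gene-set half-life summaries report mean, SEM and n", {
  hl <- matrix(c(2, 4, 6, 3, 5, 7), ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  s <- geneset_halflife_summary(c("g1", "g2"), hl)
  expect_equal(s$mean, c(3, 4))
  expect_equal(s$sem, c(1, 1))
  expect_equal(s$n, c(2, 2))
  one <- geneset_halflife_summary("g1", hl)
  expect_true(all(is.na(one$sem)))
  expect_error(geneset_halflife_summary("nope", hl), "coverage")
  # vector input
  v <- geneset_halflife_summary(c("g1", "g2"), setNames(c(2, 4), c("g1", "g2")))
  expect_equal(v$mean, 3)
  # formula oracle on a larger set
  set.seed(15)
  big <- matrix(rlnorm(30), ncol = 1, dimnames = list(sprintf("h%02d", 1:30), "c1"))
  sb <- geneset_halflife_summary(rownames(big), big)
  expect_equal(sb$sem, sd(big[, 1]) / sqrt(30), tolerance = 1e-12)
})
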