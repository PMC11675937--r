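toy_counts <- function() {
  m <- matrix(c(100, 200, 300, 50, 400, 150,
                180, 410, 620, 95, 790, 310), ncol = 2,
              dimnames = list(paste0("t", 1:6), c("s1", "s2")))
  m
}

test_that("TMM factors are 1 for identical columns and depth-only differences", {
  m <- toy_counts()
  same <- cbind(s1 = m[, 1], s2 = m[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  scaled <- cbind(a = m[, 1], b = 2 * m[, 1])
  f <- tmm_factors(scaled)
  norm <- normalize_counts(scaled, f)
  expect_equal(norm[, "a"], norm[, "b"])
})

test_that("TMM factors match the brute-force oracle and edgeR", {
  m <- toy_counts()
  f <- tmm_factors(m, reference_sample = 1)
  expect_equal(unname(f), oracle_tmm_factors(m, ref = 1), tolerance = 1e-9)
  set.seed(5)
  big <- matrix(rnbinom(400, mu = 200, size = 5), ncol = 4,
                dimnames = list(paste0("f", 1:100), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(big)),
               unname(edgeR::calcNormFactors(big, method = "TMM")),
               tolerance = 1e-12)
})

test_that("TMM factor geometric mean is 1 and all-zero samples error", {
  set.seed(8)
  m <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  m[, 2] <- 0
  expect_error(tmm_factors(m), "b")
})

test_that("TMM normalization is scale-invariant", {
  # with the unweighted trimmed mean, rescaling one column's counts is
  # exactly absorbed; precision weights make it approximate (they depend on
  # sequencing depth)
  set.seed(9)
  m <- matrix(rnbinom(240, mu = 150, size = 8), ncol = 3,
              dimnames = list(paste0("f", 1:80), c("a", "b", "c")))
  n0 <- normalize_counts(m, tmm_factors(m, reference_sample = 1, weighted = FALSE))
  m2 <- m
  m2[, "c"] <- m2[, "c"] * 4
  n1 <- normalize_counts(m2, tmm_factors(m2, reference_sample = 1, weighted = FALSE))
  expect_equal(n1, n0, tolerance = 1e-6)
  n1w <- normalize_counts(m2, tmm_factors(m2, reference_sample = 1))
  n0w <- normalize_counts(m, tmm_factors(m, reference_sample = 1))
  expect_equal(n1w, n0w, tolerance = 0.01)
})

test_that("normalize_counts scales by library size times factor", {
  m <- matrix(c(10, 90, 20, 80), ncol = 2,
              dimnames = list(c("x", "y"), c("a", "b")))
  n <- normalize_counts(m, c(a = 1, b = 1), scale = 1e6)
  expect_equal(n["x", "a"], 10 / 100 * 1e6)
  n2 <- normalize_counts(m, c(a = 1, b = 2), scale = 1e6)
  expect_equal(n2[, "b"], n[, "b"] / 2)
  expect_error(normalize_counts(m, c(q = 1, r = 1)), "match")
})

test_that("isoacceptor aggregation averages member isodecoders", {
  # TMM values for the two Ser-UGA isodecoders in the progenitor condition
  ab <- matrix(c(220526, 14398), ncol = 1,
               dimnames = list(c("tRNA-Ser-TGA-1-1", "tRNA-Ser-TGA-2-1"), "nb_1"))
  acc <- data.frame(isoacceptor_id = "Ser-TGA", amino_acid = "Ser",
                    anticodon = "TGA", n_isodecoders = 2,
                    isodecoder_group_ids = "tRNA-Ser-TGA-1-1,tRNA-Ser-TGA-2-1",
                    stringsAsFactors = FALSE)
  out <- aggregate_isoacceptors(ab, acc)
  expect_equal(out["Ser-TGA", "nb_1"], 117462)
  # single-member group is the identity
  acc1 <- acc
  acc1$isodecoder_group_ids <- "tRNA-Ser-TGA-1-1"
  acc1$n_isodecoders <- 1
  expect_equal(aggregate_isoacceptors(ab, acc1)["Ser-TGA", "nb_1"], 220526)
  # three members: plain mean, invariant to member order
  ab3 <- matrix(c(10, 20, 60), ncol = 1, dimnames = list(c("i1", "i2", "i3"), "s"))
  acc3 <- acc; acc3$isodecoder_group_ids <- "i1,i2,i3"; acc3$n_isodecoders <- 3
  expect_equal(unname(aggregate_isoacceptors(ab3, acc3)[1, 1]), 30)
  acc3$isodecoder_group_ids <- "i3,i1,i2"
  expect_equal(unname(aggregate_isoacceptors(ab3, acc3)[1, 1]), 30)
  acc3$isodecoder_group_ids <- "i1,missing"
  expect_error(aggregate_isoacceptors(ab3, acc3), "missing")
})

test_that("copy-number weighting changes the aggregate as expected", {
  ab <- matrix(c(10, 40), ncol = 1, dimnames = list(c("i1", "i2"), "s"))
  acc <- data.frame(isoacceptor_id = "Ala-AGC", amino_acid = "Ala",
                    anticodon = "AGC", n_isodecoders = 2,
                    isodecoder_group_ids = "i1,i2", stringsAsFactors = FALSE)
  w <- aggregate_isoacceptors(ab, acc, copy_weights = c(i1 = 3, i2 = 1))
  expect_equal(unname(w[1, 1]), (3 * 10 + 40) / 4)
})

test_that("fold changes flag at the inclusive 0.5 threshold", {
  ab <- matrix(c(220526, 100, 2^0.5 * 50,
                 123522, 100, 50), ncol = 2,
               dimnames = list(c("ser", "flat", "edge"), c("nb_1", "n_1")))
  samples <- data.frame(sample_id = c("nb_1", "n_1"),
                        condition = c("neuroblast", "neuron"),
                        replicate = c(1, 1))
  fc <- condition_fold_change(ab, samples, "neuroblast", "neuron")
  expect_equal(fc$log2fc[fc$feature_id == "ser"],
               log2(220526 / 123522), tolerance = 1e-12)
  expect_equal(round(fc$log2fc[fc$feature_id == "ser"], 3), 0.836)
  expect_true(fc$flagged[fc$feature_id == "ser"])
  expect_equal(fc$log2fc[fc$feature_id == "flat"], 0)
  expect_false(fc$flagged[fc$feature_id == "flat"])
  # |log2FC| exactly 0.5 is flagged (boundary inclusive)
  expect_equal(fc$log2fc[fc$feature_id == "edge"], 0.5)
  expect_true(fc$flagged[fc$feature_id == "edge"])
  expect_error(condition_fold_change(ab, samples, "neuroblast", "glia"),
               "absent")
})

test_that("zero condition means get a pseudocount and q-values join", {
  ab <- matrix(c(10, 0, 5, 4), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        condition = c("x", "y"), replicate = c(1, 1))
  fc <- condition_fold_change(ab, samples, "x", "y",
                              q_values = c(a = 0.05, b = 0.5))
  expect_true(is.finite(fc$log2fc[fc$feature_id == "b"]))
  expect_equal(fc$log2fc[fc$feature_id == "b"], log2(0.5 / 4.5))
  expect_true(fc$significant[fc$feature_id == "a"])
  expect_false(fc$significant[fc$feature_id == "b"])
})

test_that("planted isodecoder fold-change signs are recovered from NB counts", {
  ids <- sprintf("iso%02d", 1:80)
  set.seed(13)
  hit <- sample(ids, 20)
  lfc <- setNames(sample(c(-2, -1.5, -1, 1, 1.5, 2), 20, replace = TRUE), hit)
  g <- gen_counts(ids, planted_lfc = lfc, dispersion = 0.05, depth = 1e6,
                  n_reps = 3, seed = 21)
  ab <- normalize_counts(g$counts, tmm_factors(g$counts))
  fc <- condition_fold_change(ab, g$samples, "neuron", "neuroblast")
  est <- setNames(fc$log2fc, fc$feature_id)
  expect_gte(mean(sign(est[hit]) == sign(lfc)), 0.95)
})

test_that("anticodon supply excludes initiator Met and keys by anticodon", {
  acc <- data.frame(
    isoacceptor_id = c("Met-CAT", "iMet-CAT", "Ser-TGA"),
    amino_acid = c("Met", "iMet", "Ser"),
    anticodon = c("CAT", "CAT", "TGA"),
    n_isodecoders = 1,
    isodecoder_group_ids = c("m1", "m2", "s1"),
    stringsAsFactors = FALSE
  )
  ab <- c("Met-CAT" = 100, "iMet-CAT" = 50, "Ser-TGA" = 10)
  s <- anticodon_supply(ab, acc)
  expect_equal(s[["CAT"]], 100)
  expect_equal(s[["TGA"]], 10)
})
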