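# Synthetic-data generators with planted ground truth. They emit exactly the
# inputs the pipeline consumes (tRNA gene FASTA, count/half-life/expression
# tables, CDS FASTA) with the statistical structure the analysis assumes:
# negative-binomial replicate noise around planted isodecoder fold changes,
# Dirichlet synonymous-codon preference profiles with fixed amino-acid
# composition, a linear codon-frequency model for half-lives, and
# log-uniform expression. Every generator is a pure function of
# (parameters, seed).

#' Deterministic covering anticodon set
#'
#' Greedily adds Watson-Crick anticodons (in sorted codon order) until every
#' sense codon has at least one cognate under the default wobble rules, so a
#' synthetic tRNA set built from it gives every amino-acid family decoding
#' capacity.
#'
#' @param rules a `wobble_rules` object.
#' @return Character vector of anticodons.
#' @export
covering_anticodon_set <- function(rules = default_wobble_rules()) {
  set <- character(0)
  for (cd in sense_codons()) {
    cands <- cognate_trnas(cd, stats::setNames(numeric(0), character(0)), rules)$anticodon
    if (!any(cands %in% set)) set <- c(set, wc_anticodon(cd))
  }
  sort(set)
}

#' Generate a synthetic tRNA gene set
#'
#' Genes are named in gtRNAdb style (`tRNA-<AA>-<anticodon>-<i>-1`) with
#' random 72-nt bodies carrying the anticodon at positions 34-36. A chosen
#' number of families get duplicate (byte-identical) sequences to exercise
#' isodecoder collapsing.
#'
#' @param n_families number of anticodon families (ignored when `anticodons`
#'   given).
#' @param isodecoders_per_family genes per family (default 2).
#' @param seed RNG seed.
#' @param anticodons explicit anticodon vector, or `"covering"` for
#'   [covering_anticodon_set()]; default samples `n_families` Watson-Crick
#'   anticodons.
#' @param n_duplicate_pairs families whose first two genes share a sequence
#'   (default 0).
#' @param fasta_path optional path; when given the FASTA is written there.
#' @return List: `genes` (data.frame `gene_id`, `amino_acid`, `anticodon`,
#'   `sequence`), `truth` (parameters, duplicated families), `fasta_path`.
#' @export
gen_trna_set <- function(n_families = 10, isodecoders_per_family = 2, seed = 1,
                         anticodons = NULL, n_duplicate_pairs = 0,
                         fasta_path = NULL) {
  set.seed(seed)
  all_ac <- sort(unique(wc_anticodon(sense_codons())))
  if (identical(anticodons, "covering")) {
    anticodons <- covering_anticodon_set()
  } else if (is.null(anticodons)) {
    if (n_families > length(all_ac)) stop("n_families exceeds available anticodons")
    anticodons <- sort(sample(all_ac, n_families))
  } else {
    anticodons <- as_dna(anticodons)
    bad <- setdiff(anticodons, all_ac)
    if (length(bad)) stop("anticodon(s) of stop codons or invalid: ",
                          paste(bad, collapse = ", "))
  }
  if (isodecoders_per_family < 1) stop("need >= 1 isodecoder per family")
  if (n_duplicate_pairs > 0 && isodecoders_per_family < 2) {
    stop("duplicates require >= 2 isodecoders per family")
  }
  aa3 <- AA_THREE_LETTER[unname(Biostrings::GENETIC_CODE[reverse_complement(anticodons)])]
  rows <- list()
  dup_fams <- character(0)
  for (i in seq_along(anticodons)) {
    ac <- anticodons[i]
    for (j in seq_len(isodecoders_per_family)) {
      body <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = "")
      seqs <- paste0(substr(body, 1, 33), ac, substr(body, 37, 72))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = paste0("tRNA-", aa3[i], "-", ac, "-", j, "-1"),
        amino_acid = unname(aa3[i]), anticodon = ac, sequence = seqs,
        stringsAsFactors = FALSE)
    }
    if (i <= n_duplicate_pairs) {
      k <- length(rows)
      rows[[k]]$sequence <- rows[[k - 1]]$sequence
      dup_fams <- c(dup_fams, paste0(aa3[i], "-", ac))
    }
  }
  genes <- do.call(rbind, rows)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(genes$sequence)
    names(ss) <- genes$gene_id
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  list(genes = genes,
       truth = list(seed = seed, anticodons = anticodons,
                    isodecoders_per_family = isodecoders_per_family,
                    duplicated_families = dup_fams),
       fasta_path = fasta_path)
}

#' Generate negative-binomial tRNA-seq counts with planted fold changes
#'
#' Condition A means are log-uniform across features (scaled to `depth`);
#' condition B means are A means times `2^planted_lfc`. Replicate counts are
#' negative binomial with the given dispersion (Poisson when 0), with
#' per-replicate library sizes jittered uniformly by +/-20%.
#'
#' @param feature_ids feature (isodecoder group) ids, or a data.frame with a
#'   `group_id` column.
#' @param planted_lfc named log2 fold-change vector (B relative to A);
#'   unnamed features get 0.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth expected library size.
#' @param n_reps replicates per condition.
#' @param seed RNG seed.
#' @param conditions length-2 condition labels c(A, B).
#' @return List: `counts` (features x samples), `samples` (data.frame
#'   `sample_id`, `condition`, `replicate`), `truth` (means, lfc, jitter).
#' @export
gen_counts <- function(feature_ids, planted_lfc = NULL, dispersion = 0.05,
                       depth = 1e6, n_reps = 3, seed = 1,
                       conditions = c("neuroblast", "neuron")) {
  if (is.data.frame(feature_ids)) feature_ids <- feature_ids$group_id
  if (dispersion < 0 || depth <= 0) stop("dispersion >= 0 and depth > 0 required")
  set.seed(seed)
  n <- length(feature_ids)
  lfc <- stats::setNames(rep(0, n), feature_ids)
  if (!is.null(planted_lfc)) lfc[names(planted_lfc)] <- planted_lfc
  base <- 10^stats::runif(n, 0, 4)
  mu_a <- stats::setNames(base / sum(base) * depth, feature_ids)
  mu_b <- mu_a * 2^lfc
  samples <- data.frame(
    sample_id = paste0(rep(conditions, each = n_reps), "_", seq_len(n_reps)),
    condition = rep(conditions, each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    stringsAsFactors = FALSE
  )
  jitter <- stats::runif(nrow(samples), 0.8, 1.2)
  counts <- vapply(seq_len(nrow(samples)), function(s) {
    mu <- (if (samples$condition[s] == conditions[1]) mu_a else mu_b) * jitter[s]
    if (dispersion == 0) as.numeric(stats::rpois(n, mu))
    else as.numeric(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
  }, numeric(n))
  dimnames(counts) <- list(feature_ids, samples$sample_id)
  list(counts = counts, samples = samples,
       truth = list(seed = seed, mu_a = mu_a, mu_b = mu_b, lfc = lfc,
                    dispersion = dispersion, depth = depth,
                    library_jitter = stats::setNames(jitter, samples$sample_id)))
}

#' Generate a synthetic transcriptome with codon-usage profiles
#'
#' Each profile has its own synonymous-codon preference within every
#' amino-acid family: preference = (1 - divergence) * shared Dirichlet draw
#' + divergence * profile-specific Dirichlet draw, so divergence 0 makes
#' profiles identical. Amino-acid composition is held fixed across profiles,
#' isolating synonymous usage. Genes are sampled codon-by-codon; a terminal
#' TAA stop is appended and internal stops cannot occur.
#'
#' @param n_genes number of genes.
#' @param n_profiles number of usage profiles (>= 1).
#' @param profile_divergence in \[0, 1\].
#' @param length_range CDS length range in codons (inclusive).
#' @param seed RNG seed.
#' @param profile_weights sampling probabilities over profiles (default
#'   equal); lets one usage program be a minority class as codon-usage
#'   clusters are in real transcriptomes.
#' @param fasta_path optional output FASTA path.
#' @return List: `cds` (named character vector), `profiles` (named integer
#'   labels 1..n_profiles), `truth` (preference vectors, amino-acid
#'   composition, parameters), `fasta_path`.
#' @export
gen_transcriptome <- function(n_genes = 500, n_profiles = 2,
                              profile_divergence = 0.7,
                              length_range = c(100, 300), seed = 1,
                              profile_weights = NULL, fasta_path = NULL) {
  if (n_profiles < 1) stop("n_profiles >= 1 required")
  if (profile_divergence < 0 || profile_divergence > 1) {
    stop("profile_divergence must lie in [0,1]")
  }
  set.seed(seed)
  tab <- codon_table()
  fams <- split(tab$codon, tab$aa)
  aa_names <- names(fams)
  aa_comp <- as.numeric(rdirichlet(1, rep(3, length(aa_names))))
  names(aa_comp) <- aa_names
  shared <- lapply(fams, function(cds) {
    stats::setNames(as.numeric(rdirichlet(1, rep(2, length(cds)))), cds)
  })
  prefs <- lapply(seq_len(n_profiles), function(p) {
    lapply(aa_names, function(f) {
      own <- as.numeric(rdirichlet(1, rep(0.8, length(fams[[f]]))))
      stats::setNames((1 - profile_divergence) * shared[[f]] +
                        profile_divergence * own, fams[[f]])
    }) |> stats::setNames(aa_names)
  })
  if (is.null(profile_weights)) {
    profile_of <- sample(rep(seq_len(n_profiles), length.out = n_genes))
  } else {
    if (length(profile_weights) != n_profiles) stop("one weight per profile")
    profile_of <- sample(seq_len(n_profiles), n_genes, replace = TRUE,
                         prob = profile_weights)
  }
  lens <- sample(seq(length_range[1], length_range[2]), n_genes, replace = TRUE)
  gene_idx <- rep(seq_len(n_genes), lens)
  aa_seq <- sample(aa_names, sum(lens), replace = TRUE, prob = aa_comp)
  codons <- character(length(aa_seq))
  for (p in seq_len(n_profiles)) {
    in_p <- profile_of[gene_idx] == p
    for (f in aa_names) {
      idx <- which(in_p & aa_seq == f)
      if (length(idx)) {
        codons[idx] <- sample(fams[[f]], length(idx), replace = TRUE,
                              prob = prefs[[p]][[f]])
      }
    }
  }
  ids <- sprintf("gene%04d", seq_len(n_genes))
  cds <- vapply(split(codons, gene_idx), paste, character(1), collapse = "")
  cds <- stats::setNames(paste0(cds, "TAA"), ids)
  names(profile_of) <- ids
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(cds)
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  list(cds = cds, profiles = profile_of,
       truth = list(seed = seed, preferences = prefs, shared = shared,
                    aa_composition = aa_comp,
                    profile_divergence = profile_divergence),
       fasta_path = fasta_path)
}

#' Generate half-lives from a planted linear codon-frequency model
#'
#' half-life_g = baseline + sum_c beta_c * freq_gc + Normal(0, noise_sd),
#' floored at `floor`. When `noise_sd` is `NULL` it is set to 25% of the
#' range of the noiseless signal, a regime in which planted stabilizing and
#' destabilizing codons remain recoverable by CSC.
#'
#' @param freq genes x 61 frequency matrix.
#' @param planted_beta named per-codon coefficient vector (hours per unit
#'   frequency); unnamed codons get 0.
#' @param noise_sd Gaussian noise SD in hours, or `NULL` (see above).
#' @param baseline intercept in hours (default 6).
#' @param floor minimum half-life (default 0.1 h).
#' @param seed RNG seed.
#' @return List: `half_lives` (named vector, hours), `truth` (beta,
#'   noise_sd, baseline, seed).
#' @export
gen_halflives <- function(freq, planted_beta, noise_sd = NULL, baseline = 6,
                          floor = 0.1, seed = 1) {
  set.seed(seed)
  beta <- stats::setNames(rep(0, ncol(freq)), colnames(freq))
  beta[names(planted_beta)] <- planted_beta
  signal <- baseline + as.numeric(freq %*% beta)
  if (is.null(noise_sd)) noise_sd <- 0.25 * diff(range(signal))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  hl <- signal + stats::rnorm(nrow(freq), 0, noise_sd)
  hl <- pmax(hl, floor)
  if (all(hl == floor)) stop("all half-lives floored; adjust baseline/beta")
  list(half_lives = stats::setNames(hl, rownames(freq)),
       truth = list(beta = beta, noise_sd = noise_sd, baseline = baseline,
                    floor = floor, seed = seed))
}

#' Generate log-uniform expression tables per condition
#'
#' Base expression is log-uniform over `[1, dynamic_range]`, identical in
#' both conditions; optionally one profile's genes are up-weighted in one
#' condition to move codon demand between conditions.
#'
#' @param gene_ids gene ids.
#' @param dynamic_range >= 1; 1 gives all-equal expression.
#' @param seed RNG seed.
#' @param conditions length-2 condition labels.
#' @param profiles optional named profile labels (from
#'   [gen_transcriptome()]).
#' @param bias_profile,bias_condition,bias_factor up-weight `bias_profile`
#'   genes by `bias_factor` in `bias_condition`.
#' @return List: `expression` (genes x 2 matrix), `truth`.
#' @export
gen_expression <- function(gene_ids, dynamic_range = 100, seed = 1,
                           conditions = c("neuroblast", "neuron"),
                           profiles = NULL, bias_profile = NULL,
                           bias_condition = NULL, bias_factor = 1) {
  if (dynamic_range < 1) stop("dynamic_range must be >= 1")
  set.seed(seed)
  n <- length(gene_ids)
  base <- dynamic_range^stats::runif(n, 0, 1)
  expr <- matrix(base, nrow = n, ncol = 2,
                 dimnames = list(gene_ids, conditions))
  if (!is.null(bias_profile) && !is.null(bias_condition) && bias_factor != 1) {
    hit <- names(profiles)[profiles == bias_profile]
    expr[intersect(gene_ids, hit), bias_condition] <-
      expr[intersect(gene_ids, hit), bias_condition] * bias_factor
  }
  list(expression = expr,
       truth = list(seed = seed, dynamic_range = dynamic_range,
                    bias_profile = bias_profile, bias_condition = bias_condition,
                    bias_factor = bias_factor))
}

#' Simulate a full two-condition study
#'
#' Composes the generators into a complete scenario: a covering synthetic
#' tRNA set; a two-profile transcriptome; tRNA counts in which condition B's
#' pool up-weights the anticodons decoding profile-2-preferred codons (and
#' down-weights profile-1-preferred ones); half-lives from a planted linear
#' codon model (shared coefficients, independent noise per condition); and
#' log-uniform expression. All inputs are written as the plain-text formats
#' the pipeline consumes, together with a YAML truth file.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_genes transcriptome size (default 600).
#' @param profile_divergence synonymous-usage separation (default 0.8).
#' @param pool_lfc magnitude of planted tRNA log2 fold changes (default 2).
#' @param n_reps replicates per condition (default 3).
#' @param depth expected tRNA library size (default 1e6).
#' @param dispersion NB dispersion (default 0.05).
#' @param conditions condition labels (default neuroblast/neuron).
#' @return List: `paths` (named file paths), `truth` (per-stage truth),
#'   `config` (a ready [run_pipeline()] configuration list).
#' @export
simulate_study <- function(out_dir, seed = 1, n_genes = 600,
                           profile_divergence = 0.8, pool_lfc = 2,
                           n_reps = 3, depth = 1e6, dispersion = 0.05,
                           conditions = c("neuroblast", "neuron")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  seeds <- seed + 0:4

  trna <- gen_trna_set(anticodons = "covering", isodecoders_per_family = 2,
                       n_duplicate_pairs = 2, seed = seeds[1],
                       fasta_path = p("trna_genes.fasta"))
  isodec <- build_isodecoder_reference(
    parse_trna_fasta(p("trna_genes.fasta")))

  # profile 2 (differentiation-like usage program) is a minority class, as
  # codon-usage clusters are in real transcriptomes
  tx <- gen_transcriptome(n_genes = n_genes, n_profiles = 2,
                          profile_divergence = profile_divergence,
                          profile_weights = c(0.8, 0.2),
                          seed = seeds[2], fasta_path = p("cds.fasta"))

  # favored codon per family and profile -> planted anticodon fold changes
  fav <- lapply(1:2, function(pr) {
    vapply(tx$truth$preferences[[pr]], function(v) names(v)[which.max(v)],
           character(1))
  })
  lfc <- stats::setNames(rep(0, nrow(isodec)), isodec$group_id)
  ac_up <- unique(wc_anticodon(setdiff(fav[[2]], fav[[1]])))
  ac_dn <- unique(wc_anticodon(setdiff(fav[[1]], fav[[2]])))
  lfc[isodec$anticodon %in% ac_up] <- pool_lfc
  lfc[isodec$anticodon %in% ac_dn] <- -pool_lfc

  cnt <- gen_counts(isodec, planted_lfc = lfc, dispersion = dispersion,
                    depth = depth, n_reps = n_reps, seed = seeds[3],
                    conditions = conditions)
  write_feature_table(cnt$counts, p("trna_counts.tsv"))
  write_feature_table(cnt$samples, p("samples.tsv"))

  cfm <- codon_frequency_matrix(tx$cds)
  # stability coefficients coupled to decoding supply: codons decoded by
  # abundant anticodons stabilize, codons decoded by rare ones destabilize
  ac_mu <- tapply(cnt$truth$mu_a, isodec$anticodon, mean)
  wc_ab <- wc_abundance_map(stats::setNames(as.numeric(ac_mu), names(ac_mu)))
  z <- log10(wc_ab + 1)
  beta <- stats::setNames(20 * as.numeric(scale(z)), names(wc_ab))
  beta <- beta[colnames(cfm$freq)]
  hl_a <- gen_halflives(cfm$freq, beta, seed = seeds[4])
  hl_b <- gen_halflives(cfm$freq, beta, seed = seeds[4] + 1000)
  hl <- cbind(hl_a$half_lives, hl_b$half_lives[names(hl_a$half_lives)])
  colnames(hl) <- conditions
  write_feature_table(hl, p("half_lives.tsv"), id_col = "gene_id")

  ex <- gen_expression(names(tx$cds), dynamic_range = 100, seed = seeds[5],
                       conditions = conditions)
  write_feature_table(ex$expression, p("expression.tsv"), id_col = "gene_id")

  truth <- list(seed = seed, trna = trna$truth, transcriptome = tx$truth,
                counts = cnt$truth, halflife = hl_a$truth,
                expression = ex$truth,
                profiles = as.list(tx$profiles),
                favored_codons = fav,
                anticodons_up_in_b = ac_up, anticodons_down_in_b = ac_dn)
  yaml::write_yaml(list(seed = seed,
                        planted_lfc = as.list(lfc[lfc != 0]),
                        beta = as.list(round(hl_a$truth$beta, 6)),
                        profiles = as.list(tx$profiles)),
                   p("truth.yaml"))

  config <- list(
    trna_fasta = p("trna_genes.fasta"), counts = p("trna_counts.tsv"),
    samples = p("samples.tsv"), cds_fasta = p("cds.fasta"),
    half_lives = p("half_lives.tsv"), expression = p("expression.tsv"),
    condition_a = conditions[1], condition_b = conditions[2],
    out_dir = file.path(out_dir, "results"), seed = seed
  )
  list(paths = list(trna_fasta = p("trna_genes.fasta"),
                    counts = p("trna_counts.tsv"), samples = p("samples.tsv"),
                    cds_fasta = p("cds.fasta"), half_lives = p("half_lives.tsv"),
                    expression = p("expression.tsv"), truth = p("truth.yaml")),
       truth = truth, config = config)
}
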