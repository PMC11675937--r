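# Configuration-driven orchestration of the full analysis:
# reference -> quantification -> codon usage -> optimality -> multivariate.
# All outputs are plain TSV with provenance header comments (package
# version, config hash, seed), so reruns with the same config and seed are
# byte-identical.

default_pipeline_config <- function() {
  list(
    condition_a = "neuroblast", condition_b = "neuron",
    scale = 1e6, lfc_threshold = 0.5, pseudocount = 0.5,
    csc_pos_threshold = 0.01, csc_neg_threshold = -0.01,
    delta_tai_threshold = 0.2, top_fraction = 0.1, min_percent = 2,
    cai_reference_fraction = 0.05,
    k_range = 2:10, n_restarts = 10, seed = 1,
    lysidine = FALSE
  )
}

#' Read and validate a pipeline configuration
#'
#' @param config named list, or path to a YAML file. Required fields:
#'   `trna_fasta`, `counts`, `samples`, `cds_fasta`, `half_lives`,
#'   `expression`, `out_dir`. Optional fields (thresholds, condition labels,
#'   seed, ...) fall back to documented defaults.
#' @param cai_reference optional character vector of reference gene ids for
#'   CAI (e.g. ribosomal protein genes); by default the top
#'   `cai_reference_fraction` of genes by mean expression are used.
#' @return Validated config list with defaults filled in.
#' @export
pipeline_config <- function(config, cai_reference = NULL) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  required <- c("trna_fasta", "counts", "samples", "cds_fasta",
                "half_lives", "expression", "out_dir")
  missing_f <- setdiff(required, names(cfg))
  if (length(missing_f)) stop("config missing field(s): ",
                              paste(missing_f, collapse = ", "))
  for (f in c("trna_fasta", "counts", "samples", "cds_fasta",
              "half_lives", "expression")) {
    if (!file.exists(cfg[[f]])) stop("input not readable (", f, "): ", cfg[[f]])
  }
  cfg[["cai_reference"]] <- cai_reference %||% cfg[["cai_reference"]]
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order and writes TSV outputs (reference
#' map, isoacceptor abundances, isodecoder fold changes, per-codon metrics,
#' per-gene metrics, cluster assignments and inertia trace, ranked delta-SDR
#' table) plus a serialized copy of the configuration to `out_dir`.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @param cai_reference optional CAI reference gene ids.
#' @return Invisibly, a list with every intermediate result (`reference`,
#'   `quant`, `codon_usage`, `optimality`, `multivariate`, `paths`).
#' @export
run_pipeline <- function(config, cai_reference = NULL) {
  cfg <- pipeline_config(config, cai_reference)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(cfg[sort(names(cfg))])
  meta <- c(package = paste0("trnadapt ", as.character(utils::packageVersion("trnadapt"))),
            config_hash = cfg_hash, seed = cfg$seed)
  outp <- function(f) file.path(cfg$out_dir, f)
  rules <- default_wobble_rules(lysidine = isTRUE(cfg$lysidine))
  conds <- c(cfg$condition_a, cfg$condition_b)

  ref <- stage("reference", {
    genes <- parse_trna_fasta(cfg$trna_fasta)
    isodec <- build_isodecoder_reference(genes)
    isoacc <- build_isoacceptor_map(isodec)
    write_reference(isodec, isoacc, outp("isodecoder_reference.fasta"),
                    outp("reference_map.tsv"))
    list(genes = genes, isodecoders = isodec, isoacceptors = isoacc)
  })

  quant <- stage("quantification", {
    counts <- read_feature_table(cfg$counts)
    samples <- utils::read.delim(cfg$samples, comment.char = "#",
                                 stringsAsFactors = FALSE)
    factors <- tmm_factors(counts)
    abund <- normalize_counts(counts, factors, scale = cfg$scale)
    fc <- condition_fold_change(abund, samples, cfg$condition_a,
                                cfg$condition_b,
                                lfc_threshold = cfg$lfc_threshold,
                                pseudocount = cfg$pseudocount)
    message("flagged isodecoders (|log2FC| >= ", cfg$lfc_threshold, "): ",
            sum(fc$flagged))
    # isoacceptor aggregation restricted to mapped (cytosolic) isodecoders
    iso_ab <- aggregate_isoacceptors(
      abund[intersect(rownames(abund),
                      unlist(strsplit(ref$isoacceptors$isodecoder_group_ids, ","))),
            , drop = FALSE],
      ref$isoacceptors)
    iso_cm <- condition_means(iso_ab, samples)
    iso_fc <- condition_fold_change(iso_ab, samples, cfg$condition_a,
                                    cfg$condition_b,
                                    lfc_threshold = cfg$lfc_threshold)
    supply <- lapply(conds, function(cc) {
      anticodon_supply(iso_cm[, cc], ref$isoacceptors)
    })
    names(supply) <- conds
    write_feature_table(iso_ab, outp("isoacceptor_abundance.tsv"),
                        id_col = "isoacceptor_id", meta = meta)
    write_feature_table(fc, outp("isodecoder_fold_changes.tsv"), meta = meta)
    write_feature_table(iso_fc, outp("isoacceptor_fold_changes.tsv"), meta = meta)
    list(factors = factors, abundance = abund, samples = samples,
         isoacceptor_abundance = iso_ab, isoacceptor_means = iso_cm,
         fold_changes = fc, isoacceptor_fold_changes = iso_fc,
         supply = supply)
  })

  usage <- stage("codon_usage", {
    cds <- Biostrings::readDNAStringSet(cfg$cds_fasta)
    names(cds) <- sub("\\s.*", "", names(cds))
    cfm <- codon_frequency_matrix(as.character(cds))
    aa_norm <- aa_normalized_frequencies(cfm$counts)
    cfm$aa_norm <- aa_norm
    cfm
  })

  opt <- stage("optimality", {
    hl <- read_feature_table(cfg$half_lives)
    expr <- read_feature_table(cfg$expression)
    if (!all(conds %in% colnames(hl))) stop("half-life table lacks condition columns")
    if (!all(conds %in% colnames(expr))) stop("expression table lacks condition columns")
    per_cond <- lapply(conds, function(cc) {
      csc <- compute_csc(usage$freq, stats::setNames(hl[, cc], rownames(hl)))
      cls <- classify_codons(csc, cfg$csc_pos_threshold, cfg$csc_neg_threshold)
      ct <- codon_tai(quant$supply[[cc]], rules)
      tai <- stats::setNames(ct$tai, ct$codon)
      e <- stats::setNames(expr[, cc], rownames(expr))
      e <- e[e > 0]
      demand <- codon_demand(usage$freq, e)
      keep <- intersect(rownames(usage$counts), names(e))
      sdr <- compute_sdr(tai, demand, usage$counts[keep, , drop = FALSE])
      list(csc = csc, class = cls, tai = tai, W = stats::setNames(ct$W, ct$codon),
           demand = demand, sdr = sdr,
           tai_gene = stats::setNames(gene_tai(usage$counts, tai),
                                      rownames(usage$counts)),
           wc_abundance = wc_abundance_map(quant$supply[[cc]]))
    })
    names(per_cond) <- conds
    # CAI reference: supplied ids, or top fraction by mean expression
    ref_ids <- cfg[["cai_reference"]]
    if (is.null(ref_ids)) {
      me <- rowMeans(expr[, conds, drop = FALSE])
      me <- me[intersect(names(me), rownames(usage$counts))]
      n_ref <- max(2, ceiling(cfg$cai_reference_fraction * length(me)))
      ref_ids <- names(sort(me, decreasing = TRUE))[seq_len(n_ref)]
    }
    cai <- compute_cai(usage$counts,
                       usage$counts[intersect(ref_ids, rownames(usage$counts)),
                                    , drop = FALSE])
    dsdr <- delta_sdr(per_cond[[1]]$sdr$sdr_gene, per_cond[[2]]$sdr$sdr_gene,
                      fraction = cfg$top_fraction)
    effect <- lapply(per_cond, function(pc) tai_csc_effect(pc$tai, pc$csc))
    diff_cat <- differential_tai_csc(per_cond[[1]]$tai, per_cond[[2]]$tai,
                                     per_cond[[1]]$class, per_cond[[2]]$class,
                                     cfg$delta_tai_threshold)
    codon_metrics <- data.frame(codon = sense_codons(), stringsAsFactors = FALSE)
    for (cc in conds) {
      pc <- per_cond[[cc]]
      codon_metrics[[paste0("csc_", cc)]] <- unname(pc$csc[codon_metrics$codon])
      codon_metrics[[paste0("class_", cc)]] <- unname(pc$class[codon_metrics$codon])
      codon_metrics[[paste0("tai_", cc)]] <- unname(pc$tai[codon_metrics$codon])
      codon_metrics[[paste0("wc_abundance_", cc)]] <- unname(pc$wc_abundance[codon_metrics$codon])
      codon_metrics[[paste0("demand_", cc)]] <- unname(pc$demand[codon_metrics$codon])
      codon_metrics[[paste0("sdr_", cc)]] <- unname(pc$sdr$sdr_codon[codon_metrics$codon])
    }
    codon_metrics$diff_category <-
      diff_cat$category[match(codon_metrics$codon, diff_cat$codon)]
    write_feature_table(codon_metrics, outp("codon_metrics.tsv"), meta = meta)
    write_feature_table(dsdr$table, outp("delta_sdr_ranking.tsv"), meta = meta)
    list(per_condition = per_cond, cai = cai, delta_sdr = dsdr,
         effect = effect, differential = diff_cat, half_lives = hl,
         expression = expr, codon_metrics = codon_metrics,
         cai_reference_ids = ref_ids)
  })

  multi <- stage("multivariate", {
    pca <- pca_codon_usage(usage$aa_norm)
    km <- kmeans_elbow(usage$aa_norm, k_range = cfg$k_range, seed = cfg$seed,
                       n_restarts = cfg$n_restarts)
    groups <- tai_gene_groups(opt$per_condition[[1]]$tai_gene,
                              opt$per_condition[[2]]$tai_gene)
    ord <- hierarchical_order(quant$isoacceptor_means)
    clusters <- data.frame(gene_id = names(km$labels),
                           cluster = unname(km$labels),
                           pc1 = pca$scores[names(km$labels), 1],
                           pc2 = pca$scores[names(km$labels), 2],
                           stringsAsFactors = FALSE)
    write_feature_table(clusters, outp("clusters.tsv"), meta = meta)
    write_feature_table(km$trace, outp("inertia_trace.tsv"), meta = meta)
    writeLines(ord$newick, outp("isoacceptor_dendrogram.nwk"))
    list(pca = pca, kmeans = km, groups = groups, isoacceptor_order = ord,
         clusters = clusters)
  })

  gene_ids <- rownames(usage$counts)
  gm <- data.frame(gene_id = gene_ids, L = usage$L[gene_ids],
                   cai = unname(opt$cai$cai[gene_ids]),
                   stringsAsFactors = FALSE)
  for (cc in conds) {
    pc <- opt$per_condition[[cc]]
    gm[[paste0("tai_gene_", cc)]] <- unname(pc$tai_gene[gene_ids])
    gm[[paste0("sdr_", cc)]] <- unname(pc$sdr$sdr_gene[gene_ids])
    gm[[paste0("half_life_", cc)]] <-
      opt$half_lives[match(gene_ids, rownames(opt$half_lives)), cc]
    gm[[paste0("expression_", cc)]] <-
      opt$expression[match(gene_ids, rownames(opt$expression)), cc]
  }
  gm$delta_sdr <- opt$delta_sdr$table$delta_sdr[
    match(gene_ids, opt$delta_sdr$table$gene_id)]
  gm$cluster <- multi$clusters$cluster[match(gene_ids, multi$clusters$gene_id)]
  gm$tai_group <- multi$groups$group[match(gene_ids, multi$groups$gene_id)]
  write_feature_table(gm, outp("gene_metrics.tsv"), meta = meta)
  yaml::write_yaml(c(cfg[sort(names(cfg))], list(config_hash = cfg_hash)),
                   outp("config.yaml"))

  invisible(list(reference = ref, quant = quant, codon_usage = usage,
                 optimality = opt, multivariate = multi, gene_metrics = gm,
                 config = cfg, config_hash = cfg_hash,
                 paths = as.list(stats::setNames(
                   file.path(cfg$out_dir,
                             c("isodecoder_reference.fasta", "reference_map.tsv",
                               "isoacceptor_abundance.tsv",
                               "isodecoder_fold_changes.tsv",
                               "isoacceptor_fold_changes.tsv",
                               "codon_metrics.tsv", "delta_sdr_ranking.tsv",
                               "clusters.tsv", "inertia_trace.tsv",
                               "gene_metrics.tsv", "config.yaml")),
                   c("reference_fasta", "reference_map", "isoacceptor_abundance",
                     "isodecoder_fold_changes", "isoacceptor_fold_changes",
                     "codon_metrics", "delta_sdr_ranking", "clusters",
                     "inertia_trace", "gene_metrics", "config")))))
}
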