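# Codon counting and the normalized / amino-acid-normalized frequency
# matrices that feed every downstream metric (CSC, tAI_gene, CAI, demand,
# PCA). Frequencies are length-normalized: count of codon i divided by the
# total number of sense codons in the CDS.

validate_cds <- function(seq, gene_id = "<cds>", internal_stop = c("error", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  seq <- as_dna(seq)
  if (nchar(seq) %% 3 != 0) {
    stop("CDS length not divisible by 3: ", gene_id, " (", nchar(seq), " nt)")
  }
  codons <- substring(seq, seq(1, nchar(seq) - 2, by = 3), seq(3, nchar(seq), by = 3))
  stops <- stop_codons()
  # a single terminal stop is stripped, not counted
  if (length(codons) && codons[length(codons)] %in% stops) {
    codons <- codons[-length(codons)]
  }
  internal <- which(codons %in% stops)
  if (length(internal)) {
    if (internal_stop == "error") {
      stop("internal stop codon in ", gene_id, " at codon position ",
           internal[1])
    }
    codons <- codons[seq_len(internal[1] - 1)]
    message("truncated ", gene_id, " at internal stop (position ", internal[1], ")")
  }
  ambiguous <- grepl("[^ACGT]", codons)
  if (any(ambiguous)) {
    message("skipped ", sum(ambiguous), " ambiguous codon(s) in ", gene_id)
    codons <- codons[!ambiguous]
  }
  codons
}

#' Count sense codons in a coding sequence
#'
#' A single terminal stop codon is stripped silently; internal stops are an
#' error by default (`internal_stop = "truncate"` truncates there instead);
#' codons containing ambiguous bases are skipped with a message.
#'
#' @param cds a single CDS string (DNA or RNA alphabet).
#' @param gene_id label used in error messages.
#' @param internal_stop `"error"` (default) or `"truncate"`.
#' @return Named integer 61-vector of sense-codon counts, with attribute
#'   `L` = total sense codons.
#' @export
count_codons <- function(cds, gene_id = "<cds>", internal_stop = "error") {
  codons <- validate_cds(cds, gene_id, internal_stop)
  if (!length(codons)) stop("no sense codons in ", gene_id)
  counts <- table(factor(codons, levels = sense_codons()))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "L") <- sum(out)
  out
}

#' Codon count and frequency matrices for a set of coding sequences
#'
#' @param cds_set named character vector or `Biostrings::DNAStringSet` of
#'   coding sequences (names = gene ids).
#' @param internal_stop passed to [count_codons()].
#' @return List with `counts` (genes x 61 integer matrix), `freq` (rows sum
#'   to 1) and `L` (per-gene sense-codon totals).
#' @export
codon_frequency_matrix <- function(cds_set, internal_stop = "error") {
  if (inherits(cds_set, "XStringSet")) {
    ids <- names(cds_set)
    seqs <- as.character(cds_set)
  } else {
    ids <- names(cds_set)
    seqs <- as.character(cds_set)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("coding sequences must be named")
  if (anyDuplicated(ids)) stop("duplicated gene ids in CDS set")
  counts <- t(vapply(seq_along(seqs), function(i) {
    count_codons(seqs[i], gene_id = ids[i], internal_stop = internal_stop)
  }, integer(61)))
  rownames(counts) <- ids
  L <- rowSums(counts)
  list(counts = counts, freq = counts / L, L = L)
}

#' Length-normalized codon frequencies from a count vector
#'
#' @param counts named 61-vector of sense-codon counts.
#' @return Frequency vector summing to 1.
#' @export
normalized_frequencies <- function(counts) {
  L <- sum(counts)
  if (L < 1) stop("no sense codons (L = 0)")
  f <- counts / L
  attributes(f) <- list(names = names(counts))
  f
}

#' Amino-acid-normalized codon frequencies (59 dimensions)
#'
#' Within each multi-codon synonymous family, each codon's value is its
#' count divided by the family total, removing amino-acid-usage and
#' gene-length effects. The two single-codon families (ATG, TGG) are
#' dropped, giving 59 dimensions. Families with zero occurrences in a gene
#' receive 0 for all members by default (`unoccupied = "uniform"` assigns
#' 1/family-size instead).
#'
#' @param counts named 61-vector, or a genes x 61 count matrix.
#' @param unoccupied `"zero"` (default) or `"uniform"`.
#' @return 59-vector, or genes x 59 matrix with attribute
#'   `unoccupied_families` (per-gene count of absent families).
#' @export
aa_normalized_frequencies <- function(counts, unoccupied = c("zero", "uniform")) {
  unoccupied <- match.arg(unoccupied)
  tab <- codon_table()
  multi <- tab$codon[!tab$single_codon_family]
  fam <- tab$aa[!tab$single_codon_family]
  if (is.matrix(counts)) {
    m <- counts[, multi, drop = FALSE]
    fam_tot <- t(rowsum(t(m), fam))          # genes x families
    denom <- fam_tot[, fam, drop = FALSE]    # genes x 59
    out <- m / denom
    if (unoccupied == "zero") out[denom == 0] <- 0
    else out[denom == 0] <- rep(1 / table(fam)[fam], each = nrow(m))[denom == 0]
    attr(out, "unoccupied_families") <- rowSums(fam_tot == 0)
    return(out)
  }
  x <- counts[multi]
  fam_tot <- tapply(x, fam, sum)[fam]
  out <- ifelse(fam_tot > 0, x / fam_tot,
                if (unoccupied == "zero") 0 else 1 / as.integer(table(fam)[fam]))
  stats::setNames(as.numeric(out), multi)
}

#' Select genes by codon-set content
#'
#' Per-gene content is the summed length-normalized frequency over a codon
#' set. Either the top `top_fraction` of genes (ties broken by gene id,
#' deterministic) or all genes with content >= `min_percent`/100 (boundary
#' inclusive) are returned.
#'
#' @param freq genes x 61 frequency matrix.
#' @param codon_set character vector of sense codons.
#' @param top_fraction fraction in (0, 1]; `ceiling(fraction * n)` genes.
#' @param min_percent content threshold in percent (alternative to
#'   `top_fraction`).
#' @return data.frame `gene_id`, `content` (selected genes, ranked).
#' @export
rank_by_content <- function(freq, codon_set, top_fraction = NULL,
                            min_percent = NULL) {
  if (length(codon_set) == 0) stop("empty codon set")
  bad <- setdiff(codon_set, sense_codons())
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  content <- rowSums(freq[, codon_set, drop = FALSE])
  ord <- order(-content, rownames(freq))
  ranked <- data.frame(gene_id = rownames(freq)[ord],
                       content = unname(content[ord]),
                       stringsAsFactors = FALSE)
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0,1]")
    n <- ceiling(top_fraction * nrow(ranked))
    return(ranked[seq_len(n), , drop = FALSE])
  }
  if (!is.null(min_percent)) {
    if (min_percent < 0) stop("min_percent must be >= 0")
    return(ranked[ranked$content >= min_percent / 100, , drop = FALSE])
  }
  stop("supply top_fraction or min_percent")
}
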