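#' Geometric mean
#'
#' Computed as exp(mean(log(x))) for numerical safety; optional weights give
#' the weighted geometric mean (used for codon-count-weighted gene metrics).
#'
#' @param x positive numeric vector.
#' @param w optional nonnegative weights (same length as `x`).
#' @return The (weighted) geometric mean.
#' @export
geometric_mean <- function(x, w = NULL) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  if (is.null(w)) return(exp(mean(log(x))))
  if (length(w) != length(x)) stop("weights and values must align")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative with positive sum")
  exp(sum(w * log(x)) / sum(w))
}

# Dirichlet sampler via normalized gammas; no installed package exposes one.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV table with a feature-id first column into a matrix
#'
#' Lines starting with `#` are treated as comments.
#'
#' @param path TSV file; first column feature ids, remaining columns numeric.
#' @return Numeric matrix with feature rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a feature-id column plus >=1 value column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids in ", path)
  m
}

#' Write a matrix or data.frame as TSV with provenance comment lines
#'
#' @param x matrix (feature rownames) or data.frame.
#' @param path output file.
#' @param id_col name for the rowname column when `x` is a matrix.
#' @param meta named character vector written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_col = "feature_id", meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  }
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- id_col
  } else {
    df <- x
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
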