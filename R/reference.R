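# Mature-tRNA reference construction: parse gtRNAdb-style gene FASTAs,
# collapse identical mature sequences into isodecoder groups (appending the
# universal 3' CCA), and partition isodecoders into isoacceptor (anticodon)
# groups. Isoacceptor abundance is the decoding supply used by tAI and SDR.

TRNA_HEADER_RE <- "tRNA-([A-Za-z]{3,4})-([ACGTUNacgtun]{3})(-[0-9]+)?(-[0-9]+)?"

#' Parse a gtRNAdb-style tRNA gene FASTA
#'
#' Headers must contain a `tRNA-<AA>-<Anticodon>-<i>-<j>` token, e.g.
#' `tRNA-Ser-UGA-1-1`. Amino acid may be a three-letter code or `iMet`,
#' `SeC`, `Und` (pseudogene). Records whose header contains a mitochondrial
#' tag (`mt-tRNA`, `mito`, `MT-`) are flagged `origin = "mitochondrial"`.
#' Unparsable headers are dropped with a warning and reported in the
#' `"failures"` attribute.
#'
#' @param fasta_path path to the FASTA file.
#' @return data.frame with columns `gene_id`, `amino_acid`, `anticodon`
#'   (DNA alphabet), `mature_sequence` (DNA alphabet, no CCA assumed),
#'   `origin`; attribute `failures` holds offending headers.
#' @export
parse_trna_fasta <- function(fasta_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path)
  headers <- names(seqs)
  m <- regmatches(headers, regexec(TRNA_HEADER_RE, headers))
  ok <- lengths(m) > 0 & vapply(m, function(x) length(x) >= 3 && nzchar(x[2]), logical(1))
  failures <- headers[!ok]
  if (length(failures)) {
    warning(length(failures), " record(s) with unparsable tRNA header: ",
            paste(utils::head(failures, 5), collapse = "; "))
  }
  if (!any(ok)) stop("no parsable tRNA headers in ", fasta_path)
  m <- m[ok]
  headers <- headers[ok]
  seq_chr <- as_dna(as.character(seqs[ok]))
  bad_alpha <- grepl("[^ACGT]", seq_chr)
  if (any(bad_alpha)) {
    warning(sum(bad_alpha), " record(s) with non-ACGTU bases dropped")
    failures <- c(failures, headers[bad_alpha])
    m <- m[!bad_alpha]; headers <- headers[!bad_alpha]; seq_chr <- seq_chr[!bad_alpha]
  }
  if (!length(headers)) stop("no valid tRNA records in ", fasta_path)
  gene_id <- vapply(m, function(x) x[1], character(1))
  aa <- vapply(m, function(x) x[2], character(1))
  anticodon <- as_dna(vapply(m, function(x) x[3], character(1)))
  mito <- grepl("mt-tRNA|mito|\\bMT-", headers, ignore.case = TRUE)
  out <- data.frame(
    gene_id = gene_id,
    amino_acid = aa,
    anticodon = anticodon,
    mature_sequence = seq_chr,
    origin = ifelse(mito, "mitochondrial", "nuclear"),
    stringsAsFactors = FALSE
  )
  attr(out, "failures") <- failures
  out
}

#' Collapse identical mature tRNA sequences into isodecoder groups
#'
#' Genes with byte-identical mature sequences are merged; the collapsed
#' reference sequence is the mature sequence with `CCA` appended once.
#' Merged groups are renamed `tRNA-<AA>-<anticodon>-X` (with a trailing
#' ordinal, sorted by sequence, when several merged groups share one
#' anticodon family); single-member groups keep the gene id.
#'
#' @param genes data.frame as returned by [parse_trna_fasta()].
#' @return data.frame with columns `group_id`, `amino_acid`, `anticodon`,
#'   `origin`, `mature_sequence`, `reference_sequence` (ends in CCA),
#'   `copy_number`, `member_gene_ids` (comma-separated).
#' @export
build_isodecoder_reference <- function(genes) {
  if (!is.data.frame(genes) || nrow(genes) == 0) stop("empty gene list")
  key <- genes$mature_sequence
  groups <- split(seq_len(nrow(genes)), key)
  rows <- lapply(groups, function(idx) {
    g <- genes[idx, , drop = FALSE]
    if (length(unique(g$anticodon)) > 1 || length(unique(g$amino_acid)) > 1) {
      stop("genes with identical sequence but inconsistent annotation: ",
           paste(g$gene_id, collapse = ", "))
    }
    data.frame(
      group_id = if (nrow(g) == 1) g$gene_id[1] else NA_character_,
      amino_acid = g$amino_acid[1],
      anticodon = g$anticodon[1],
      origin = g$origin[1],
      mature_sequence = g$mature_sequence[1],
      copy_number = nrow(g),
      member_gene_ids = paste(sort(g$gene_id), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # name merged groups: family prefix + "-X" (+ ordinal on collision)
  merged <- which(is.na(out$group_id))
  if (length(merged)) {
    fam <- paste0("tRNA-", out$amino_acid[merged], "-", out$anticodon[merged])
    for (f in unique(fam)) {
      idx <- merged[fam == f]
      idx <- idx[order(out$mature_sequence[idx])]
      out$group_id[idx] <- if (length(idx) == 1) paste0(f, "-X")
                           else paste0(f, "-X", seq_along(idx))
    }
  }
  if (anyDuplicated(out$group_id)) {
    stop("isodecoder group ids collide: ",
         paste(out$group_id[duplicated(out$group_id)], collapse = ", "))
  }
  out$reference_sequence <- paste0(out$mature_sequence, "CCA")
  out <- out[order(out$group_id), c("group_id", "amino_acid", "anticodon",
                                    "origin", "mature_sequence",
                                    "reference_sequence", "copy_number",
                                    "member_gene_ids")]
  rownames(out) <- NULL
  out
}

#' Partition isodecoder groups into isoacceptor (anticodon) groups
#'
#' Cytosolic tRNAs for the standard amino acids (plus initiator Met as its
#' own group) are partitioned by (amino acid, anticodon). Selenocysteine
#' (`SeC`), pseudogene (`Und`) and mitochondrial records are excluded,
#' mirroring an analysis restricted to cytosolic decoding capacity.
#'
#' @param isodecoders data.frame from [build_isodecoder_reference()].
#' @return data.frame with columns `isoacceptor_id` (`<AA>-<anticodon>`),
#'   `amino_acid`, `anticodon`, `n_isodecoders`, `isodecoder_group_ids`
#'   (comma-separated), sorted by id.
#' @export
build_isoacceptor_map <- function(isodecoders) {
  keep <- isodecoders$origin == "nuclear" &
    !(isodecoders$amino_acid %in% c("SeC", "Und"))
  d <- isodecoders[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no cytosolic standard-amino-acid isodecoders")
  key <- paste0(d$amino_acid, "-", d$anticodon)
  groups <- split(seq_len(nrow(d)), key)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    idx <- groups[[k]]
    data.frame(
      isoacceptor_id = k,
      amino_acid = d$amino_acid[idx[1]],
      anticodon = d$anticodon[idx[1]],
      n_isodecoders = length(idx),
      isodecoder_group_ids = paste(sort(d$group_id[idx]), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$isoacceptor_id), ]
  rownames(out) <- NULL
  out
}

#' Write the collapsed isodecoder reference as FASTA and mapping TSV
#'
#' @param isodecoders data.frame from [build_isodecoder_reference()].
#' @param isoacceptors data.frame from [build_isoacceptor_map()].
#' @param fasta_path output FASTA of CCA-appended reference sequences.
#' @param map_path output TSV mapping isodecoder group to isoacceptor.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(isodecoders, isoacceptors, fasta_path, map_path) {
  seqs <- Biostrings::DNAStringSet(isodecoders$reference_sequence)
  names(seqs) <- isodecoders$group_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  iso_of <- stats::setNames(
    rep(isoacceptors$isoacceptor_id, isoacceptors$n_isodecoders),
    unlist(strsplit(isoacceptors$isodecoder_group_ids, ","))
  )
  map <- data.frame(
    group_id = isodecoders$group_id,
    amino_acid = isodecoders$amino_acid,
    anticodon = isodecoders$anticodon,
    origin = isodecoders$origin,
    copy_number = isodecoders$copy_number,
    isoacceptor_id = unname(iso_of[isodecoders$group_id]),
    member_gene_ids = isodecoders$member_gene_ids,
    stringsAsFactors = FALSE
  )
  write_feature_table(map, map_path)
  invisible(c(fasta = fasta_path, map = map_path))
}
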