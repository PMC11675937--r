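# Genetic-code lookup tables shared by every metric. All sequences are held
# internally in DNA alphabet (T, not U); user-facing input may use either.

AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' The 61 sense codons
#'
#' @return Character vector of the 61 sense codons (DNA alphabet, sorted).
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Stop codons
#' @return Character vector of the three stop codons.
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' Codon table with amino-acid families
#'
#' One row per sense codon with its one- and three-letter amino acid. The
#' amino acid defines the synonymous family used for tAI and CAI
#' normalization (all six Ser codons form one family).
#'
#' @return data.frame with columns `codon`, `aa`, `amino_acid`,
#'   `family_size`, `single_codon_family`.
#' @export
codon_table <- function() {
  codons <- sense_codons()
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  fam_size <- as.integer(table(aa)[aa])
  data.frame(
    codon = codons,
    aa = aa,
    amino_acid = unname(AA_THREE_LETTER[aa]),
    family_size = fam_size,
    single_codon_family = fam_size == 1L,
    stringsAsFactors = FALSE
  )
}

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' @param x character vector of sequences (may contain U/u).
#' @return Uppercase DNA-alphabet strings.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of short DNA strings
#'
#' @param x character vector (DNA or RNA alphabet; U treated as T).
#' @return Reverse complements in DNA alphabet.
#' @export
reverse_complement <- function(x) {
  x <- as_dna(x)
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Watson-Crick anticodon of a codon
#'
#' The anticodon read 5'->3' is the reverse complement of the codon.
#'
#' @param codon character vector of codons.
#' @return Anticodons (DNA alphabet).
#' @export
wc_anticodon <- function(codon) reverse_complement(codon)
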