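# Codon:anticodon pairing rules for the tRNA adaptation index. The wobble
# position is codon base 3 pairing anticodon base 1 (5'->3'); each pairing
# carries a selective penalty s in [0,1] (Watson-Crick pairs s = 0), so a
# cognate contributes (1 - s) * abundance to the codon's decoding weight.

#' Default wobble rule set (dos Reis 2004 s-values, eukaryote mode)
#'
#' Watson-Crick pairings have s = 0; wobble penalties are s(G:U) = 0.41,
#' s(I:C) = 0.28, s(I:A) = 0.9999, s(U:G) = 0.68, with a genomically encoded
#' anticodon A treated as inosine. The bacterial lysidine rule (ATA read by
#' a modified CAT anticodon, s = 0.89) is carried but disabled by default.
#'
#' @param lysidine logical; enable the bacterial lysidine rule for codon ATA.
#' @return Object of class `wobble_rules`: a data.frame with columns
#'   `codon_third`, `anticodon_first`, `pairing`, `s`, plus attributes.
#' @export
default_wobble_rules <- function(lysidine = FALSE) {
  rules <- data.frame(
    codon_third    = c("T", "T", "C", "C", "A", "A", "G", "G"),
    anticodon_first = c("A", "G", "G", "A", "T", "A", "C", "T"),
    pairing = c("WC A:U", "G:U", "WC G:C", "I:C", "WC U:A", "I:A",
                "WC C:G", "U:G"),
    s = c(0, 0.41, 0, 0.28, 0, 0.9999, 0, 0.68),
    stringsAsFactors = FALSE
  )
  wobble_rules(rules, lysidine = lysidine, lysidine_s = 0.89)
}

#' Construct and validate a wobble rule set
#'
#' @param rules data.frame with columns `codon_third`, `anticodon_first`,
#'   `pairing`, `s`.
#' @param lysidine logical, see [default_wobble_rules()].
#' @param lysidine_s penalty for the lysidine pairing.
#' @return Validated `wobble_rules` object.
#' @export
wobble_rules <- function(rules, lysidine = FALSE, lysidine_s = 0.89) {
  stopifnot(is.data.frame(rules),
            all(c("codon_third", "anticodon_first", "pairing", "s") %in% names(rules)))
  if (any(rules$s < 0 | rules$s > 1)) stop("wobble penalties s must lie in [0,1]")
  wc <- grepl("^WC", rules$pairing)
  if (any(rules$s[wc] != 0)) stop("Watson-Crick pairings must have s = 0")
  thirds <- c("T", "C", "A", "G")
  if (!all(thirds %in% rules$codon_third[wc])) {
    stop("every codon third base needs a Watson-Crick rule")
  }
  structure(rules, class = c("wobble_rules", "data.frame"),
            lysidine = lysidine, lysidine_s = lysidine_s)
}

#' Cognate tRNAs of a codon under a wobble rule set
#'
#' Returns the Watson-Crick anticodon (reverse complement of the codon) plus
#' all wobble-readable anticodons, each with its penalty s and measured
#' abundance (0 when the anticodon is absent from the supplied pool). Codon
#' ATG is restricted to its Watson-Crick anticodon CAT (elongator Met; a
#' generic U:G rule would let Ile tRNAs appear as Met cognates), and TGG to
#' CCA (excluding the selenocysteine anticodon TCA).
#'
#' @param codon a single sense codon (DNA or RNA alphabet).
#' @param isoacceptor_abundances named nonnegative numeric vector keyed by
#'   anticodon (DNA alphabet); typically one condition's isoacceptor means.
#' @param rules a `wobble_rules` object.
#' @return data.frame with columns `anticodon`, `pairing`, `s`, `abundance`.
#' @export
cognate_trnas <- function(codon, isoacceptor_abundances,
                          rules = default_wobble_rules()) {
  stopifnot(length(codon) == 1, inherits(rules, "wobble_rules"))
  codon <- as_dna(codon)
  if (!codon %in% sense_codons()) {
    stop("not a sense codon: ", codon,
         if (codon %in% stop_codons()) " (stop codon)" else "")
  }
  if (any(isoacceptor_abundances < 0)) stop("abundances must be nonnegative")
  third <- substr(codon, 3, 3)
  stem <- substr(reverse_complement(codon), 2, 3)
  r <- rules[rules$codon_third == third, , drop = FALSE]
  out <- data.frame(
    anticodon = paste0(r$anticodon_first, stem),
    pairing = r$pairing,
    s = r$s,
    stringsAsFactors = FALSE
  )
  if (codon %in% c("ATG", "TGG")) out <- out[grepl("^WC", out$pairing), , drop = FALSE]
  if (codon == "ATA" && isTRUE(attr(rules, "lysidine"))) {
    out <- rbind(out, data.frame(anticodon = "CAT", pairing = "lysidine C*:A",
                                 s = attr(rules, "lysidine_s")))
  }
  ab <- isoacceptor_abundances[out$anticodon]
  out$abundance <- ifelse(is.na(ab), 0, unname(ab))
  rownames(out) <- NULL
  out
}
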