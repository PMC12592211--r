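# Codon-level utilities shared by the simulator and the gametologue module.
# The standard genetic code; stop codons never appear inside simulated CDSs
# and mutations to stops are counted as nonsynonymous.

BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Translate an in-frame CDS to protein
#' @param cds In-frame nucleotide string (length a multiple of 3). A single
#'   trailing stop codon is trimmed.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) abort("CDS length must be a multiple of 3")
  gc <- genetic_code()
  cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- gc[cod]
  if (anyNA(aa)) abort("CDS contains an untranslatable codon")
  if (length(aa) > 1 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) abort("CDS contains an internal stop codon")
  paste(aa, collapse = "")
}

# Per-codon NG86 synonymous site count: at each position, the fraction of
# the three possible changes that preserve the amino acid (changes to stop
# codons count as nonsynonymous). Returns a named vector over sense codons.
ng86_site_table <- function() {
  gc <- genetic_code()
  sense <- sense_codons()
  s <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    chars <- strsplit(cod, "")[[1]]
    syn <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, chars[p])) {
        alt <- chars
        alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] == gc[[cod]]) syn <- syn + 1 / 3
      }
    }
    s[cod] <- syn
  }
  s
}

# Positions (within codon) where every substitution is synonymous,
# i.e. fourfold-degenerate sites. Returns list codon -> integer positions.
fourfold_positions <- function() {
  gc <- genetic_code()
  sense <- sense_codons()
  out <- setNames(vector("list", length(sense)), sense)
  for (cod in sense) {
    chars <- strsplit(cod, "")[[1]]
    pos <- integer(0)
    for (p in 1:3) {
      alts <- vapply(setdiff(BASES, chars[p]), function(b) {
        alt <- chars; alt[p] <- b
        gc[[paste(alt, collapse = "")]]
      }, character(1))
      if (all(alts == gc[[cod]])) pos <- c(pos, p)
    }
    out[[cod]] <- pos
  }
  out
}

# Cached lookups (computed once per session).
codon_env <- new.env(parent = emptyenv())

get_ng86_sites <- function() {
  if (is.null(codon_env$sites)) codon_env$sites <- ng86_site_table()
  codon_env$sites
}

get_fourfold <- function() {
  if (is.null(codon_env$ff)) codon_env$ff <- fourfold_positions()
  codon_env$ff
}

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}
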