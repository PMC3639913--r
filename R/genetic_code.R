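# Genetic-code constants used throughout the package. DNA alphabet is used
# internally; RNA input is mapped to DNA on read.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Standard genetic code tables
#'
#' `sense_codons()` returns the 61 sense codons (DNA alphabet, alphabetical
#' order); `codon_aa_map()` maps each sense codon to its one-letter amino
#' acid; `amino_acids()` returns the 20 amino acids in the fixed order used
#' for all frequency vectors.
#'
#' @return Character vectors; `codon_aa_map()` is named by codon.
#' @export
sense_codons <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  sort(names(code)[code != "*"])
}

#' @rdname sense_codons
#' @export
codon_aa_map <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code[sense_codons()]
}

#' @rdname sense_codons
#' @export
amino_acids <- function() {
  sort(unique(unname(codon_aa_map())))
}

# codons grouped by amino acid (list named by aa)
synonym_families <- function() {
  map <- codon_aa_map()
  split(names(map), unname(map))
}

# translate a QC-passed CDS (drops the terminal stop codon)
translate_cds <- function(cds) {
  cds <- normalize_nt(cds)
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L, n >= 6L)
  codons <- substring(cds, seq(1L, n - 3L, by = 3L), seq(3L, n - 3L, by = 3L))
  map <- codon_aa_map()
  if (any(!codons %in% names(map))) {
    stop("CDS contains an internal stop or invalid codon", call. = FALSE)
  }
  unname(map[codons])
}

# split a CDS into codons, optionally dropping the terminal stop
cds_codons <- function(cds, drop_stop = TRUE) {
  cds <- normalize_nt(cds)
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L, n >= 3L)
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  if (drop_stop && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  codons
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
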