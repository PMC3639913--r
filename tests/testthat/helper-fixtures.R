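# Shared fixtures, built in code once per test run.

fx <- generate_weight_fixtures(seed = 42)

# a random QC-valid CDS: ATG + interior sense codons (no internal stop) + stop
random_cds <- function(n_codons, seed = NULL) {
  draw <- function() {
    interior <- sample(setdiff(sense_codons(), "ATG"), n_codons - 2L,
                       replace = TRUE)
    paste0("ATG", paste(interior, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
  }
  if (!is.null(seed)) set.seed(seed)
  draw()
}

# uniform random nucleotide string
random_nt <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# a small transcript table for sequence_io tests
toy_transcripts <- function() {
  data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("g1", "g1", "g2", "g3"),
    cdna = c(strrep("A", 300), strrep("A", 900), strrep("C", 400), ""),
    cds = c("ATGAAATAA", "ATGCCCAAATAA", "ATGGGGTGA", "ATGTTTTAG"),
    utr5 = c("", "", "", ""),
    utr3 = c("", "", "", ""),
    stringsAsFactors = FALSE
  )
}
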