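# Per-gene codon- and amino-acid-level translational features.

# codon count matrix (genes x 61 sense codons), terminal stop excluded
codon_count_matrix <- function(cds) {
  set <- Biostrings::DNAStringSet(normalize_nt(cds))
  counts <- Biostrings::oligonucleotideFrequency(set, width = 3L, step = 3L)
  codons <- sense_codons()
  counts[, codons, drop = FALSE]
}

check_qc_cds <- function(cds) {
  n <- nchar(cds)
  ok <- n %% 3L == 0L & n >= 6L &
    substring(cds, 1L, 3L) == "ATG" &
    substring(cds, n - 2L, n) %in% STOP_CODONS &
    !grepl("N", cds, fixed = TRUE)
  if (!all(ok)) {
    stop("CDS does not satisfy the QC invariants (ATG start, stop end, ",
         "length divisible by 3, no N)", call. = FALSE)
  }
  invisible(TRUE)
}

#' tRNA adaptation index of a coding sequence
#'
#' Geometric mean of the tAI relative-adaptiveness weights over the gene's
#' sense codons; the terminal stop codon is excluded and the initiator ATG
#' is included by default.
#'
#' @param cds A QC-passed coding sequence (or character vector of them).
#' @param weights A `codon_weights` object with label `"tai"`.
#' @param include_start Include the initiator ATG codon (default `TRUE`).
#' @return Numeric vector of scores in (0, 1].
#' @examples
#' w <- codon_weights(setNames(rep(1, 61), sense_codons()), "tai")
#' gene_tai("ATGAAATAA", w)  # every codon weight 1 -> tAI = 1
#' @export
gene_tai <- function(cds, weights, include_start = TRUE) {
  stopifnot(inherits(weights, "codon_weights"))
  if (attr(weights, "label") != "tai") {
    stop("gene_tai() needs weights with label 'tai'", call. = FALSE)
  }
  cds <- normalize_nt(cds)
  check_qc_cds(cds)
  counts <- codon_count_matrix(cds)
  if (!include_start) counts[, "ATG"] <- pmax(counts[, "ATG"] - 1L, 0L)
  total <- rowSums(counts)
  if (any(total == 0)) stop("no usable codons in CDS", call. = FALSE)
  as.numeric(exp((counts %*% log(as.numeric(weights))) / total))
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of CAI relative-adaptiveness weights over the gene's
#' sense codons. Following the standard CAI convention, codons of the
#' single-codon amino acids Met (ATG) and Trp (TGG) are excluded from the
#' mean, as is the terminal stop codon.
#'
#' @inheritParams gene_tai
#' @param weights A `codon_weights` object with label `"cai"`, e.g. from
#'   [cai_weights_from_usage()].
#' @return Numeric vector of scores in (0, 1].
#' @export
gene_cai <- function(cds, weights) {
  stopifnot(inherits(weights, "codon_weights"))
  if (attr(weights, "label") != "cai") {
    stop("gene_cai() needs weights with label 'cai'", call. = FALSE)
  }
  cds <- normalize_nt(cds)
  check_qc_cds(cds)
  counts <- codon_count_matrix(cds)
  counts[, c("ATG", "TGG")] <- 0L
  total <- rowSums(counts)
  if (any(total == 0)) stop("no usable codons in CDS", call. = FALSE)
  as.numeric(exp((counts %*% log(as.numeric(weights))) / total))
}

#' GC and GC3 content of a coding sequence
#'
#' `gc_frac` is the G+C fraction over the whole CDS; `gc3_frac` is the G+C
#' fraction at third codon positions of sense codons (the terminal stop is
#' excluded).
#'
#' @inheritParams gene_tai
#' @return Data frame with columns `gc_frac` and `gc3_frac`.
#' @export
gc_metrics <- function(cds) {
  cds <- normalize_nt(cds)
  check_qc_cds(cds)
  set <- Biostrings::DNAStringSet(cds)
  gc <- Biostrings::letterFrequency(set, "GC") / nchar(cds)
  counts <- codon_count_matrix(cds)
  third <- substring(colnames(counts), 3L, 3L)
  gc3 <- rowSums(counts[, third %in% c("G", "C"), drop = FALSE]) /
    rowSums(counts)
  data.frame(gc_frac = as.numeric(gc), gc3_frac = as.numeric(gc3))
}

#' Amino-acid frequencies of the encoded protein
#'
#' Fractions over the translated protein, excluding the stop; each row sums
#' to 1.
#'
#' @inheritParams gene_tai
#' @return Matrix (genes x 20) with amino acids in [amino_acids()] order.
#' @export
aa_frequencies <- function(cds) {
  cds <- normalize_nt(cds)
  check_qc_cds(cds)
  counts <- aa_count_matrix(cds)
  counts / rowSums(counts)
}

# raw amino-acid counts (genes x 20), stop excluded
aa_count_matrix <- function(cds) {
  counts <- codon_count_matrix(cds)
  map <- codon_aa_map()
  aas <- amino_acids()
  ind <- outer(map[colnames(counts)], aas, "==") * 1
  out <- counts %*% ind
  colnames(out) <- aas
  out
}

#' Expression-weighted amino-acid usage of a gene cohort
#'
#' Cohort-level amino-acid usage in which each gene's amino-acid counts are
#' weighted by its mRNA level:
#' `F_a = sum_g n_ag * E_g / sum_g L_g * E_g`,
#' with `n_ag` the count of amino acid `a` in gene `g`, `L_g` the protein
#' length and `E_g` the gene's mRNA level. Reduces to [aa_frequencies()]
#' for a single-gene cohort and is invariant to rescaling all `E_g`.
#'
#' @param cds Character vector of QC-passed coding sequences.
#' @param expression Positive mRNA levels, one per gene.
#' @return Named 20-vector of fractions summing to 1.
#' @export
expression_weighted_aa_usage <- function(cds, expression) {
  if (length(cds) == 0L) stop("empty cohort", call. = FALSE)
  if (length(expression) != length(cds)) {
    stop("expression must have one value per gene", call. = FALSE)
  }
  if (any(!is.finite(expression)) || any(expression <= 0)) {
    stop("expression values must be positive", call. = FALSE)
  }
  counts <- aa_count_matrix(normalize_nt(cds))
  num <- colSums(counts * expression)
  num / sum(rowSums(counts) * expression)
}

#' Assemble the regression covariates for a set of genes
#'
#' Computes, per gene: natural-log sequence lengths, tAI, CAI, GC/GC3,
#' folding energies of the requested 50-nt windows, the 20 amino-acid
#' frequencies (columns `aa_A` ... `aa_Y`), and the composite ratio
#' `tai / log(cds_len)`. Zero-length UTRs yield `NA` log-lengths and
#' windows that cannot be extracted yield `NA` energies; downstream
#' analyses use listwise deletion.
#'
#' @param genes Data frame of QC-passed gene records
#'   (from [qc_filter()]`$genes`).
#' @param tai_weights,cai_weights `codon_weights` objects (either may be
#'   `NULL` to skip that column).
#' @param windows Character vector of window names (see [window_specs()]);
#'   default the 5'UTR end window used as the regression dG covariate.
#' @param seed Seed for the random cDNA window, when requested.
#' @param engine Folding engine passed to [mfe_energy()].
#' @return Data frame with one row per gene.
#' @export
gene_features <- function(genes, tai_weights = NULL, cai_weights = NULL,
                          windows = "utr5_minus52_minus2", seed = 1L,
                          engine = "builtin") {
  stopifnot(is.data.frame(genes), nrow(genes) > 0L)
  cds <- normalize_nt(genes$cds)
  check_qc_cds(cds)
  log_or_na <- function(n) ifelse(n > 0, log(n), NA_real_)
  out <- data.frame(
    gene_id = genes$gene_id,
    log_cds_len = log(nchar(cds)),
    log_utr5_len = log_or_na(nchar(genes$utr5)),
    log_utr3_len = log_or_na(nchar(genes$utr3)),
    stringsAsFactors = FALSE
  )
  if (!is.null(tai_weights)) out$tai <- gene_tai(cds, tai_weights)
  if (!is.null(cai_weights)) out$cai <- gene_cai(cds, cai_weights)
  out <- cbind(out, gc_metrics(cds))
  if (length(windows)) {
    folded <- fold_windows(genes, windows = windows, seed = seed,
                           engine = engine)
    for (wname in windows) {
      sub <- folded[folded$window == wname, c("gene_id", "dg")]
      out[[paste0("dg_", wname)]] <- sub$dg[match(out$gene_id, sub$gene_id)]
    }
  }
  aafq <- aa_frequencies(cds)
  colnames(aafq) <- paste0("aa_", colnames(aafq))
  out <- cbind(out, as.data.frame(aafq))
  if (!is.null(tai_weights)) {
    out$tai_over_logLcds <- out$tai / out$log_cds_len
  }
  rownames(out) <- NULL
  out
}
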