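# Per-codon relative-adaptiveness weight tables (tAI and CAI flavours).

#' Construct a codon weight table
#'
#' A `codon_weights` object maps the 61 sense codons to relative
#' adaptiveness values in (0, 1], max-normalized so the best codon has
#' weight 1. Zero weights are replaced by the geometric mean of the
#' non-zero weights (the usual convention when a codon has no decoding
#' tRNA in the table), so downstream geometric means stay finite.
#'
#' @param weights Named numeric vector covering all 61 sense codons
#'   (names are DNA codons); values must be non-negative with at least one
#'   positive value.
#' @param label Either `"tai"` or `"cai"`.
#' @return A `codon_weights` object (named numeric vector with attributes).
#' @export
codon_weights <- function(weights, label = c("tai", "cai")) {
  label <- match.arg(label)
  codons <- sense_codons()
  if (!all(codons %in% names(weights))) {
    missing <- setdiff(codons, names(weights))
    stop("weight table is missing codons: ", paste(head(missing), collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(weights[codons])
  names(w) <- codons
  if (any(is.na(w)) || any(w < 0)) {
    stop("codon weights must be non-negative and non-missing", call. = FALSE)
  }
  if (max(w) <= 0) stop("all codon weights are zero", call. = FALSE)
  w <- w / max(w)
  if (any(w == 0)) {
    gm <- exp(mean(log(w[w > 0])))
    w[w == 0] <- gm
  }
  structure(w, label = label, class = "codon_weights")
}

#' @export
print.codon_weights <- function(x, ...) {
  cat(sprintf("codon_weights (%s): %d sense codons, range [%.4g, 1]\n",
              attr(x, "label"), length(x), min(x)))
  invisible(x)
}

#' Third-position codon:anticodon pairing rules with wobble penalties
#'
#' Returns the default pairing table used by [build_tai_weights()]. Each row
#' gives a codon third base, an anticodon first base (both DNA alphabet;
#' an `A` at the anticodon wobble position is treated as inosine), and a
#' selective penalty `s` in the unit interval. Watson-Crick pairs carry `s = 0`;
#' wobble pairs carry the standard penalties of the tAI construction
#' (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68).
#'
#' @return Data frame with columns `codon3`, `anticodon1`, `s`.
#' @export
wobble_rules <- function() {
  data.frame(
    codon3     = c("T", "C", "A", "G", "T", "C", "A", "G"),
    anticodon1 = c("A", "G", "T", "C", "G", "A", "A", "T"),
    s          = c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68),
    stringsAsFactors = FALSE
  )
}

#' Build tAI codon weights from tRNA gene copy numbers
#'
#' Absolute adaptiveness of codon i is `W_i = sum_j (1 - s_ij) * tGCN_j`
#' over the tRNAs j whose anticodon can decode codon i: the anticodon's
#' positions 2-3 must be the Watson-Crick complement of the codon's
#' positions 2 and 1, and the third-position pairing must appear in the
#' wobble table. Relative weights are `w_i = W_i / max(W)`; codons with
#' `w = 0` receive the geometric mean of the non-zero weights.
#'
#' @param trna Data frame with columns `anticodon` (DNA, 5'->3') and
#'   `copies` (non-negative gene copy numbers).
#' @param wobble Pairing table as from [wobble_rules()].
#' @return A `codon_weights` object with label `"tai"`.
#' @export
build_tai_weights <- function(trna, wobble = wobble_rules()) {
  stopifnot(is.data.frame(trna), all(c("anticodon", "copies") %in% names(trna)))
  trna$anticodon <- normalize_nt(trna$anticodon)
  if (any(trna$copies < 0)) stop("tRNA copy numbers must be >= 0", call. = FALSE)
  if (sum(trna$copies) <= 0) stop("all tRNA copy numbers are zero", call. = FALSE)
  codons <- sense_codons()
  W <- setNames(numeric(length(codons)), codons)
  for (k in seq_len(nrow(trna))) {
    anti <- trna$anticodon[k]
    copies <- trna$copies[k]
    if (copies == 0 || nchar(anti) != 3L) next
    # codon positions 1-2 are fixed by anticodon positions 3-2 (WC)
    stem <- revcomp(anti)            # full WC codon for this anticodon
    prefix <- substring(stem, 1L, 2L)
    a1 <- substring(anti, 1L, 1L)
    hits <- wobble[wobble$anticodon1 == a1, , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      codon <- paste0(prefix, hits$codon3[r])
      if (codon %in% codons) {
        W[codon] <- W[codon] + (1 - hits$s[r]) * copies
      }
    }
  }
  codon_weights(W, label = "tai")
}

#' CAI relative adaptiveness from a reference codon-usage table
#'
#' Implements the classic relative-adaptiveness construction: within each
#' synonymous family, `w_i = f_i / max(f)` where `f` are codon frequencies
#' in a reference set of highly expressed genes.
#'
#' @param usage Named numeric vector of codon frequencies or counts for the
#'   61 sense codons.
#' @return A `codon_weights` object with label `"cai"`.
#' @export
cai_weights_from_usage <- function(usage) {
  codons <- sense_codons()
  if (!all(codons %in% names(usage))) {
    stop("usage table must cover all 61 sense codons", call. = FALSE)
  }
  f <- as.numeric(usage[codons])
  names(f) <- codons
  fam <- synonym_families()
  w <- f
  for (codset in fam) {
    m <- max(f[codset])
    w[codset] <- if (m > 0) f[codset] / m else 0
  }
  codon_weights(w, label = "cai")
}

#' Read and write codon weight / tRNA copy-number TSV tables
#'
#' `read_codon_weights()` expects columns `codon` and `w` (61 rows);
#' `read_trna_table()` expects columns `anticodon` and `copies`;
#' `read_aa_scores()` expects columns `aa` and `size_complexity` (20 rows).
#'
#' @param path File path.
#' @param label Weight flavour for `read_codon_weights()`.
#' @return `read_codon_weights()`: a `codon_weights` object; the others:
#'   data frames.
#' @export
read_codon_weights <- function(path, label = c("tai", "cai")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "w") %in% names(tab)))
  codon_weights(setNames(tab$w, normalize_nt(tab$codon)), match.arg(label))
}

#' @rdname read_codon_weights
#' @param weights A `codon_weights` object.
#' @export
write_codon_weights <- function(weights, path) {
  write.table(data.frame(codon = names(weights), w = as.numeric(weights)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_codon_weights
#' @export
read_trna_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("anticodon", "copies") %in% names(tab)))
  tab$anticodon <- normalize_nt(tab$anticodon)
  tab
}

#' @rdname read_codon_weights
#' @export
read_aa_scores <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "size_complexity") %in% names(tab)))
  tab
}

# per-amino-acid isoacceptor copy totals from an anticodon-level table
isoacceptor_by_aa <- function(trna) {
  map <- codon_aa_map()
  wc_codon <- revcomp(trna$anticodon)
  aa <- map[wc_codon]
  keep <- !is.na(aa)
  sums <- tapply(trna$copies[keep], aa[keep], sum)
  out <- setNames(numeric(length(amino_acids())), amino_acids())
  out[names(sums)] <- sums
  out
}
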