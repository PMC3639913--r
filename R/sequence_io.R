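# Reading per-gene sequence sets and applying coding-sequence quality control.

#' Read per-gene transcript sequences from FASTA files
#'
#' Reads one FASTA file per sequence region (cDNA, CDS, 5'UTR, 3'UTR) and
#' assembles one row per transcript. Headers must parse into a gene id and a
#' transcript id; the default convention is `>gene_id|transcript_id`.
#' Sequences are uppercased and RNA `U` is mapped to `T` on read.
#'
#' @param cdna,cds,utr5,utr3 Paths to FASTA files. `cds` is required; the
#'   others are optional (missing regions become empty strings).
#' @param header_split Regular expression splitting the FASTA header into
#'   `gene_id` and `transcript_id` (first two fields). Default `"\\|"`.
#' @return A data frame with columns `transcript_id`, `gene_id`, `cdna`,
#'   `cds`, `utr5`, `utr3`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1|t1", "ATGAAATAA", ">g2|t1", "ATGCCCTGA"), fa)
#' read_gene_sequences(cds = fa)
#' @export
read_gene_sequences <- function(cds, cdna = NULL, utr5 = NULL, utr3 = NULL,
                                header_split = "\\|") {
  read_one <- function(path) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) {
      warning("empty FASTA file: ", path, call. = FALSE)
      return(data.frame(gene_id = character(), transcript_id = character(),
                        seq = character(), stringsAsFactors = FALSE))
    }
    headers <- sub("\\s.*$", "", names(set))
    parts <- strsplit(headers, header_split)
    bad <- vapply(parts, function(p) length(p) < 2L || any(!nzchar(p[1:2])),
                  logical(1))
    if (any(bad)) {
      stop("unparseable FASTA header: '", headers[which(bad)[1]], "' in ",
           path, call. = FALSE)
    }
    data.frame(
      gene_id = vapply(parts, `[[`, character(1), 1L),
      transcript_id = vapply(parts, `[[`, character(1), 2L),
      seq = normalize_nt(as.character(set)),
      stringsAsFactors = FALSE
    )
  }

  cds_tab <- read_one(cds)
  if (is.null(cds_tab)) stop("a CDS FASTA is required", call. = FALSE)
  if (anyDuplicated(cds_tab$transcript_id)) {
    dup <- cds_tab$transcript_id[duplicated(cds_tab$transcript_id)][1]
    stop("duplicate transcript_id in CDS FASTA: ", dup, call. = FALSE)
  }
  blank <- rep("", nrow(cds_tab))
  out <- data.frame(
    transcript_id = cds_tab$transcript_id,
    gene_id = cds_tab$gene_id,
    cdna = blank, cds = cds_tab$seq, utr5 = blank, utr3 = blank,
    stringsAsFactors = FALSE
  )
  for (region in c("cdna", "utr5", "utr3")) {
    tab <- read_one(switch(region, cdna = cdna, utr5 = utr5, utr3 = utr3))
    if (is.null(tab)) next
    if (anyDuplicated(tab$transcript_id)) {
      dup <- tab$transcript_id[duplicated(tab$transcript_id)][1]
      stop("duplicate transcript_id in ", region, " FASTA: ", dup,
           call. = FALSE)
    }
    idx <- match(out$transcript_id, tab$transcript_id)
    out[[region]] <- ifelse(is.na(idx), "", tab$seq[idx])
  }
  # default cDNA: concatenation of the annotated regions when no cDNA file
  if (is.null(cdna)) {
    out$cdna <- paste0(out$utr5, out$cds, out$utr3)
  }
  rownames(out) <- NULL
  out
}

#' Collapse alternative transcripts to one representative per gene
#'
#' Keeps, for each gene, the transcript with the longest sequence (cDNA by
#' default). Length ties are broken by the lexicographically smallest
#' transcript id, so the result does not depend on input order.
#'
#' @param transcripts Data frame as returned by [read_gene_sequences()].
#' @param by Region whose length defines "longest": `"cdna"` (default) or
#'   `"cds"`.
#' @return A data frame with one row per `gene_id`.
#' @export
select_longest_isoform <- function(transcripts, by = c("cdna", "cds")) {
  by <- match.arg(by)
  if (nrow(transcripts) == 0L) stop("no transcripts supplied", call. = FALSE)
  len <- nchar(transcripts[[by]])
  ord <- order(transcripts$gene_id, -len, transcripts$transcript_id)
  sorted <- transcripts[ord, , drop = FALSE]
  keep <- !duplicated(sorted$gene_id)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

qc_rules <- c(
  n_content = "sequence contains N",
  start_codon = "CDS does not start with ATG",
  stop_codon = "CDS does not end with a stop codon",
  length_multiple_of_3 = "CDS length not divisible by 3"
)

#' Coding-sequence quality filter
#'
#' Applies the coding-sequence quality rules: no `N` in any retained
#' sequence, CDS starts with `ATG`, CDS ends with a stop codon
#' (`TAA`/`TAG`/`TGA`), and CDS length divisible by 3. Records lacking a CDS
#' (non-coding) are dropped up front. Each removal is attributed to the
#' first failing rule in the fixed order N-content, start, stop,
#' divisibility.
#'
#' @param transcripts Data frame with one row per gene (after
#'   [select_longest_isoform()]) and columns `gene_id`, `cdna`, `cds`,
#'   `utr5`, `utr3`.
#' @return A list with `genes` (retained records, plus `cds_len`,
#'   `utr5_len`, `utr3_len`, `gene_len` columns) and `report` (a `qc_report`
#'   object: per-rule removal counts).
#' @export
qc_filter <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  n_input <- nrow(transcripts)
  coding <- nzchar(transcripts$cds %||% character(0))
  x <- transcripts[coding, , drop = FALSE]
  removed <- c(non_coding = sum(!coding),
               setNames(integer(length(qc_rules)), names(qc_rules)))

  if (nrow(x) > 0L) {
    seq_all <- paste0(x$cdna, x$cds, x$utr5, x$utr3)
    fail <- cbind(
      n_content = grepl("N", seq_all, fixed = TRUE),
      start_codon = substring(x$cds, 1L, 3L) != "ATG",
      stop_codon = {
        n <- nchar(x$cds)
        tail3 <- substring(x$cds, pmax(n - 2L, 1L), n)
        !(tail3 %in% STOP_CODONS) | n < 3L
      },
      length_multiple_of_3 = nchar(x$cds) %% 3L != 0L
    )
    first_fail <- apply(fail, 1L, function(f) {
      w <- which(f)
      if (length(w)) w[1] else 0L
    })
    for (i in seq_along(qc_rules)) {
      removed[names(qc_rules)[i]] <- sum(first_fail == i)
    }
    x <- x[first_fail == 0L, , drop = FALSE]
  }

  x$cds_len <- nchar(x$cds)
  x$utr5_len <- nchar(x$utr5)
  x$utr3_len <- nchar(x$utr3)
  x$gene_len <- nchar(x$cdna)
  rownames(x) <- NULL

  report <- structure(
    list(n_input = n_input,
         n_removed_by_rule = removed,
         n_retained = nrow(x)),
    class = "qc_report"
  )
  stopifnot(report$n_input == report$n_retained + sum(removed))
  list(genes = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Sequence QC report\n")
  cat("  input records:   ", x$n_input, "\n")
  for (rule in names(x$n_removed_by_rule)) {
    cat(sprintf("  removed (%s): %d\n", rule, x$n_removed_by_rule[[rule]]))
  }
  cat("  retained:        ", x$n_retained, "\n")
  invisible(x)
}

#' Write a QC report as a two-column TSV (rule, count)
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    rule = c("input", names(report$n_removed_by_rule), "retained"),
    count = c(report$n_input, unname(report$n_removed_by_rule),
              report$n_retained)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene records to a multi-record FASTA file
#'
#' Headers follow the `>gene_id|transcript_id` convention understood by
#' [read_gene_sequences()]. A `transcript_id` column is used when present,
#' otherwise `<gene_id>.1`.
#'
#' @param genes Data frame with `gene_id` and the requested sequence column.
#' @param path Output path.
#' @param region Which sequence column to write.
#' @export
write_gene_fasta <- function(genes, path,
                             region = c("cds", "cdna", "utr5", "utr3")) {
  region <- match.arg(region)
  tx <- genes$transcript_id %||% paste0(genes$gene_id, ".1")
  keep <- nzchar(genes[[region]])
  set <- Biostrings::DNAStringSet(genes[[region]][keep])
  names(set) <- paste0(genes$gene_id, "|", tx)[keep]
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
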