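# Fixed 50-nt window extraction and minimum-free-energy folding.

WINDOW_NAMES <- c("cdna_first50", "utr5_minus52_minus2", "cds_first50",
                  "cds_last50", "cdna_last50", "cdna_random50")
WINDOW_LEN <- 50L

# allowed base pairs, in the order used by the C++ energy matrix
pair_levels <- function() c("AU", "UA", "GC", "CG", "GU", "UG")

#' The six 50-nt folding windows
#'
#' Returns the closed set of window names: the first 50 bases of the cDNA,
#' the 50 bases of the 5'UTR ending two bases upstream of the CDS start
#' (positions -51..-2), the first and last 50 bases of the CDS, the last
#' 50 bases of the cDNA, and a random 50-base cDNA window.
#'
#' @return Character vector of window names.
#' @export
window_specs <- function() WINDOW_NAMES

#' Extract one 50-nt folding window from a gene record
#'
#' Windows are extracted from the gene's cDNA, CDS or 5'UTR. A region
#' shorter than the window requires yields a missing result (with a reason)
#' rather than an error. The 5'UTR window takes the 50 nt ending at
#' position -2 relative to the CDS start, i.e. positions -51..-2: the
#' region nominally spans 51 positions, so the base adjacent to the start
#' codon is dropped to keep all windows at 50 nt. The random cDNA window
#' start is drawn uniformly over valid offsets using `seed`.
#'
#' @param gene A one-row data frame (or list) with `cdna`, `cds`, `utr5`.
#' @param window One of [window_specs()].
#' @param seed Seed for `cdna_random50`.
#' @return A list with `sequence` (50-nt string or `NA`) and
#'   `missing_reason` (`NA` or a string).
#' @export
extract_window <- function(gene, window, seed = 1L) {
  window <- match.arg(window, WINDOW_NAMES)
  miss <- function(reason) list(sequence = NA_character_,
                                missing_reason = reason)
  ok <- function(s) list(sequence = s, missing_reason = NA_character_)
  w <- WINDOW_LEN
  cdna <- normalize_nt(gene$cdna %||% "")
  cds <- normalize_nt(gene$cds %||% "")
  utr5 <- normalize_nt(gene$utr5 %||% "")
  switch(window,
    cdna_first50 = if (nchar(cdna) < w) miss("cdna shorter than 50 nt")
                   else ok(substring(cdna, 1L, w)),
    cdna_last50 = if (nchar(cdna) < w) miss("cdna shorter than 50 nt")
                  else ok(substring(cdna, nchar(cdna) - w + 1L, nchar(cdna))),
    cds_first50 = if (nchar(cds) < w) miss("cds shorter than 50 nt")
                  else ok(substring(cds, 1L, w)),
    cds_last50 = if (nchar(cds) < w) miss("cds shorter than 50 nt")
                 else ok(substring(cds, nchar(cds) - w + 1L, nchar(cds))),
    utr5_minus52_minus2 = {
      L <- nchar(utr5)
      if (L < w + 1L) miss("utr5 shorter than 51 nt")
      else ok(substring(utr5, L - w, L - 1L))
    },
    cdna_random50 = {
      L <- nchar(cdna)
      if (L < w) miss("cdna shorter than 50 nt")
      else {
        start <- with_seed(seed, sample.int(L - w + 1L, 1L))
        ok(substring(cdna, start, start + w - 1L))
      }
    }
  )
}

#' Stacked-pair energy table of the built-in folder
#'
#' A 6x6 matrix of stacking free energies (kcal/mol, all negative) indexed
#' by outer and inner base pair (`AU`, `UA`, `GC`, `CG`, `GU`, `UG`). The
#' default values are a simplified nearest-neighbour-like set shipped with
#' the package (`inst/extdata/stack_energies.tsv`); any table of the same
#' shape can be supplied to [mfe_energy()].
#'
#' @param path Optional TSV with columns `pair_step` (e.g. `"GC/CG"`,
#'   outer/inner) and `energy`.
#' @return Numeric 6x6 matrix with dimnames `AU`, `UA`, `GC`, `CG`, `GU`, `UG`.
#' @export
stack_energies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stack_energies.tsv", package = "transig",
                        mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_step", "energy") %in% names(tab)))
  lev <- pair_levels()
  m <- matrix(NA_real_, 6, 6, dimnames = list(outer = lev, inner = lev))
  parts <- strsplit(tab$pair_step, "/", fixed = TRUE)
  for (i in seq_along(parts)) {
    m[parts[[i]][1], parts[[i]][2]] <- tab$energy[i]
  }
  if (anyNA(m)) stop("stack energy table does not cover all 36 pair steps",
                     call. = FALSE)
  if (any(m > 0)) stop("stack energies must be <= 0", call. = FALSE)
  m
}

#' Minimum free energy of an RNA sequence
#'
#' The built-in engine performs dynamic-programming maximum-stability
#' folding over nested structures with Watson-Crick and GU pairs, a minimum
#' hairpin loop of 3 unpaired bases, and additive stacked-pair energies
#' from [stack_energies()]; unstacked pairs and loops carry no energy, so
#' the result is always <= 0 and the model is deliberately simpler than a
#' full nearest-neighbour model with loop entropies. An external engine can
#' be plugged in as `"exec:/path/to/prog"`: the program is called with the
#' sequence as its single argument and must print a single number (the MFE
#' in kcal/mol) to stdout.
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`U`/`T` (either case).
#' @param engine `"builtin"` (default) or `"exec:<path>"`.
#' @param energies Stacked-pair energy matrix (built-in engine only).
#' @param min_hairpin Minimum unpaired bases in a hairpin loop (default 3).
#' @return The MFE in kcal/mol (<= 0).
#' @examples
#' mfe_energy("AAAAAAAAAA")  # no pairable structure -> 0
#' @export
mfe_energy <- function(seq, engine = "builtin", energies = stack_energies(),
                       min_hairpin = 3L) {
  stopifnot_scalar_string(seq, "seq")
  s <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", s)) {
    stop("invalid characters in sequence: only A, C, G, U/T allowed",
         call. = FALSE)
  }
  if (identical(engine, "builtin")) {
    return(.fold_mfe_cpp(s, energies, as.integer(min_hairpin)))
  }
  if (startsWith(engine, "exec:")) {
    prog <- substring(engine, 6L)
    if (!nzchar(Sys.which(prog)) && !file.exists(prog)) {
      stop("external folding engine not found: ", prog, call. = FALSE)
    }
    out <- system2(prog, args = shQuote(s), stdout = TRUE)
    dg <- suppressWarnings(as.numeric(out[length(out)]))
    if (is.na(dg)) stop("external engine did not return a number", call. = FALSE)
    return(min(dg, 0))
  }
  stop("unknown engine: ", engine, call. = FALSE)
}

#' Fold selected windows for a set of genes
#'
#' Extracts each requested window for each gene and computes its MFE.
#' Missing windows (region too short) are reported with a reason and an
#' `NA` energy rather than dropped silently.
#'
#' @param genes Data frame of gene records with `gene_id`, `cdna`, `cds`,
#'   `utr5` columns.
#' @param windows Window names, see [window_specs()].
#' @param seed Base seed for random windows; gene `i` uses `seed + i - 1`
#'   so results are order-stable.
#' @param engine,energies Passed to [mfe_energy()].
#' @return Data frame: `gene_id`, `window`, `sequence`, `dg`, `engine`,
#'   `missing_reason`.
#' @export
fold_windows <- function(genes, windows = window_specs(), seed = 1L,
                         engine = "builtin", energies = stack_energies()) {
  windows <- match.arg(windows, WINDOW_NAMES, several.ok = TRUE)
  rows <- vector("list", nrow(genes) * length(windows))
  r <- 0L
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    for (wname in windows) {
      win <- extract_window(gene, wname, seed = seed + i - 1L)
      dg <- if (is.na(win$sequence)) NA_real_ else {
        mfe_energy(win$sequence, engine = engine, energies = energies)
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        gene_id = gene$gene_id, window = wname, sequence = win$sequence,
        dg = dg, engine = engine, missing_reason = win$missing_reason,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
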