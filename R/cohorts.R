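# Assembling the four gene groups from expression metadata.

#' Read expression and category TSV tables
#'
#' `read_expression_table()` expects columns `gene_id`, `mean_expr`,
#' `sd_expr`, `n_tissues`, `source`; `read_category_table()` expects
#' `gene_id`, `category`.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_expression_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "mean_expr", "sd_expr", "n_tissues", "source")
  if (!all(req %in% names(tab))) {
    stop("expression table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname read_expression_table
#' @export
read_category_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(tab))) {
    stop("category table must have columns gene_id, category", call. = FALSE)
  }
  tab
}

#' Assign genes to the four expression-defined groups
#'
#' Group 1 is the whole stable-expression set. Group 2 is the subset of
#' Group 1 expressed in at least 2 tissues with coefficient of variation
#' (sd/mean) strictly below 0.4; Group 3 tightens this to at least 3
#' tissues. Group 4 is the independent comparison set minus any gene
#' already in Group 1, so Groups 3 in 2 in 1 are nested and Group 4 is
#' disjoint from Group 1 by construction.
#'
#' @param records Data frame with columns `gene_id`, `mean_expr` (> 0),
#'   `sd_expr` (>= 0), `n_tissues` (integer >= 1) and `source`
#'   (`"stable_set"` or `"vogel_set"`); unique by (`gene_id`, `source`).
#' @param cv_threshold Strict upper bound on sd/mean (default 0.4).
#' @return Data frame `gene_id`, logical columns `group1`..`group4`, and
#'   `cv`.
#' @examples
#' rec <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   mean_expr = c(10, 10, 5), sd_expr = c(3, 5, 1),
#'                   n_tissues = c(3, 2, 4),
#'                   source = c("stable_set", "stable_set", "vogel_set"))
#' assign_groups(rec)
#' @export
assign_groups <- function(records, cv_threshold = 0.4) {
  req <- c("gene_id", "mean_expr", "sd_expr", "n_tissues", "source")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  if (!all(records$source %in% c("stable_set", "vogel_set"))) {
    stop("source must be 'stable_set' or 'vogel_set'", call. = FALSE)
  }
  key <- paste(records$gene_id, records$source, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (gene_id, source) record: ", dup$gene_id, " / ",
         dup$source, call. = FALSE)
  }
  if (any(records$mean_expr <= 0)) stop("mean_expr must be > 0", call. = FALSE)
  if (any(records$sd_expr < 0)) stop("sd_expr must be >= 0", call. = FALSE)
  if (any(records$n_tissues < 1)) stop("n_tissues must be >= 1", call. = FALSE)

  cv <- records$sd_expr / records$mean_expr
  stable <- records$source == "stable_set"
  stable_ids <- records$gene_id[stable]

  out <- data.frame(
    gene_id = records$gene_id,
    source = records$source,
    cv = cv,
    group1 = stable,
    group2 = stable & records$n_tissues >= 2L & cv < cv_threshold,
    group3 = stable & records$n_tissues >= 3L & cv < cv_threshold,
    group4 = !stable & !(records$gene_id %in% stable_ids),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Long-format group membership
#'
#' Converts the wide logical output of [assign_groups()] into rows of
#' (`gene_id`, `group`), one per membership.
#'
#' @param assignments Output of [assign_groups()].
#' @return Data frame with columns `gene_id`, `group` (`"group1"`..`"group4"`).
#' @export
group_membership_long <- function(assignments) {
  groups <- paste0("group", 1:4)
  pieces <- lapply(groups, function(g) {
    data.frame(gene_id = assignments$gene_id[assignments[[g]]], group = g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
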