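# Correlation tables, nonparametric group comparisons and pooled
# gene-category frequency tests.

#' Spearman correlations between gene features and mRNA levels
#'
#' One row per feature: Spearman's rho (average-rank ties method), the
#' two-sided p-value (asymptotic t approximation, as appropriate with
#' ties) and the number of complete pairs. Features with fewer than 3
#' complete pairs or zero rank variance are reported with `NA` rho.
#'
#' @param features Data frame (or matrix) of per-gene feature columns.
#' @param response Numeric vector of mRNA levels (same length as rows).
#' @param columns Optional subset of feature columns to correlate;
#'   defaults to all numeric columns.
#' @return Data frame `feature`, `rho`, `p_value`, `n`.
#' @export
spearman_table <- function(features, response, columns = NULL) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(response))
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  rows <- lapply(columns, function(col) {
    x <- features[[col]]
    keep <- is.finite(x) & is.finite(response)
    n <- sum(keep)
    if (n < 3L || length(unique(x[keep])) < 2L ||
        length(unique(response[keep])) < 2L) {
      return(data.frame(feature = col, rho = NA_real_, p_value = NA_real_,
                        n = n, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      cor.test(x[keep], response[keep], method = "spearman", exact = FALSE)
    )
    data.frame(feature = col, rho = unname(ct$estimate),
               p_value = ct$p.value, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a feature across gene groups
#'
#' Omnibus Kruskal-Wallis test followed by all pairwise two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests with Bonferroni correction:
#' each pairwise p-value is multiplied by the number of pairs and capped
#' at 1.
#'
#' @param values Numeric feature values.
#' @param groups Group labels (factor or character), one per value.
#' @return A list of class `group_comparison`: `kruskal_p`, `pairwise`
#'   (data frame `group_i`, `group_j`, `p_raw`, `p_adjusted`), `n_pairs`.
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  kw <- kruskal.test(values, groups)
  pairs <- combn(levels(groups), 2L)
  n_pairs <- ncol(pairs)
  pw <- lapply(seq_len(n_pairs), function(k) {
    gi <- pairs[1, k]; gj <- pairs[2, k]
    p <- suppressWarnings(
      wilcox.test(values[groups == gi], values[groups == gj],
                  alternative = "two.sided", exact = FALSE)$p.value
    )
    data.frame(group_i = gi, group_j = gj, p_raw = p,
               p_adjusted = min(p * n_pairs, 1), stringsAsFactors = FALSE)
  })
  structure(
    list(kruskal_p = kw$p.value, pairwise = do.call(rbind, pw),
         n_pairs = n_pairs),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis p = %.3g; %d pairwise Mann-Whitney tests ",
              x$kruskal_p, x$n_pairs))
  cat("(Bonferroni-adjusted)\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Pooled gene-category frequencies and pairwise chi-squared tests
#'
#' For each group, pools the genes annotated to the `pooled` categories
#' (pool A) and compares them against the genes annotated only to the
#' remaining categories (pool B). Genes are counted once per pool
#' (annotations to several pooled categories collapse to one), and genes
#' in pool A are removed from pool B. The frequency is `|A| / (|A| + |B|)`.
#' Group pairs are compared with Pearson's chi-squared test with Yates'
#' continuity correction on the (|A|, |B|) counts.
#'
#' Precomputed counts can be supplied directly via `counts` (columns
#' `group`, `n_pool`, `n_rest`), bypassing the annotation tables.
#'
#' @param categories Data frame (`gene_id`, `category`), possibly several
#'   rows per gene.
#' @param membership Long-format group membership (`gene_id`, `group`),
#'   e.g. from [group_membership_long()].
#' @param pooled Category names forming pool A.
#' @param counts Optional precomputed per-group counts (see above).
#' @return A list of class `category_enrichment`: `by_group` (data frame
#'   `group`, `n_pool`, `n_rest`, `frequency`) and `pairwise` (data frame
#'   with Yates-corrected chi-squared statistics and p-values).
#' @export
category_pool_frequencies <- function(categories = NULL, membership = NULL,
                                      pooled = c("translation",
                                                 "ribosome biogenesis"),
                                      counts = NULL) {
  if (is.null(counts)) {
    stopifnot(is.data.frame(categories), is.data.frame(membership))
    groups <- unique(membership$group)
    counts <- do.call(rbind, lapply(groups, function(g) {
      ids <- unique(membership$gene_id[membership$group == g])
      sub <- categories[categories$gene_id %in% ids, , drop = FALSE]
      pool_a <- unique(sub$gene_id[sub$category %in% pooled])
      pool_b <- setdiff(unique(sub$gene_id[!sub$category %in% pooled]),
                        pool_a)
      data.frame(group = g, n_pool = length(pool_a), n_rest = length(pool_b),
                 stringsAsFactors = FALSE)
    }))
  } else {
    counts <- as.data.frame(counts)
    stopifnot(all(c("group", "n_pool", "n_rest") %in% names(counts)))
  }
  total <- counts$n_pool + counts$n_rest
  counts$frequency <- ifelse(total > 0, counts$n_pool / total, NA_real_)

  pw <- NULL
  if (nrow(counts) >= 2L) {
    idx <- combn(seq_len(nrow(counts)), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      tab <- rbind(c(counts$n_pool[i], counts$n_rest[i]),
                   c(counts$n_pool[j], counts$n_rest[j]))
      if (any(rowSums(tab) == 0)) {
        stat <- NA_real_; p <- NA_real_
      } else {
        ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
        stat <- unname(ht$statistic); p <- ht$p.value
      }
      data.frame(group_i = counts$group[i], group_j = counts$group[j],
                 statistic = stat, p_value = p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(by_group = counts, pairwise = pw),
            class = "category_enrichment")
}

#' @export
print.category_enrichment <- function(x, ...) {
  cat("Pooled category frequencies by group\n")
  df <- x$by_group
  df$frequency <- sprintf("%.2f%%", 100 * df$frequency)
  print(df, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise chi-squared (Yates-corrected)\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
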