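# Independent brute-force oracles. These deliberately avoid the package's
# vectorized implementation paths: plain loops over codons, ranks computed
# by hand, orderings enumerated explicitly, structures enumerated one by one.

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

oracle_tai <- function(cds, weights, include_start = TRUE) {
  codons <- split_codons(cds)
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  if (!include_start) codons <- codons[-1]
  s <- 0
  for (cd in codons) s <- s + log(as.numeric(weights[cd]))
  exp(s / length(codons))
}

oracle_cai <- function(cds, weights) {
  codons <- split_codons(cds)
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA", "ATG", "TGG")]
  s <- 0
  for (cd in codons) s <- s + log(as.numeric(weights[cd]))
  exp(s / length(codons))
}

oracle_gc <- function(cds) {
  bases <- strsplit(cds, "")[[1]]
  mean(bases %in% c("G", "C"))
}

oracle_gc3 <- function(cds) {
  codons <- split_codons(cds)
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  third <- substring(codons, 3, 3)
  mean(third %in% c("G", "C"))
}

oracle_aa_freq <- function(cds) {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  codons <- split_codons(cds)
  aa <- code[codons]
  aa <- aa[aa != "*"]
  counts <- setNames(numeric(20), amino_acids())
  for (a in aa) counts[a] <- counts[a] + 1
  counts / sum(counts)
}

oracle_ewau <- function(cds_vec, expr) {
  num <- setNames(numeric(20), amino_acids())
  den <- 0
  for (g in seq_along(cds_vec)) {
    code <- as.character(Biostrings::GENETIC_CODE)
    names(code) <- names(Biostrings::GENETIC_CODE)
    aa <- code[split_codons(cds_vec[g])]
    aa <- aa[aa != "*"]
    for (a in aa) num[a] <- num[a] + expr[g]
    den <- den + length(aa) * expr[g]
  }
  num / den
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  n <- length(x)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..p (p small)
all_perms <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(p - 1L)) {
    for (pos in 0:(p - 1L)) {
      out[[length(out) + 1L]] <- append(sub, p, after = pos)
    }
  }
  out
}

# LMG by explicit enumeration of every predictor ordering, R^2 via lm()
oracle_lmg <- function(X, y) {
  p <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  shares <- numeric(p)
  perms <- all_perms(p)
  for (perm in perms) {
    prev <- 0
    for (i in seq_along(perm)) {
      cur <- r2(perm[seq_len(i)])
      shares[perm[i]] <- shares[perm[i]] + (cur - prev)
      prev <- cur
    }
  }
  shares <- shares / length(perms)
  shares / r2(seq_len(p))
}

# Exhaustive enumeration of all nested secondary structures (minimum
# hairpin loop h), scored by the same stacked-pair energy table as the
# built-in folder. Memoizes interval enumerations for speed; the scoring
# itself touches every structure explicitly.
oracle_mfe <- function(seq, energies = stack_energies(), h = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(s)
  if (n < h + 2) return(0)
  ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pair_ok <- function(i, j) paste0(s[i], s[j]) %in% ok_pairs
  cache <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (j - i < h + 1) return(list(matrix(0L, 0, 2)))
    key <- paste(i, j)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- enum(i + 1L, j)                     # i unpaired
    for (k in seq(i + h + 1L, j)) {
      if (pair_ok(i, k)) {
        left <- enum(i + 1L, k - 1L)
        right <- if (k + 1L <= j) enum(k + 1L, j) else list(matrix(0L, 0, 2))
        for (a in left) {
          for (b in right) {
            out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
          }
        }
      }
    }
    cache[[key]] <- out
    out
  }
  structs <- enum(1L, n)
  best <- 0
  for (st in structs) {
    if (nrow(st) < 2) next
    keys <- paste(st[, 1], st[, 2])
    e <- 0
    for (r in seq_len(nrow(st))) {
      i <- st[r, 1]; j <- st[r, 2]
      if (paste(i + 1, j - 1) %in% keys) {
        e <- e + energies[paste0(s[i], s[j]), paste0(s[i + 1], s[j - 1])]
      }
    }
    if (e < best) best <- e
  }
  best
}
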