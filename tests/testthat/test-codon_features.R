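uniform_w <- codon_weights(setNames(rep(1, 61), sense_codons()), "tai")

test_that("gene_tai is the geometric mean of codon weights", {
  expect_equal(gene_tai("ATGAAATAA", uniform_w), 1)

  # two scored codons with w = 0.5 and 0.125 -> sqrt(0.0625) = 0.25
  w <- setNames(rep(1, 61), sense_codons())
  w["AAA"] <- 0.5; w["CCC"] <- 0.125
  tw <- codon_weights(w, "tai")
  expect_equal(gene_tai("ATGAAACCCTAA", tw, include_start = FALSE), 0.25)

  # random genes match the naive loop to 1e-12
  for (s in 1:5) {
    cds <- random_cds(50, seed = s)
    expect_equal(gene_tai(cds, fx$tai_weights),
                 oracle_tai(cds, fx$tai_weights), tolerance = 1e-12)
  }

  expect_error(gene_tai("ATGAAATAA", fx$cai_weights), "label")
})

test_that("gene_tai is codon-order invariant and synonym-monotone", {
  set.seed(11)
  cds <- random_cds(60)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  interior <- codons[2:(length(codons) - 1)]
  shuffled <- paste0(codons[1], paste(sample(interior), collapse = ""),
                     codons[length(codons)])
  expect_equal(gene_tai(cds, fx$tai_weights), gene_tai(shuffled, fx$tai_weights))

  # replacing a codon by a strictly higher-weight synonym raises tAI
  map <- codon_aa_map()
  w <- as.numeric(fx$tai_weights)
  names(w) <- names(fx$tai_weights)
  for (i in seq_along(interior)) {
    syn <- names(map)[map == map[[interior[i]]]]
    better <- syn[w[syn] > w[interior[i]]]
    if (length(better)) {
      swapped <- interior
      swapped[i] <- better[1]
      cds2 <- paste0(codons[1], paste(swapped, collapse = ""),
                     codons[length(codons)])
      expect_gt(gene_tai(cds2, fx$tai_weights), gene_tai(cds, fx$tai_weights))
      break
    }
  }
})

test_that("gene_cai follows the Sharp-Li convention", {
  # a gene using only each family's best synonym scores 1
  map <- codon_aa_map()
  w <- as.numeric(fx$cai_weights)
  names(w) <- names(fx$cai_weights)
  best <- vapply(split(names(map), unname(map)),
                 function(cs) cs[which.max(w[cs])], character(1))
  cds <- paste0("ATG", paste(best[c("K", "E", "L", "S", "F")], collapse = ""),
                "TAA")
  expect_equal(gene_cai(cds, fx$cai_weights), 1)

  # one amino-acid type, equal counts of w = 1 and w = 0.25 codons -> 0.5
  usage <- setNames(rep(1, 61), sense_codons())
  usage["AAA"] <- 8; usage["AAG"] <- 2   # w: AAA 1, AAG 0.25
  cw <- cai_weights_from_usage(usage)
  expect_equal(gene_cai("ATGAAAAAGTAA", cw), 0.5)

  # Met and Trp codons are excluded from the mean
  expect_equal(gene_cai("ATGTGGAAATAA", cw),
               gene_cai("ATGAAATAA", cw))

  for (s in 6:10) {
    cds <- random_cds(50, seed = s)
    expect_equal(gene_cai(cds, fx$cai_weights),
                 oracle_cai(cds, fx$cai_weights), tolerance = 1e-12)
  }
})

test_that("GC metrics match positional counting", {
  res <- gc_metrics("ATGGCGTAA")
  expect_equal(res$gc3_frac, 1)          # third bases of ATG, GCG: G, G
  expect_equal(gc_metrics("ATGAAATAA")$gc_frac, 1 / 9)  # single G in ATG
  for (s in 11:15) {
    cds <- random_cds(40, seed = s)
    res <- gc_metrics(cds)
    expect_equal(res$gc_frac, oracle_gc(cds), tolerance = 1e-12)
    expect_equal(res$gc3_frac, oracle_gc3(cds), tolerance = 1e-12)
  }
})

test_that("amino-acid frequencies are protein fractions summing to one", {
  f <- aa_frequencies("ATGAAATAA")
  expect_equal(unname(f[1, "M"]), 0.5)
  expect_equal(unname(f[1, "K"]), 0.5)
  expect_equal(sum(f), 1)

  homopolymer <- paste0("ATG", strrep("AAA", 30), "TAA")
  f2 <- aa_frequencies(homopolymer)
  expect_equal(unname(f2[1, "K"]), 30 / 31)

  for (s in 16:20) {
    cds <- random_cds(45, seed = s)
    expect_equal(unname(aa_frequencies(cds)[1, ]),
                 unname(oracle_aa_freq(cds)), tolerance = 1e-12)
  }
})

test_that("expression-weighted amino-acid usage reduces and rescales correctly", {
  cds1 <- random_cds(40, seed = 21)
  # single-gene cohort: the expression weight cancels
  expect_equal(unname(expression_weighted_aa_usage(cds1, 123)),
               unname(aa_frequencies(cds1)[1, ]), tolerance = 1e-12)
  # two identical genes with different E give the shared frequencies
  expect_equal(unname(expression_weighted_aa_usage(c(cds1, cds1), c(1, 9))),
               unname(aa_frequencies(cds1)[1, ]), tolerance = 1e-12)

  set.seed(22)
  cohort <- vapply(1:20, function(i) random_cds(sample(30:60, 1)), character(1))
  expr <- runif(20, 1, 100)
  f <- expression_weighted_aa_usage(cohort, expr)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(unname(f), unname(oracle_ewau(cohort, expr)), tolerance = 1e-12)
  # invariant to rescaling all expression values
  expect_equal(unname(expression_weighted_aa_usage(cohort, expr * 1e3)),
               unname(f), tolerance = 1e-12)

  expect_error(expression_weighted_aa_usage(character(0), numeric(0)), "empty")
  expect_error(expression_weighted_aa_usage(cds1, -1), "positive")
})

test_that("gene_features assembles the covariate table", {
  set.seed(23)
  genes <- do.call(rbind, lapply(1:4, function(i) {
    generate_gene(sprintf("g%d", i), 0.35, 300, utr5_len = 80, utr3_len = 150,
                  weights = fx$tai_weights, clamp_tai = TRUE)
  }))
  f <- gene_features(genes, fx$tai_weights, fx$cai_weights)
  expect_equal(f$log_cds_len, log(nchar(genes$cds)))
  expect_true(all(f$dg_utr5_minus52_minus2 <= 0))
  expect_equal(rowSums(f[, paste0("aa_", amino_acids())]), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(f$tai_over_logLcds, f$tai / f$log_cds_len)

  # a too-short 5'UTR yields a missing dG, not an error
  short <- genes
  short$utr5[1] <- strrep("A", 20)
  short$cdna <- paste0(short$utr5, short$cds, short$utr3)
  f2 <- gene_features(short, fx$tai_weights, fx$cai_weights)
  expect_true(is.na(f2$dg_utr5_minus52_minus2[1]))
  expect_false(anyNA(f2$dg_utr5_minus52_minus2[-1]))
})
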