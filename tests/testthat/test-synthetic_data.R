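test_that("weight fixtures are deterministic and satisfy their contracts", {
  a <- generate_weight_fixtures(seed = 5)
  b <- generate_weight_fixtures(seed = 5)
  expect_identical(a, b)
  expect_equal(max(as.numeric(a$tai_weights)), 1)
  expect_equal(nrow(a$aa_scores), 20L)
  expect_true(all(a$trna$copies >= 1))
  for (s in c(1, 9, 17, 33)) {
    rho <- generate_weight_fixtures(seed = s)$score_copy_spearman
    expect_gte(rho, -0.70)
    expect_lte(rho, -0.40)
  }
})

test_that("generated genes hit their tAI target and always pass QC", {
  set.seed(12)
  for (target in c(0.30, 0.37, 0.43)) {
    gene <- generate_gene("g", target, cds_len = 900, utr5_len = 100,
                          utr3_len = 200, weights = fx$tai_weights)
    expect_lt(abs(gene_tai(gene$cds, fx$tai_weights) - target), 0.03)
    res <- qc_filter(gene)
    expect_equal(res$report$n_retained, 1L)
  }
  expect_error(
    generate_gene("g", 0.99, cds_len = 300, weights = fx$tai_weights),
    "unreachable target_tai"
  )
})

test_that("dataset generation is seed-deterministic end to end", {
  cfg <- synthetic_config(n_genes = 40, seed = 13, n_vogel = 25L,
                          vogel_overlap = 4L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$categories, d2$categories)
  expect_identical(d1$features, d2$features)
})

test_that("stored features equal an independent recomputation", {
  ds <- generate_dataset(synthetic_config(n_genes = 30, seed = 14,
                                          include_vogel = FALSE))
  redo <- gene_features(ds$genes, tai_weights = ds$tables$tai_weights,
                        cai_weights = ds$tables$cai_weights,
                        windows = "utr5_minus52_minus2",
                        seed = ds$config$seed + 2L)
  num <- vapply(redo, is.numeric, logical(1))
  expect_equal(as.matrix(redo[num]), as.matrix(ds$features[num]),
               tolerance = 1e-9)
})

test_that("the generative linear model matches the stored truth", {
  ds <- generate_dataset(synthetic_config(n_genes = 120, seed = 15,
                                          include_vogel = FALSE))
  f <- ds$features
  y <- log(ds$expression$mean_expr)
  X <- as.matrix(f[, names(ds$truth$beta)])
  resid <- y - X %*% ds$truth$beta
  # residual = intercept + noise: its SD should match the configured noise
  expect_lt(abs(sd(resid) - ds$truth$noise_sd) / ds$truth$noise_sd, 0.35)
  # the fitted coefficients should be near the truth
  fit <- lm(y ~ X)
  expect_lt(max(abs(coef(fit)[-1] - ds$truth$beta) /
                  pmax(abs(ds$truth$beta), 1e-6)), 0.8)
})

test_that("true coefficients are covered by 95% CIs at the nominal rate", {
  covered <- 0L
  total <- 0L
  for (s in 1:200) {
    ds <- generate_dataset(synthetic_config(n_genes = 100, seed = 4000 + s,
                                            include_vogel = FALSE))
    d <- cbind(ds$features, y = log(ds$expression$mean_expr))
    fml <- as.formula(paste("y ~", paste(names(ds$truth$beta), collapse = "+")))
    ci <- confint(lm(fml, data = d))[names(ds$truth$beta), ]
    covered <- covered + sum(ci[, 1] <= ds$truth$beta &
                               ds$truth$beta <= ci[, 2])
    total <- total + length(ds$truth$beta)
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.975)
})

test_that("datasets write to plain-text files and read back", {
  ds <- generate_dataset(synthetic_config(n_genes = 25, seed = 16,
                                          n_vogel = 22L, vogel_overlap = 2L))
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cds.fa", "cdna.fa", "utr5.fa", "utr3.fa", "expression.tsv",
    "categories.tsv", "codon_weights_tai.tsv", "trna_copies.tsv",
    "aa_scores.tsv", "features.tsv", "truth.json"
  )))))
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(nrow(expr), nrow(ds$expression))
  cats <- read_category_table(file.path(dir, "categories.tsv"))
  expect_true(all(c("gene_id", "category") %in% names(cats)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 16L)
  w <- read_codon_weights(file.path(dir, "codon_weights_tai.tsv"), "tai")
  expect_equal(as.numeric(w), as.numeric(ds$tables$tai_weights),
               tolerance = 1e-12)
})

test_that("category labels are enriched for the translation pool among high expressors", {
  ds <- generate_dataset(synthetic_config(n_genes = 400, seed = 17,
                                          include_vogel = FALSE))
  y <- log(ds$expression$mean_expr)
  pool_ids <- unique(ds$categories$gene_id[
    ds$categories$category %in% c("translation", "ribosome biogenesis")])
  in_pool <- ds$expression$gene_id %in% pool_ids
  expect_gt(mean(y[in_pool]), mean(y[!in_pool]))
})
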