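test_that("FASTA round trip preserves generated gene sequences", {
  set.seed(7)
  genes <- do.call(rbind, lapply(1:5, function(i) {
    generate_gene(sprintf("g%d", i), target_tai = 0.35, cds_len = 300,
                  utr5_len = 80, utr3_len = 120, weights = fx$tai_weights,
                  clamp_tai = TRUE)
  }))
  dir <- withr_like_tempdir <- tempfile("fasta")
  dir.create(dir)
  for (region in c("cds", "cdna", "utr5", "utr3")) {
    write_gene_fasta(genes, file.path(dir, paste0(region, ".fa")), region)
  }
  back <- read_gene_sequences(cds = file.path(dir, "cds.fa"),
                              cdna = file.path(dir, "cdna.fa"),
                              utr5 = file.path(dir, "utr5.fa"),
                              utr3 = file.path(dir, "utr3.fa"))
  back <- back[match(genes$gene_id, back$gene_id), ]
  expect_equal(nrow(back), 5L)
  expect_equal(back$cds, genes$cds)
  expect_equal(back$cdna, genes$cdna)
  expect_equal(back$utr5, genes$utr5)
  expect_equal(back$utr3, genes$utr3)
})

test_that("FASTA reading validates headers and ids and normalizes alphabet", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1|t1", "atgaaauaa", ">g2|t1b", "ATGCCCTGA"), fa)
  tx <- read_gene_sequences(cds = fa)
  expect_equal(nrow(tx), 2L)
  expect_equal(tx$cds[1], "ATGAAATAA")  # uppercased, U -> T

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">g1|t1", "ATGAAATAA", ">g2|t1", "ATGCCCTGA"), dup)
  expect_error(read_gene_sequences(cds = dup), "duplicate transcript_id")

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">justonefield", "ATGAAATAA"), bad)
  expect_error(read_gene_sequences(cds = bad), "justonefield")

  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_warning(tx0 <- read_gene_sequences(cds = empty), "empty")
  expect_equal(nrow(tx0), 0L)
})

test_that("longest-isoform selection keeps the longest cDNA with a stable tie-break", {
  tx <- toy_transcripts()
  kept <- select_longest_isoform(tx)
  expect_equal(sort(kept$gene_id), c("g1", "g2", "g3"))
  expect_equal(kept$transcript_id[kept$gene_id == "g1"], "t2")  # 900 > 300

  tie <- data.frame(transcript_id = c("T2", "T1"), gene_id = "g",
                    cdna = c(strrep("A", 600), strrep("C", 600)),
                    cds = c("ATGTAA", "ATGTAA"), utr5 = "", utr3 = "",
                    stringsAsFactors = FALSE)
  expect_equal(select_longest_isoform(tie)$transcript_id, "T1")

  # permutation invariance
  perm <- tx[c(3, 1, 4, 2), ]
  expect_equal(select_longest_isoform(perm)[order(select_longest_isoform(perm)$gene_id), "transcript_id"],
               kept[order(kept$gene_id), "transcript_id"])

  # selection by CDS length instead of cDNA length
  by_cds <- select_longest_isoform(tx, by = "cds")
  expect_equal(by_cds$transcript_id[by_cds$gene_id == "g1"], "t2")
})

test_that("qc_filter applies the four rules with first-fail attribution", {
  mk <- function(cds, gene_id = paste0("g", seq_along(cds))) {
    data.frame(gene_id = gene_id, cdna = cds, cds = cds, utr5 = "", utr3 = "",
               stringsAsFactors = FALSE)
  }
  res <- qc_filter(mk(c("ATGAAATAA",   # clean
                        "ATGAAACCC",   # no stop
                        "ATGANATAA",   # contains N (also no stop frame issues)
                        "TTGAAATAA",   # bad start
                        "ATGAATAA")))  # not divisible by 3
  expect_equal(res$genes$gene_id, "g1")
  rem <- res$report$n_removed_by_rule
  expect_equal(unname(rem[c("n_content", "start_codon", "stop_codon",
                            "length_multiple_of_3")]), c(1L, 1L, 1L, 1L))
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(rem))

  # attribution goes to the FIRST failing rule: N beats bad start
  both <- qc_filter(mk("TTGNAATAA"))
  expect_equal(unname(both$report$n_removed_by_rule["n_content"]), 1L)
  expect_equal(unname(both$report$n_removed_by_rule["start_codon"]), 0L)

  # records without a CDS (non-coding) are dropped up front
  nc <- mk(c("ATGAAATAA", ""))
  expect_equal(unname(qc_filter(nc)$report$n_removed_by_rule["non_coding"]), 1L)

  # idempotence: filtering retained genes removes nothing
  again <- qc_filter(res$genes)
  expect_equal(again$report$n_retained, nrow(res$genes))
  expect_equal(sum(again$report$n_removed_by_rule), 0L)
})

test_that("QC reports serialize as rule/count TSV", {
  res <- qc_filter(data.frame(gene_id = "g", cdna = "ATGAAATAA",
                              cds = "ATGAAATAA", utr5 = "", utr3 = "",
                              stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".tsv")
  write_qc_report(res$report, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("rule", "count"))
  expect_equal(tab$count[tab$rule == "retained"], 1L)
})
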