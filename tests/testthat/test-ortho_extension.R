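blosum62 <- proteoseed:::substitution_matrix("BLOSUM62")

test_that("self-alignment scores the BLOSUM62 diagonal sum", {
  set.seed(81)
  for (k in 1:10) {
    s <- random_protein(10)
    al <- smith_waterman(s, s)
    expect_equal(al$score,
                 sum(diag(blosum62[strsplit(s, "")[[1]],
                                   strsplit(s, "")[[1]]])))
    expect_identical(al$query_start, 1L)
    expect_identical(al$subject_end, 10L)
  }
})

test_that("dissimilar strings give an empty zero-score alignment", {
  al <- smith_waterman("WWWW", "GGGG")
  expect_identical(al$score, 0)
  expect_identical(al$query_aligned, "")
})

test_that("alignment scores equal the brute-force affine-gap DP", {
  set.seed(82)
  for (k in 1:100) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    got <- smith_waterman(a, b, score_only = TRUE)$score
    want <- oracle_sw_score(a, b, blosum62)
    expect_identical(got, as.numeric(want))
  }
})

test_that("the expectation value follows its closed form", {
  p <- alignment_params()
  m <- 120L; n <- 5e6
  s_unit <- log(p$karlin_k * m * n) / p$karlin_lambda
  expect_equal(evalue(s_unit, m, n), 1.0, tolerance = 1e-12)
  expect_equal(evalue(100, m, 2 * n) / evalue(100, m, n), 2)
  set.seed(83)
  for (k in 1:50) {
    s <- runif(1, 20, 500); mm <- sample(50:500, 1); nn <- runif(1, 1e4, 1e8)
    expect_equal(evalue(s, mm, nn),
                 0.041 * mm * nn * exp(-0.267 * s), tolerance = 1e-12)
  }
})

test_that("planted homologs in unannotated regions are found; annotated ones suppressed", {
  fx <- make_fixture(seed = 3)
  cl <- simulate_clade(fx$sim, fx$cfg)
  genes <- fx$sim$ledger$genes
  miss <- genes[genes$category == "missed_gene", ][1:2, ]
  novel <- setNames(miss$protein, miss$gene_id)
  subj_g <- lapply(cl$subjects, `[[`, "genomes")
  subj_a <- lapply(cl$subjects, `[[`, "annotation")
  # subjects annotate their orthologs, so every hit is suppressed
  none <- find_unannotated_homologs(novel, subj_g, subj_a)
  expect_identical(nrow(none), 0L)
  # removing the ortholog from one subject annotation exposes the region
  drop_tag <- paste0(names(cl$subjects)[1], "_", miss$gene_id[1])
  a1 <- subj_a[[1]]
  subj_a[[1]] <- a1[a1$locus_tag != drop_tag, ]
  hits <- find_unannotated_homologs(novel, subj_g[1], subj_a[1])
  expect_identical(unique(hits$query_id), miss$gene_id[1])
  expect_true(all(hits$e_value < 1e-20))
  # tightening the cutoff never adds hits
  cfg_tight <- pipeline_config(evalue_novel = 1e-40)
  hits_tight <- find_unannotated_homologs(novel, subj_g[1], subj_a[1],
                                          cfg_tight)
  expect_true(nrow(hits_tight) <= nrow(hits))
})

test_that("an identity clade confirms every start and corrects none", {
  fx <- make_fixture(seed = 3)
  cfg0 <- simulation_config(seed = 3,
                            clade = list(n_subjects = 1, aa_divergence = 0,
                                         subject_start_error_rate = 0,
                                         gene_loss_p = 0,
                                         too_long_frac = 0.7))
  cl <- simulate_clade(fx$sim, cfg0)
  genes <- fx$sim$ledger$genes[!fx$sim$ledger$genes$frameshifted, ]
  q <- data.frame(query_id = genes$gene_id, protein = genes$protein,
                  stringsAsFactors = FALSE)
  pr <- propagate_start_corrections(q, cl$subjects)
  expect_identical(pr$rate, 0)
  expect_true(all(pr$calls$verdict == "confirmed"))
  expect_identical(nrow(pr$calls), nrow(genes))
})

test_that("verdicts partition hits and recover planted subject start errors", {
  fx <- make_fixture(seed = 3)
  cl <- simulate_clade(fx$sim, fx$cfg)
  genes <- fx$sim$ledger$genes[!fx$sim$ledger$genes$frameshifted, ]
  q <- data.frame(query_id = genes$gene_id, protein = genes$protein,
                  stringsAsFactors = FALSE)
  pr <- propagate_start_corrections(q, cl$subjects)
  expect_true(all(pr$calls$verdict %in% c("confirmed", "corrected",
                                          "undecidable")))
  led <- cl$ledger_clade
  merged <- merge(pr$calls, led, by = "subject_locus")
  expect_gt(nrow(merged), 0)
  planted <- merged$error != "none"
  expect_true(all(merged$verdict[planted] == "corrected"))
  expect_true(all(merged$verdict[!planted] == "confirmed"))
  # corrected calls point at the true start, with the documented sign
  corr <- merged[planted & merged$verdict == "corrected", ]
  expect_true(all(corr$proposed_start == corr$true_start))
  expect_true(all(corr$offset_codons.x == corr$offset_codons.y))
})

test_that("tabular hit files read with the standard twelve columns", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "85.3", "120", "17", "1", "1", "120",
                   "11", "130", "4e-21", "210", sep = "\t"), tmp)
  h <- read_tabular_hits(tmp)
  expect_identical(ncol(h), 12L)
  expect_equal(h$evalue, 4e-21)
  writeLines("only\tthree\tcols", tmp)
  expect_error(read_tabular_hits(tmp), "12")
})
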