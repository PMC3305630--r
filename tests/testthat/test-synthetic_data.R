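test_that("generation is deterministic and respects the layout contract", {
  cfg <- simulation_config(seed = 101)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genomes[[1]]$sequence, b$genomes[[1]]$sequence)
  expect_identical(a$ledger$genes, b$ledger$genes)

  genes <- a$ledger$genes
  expect_identical(nrow(genes), cfg$n_genes)
  lo <- pmin(genes$start_coord, genes$stop_coord)
  hi <- pmax(genes$start_coord, genes$stop_coord)
  ord <- order(lo)
  expect_true(all(lo[ord][-1] > hi[ord][-length(hi)]))   # no overlaps
  # every protein begins with Met and its span includes the stop codon
  expect_true(all(substr(genes$protein, 1, 1) == "M"))
  expect_identical(coords_to_length(genes$start_coord, genes$stop_coord),
                   nchar(genes$protein) + 1L)
  expect_error(generate_genome(simulation_config(seed = 1, n_genes = 200)),
               "infeasible")
})

test_that("planted errors follow their definitions and are fully ledgered", {
  fx <- make_fixture(seed = 102)
  sim <- fx$sim
  cfg <- fx$cfg
  err <- sim$ledger$errors
  for (cat in names(cfg$error_counts)) {
    expect_identical(sum(err$category == cat),
                     as.integer(cfg$error_counts[[cat]]))
  }
  expect_identical(sum(err$category == "one_hit"), cfg$n_one_hit)

  genes <- sim$ledger$genes
  pub <- sim$annotation_published
  # genome grows by exactly one base per planted insertion
  expect_identical(nchar(sim$genomes[[1]]$sequence),
                   cfg$genome_length_nt +
                     as.integer(cfg$error_counts[["base_insertion"]]))
  # an overextended annotation strictly contains the true CDS, same stop
  for (i in which(err$category == "wrong_start_long")) {
    g <- genes[genes$gene_id == err$gene_id[i], ]
    p <- pub[pub$locus_tag == err$gene_id[i], ]
    expect_identical(p$stop_coord, g$stop_coord)
    expect_gt(abs(p$start_coord - p$stop_coord),
              abs(g$start_coord - g$stop_coord))
    # the published start is canonical and in frame
    expect_identical((p$start_coord - g$start_coord) %% 3, 0)
  }
  # removed genes are really absent; fakes really present
  expect_false(any(err$gene_id[err$category %in%
                                 c("missed_gene", "spurious_cds",
                                   "one_hit", "base_insertion")] %in%
                     pub$locus_tag))
  expect_true(all(na.omit(err$fake_tag) %in% pub$locus_tag))
  # the recorded homopolymer run is a genuine run containing the insertion
  for (i in which(err$category == "base_insertion")) {
    s <- sim$genomes[[1]]$sequence
    run <- substr(s, err$run_lo[i], err$run_hi[i])
    expect_identical(length(unique(strsplit(run, "")[[1]])), 1L)
    expect_true(err$inserted_pos[i] >= err$run_lo[i] &&
                  err$inserted_pos[i] <= err$run_hi[i])
  }
})

test_that("simulated evidence respects detection guarantees and FDR plumbing", {
  fx <- make_fixture(seed = 103)
  ps <- fx$ps
  expect_true(all(c("peptide", "orf_id", "p_value", "rank",
                    "spectral_count", "condition", "tryptic_status") %in%
                    names(ps$psms)))
  # a zero false-match rate produces an empty decoy table and zero FDR
  fx0 <- make_fixture(seed = 103, false_psm_rate = 0)
  expect_identical(nrow(filter_psms(fx0$ps$decoy_psms)), 0L)
  expect_identical(decoy_fdr(filter_psms(fx0$ps$psms),
                             filter_psms(fx0$ps$decoy_psms)), 0)
  # every error-carrying gene is expressed
  genes <- fx$sim$ledger$genes
  expect_true(all(genes$gene_id[genes$category != "none"] %in%
                    ps$expressed))
  # one-hit genes have exactly one confident peptide
  tr <- ps$transcription
  expect_identical(nrow(tr), fx$cfg$n_one_hit)
})

test_that("the decoy FDR estimate is unbiased at planted rates", {
  # binomial check at 1%: pooled over seeds, the estimate must sit inside
  # the 99% interval around the planted rate among confident matches
  rates <- vapply(201:212, function(s) {
    fx <- make_fixture(seed = s)
    decoy_fdr(filter_psms(fx$ps$psms), filter_psms(fx$ps$decoy_psms),
              "peptide")
  }, numeric(1))
  r <- 0.01
  n_eff <- 450 * length(rates)   # ~distinct peptides per seed
  expect_lt(abs(mean(rates) - r), 3 * sqrt(r * (1 - r) / n_eff) + 0.002)
})

test_that("clade simulation hits the configured divergence and error rate", {
  fx <- make_fixture(seed = 104)
  cl <- simulate_clade(fx$sim, fx$cfg)
  led <- cl$ledger_clade
  genes <- fx$sim$ledger$genes
  # mean pairwise ortholog identity ~ 1 - aa_divergence
  idents <- vapply(sample(nrow(led), 40), function(i) {
    sub <- cl$subjects[[led$subject[i]]]
    cds <- sub$annotation[sub$annotation$locus_tag == led$subject_locus[i], ]
    if (led$error[i] != "none") return(NA_real_)
    prot_s <- extract_and_translate(sub$genomes[[1]], cds)
    prot_q <- genes$protein[genes$gene_id == led$gene_id[i]]
    n <- min(nchar(prot_s), nchar(prot_q))
    mean(strsplit(substr(prot_s, 1, n), "")[[1]] ==
           strsplit(substr(prot_q, 1, n), "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(idents, na.rm = TRUE) - 0.90), 0.02)
  # planted error fraction near the configured 12%
  expect_lt(abs(mean(led$error != "none") - 0.12), 0.06)
  # determinism
  cl2 <- simulate_clade(fx$sim, fx$cfg)
  expect_identical(cl$subjects[[1]]$genomes[[1]]$sequence,
                   cl2$subjects[[1]]$genomes[[1]]$sequence)
})
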