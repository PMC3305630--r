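# A compact hand-built genome for the classifier tests: two real genes on
# known strands with an intergenic region large enough to host a novel
# ORF, all coordinates chosen so calls can be asserted exactly.

test_that("choose_start returns the nearest upstream canonical codon", {
  fx <- make_fixture(seed = 6)
  db <- fx$db
  genomes <- fx$sim$genomes
  cfg <- pipeline_config()
  set.seed(51)
  picked <- 0
  for (i in sample(nrow(db$orfs), 200)) {
    orf <- db$orfs[i, ]
    k <- sample(nchar(orf$aa), 1)
    got <- choose_start(orf, k, genomes, cfg)
    # exhaustive upstream scan oracle
    g <- genomes[[orf$replicon_id]]
    want <- NA_integer_
    for (j in k:1) {
      pos <- if (orf$frame > 0) orf$span_start + 3 * (j - 1)
             else orf$span_start - 3 * (j - 1)
      codon <- if (orf$frame > 0) substr(g$sequence, pos, pos + 2)
               else oracle_revcomp(substr(g$sequence, pos - 2, pos))
      if (codon %in% c("ATG", "GTG", "TTG")) { want <- pos; break }
    }
    expect_identical(got, as.integer(want))
    if (!is.na(want)) picked <- picked + 1
  }
  expect_gt(picked, 100)   # the oracle comparison exercised real picks
})

test_that("validated unannotated ORFs are classified by overlap and support", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  r <- suppressWarnings(suppressMessages(
    refine_annotation(fx$ps$psms, fx$db, sim$annotation_published,
                      sim$genomes, transcription = fx$ps$transcription)))
  calls <- r$calls
  genes <- sim$ledger$genes
  err <- sim$ledger$errors

  # planted missed genes come back as novel calls at their stop codon
  for (gid in err$gene_id[err$category == "missed_gene"]) {
    gstop <- genes$stop_coord[genes$gene_id == gid]
    expect_true(any(calls$category == "novel_cds" &
                      calls$new_stop == gstop))
  }
  # planted fake CDSs are displaced, never kept
  for (ft in na.omit(err$fake_tag)) {
    expect_true(any(grepl(ft, calls$displaced_locus)))
  }
  # novel calls carry canonical starts and proper evidence
  nv <- calls[calls$category == "novel_cds", ]
  expect_true(all(nv$start_codon %in% c("ATG", "GTG", "TTG")))
  # proposed new genes never overlap one another
  new <- calls[calls$category %in% c("novel_cds", "wrong_cds_replacement") &
                 !is.na(calls$new_start), ]
  if (nrow(new) > 1) {
    lo <- pmin(new$new_start, new$new_stop)
    hi <- pmax(new$new_start, new$new_stop)
    ord <- order(lo)
    expect_true(all(lo[ord][-1] > hi[ord][-nrow(new)]))
  }
})

test_that("a validated ORF overlapping a detected gene is a conflict, not a call", {
  fx <- make_fixture(seed = 6)
  db <- fx$db
  sim <- fx$sim
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, db, sim$genomes)
  ev <- aggregate_to_proteins(mapped, filtered)
  # make one displaced (undetected) locus look detected via homology
  err <- sim$ledger$errors
  fake <- na.omit(err$fake_tag)[1]
  hs <- setNames(TRUE, fake)
  cls <- classify_detected_orfs(ev, mapped, sim$annotation_published, db,
                                sim$genomes, homology_support = hs)
  gid <- err$gene_id[!is.na(err$fake_tag)][1]
  gstop <- sim$ledger$genes$stop_coord[sim$ledger$genes$gene_id == gid]
  row <- cls[!is.na(cls$new_stop) & cls$new_stop == gstop, ]
  expect_identical(row$category, "conflict")
  expect_match(row$note, fake)
})

test_that("one-hit wonders need the stringent p-value and isolation", {
  fx <- make_fixture(seed = 6)
  db <- fx$db
  sim <- fx$sim
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, db, sim$genomes)
  ev <- aggregate_to_proteins(mapped, filtered)
  spans <- detected_gene_spans(ev, mapped, sim$annotation_published, db,
                               sim$genomes)
  cand <- one_hit_wonder_candidates(ev, mapped, sim$annotation_published,
                                    db, sim$genomes, spans)
  oh_genes <- sim$ledger$genes[sim$ledger$genes$category == "one_hit", ]
  expect_identical(nrow(cand), nrow(oh_genes))

  # the boundary is strict: exactly 3.2e-5 is rejected
  ev2 <- ev
  ev2$best_p_value[ev2$status == "one_hit"] <- 3.2e-5
  cand2 <- one_hit_wonder_candidates(ev2, mapped,
                                     sim$annotation_published, db,
                                     sim$genomes, spans)
  expect_identical(nrow(cand2), 0L)

  # transcription evidence promotes exactly the transcribed subset
  prom <- accept_with_transcription(cand, fx$ps$transcription)
  expect_identical(sum(prom$category == "novel_cds"),
                   length(sim$ledger$transcribed_one_hit))
  expect_warning(
    accept_with_transcription(cand, setNames(TRUE, "no:such:orf")),
    "unknown")
})

test_that("semi-tryptic N-terminal peptides confirm or correct starts", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, fx$db, sim$genomes)
  v <- validate_starts_semitryptic(mapped, sim$annotation_published,
                                   fx$db, sim$genomes)
  expect_true(all(v$category %in% c("start_confirmed", "start_corrected",
                                    "rejected")))
  expect_true(all(v$nterm_category[v$category != "rejected"] %in%
                    c("ATG_met_retained", "ATG_met_removed",
                      "GTG_met_retained", "GTG_met_removed",
                      "TTG_met_removed")))
  # every overextended annotation with its N-terminal peptide observed is
  # corrected to the exact true start
  err <- sim$ledger$errors
  long <- err[err$category == "wrong_start_long", ]
  for (i in seq_len(nrow(long))) {
    row <- v[v$locus_tag == long$gene_id[i], ]
    expect_identical(row$category, "start_corrected")
    expect_identical(row$new_start, long$true_start[i])
  }
  # confirmations point at the annotated start of well-annotated genes
  conf <- v[v$category == "start_confirmed", ]
  expect_true(all(conf$locus_tag %in%
                    sim$ledger$genes$gene_id[sim$ledger$genes$category ==
                                               "none"]))
})

test_that("upstream tryptic peptides extend truncated annotations exactly", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, fx$db, sim$genomes)
  ev <- aggregate_to_proteins(mapped, filtered)
  spans <- detected_gene_spans(ev, mapped, sim$annotation_published,
                               fx$db, sim$genomes)
  ext <- nterm_extension_scan(mapped, sim$annotation_published, fx$db,
                              sim$genomes, spans)
  err <- sim$ledger$errors
  short <- err[err$category == "wrong_start_short", ]
  hits <- ext[!is.na(ext$new_start), ]
  expect_gte(sum(hits$locus_tag %in% short$gene_id &
                   hits$new_start %in% short$true_start), nrow(short) - 1L)
})

test_that("start-codon usage summarises confirmed and corrected calls", {
  mk <- function(codon, n, cat = "start_confirmed") {
    do.call(rbind, replicate(n, proteoseed:::call_row(
      cat, start_codon = codon), simplify = FALSE))
  }
  calls <- rbind(mk("ATG", 94), mk("GTG", 5, "start_corrected"),
                 mk("TTG", 1))
  u <- start_codon_usage(calls)
  expect_equal(u$percent[u$codon == "ATG"], 94)
  expect_equal(u$percent[u$codon == "GTG"], 5)
  expect_equal(u$percent[u$codon == "TTG"], 1)
  allatg <- start_codon_usage(mk("ATG", 10))
  expect_equal(allatg$percent, c(100, 0, 0))
  expect_identical(nrow(start_codon_usage(proteoseed:::empty_calls())), 0L)
})

test_that("codon usage of simulated starts recovers the planted mix", {
  set.seed(52)
  cfg <- simulation_config(seed = 900, n_genes = 60,
                           genome_length_nt = 90000)
  counts <- c(ATG = 0, GTG = 0, TTG = 0)
  for (s in 0:3) {
    cfg2 <- simulation_config(seed = 900 + s, n_genes = 60,
                              genome_length_nt = 90000)
    gen <- generate_genome(cfg2)
    tab <- table(gen$ledger$genes$start_codon)
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  frac <- counts / sum(counts)
  # multinomial 99% CI at n = 240 around (0.94, 0.05, 0.01)
  expect_lt(abs(frac[["ATG"]] - 0.94), 3 * sqrt(0.94 * 0.06 / 240))
  expect_lt(abs(frac[["GTG"]] - 0.05), 3 * sqrt(0.05 * 0.95 / 240) + 0.01)
})
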