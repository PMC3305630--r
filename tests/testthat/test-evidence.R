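psm_row <- function(peptide, orf_id, p = 1e-6, rank = 1L, sc = 2L,
                    status = "full") {
  data.frame(peptide = peptide, orf_id = orf_id, p_value = p, rank = rank,
             spectral_count = sc, condition = "exp_rich",
             tryptic_status = status, stringsAsFactors = FALSE)
}

test_that("PSM tables round-trip and malformed rows are rejected by line", {
  tab <- rbind(psm_row("PEPTIDEK", "o1"), psm_row("ANOTHERK", "o2"),
               psm_row("THIRDR", "o1", p = 0.004))
  tmp <- tempfile(fileext = ".tsv")
  write_psm_table(tab, tmp)
  back <- read_psm_table(tmp)
  expect_equal(back, tab)

  bad <- rbind(tab, psm_row("BADONE", "o3", p = 0))
  write_psm_table(bad, tmp)
  expect_warning(kept <- read_psm_table(tmp), "line")
  expect_identical(nrow(kept), 3L)

  writeLines("peptide\torf_id\tp_value", tmp)
  expect_error(read_psm_table(tmp), "required column")
})

test_that("identity filter is strict and rank-aware", {
  tab <- rbind(psm_row("A_EXACT", "o", p = 0.005),
               psm_row("B_BELOW", "o", p = 0.0049),
               psm_row("C_RANK2", "o", p = 1e-9, rank = 2L))
  kept <- filter_psms(tab)
  expect_identical(kept$peptide, "B_BELOW")
  set.seed(41)
  p <- runif(1000, 0, 0.02)
  tab2 <- psm_row(sprintf("P%04d", 1:1000), "o")
  tab2$p_value <- p
  expect_identical(nrow(filter_psms(tab2)), sum(p < 0.005))
})

test_that("decoy FDR follows its definition and handles the empty case", {
  t100 <- psm_row(sprintf("T%03d", 1:100), "o")
  expect_identical(decoy_fdr(t100, t100[0, ]), 0)
  t1000 <- psm_row(sprintf("T%04d", 1:1000), "o")
  d2 <- psm_row(c("D1", "D2"), "DECOY_o")
  expect_equal(decoy_fdr(t1000, d2, "peptide"), 0.002)
  expect_warning(res <- decoy_fdr(t1000[0, ], d2), "undefined")
  expect_true(is.na(res))
})

test_that("reversed decoys preserve lengths and reverse residue order", {
  fx <- make_fixture(seed = 6)
  dec <- make_decoy_db(fx$db)
  expect_identical(nchar(dec$orfs$aa), nchar(fx$db$orfs$aa))
  i <- 5
  expect_identical(dec$orfs$aa[i],
                   paste(rev(strsplit(fx$db$orfs$aa[i], "")[[1]]),
                         collapse = ""))
  expect_true(all(startsWith(dec$orfs$orf_id, "DECOY_")))
})

test_that("peptide-to-genome mapping places offsets on both strands", {
  fx <- make_fixture(seed = 6)
  db <- fx$db
  plus <- db$orfs[db$orfs$frame > 0 & nchar(db$orfs$aa) > 60, ][1, ]
  pep <- substr(plus$aa, 1, 12)
  m <- map_psms(psm_row(pep, plus$orf_id), db, fx$sim$genomes)
  own <- m[m$orf_id == plus$orf_id, ]
  expect_identical(own$genomic_start[own$aa_offset0 == 0L], plus$span_start)

  minus <- db$orfs[db$orfs$frame < 0 & nchar(db$orfs$aa) > 60, ][1, ]
  pep2 <- substr(minus$aa, 11, 25)
  m2 <- map_psms(psm_row(pep2, minus$orf_id), db, fx$sim$genomes)
  own2 <- m2[m2$orf_id == minus$orf_id, ][1, ]
  expect_true(own2$genomic_start > own2$genomic_end)
  g <- fx$sim$genomes[[own2$replicon_id]]
  rc <- oracle_revcomp(substr(g$sequence, own2$genomic_end,
                              own2$genomic_start))
  expect_identical(oracle_translate(rc), pep2)

  expect_error(map_psms(psm_row("WWWWWWWW", plus$orf_id), db,
                        fx$sim$genomes), "corrupt")
})

test_that("simulated PSMs map with a 100% re-translation round trip", {
  fx <- make_fixture(seed = 6)
  filtered <- filter_psms(fx$ps$psms)
  # map_psms stops on any round-trip failure, so completing is the assertion
  m <- map_psms(filtered, fx$db, fx$sim$genomes)
  expect_gt(nrow(m), 100)
  expect_identical(nchar(m$peptide) * 3L,
                   abs(m$genomic_end - m$genomic_start) + 1L)
  # multi-occurrence peptides yield one row per occurrence, flagged shared
  tab <- table(m$peptide[m$tryptic_status == "full"])
  multi <- names(tab)[tab > 1]
  if (length(multi) > 0) {
    expect_true(all(m$shared[m$peptide %in% multi]))
  }
})

test_that("protein aggregation applies the two-distinct-peptide rule", {
  fx <- make_fixture(seed = 6)
  db <- fx$db
  orf <- db$orfs[nchar(db$orfs$aa) > 80, ][1, ]
  pepA <- substr(orf$aa, 3, 14)
  pepB <- substr(orf$aa, 31, 44)
  two <- rbind(psm_row(pepA, orf$orf_id), psm_row(pepB, orf$orf_id))
  m <- map_psms(two, db)
  ev <- aggregate_to_proteins(m, two)
  expect_identical(ev$status[ev$orf_id == orf$orf_id], "validated")

  # one peptide seen 50 times is still a one-hit wonder
  one <- psm_row(pepA, orf$orf_id, sc = 50L)
  m1 <- map_psms(one, db)
  ev1 <- aggregate_to_proteins(m1, one)
  row <- ev1[ev1$orf_id == orf$orf_id, ]
  expect_identical(row$status, "one_hit")
  expect_identical(row$total_spectra, 50L)

  # statuses partition ORFs
  filtered <- filter_psms(fx$ps$psms)
  mm <- map_psms(filtered, db, fx$sim$genomes)
  evv <- aggregate_to_proteins(mm, filtered)
  expect_false(anyDuplicated(evv$orf_id) > 0)
  expect_true(all(evv$status %in% c("validated", "one_hit",
                                    "unsupported")))
  expect_true(all(evv$status[evv$n_peptides >= 2] == "validated"))
  expect_true(all(evv$status[evv$n_peptides == 1] == "one_hit"))
})
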