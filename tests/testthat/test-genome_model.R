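test_that("coords_to_length reproduces published coordinate arithmetic", {
  # reading-direction convention: minus strand iff start > stop
  expect_identical(coords_to_length(300016, 300507), 164L)
  expect_identical(coords_to_length(358784, 358125), 220L)
  expect_identical(coords_to_length(100, 102), 1L)
  expect_error(coords_to_length(1, 5), "divisible")
})

test_that("genome FASTA I/O round-trips with case normalisation", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">repA circular thing", "acgtACGT", ">repB", "GGGCCCAAATTT"),
             tmp)
  g <- read_genome(tmp)
  expect_length(g, 2)
  expect_identical(g[["repA"]]$sequence, "ACGTACGT")
  expect_identical(nchar(g[["repB"]]$sequence), 12L)

  set.seed(11)
  tmp2 <- tempfile(fileext = ".fa")
  big <- list(genome_record("chr", random_dna(50000)))
  names(big) <- "chr"
  write_genome(big, tmp2)
  again <- read_genome(tmp2)
  expect_identical(again[["chr"]]$sequence, big[["chr"]]$sequence)

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTQQ"), bad)
  expect_error(read_genome(bad), "x")
})

test_that("extract_and_translate honours strand, initiators and stops", {
  g <- genome_record("r", "ATGAAATAA")
  expect_identical(
    extract_and_translate(g, list(start_coord = 1, stop_coord = 9)), "MK")
  # the same CDS read from the minus strand of the reverse complement
  grc <- genome_record("r", oracle_revcomp("ATGAAATAA"))
  expect_identical(
    extract_and_translate(grc, list(start_coord = 9, stop_coord = 1)), "MK")
  # GTG initiator rendered as Met only at position 1
  g2 <- genome_record("r", "GTGGTGAAATAA")
  expect_identical(
    extract_and_translate(g2, list(start_coord = 1, stop_coord = 12)),
    "MVK")
  # internal stop carries its genomic position
  g3 <- genome_record("r", "ATGTAAAAATAA")
  expect_error(
    extract_and_translate(g3, list(start_coord = 1, stop_coord = 12)),
    "position 4")
  # ambiguity codes translate to X
  g4 <- genome_record("r", "ATGANAAAA")
  expect_identical(
    extract_and_translate(g4, list(start_coord = 1, stop_coord = 9)),
    "MXK")
})

test_that("random CDS translations match the codon-by-codon oracle", {
  set.seed(42)
  g <- genome_record("chr", random_dna(9000))
  for (k in 1:300) {
    len <- 3 * sample(5:60, 1)
    lo <- sample(seq_len(9000 - len), 1)
    strand <- sample(c(1, -1), 1)
    cds <- if (strand == 1) {
      list(start_coord = lo, stop_coord = lo + len - 1)
    } else {
      list(start_coord = lo + len - 1, stop_coord = lo)
    }
    dna <- substr(g$sequence, lo, lo + len - 1)
    if (strand == -1) dna <- oracle_revcomp(dna)
    exp_aa <- oracle_translate(dna)
    if (grepl("\\*", substr(exp_aa, 1, nchar(exp_aa) - 1))) {
      expect_error(extract_and_translate(g, cds), "internal stop")
    } else {
      got <- extract_and_translate(g, cds)
      want <- sub("\\*$", "", exp_aa)
      if (substr(dna, 1, 3) %in% c("GTG", "TTG") && nchar(want) > 0) {
        substr(want, 1, 1) <- "M"
      }
      expect_identical(got, want)
    }
  }
})

test_that("GFF3 and TSV annotation dialects convert strand conventions", {
  tmp <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t358125\t358784\t.\t-\t0\tID=SPO_PG005;locus_tag=SPO_PG005",
    "chr\tsrc\tCDS\t300016\t300507\t.\t+\t0\tID=SPOA_PG001;locus_tag=SPOA_PG001"),
    tmp)
  ann <- read_annotation(tmp)
  minus <- ann[ann$locus_tag == "SPO_PG005", ]
  expect_identical(minus$start_coord, 358784L)
  expect_identical(minus$stop_coord, 358125L)
  plus <- ann[ann$locus_tag == "SPOA_PG001", ]
  expect_identical(plus$start_coord, 300016L)
  expect_identical(plus$stop_coord, 300507L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\treplicon\tstart\tstop",
               "g1\tchr\t400\t299"), tsv)
  ann2 <- read_annotation(tsv)
  expect_identical(ann2$start_coord, 400L)
  expect_identical(ann2$stop_coord, 299L)

  empty <- tempfile(fileext = ".tsv")
  writeLines("locus_tag\treplicon\tstart\tstop", empty)
  expect_identical(nrow(read_annotation(empty)), 0L)
})

test_that("annotation round-trips through GFF3 and flags bad spans", {
  genomes <- list(chr = genome_record("chr", random_dna(2000)))
  ann <- read_annotation({
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("locus_tag\treplicon\tstart\tstop",
                 "gA\tchr\t10\t309", "gB\tchr\t900\t601"), tsv)
    tsv
  }, genomes)
  out <- tempfile(fileext = ".gff3")
  write_annotation(ann, out, genomes)
  back <- read_annotation(out, genomes)
  expect_identical(back$locus_tag, ann$locus_tag)
  expect_identical(back$start_coord, ann$start_coord)
  expect_identical(back$stop_coord, ann$stop_coord)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\treplicon\tstart\tstop", "gX\tchr\t10\t13"), bad)
  expect_warning(annb <- read_annotation(bad, genomes), "flagged")
  expect_true(annb$flag[1])    # kept, not dropped
})

test_that("strand symmetry: mirroring genome and annotation preserves proteins", {
  set.seed(5)
  fx <- make_fixture(seed = 5)
  genes <- fx$gen$ledger$genes
  g <- fx$gen$genomes[[1]]
  L <- nchar(g$sequence)
  grc <- genome_record("chr", oracle_revcomp(g$sequence))
  for (i in sample(nrow(genes), 10)) {
    aa1 <- extract_and_translate(g, list(start_coord = genes$start_coord[i],
                                         stop_coord = genes$stop_coord[i]))
    aa2 <- extract_and_translate(grc, list(
      start_coord = L - genes$start_coord[i] + 1L,
      stop_coord = L - genes$stop_coord[i] + 1L))
    expect_identical(aa1, aa2)
  }
})
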