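test_that("frame-split candidates require same strand, distinct frames", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, fx$db, sim$genomes)
  full <- mapped[mapped$tryptic_status == "full", ]
  ev <- aggregate_to_proteins(mapped, filtered)
  ann_orfs <- suppressWarnings(
    containing_orf(sim$annotation_published, fx$db, sim$genomes))
  cands <- detect_frame_split_candidates(full, fx$db,
                                         annotated_orfs = na.omit(ann_orfs),
                                         evidence = ev)
  expect_gt(length(cands), 0)
  for (cand in cands) {
    up <- proteoseed:::parse_orf_id(cand$orf_up)
    down <- proteoseed:::parse_orf_id(cand$orf_down)
    expect_identical(sign(up$frame), sign(down$frame))
    expect_false(up$frame == down$frame)
    expect_lte(cand$interval_hi - cand$interval_lo + 1L,
               pipeline_config()$frame_gap_max_nt)
  }
})

test_that("planted base insertions are resolved within the homopolymer run", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  r <- suppressWarnings(suppressMessages(
    refine_annotation(fx$ps$psms, fx$db, sim$annotation_published,
                      sim$genomes, transcription = fx$ps$transcription)))
  err <- sim$ledger$errors
  ins <- err[err$category == "base_insertion", ]
  expect_identical(length(r$seq_errors), nrow(ins))
  for (i in seq_len(nrow(ins))) {
    hit <- FALSE
    for (evn in r$seq_errors) {
      for (sc in evn$calls) {
        if (sc$mode == "deletion" &&
            sc$interval[1] <= ins$inserted_pos[i] &&
            sc$interval[2] >= ins$inserted_pos[i]) {
          hit <- TRUE
          # the equivalence interval spans at least the homopolymer run
          expect_lte(sc$interval[1], ins$run_lo[i])
          expect_gte(sc$interval[2], ins$run_hi[i])
          # the corrected protein carries every supporting peptide and
          # equals the true unbroken protein of the planted gene
          # deleting the truly inserted base reproduces the unbroken
          # protein exactly (equivalent deletions elsewhere in the
          # interval yield the same peptides but may differ in unobserved
          # junction residues, hence only peptide containment is asserted
          # on the stored call)
          genes <- sim$ledger$genes
          gi <- match(ins$gene_id[i], genes$gene_id)
          g <- sim$genomes[[sc$replicon_id]]
          p <- ins$inserted_pos[i]
          fixed_seq <- paste0(substr(g$sequence, 1, p - 1),
                              substr(g$sequence, p + 1,
                                     nchar(g$sequence)))
          gfix <- genome_record(g$replicon_id, fixed_seq)
          adj <- function(x) ifelse(x > p, x - 1L, x)
          refit <- extract_and_translate(gfix, list(
            start_coord = adj(genes$start_coord[gi]),
            stop_coord = adj(genes$stop_coord[gi])))
          expect_identical(refit, genes$protein[gi])
          for (pep in sc$peptides) {
            expect_true(grepl(pep, sc$corrected_protein, fixed = TRUE))
          }
        }
      }
    }
    expect_true(hit)
  }
})

test_that("applying an accepted deletion removes the frame split", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  r <- suppressWarnings(suppressMessages(
    refine_annotation(fx$ps$psms, fx$db, sim$annotation_published,
                      sim$genomes, transcription = fx$ps$transcription)))
  evn <- r$seq_errors[[1]]
  sc <- evn$calls[[1]]
  g <- sim$genomes[[sc$replicon_id]]
  p <- sc$interval[1]
  fixed_seq <- paste0(substr(g$sequence, 1, p - 1),
                      substr(g$sequence, p + 1, nchar(g$sequence)))
  genomes2 <- list(genome_record(sc$replicon_id, fixed_seq))
  names(genomes2) <- sc$replicon_id
  db2 <- build_search_db(enumerate_orfs(genomes2))
  # the supporting peptides now co-locate in a single ORF
  hits <- proteoseed:::peptide_db_hits(sc$peptides, db2)
  expect_identical(length(unique(hits$orf_id[!startsWith(hits$orf_id,
                                                         "CONTAM_")])),
                   1L)
})

test_that("a candidate that no single edit can fuse returns nothing", {
  set.seed(61)
  genomes <- list(chr = genome_record("chr", random_dna(3000)))
  cand <- list(orf_up = "chr:+1:1-300", orf_down = "chr:+2:401-700",
               replicon_id = "chr", strand = 1L,
               interval_lo = 301L, interval_hi = 400L,
               peptides = c("WWWWWWWWWW", "YYYYYYYYYY"))
  expect_null(resolve_sequence_error(cand, genomes))
})

test_that("an error-free simulation yields no sequencing-error events", {
  fx <- make_fixture(seed = 71,
                     error_counts = c(missed_gene = 2, wrong_start_long = 1,
                                      wrong_start_short = 1,
                                      spurious_cds = 1, base_insertion = 0))
  r <- suppressWarnings(suppressMessages(
    refine_annotation(fx$ps$psms, fx$db, fx$sim$annotation_published,
                      fx$sim$genomes,
                      transcription = fx$ps$transcription)))
  expect_identical(length(r$seq_errors), 0L)
})

test_that("shortening a detected gene resolves a 5' overlap when possible", {
  fx <- make_fixture(seed = 6)
  sim <- fx$sim
  db <- fx$db
  filtered <- filter_psms(fx$ps$psms)
  mapped <- map_psms(filtered, db, sim$genomes)
  # construct the overlap pattern: a detected annotated gene whose own
  # peptides all sit well downstream, conflicting with a call upstream
  ann <- sim$annotation_published
  genes <- sim$ledger$genes
  normal <- genes[genes$category == "none", ]
  found <- FALSE
  for (i in seq_len(nrow(normal))) {
    oid <- suppressWarnings(containing_orf(
      ann[ann$locus_tag == normal$gene_id[i], ], db, sim$genomes))
    if (is.na(oid)) next
    cds <- ann[ann$locus_tag == normal$gene_id[i], ]
    strand <- if (cds$start_coord > cds$stop_coord) -1L else 1L
    orf <- db$orfs[db$orfs$orf_id == oid, ]
    k_cds <- abs(cds$start_coord - orf$span_start) %/% 3 + 1
    # emulate the published pattern: the gene's first validated peptide
    # sits far downstream of the annotated start, and a new call overlaps
    # only that undetected 5' region
    mapped2 <- mapped[!(mapped$orf_id == oid &
                          mapped$aa_offset0 < k_cds + 40), ]
    own <- mapped2[mapped2$orf_id == oid &
                     mapped2$tryptic_status == "full", ]
    if (nrow(own) == 0) next
    conflict <- proteoseed:::call_row(
      "novel_cds", orf_id = "synthetic:conflict",
      replicon_id = cds$replicon_id,
      new_start = cds$start_coord,
      new_stop = cds$start_coord + strand * 29L)
    sh <- shorten_conflicting_cds(normal$gene_id[i], conflict, mapped2,
                                  ann, db, sim$genomes)
    expect_true(sh$category %in% c("start_corrected", "conflict"))
    if (sh$category == "start_corrected") {
      found <- TRUE
      lo <- min(sh$new_start, sh$new_stop)
      hi <- max(sh$new_start, sh$new_stop)
      expect_false(lo <= max(conflict$new_start, conflict$new_stop) &&
                     hi >= min(conflict$new_start, conflict$new_stop))
      expect_true(sh$start_codon %in% c("ATG", "GTG", "TTG"))
    }
  }
  expect_true(found)

  # a peptide inside the overlap region is irreconcilable
  gid <- normal$gene_id[1]
  cds <- ann[ann$locus_tag == gid, ]
  whole <- proteoseed:::call_row(
    "novel_cds", orf_id = "synthetic:conflict2",
    replicon_id = cds$replicon_id,
    new_start = cds$start_coord, new_stop = cds$stop_coord)
  sh2 <- shorten_conflicting_cds(gid, whole, mapped, ann, db, sim$genomes)
  expect_identical(sh2$category, "conflict")
})
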