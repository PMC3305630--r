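# End-to-end orchestration: filter -> map -> aggregate -> frameshift
# resolution -> classification -> one-hit handling -> N-terminus
# validation -> reporting.

#' Refine an annotation from PSM evidence
#'
#' Runs the complete refinement stage in memory: PSMs are filtered
#' (rank 1, p below the identity threshold), mapped onto the genome,
#' aggregated to protein-level evidence; frameshift candidates are
#' resolved into sequencing-error calls (their ORFs are then excluded from
#' novel-gene classification); validated unannotated ORFs are classified
#' as novel genes, replacements of wrong CDSs, or conflicts; one-hit
#' wonders are screened and optionally promoted by transcription evidence;
#' strictly tryptic upstream peptides yield N-terminal extensions and
#' semi-tryptic N-terminal peptides confirm or correct start codons;
#' conflicts with detected genes are attempted to be resolved by
#' shortening. New loci are named `{replicon}_PG{NNN}` in coordinate
#' order.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param db An `orf_db` built from the same genome.
#' @param annotation The published `annotation_set`.
#' @param genomes Named list of [genome_record()]s.
#' @param config A [pipeline_config()].
#' @param homology_support Optional named logical vector by locus_tag.
#' @param transcription Optional transcription-evidence table (`orf_id`,
#'   `transcribed`) for one-hit candidates.
#' @return List of class `refinement_result`: `calls` (ordered calls data
#'   frame with `locus_tag` assigned for new genes), `seq_errors` (list of
#'   `seq_error_call`), `evidence`, `mapped`, `start_usage`, `config`.
#' @export
refine_annotation <- function(psms, db, annotation, genomes,
                              config = pipeline_config(),
                              homology_support = NULL,
                              transcription = NULL) {
  filtered <- filter_psms(psms, config$psm_p_max)
  mapped <- map_psms(filtered, db, genomes)
  ev <- aggregate_to_proteins(mapped, filtered)
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  det_spans <- detected_gene_spans(ev, mapped, annotation, db, genomes)

  fs <- detect_frame_split_candidates(
    mapped[mapped$tryptic_status == "full", , drop = FALSE], db, config,
    annotated_orfs = stats::na.omit(ann_orfs), evidence = ev,
    detected_spans = det_spans)
  seq_errors <- list()
  seqerr_orfs <- character(0)
  for (cand in fs) {
    res <- resolve_sequence_error(cand, genomes, config = config)
    if (!is.null(res)) {
      # one event per candidate pair; all ranked equivalent solutions kept
      seq_errors[[length(seq_errors) + 1L]] <-
        list(orf_up = cand$orf_up, orf_down = cand$orf_down,
             replicon_id = cand$replicon_id, calls = res)
      seqerr_orfs <- c(seqerr_orfs, cand$orf_up, cand$orf_down)
    }
  }
  cls <- classify_detected_orfs(ev, mapped, annotation, db, genomes,
                                homology_support, config,
                                exclude_orfs = seqerr_orfs)
  onehit <- one_hit_wonder_candidates(ev, mapped, annotation, db, genomes,
                                      det_spans, config,
                                      exclude_orfs = seqerr_orfs)
  if (!is.null(transcription)) {
    onehit <- accept_with_transcription(onehit, transcription)
  }
  ext <- nterm_extension_scan(mapped, annotation, db, genomes, det_spans,
                              config)
  semi <- validate_starts_semitryptic(mapped, annotation, db, genomes,
                                      config)

  # try to resolve conflicts by shortening the detected gene
  resolved <- list()
  conflicts <- which(cls$category == "conflict")
  for (ci in conflicts) {
    note <- cls$note[ci]
    loci <- sub("^overlaps detected/homology-supported: ", "", note)
    loci <- strsplit(loci, ",")[[1]]
    loci <- loci[loci %in% annotation$locus_tag]
    all_ok <- length(loci) > 0
    for (lt in loci) {
      sh <- shorten_conflicting_cds(lt, cls[ci, ], mapped, annotation, db,
                                    genomes, config)
      resolved[[length(resolved) + 1L]] <- sh
      if (sh$category != "start_corrected") all_ok <- FALSE
    }
    if (all_ok) {
      cls$category[ci] <- "novel_cds"
      cls$note[ci] <- paste("overlap resolved by shortening",
                            paste(loci, collapse = ","))
    }
  }
  shorten_calls <- rbind_calls(resolved)

  calls <- rbind(cls, onehit, ext, semi, shorten_calls)
  # drop duplicate start corrections reached by both the extension and the
  # semi-tryptic route
  is_start <- calls$category %in% c("start_corrected", "nterm_extension")
  dup <- is_start & duplicated(paste(calls$locus_tag, calls$new_start)) &
    !is.na(calls$new_start)
  calls <- calls[!dup, , drop = FALSE]
  ord <- order(calls$replicon_id,
               pmin(calls$new_start, calls$new_stop, na.rm = FALSE),
               calls$category)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  new_gene <- calls$category %in% c("novel_cds", "wrong_cds_replacement",
                                    "one_hit_candidate")
  if (any(new_gene)) {
    calls$locus_tag[new_gene] <- sprintf("%s_PG%03d",
                                         calls$replicon_id[new_gene],
                                         seq_len(sum(new_gene)))
  }
  structure(list(calls = calls, seq_errors = seq_errors, evidence = ev,
                 mapped = mapped, start_usage = start_codon_usage(calls),
                 config = config),
            class = "refinement_result")
}

#' Residue coverage of a protein by mapped peptides
#'
#' Percentage of residues covered by at least one mapped peptide, rounded
#' half-up to an integer percent.
#'
#' @param protein_len Protein length in residues.
#' @param offsets0 0-based peptide start offsets.
#' @param pep_lens Peptide lengths, parallel to `offsets0`.
#' @return Integer percent.
#' @export
coverage_pct <- function(protein_len, offsets0, pep_lens) {
  if (protein_len <= 0) return(0L)
  covered <- logical(protein_len)
  for (i in seq_along(offsets0)) {
    lo <- offsets0[i] + 1L
    hi <- min(protein_len, offsets0[i] + pep_lens[i])
    if (lo <= protein_len) covered[lo:hi] <- TRUE
  }
  as.integer(floor(100 * mean(covered) + 0.5))
}

#' Write report tables for a refinement result
#'
#' Emits a call table in the style of a novel-gene summary (target,
#' category, plausible CDS start, stop, length in amino acids, peptides
#' assigned, percent proteomic coverage), an optional clade hit table, a
#' plain-text summary (counts per category, start-codon usage, decoy FDR
#' when supplied) and a revised GFF3 with corrections applied.
#'
#' @param result A `refinement_result`.
#' @param outdir Output directory (created if missing).
#' @param db The `orf_db` used (for coverage computation).
#' @param annotation The published annotation (revised GFF3 basis).
#' @param genomes Genome records (GFF3 pragmas).
#' @param clade_hits Optional data frame from [find_unannotated_homologs()].
#' @param fdr Optional named numeric (e.g. peptide/protein decoy FDR
#'   fractions) echoed in the summary.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_reports <- function(result, outdir, db, annotation, genomes,
                          clade_hits = NULL, fdr = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  calls <- result$calls
  mapped <- result$mapped
  cov <- vapply(seq_len(nrow(calls)), function(i) {
    oid <- calls$orf_id[i]
    if (is.na(oid) || !oid %in% db$orfs$orf_id) return(NA_integer_)
    if (is.na(calls$new_start[i]) || is.na(calls$new_stop[i])) {
      return(NA_integer_)
    }
    orf <- db$orfs[db$orfs$orf_id == oid, ]
    m <- mapped[mapped$orf_id == oid, , drop = FALSE]
    k0 <- abs(calls$new_start[i] - orf$span_start) %/% 3L  # 0-based
    plen <- coords_to_length(calls$new_start[i], calls$new_stop[i]) - 1L
    keep <- m$aa_offset0 >= k0
    coverage_pct(plen, m$aa_offset0[keep] - k0, nchar(m$peptide[keep]))
  }, integer(1))
  tab <- data.frame(
    target = ifelse(is.na(calls$locus_tag), calls$orf_id, calls$locus_tag),
    category = calls$category,
    cds_start = calls$new_start,
    stop = calls$new_stop,
    length_aa = ifelse(is.na(calls$new_start) | is.na(calls$new_stop),
                       NA_integer_,
                       (abs(calls$new_stop - calls$new_start) + 1L) %/% 3L),
    peptides_assigned = calls$n_peptides,
    coverage_pct = cov,
    displaced_locus = calls$displaced_locus,
    nterm_category = calls$nterm_category,
    start_codon = calls$start_codon,
    note = calls$note,
    stringsAsFactors = FALSE)
  calls_path <- file.path(outdir, "calls.tsv")
  write.table(tab, calls_path, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(calls = calls_path)
  if (!is.null(clade_hits)) {
    clade_path <- file.path(outdir, "clade_novel_hits.tsv")
    write.table(clade_hits, clade_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, clade = clade_path)
  }

  # revised annotation
  rev_ann <- annotation
  displaced <- unlist(strsplit(stats::na.omit(calls$displaced_locus), ","))
  rev_ann <- rev_ann[!rev_ann$locus_tag %in% displaced, , drop = FALSE]
  fix <- calls$category %in% c("start_corrected", "nterm_extension") &
    !is.na(calls$new_start) & !is.na(calls$locus_tag)
  for (i in which(fix)) {
    j <- match(calls$locus_tag[i], rev_ann$locus_tag)
    if (!is.na(j)) rev_ann$start_coord[j] <- calls$new_start[i]
  }
  add <- calls$category %in% c("novel_cds", "wrong_cds_replacement") &
    !is.na(calls$new_start)
  if (any(add)) {
    rev_ann <- rbind(rev_ann, data.frame(
      locus_tag = calls$locus_tag[add],
      replicon_id = calls$replicon_id[add],
      start_coord = calls$new_start[add],
      stop_coord = calls$new_stop[add],
      product = "hypothetical protein, proteogenomic",
      source = "proteogenomic", flag = FALSE, stringsAsFactors = FALSE))
  }
  gff_path <- file.path(outdir, "revised.gff3")
  write_annotation(rev_ann, gff_path, genomes)
  paths <- c(paths, gff = gff_path)

  counts <- table(calls$category)
  summary_lines <- c(
    "proteoseed refinement summary",
    sprintf("calls: %s",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = " ")),
    sprintf("sequencing errors resolved: %d", length(result$seq_errors)))
  su <- result$start_usage
  if (nrow(su) > 0) {
    summary_lines <- c(summary_lines, sprintf(
      "start codon usage: %s",
      paste(sprintf("%s %.1f%%", su$codon, su$percent), collapse = " ")))
  }
  if (!is.null(fdr)) {
    summary_lines <- c(summary_lines, sprintf(
      "decoy FDR: %s",
      paste(sprintf("%s %.2f%%", names(fdr), 100 * fdr), collapse = " ")))
  }
  sum_path <- file.path(outdir, "summary.txt")
  writeLines(summary_lines, sum_path)
  c(paths, summary = sum_path)
}

#' Run the pipeline from files
#'
#' Thin file-level orchestration over the in-memory stages: reads genome,
#' annotation and PSM evidence, builds (or reuses) the six-frame database,
#' maps and refines, writes reports and a run manifest. The database stage
#' is cached by input digest: rerunning with identical inputs reuses
#' `db.fa` and reproduces identical call tables.
#'
#' @param genome_path FASTA genome.
#' @param annotation_path GFF3 or TSV published annotation.
#' @param psm_path PSM TSV.
#' @param outdir Output directory.
#' @param config A [pipeline_config()].
#' @param contaminant_path Optional contaminant FASTA.
#' @param decoy_psm_path Optional decoy PSM TSV (enables FDR reporting).
#' @param homology_path Optional TSV (`locus_tag`, `supported`).
#' @param transcription_path Optional TSV (`orf_id`, `transcribed`).
#' @return The run manifest (list): config snapshot, input digests, stage
#'   timings (seconds), output paths, package version.
#' @export
run_pipeline <- function(genome_path, annotation_path, psm_path, outdir,
                         config = pipeline_config(),
                         contaminant_path = NULL, decoy_psm_path = NULL,
                         homology_path = NULL, transcription_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  digests <- tools::md5sum(c(genome_path, annotation_path, psm_path))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  genomes <- read_genome(genome_path)
  annotation <- read_annotation(annotation_path, genomes)
  psms <- read_psm_table(psm_path)
  timings["read"] <- tic() - t0

  db_path <- file.path(outdir, "db.fa")
  stamp_path <- file.path(outdir, "db.digest")
  t0 <- tic()
  genome_digest <- unname(digests[genome_path])
  reuse <- file.exists(db_path) && file.exists(stamp_path) &&
    identical(readLines(stamp_path, n = 1L), genome_digest)
  if (reuse) {
    db <- read_search_db(db_path, config$min_orf_aa)
  } else {
    orfs <- enumerate_orfs(genomes, min_length_aa = config$min_orf_aa)
    db <- build_search_db(orfs, contaminant_path, out = db_path,
                          min_length_aa = config$min_orf_aa)
    writeLines(genome_digest, stamp_path)
  }
  timings["build_db"] <- tic() - t0

  homology <- NULL
  if (!is.null(homology_path)) {
    h <- read.delim(homology_path, stringsAsFactors = FALSE)
    homology <- setNames(as.logical(h$supported), h$locus_tag)
  }
  transcription <- NULL
  if (!is.null(transcription_path)) {
    transcription <- read.delim(transcription_path,
                                stringsAsFactors = FALSE)
  }
  t0 <- tic()
  result <- refine_annotation(psms, db, annotation, genomes, config,
                              homology_support = homology,
                              transcription = transcription)
  timings["refine"] <- tic() - t0

  fdr <- NULL
  if (!is.null(decoy_psm_path)) {
    decoys <- filter_psms(read_psm_table(decoy_psm_path), config$psm_p_max)
    filtered <- filter_psms(psms, config$psm_p_max)
    fdr <- c(peptide = decoy_fdr(filtered, decoys, "peptide"),
             protein = decoy_fdr(filtered, decoys, "protein"))
  }
  t0 <- tic()
  paths <- write_reports(result, outdir, db, annotation, genomes,
                         fdr = fdr)
  timings["report"] <- tic() - t0

  manifest <- list(config = unclass(config), digests = digests,
                   timings = timings, outputs = paths,
                   version = as.character(utils::packageVersion("proteoseed")))
  manifest_path <- file.path(outdir, "manifest.dcf")
  write.dcf(data.frame(
    genome_md5 = genome_digest,
    annotation_md5 = unname(digests[annotation_path]),
    psms_md5 = unname(digests[psm_path]),
    version = manifest$version), manifest_path)
  manifest$result <- result
  invisible(manifest)
}
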