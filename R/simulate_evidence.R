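# Peptide-evidence and sister-genome simulation on top of plant_errors().

SIM_CONDITIONS <- c("exp_rich", "stat_rich", "uv_stress", "benzoate",
                    "membrane")

draw_true_p <- function(n) 10^runif(n, -9, -4)

# one semi-tryptic N-terminal peptide for a protein: intact (start 1) or
# Met-excised (start 2); NULL when no tryptic C-terminus gives a peptide
# of workable length
semi_nterm_peptide <- function(protein, removed, min_len = 6L,
                               max_len = 40L) {
  s <- if (removed) 2L else 1L
  ct <- tryptic_cterm_positions(protein)
  ct <- ct[ct - s + 1L >= min_len & ct - s + 1L <= max_len]
  if (length(ct) == 0) return(NULL)
  substr(protein, s, ct[1])
}

#' Simulate peptide-spectrum matches against an ORF database
#'
#' Expressed genes are drawn gene-wise; their true proteins (including
#' genes absent from the published annotation and the unbroken protein
#' across planted base insertions) are digested and peptides detected with
#' the configured probabilities. Genes carrying planted errors always
#' receive their diagnostic evidence: at least two distinct peptides for
#' missed and displaced genes, the most N-terminal tryptic peptide for
#' truncated annotations, a semi-tryptic N-terminal peptide for
#' overextended annotations, and peptides on both sides of a planted
#' insertion. One-hit genes receive exactly one high-confidence peptide.
#' Random (false) matches and a mirrored reversed-decoy table are injected
#' at the configured rate among confident identifications, with additional
#' sub-threshold random matches so the identity filter is exercised.
#'
#' @param sim Output of [plant_errors()].
#' @param db The `orf_db` built from the published (mutated) genome.
#' @param config A [simulation_config()].
#' @return List `psms`, `decoy_psms` (PSM data frames),
#'   `transcription` (data frame `orf_id`, `transcribed` for one-hit
#'   loci), and `expressed` (gene ids drawn as expressed).
#' @export
simulate_psms <- function(sim, db, config = simulation_config()) {
  set.seed(config$seed + 2L)
  genes <- sim$ledger$genes
  n <- nrow(genes)
  forced <- genes$category != "none"
  expressed <- runif(n) < config$gene_detect_p | forced
  rows <- list()
  add_row <- function(pep, status = "full", p = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, orf_id = NA_character_,
      p_value = if (is.null(p)) draw_true_p(1) else p,
      rank = 1L,
      spectral_count = rnbinom(1, size = config$spectral_size,
                               mu = config$spectral_mu) + 1L,
      condition = sample(SIM_CONDITIONS, 1L),
      tryptic_status = status, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    if (!expressed[i]) next
    prot <- genes$protein[i]
    cat <- genes$category[i]
    if (cat == "one_hit") {
      peps <- tryptic_digest(prot)$sequence
      if (length(peps) == 0) next
      add_row(sample(peps, 1L), p = 10^runif(1, -9, -5))
      next
    }
    digest <- tryptic_digest(prot)
    det <- runif(nrow(digest)) < config$pep_detect_p
    if (cat %in% c("missed_gene", "spurious_cds") && sum(det) < 2L &&
        nrow(digest) >= 2L) {
      det[sample(nrow(digest), 2L)] <- TRUE
    }
    if (cat == "spurious_cds") {
      # the discordance with the fake overlapping CDS is only visible when
      # a peptide covers the 5' conflict region
      first <- which(digest$start_offset == 0L)
      if (length(first) > 0) {
        det[first[1]] <- TRUE
      } else {
        fr <- tryptic_fragments(prot)
        e <- if (fr$end[1] >= 6L || length(fr$end) < 2L) fr$end[1]
             else fr$end[2]
        add_row(substr(prot, 1L, e))
      }
    }
    if (cat == "wrong_start_short") {
      # guarantee the most N-terminal tryptic peptide; fall back to the
      # first+second fragment when the first alone is too short
      first <- which(digest$start_offset == 0L)
      if (length(first) > 0) {
        det[first[1]] <- TRUE
      } else {
        fr <- tryptic_fragments(prot)
        e <- if (fr$end[1] >= 6L || length(fr$end) < 2L) fr$end[1]
             else fr$end[2]
        add_row(substr(prot, 1L, e))
      }
      if (sum(det) < 2L && nrow(digest) >= 2L) {
        det[sample(nrow(digest), 2L)] <- TRUE
      }
    }
    p_override <- rep(NA_real_, nrow(digest))
    if (cat == "base_insertion") {
      err <- sim$ledger$errors
      err <- err[err$gene_id == genes$gene_id[i], ]
      off_nt <- abs(err$inserted_pos - genes$start_coord[i])
      r_break <- off_nt %/% 3L
      pend <- digest$start_offset + nchar(digest$sequence)
      # diagnostic peptides: the two upstream peptides closest to the
      # break, and the downstream peptide closest to it, identified at
      # high confidence (the reported real cases are exactly those whose
      # bridging peptide was a confident single identification)
      up_idx <- which(pend <= r_break - 2L)
      up_idx <- up_idx[order(-pend[up_idx])]
      down_idx <- which(digest$start_offset >= r_break + 2L)
      down_idx <- down_idx[order(digest$start_offset[down_idx])]
      det[head(up_idx, 2L)] <- TRUE
      if (length(down_idx) > 0) {
        det[down_idx[1]] <- TRUE
        p_override[down_idx[1]] <- 10^runif(1, -9, -5)
      }
    }
    for (kk in which(det)) {
      add_row(digest$sequence[kk],
              p = if (is.na(p_override[kk])) NULL else p_override[kk])
    }
    # semi-tryptic N-terminal peptide
    nterm <- runif(1) < config$nterm_detect_p ||
      cat == "wrong_start_long"
    if (nterm && cat != "base_insertion") {
      removed <- genes$start_codon[i] == "TTG" ||
        runif(1) < config$met_removed_p
      sp <- semi_nterm_peptide(prot, removed)
      if (!is.null(sp)) add_row(sp, status = "semi_N")
    }
  }
  psms <- if (length(rows) == 0) {
    data.frame(peptide = character(), orf_id = character(),
               p_value = numeric(), rank = integer(),
               spectral_count = integer(), condition = character(),
               tryptic_status = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)

  # resolve each peptide's database entry; peptides absent from the
  # database (e.g. spanning a planted insertion break) are dropped, as a
  # search engine would never report them
  if (nrow(psms) > 0) {
    hits <- peptide_db_hits(unique(psms$peptide), db)
    semi_miss <- setdiff(unique(psms$peptide[psms$tryptic_status ==
                                               "semi_N"]), hits$peptide)
    if (length(semi_miss) > 0) {
      hits <- rbind(hits, semi_retained_hits(semi_miss, db))
    }
    first_hit <- hits[!duplicated(hits$peptide), ]
    psms$orf_id <- first_hit$orf_id[match(psms$peptide, first_hit$peptide)]
    psms <- psms[!is.na(psms$orf_id), , drop = FALSE]
  }

  # random matches: confident ones at the planted rate among distinct true
  # identifications, sub-threshold ones on top (the raw random-match
  # p-value spectrum is roughly uniform up to 0.05, of which the window
  # below 0.005 survives the identity filter)
  n_true <- length(unique(psms$peptide))
  r <- config$false_psm_rate
  random_match <- function(n_conf, n_junk, decoy = FALSE) {
    total <- n_conf + n_junk
    if (total == 0 || nrow(db$orfs) == 0) return(NULL)
    out <- vector("list", total)
    for (k in seq_len(total)) {
      orf <- db$orfs[sample(nrow(db$orfs), 1L), ]
      aa <- if (decoy) paste(rev(strsplit(orf$aa, "")[[1]]), collapse = "")
            else orf$aa
      dg <- tryptic_digest(aa)
      if (nrow(dg) == 0) next
      pep <- dg$sequence[sample(nrow(dg), 1L)]
      p <- if (k <= n_conf) runif(1, 1e-4, 0.005) else runif(1, 0.005, 0.05)
      out[[k]] <- data.frame(
        peptide = pep,
        orf_id = if (decoy) paste0("DECOY_", orf$orf_id) else orf$orf_id,
        p_value = p, rank = 1L,
        spectral_count = 1L, condition = sample(SIM_CONDITIONS, 1L),
        tryptic_status = "full", stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) NULL else do.call(rbind, out)
  }
  fp <- random_match(rbinom(1, n_true, r), rbinom(1, n_true, 9 * r))
  if (!is.null(fp)) psms <- rbind(psms, fp)
  decoys <- random_match(rbinom(1, n_true, r), rbinom(1, n_true, 9 * r),
                         decoy = TRUE)
  decoy_psms <- if (is.null(decoys)) psms[0, ] else decoys
  rownames(psms) <- NULL

  onehit <- genes[genes$category == "one_hit", , drop = FALSE]
  transcription <- data.frame(orf_id = character(), transcribed = logical(),
                              stringsAsFactors = FALSE)
  if (nrow(onehit) > 0) {
    ann_oh <- new_annotation_set(data.frame(
      locus_tag = onehit$gene_id, replicon_id = onehit$replicon_id,
      start_coord = onehit$start_coord, stop_coord = onehit$stop_coord,
      product = NA_character_, source = "original",
      stringsAsFactors = FALSE))
    oh_orfs <- suppressWarnings(containing_orf(ann_oh, db, sim$genomes))
    transcription <- data.frame(
      orf_id = oh_orfs,
      transcribed = onehit$gene_id %in% sim$ledger$transcribed_one_hit,
      stringsAsFactors = FALSE)
    transcription <- transcription[!is.na(transcription$orf_id), ]
  }
  list(psms = psms, decoy_psms = decoy_psms, transcription = transcription,
       expressed = genes$gene_id[expressed])
}

#' Simulate a clade of sister genomes with planted start errors
#'
#' Subject genomes are derived gene by gene from the true gene set:
#' residues are substituted at the configured amino-acid divergence,
#' codons are resampled (adding synonymous divergence), intergenic
#' sequence is drawn fresh, and genes are occasionally lost. Subject
#' annotations carry start errors at the configured rate, either
#' overextended (an engineered upstream in-frame ATG with recoded stops,
#' the ab-initio longest-sequence bias) or truncated (an internal
#' canonical codon). Genes broken by planted insertions are excluded from
#' orthology. Deterministic given the seed.
#'
#' @param sim Output of [plant_errors()] (or [generate_genome()]).
#' @param config A [simulation_config()].
#' @return List `subjects` (named list of `list(genomes, annotation)`) and
#'   `ledger_clade` (data frame subject, gene_id, subject_locus, error in
#'   none/too_long/too_short, true_start, annotated_start, offset_codons).
#' @export
simulate_clade <- function(sim, config = simulation_config()) {
  set.seed(config$seed + 3L)
  cl <- config$clade
  stopifnot(cl$aa_divergence >= 0, cl$aa_divergence <= 0.5)
  genes <- sim$ledger$genes
  genes <- genes[!genes$frameshifted, , drop = FALSE]
  gc <- config$gc_content
  aa_pool <- setdiff(unique(vapply(SENSE_CODONS, function(cd)
    translate_str(cd), character(1))), "M")
  # codon choices per amino acid, GC-weighted
  cod_by_aa <- split(SENSE_CODONS,
                     vapply(SENSE_CODONS, function(cd) translate_str(cd),
                            character(1)))
  cod_w <- lapply(cod_by_aa, function(cands) codon_weights(cands, gc))
  # GC-weighted codon choice, vectorised over a residue vector
  pick_codons <- function(res_vec) {
    out <- character(length(res_vec))
    for (a in unique(res_vec)) {
      cands <- cod_by_aa[[a]]
      if (is.null(cands)) stop("no codon for residue ", a)
      ii <- which(res_vec == a)
      out[ii] <- if (length(cands) == 1L) cands
                 else sample(cands, length(ii), replace = TRUE,
                             prob = cod_w[[a]])
    }
    out
  }
  subjects <- list()
  ledger <- list()
  for (s in seq_len(cl$n_subjects)) {
    sname <- sprintf("subject%02d", s)
    pieces <- character(0)
    pos <- 0L
    ann_rows <- list()
    for (gi in seq_len(nrow(genes))) {
      if (runif(1) < cl$gene_loss_p) next
      prot <- genes$protein[gi]
      res <- strsplit(prot, "", fixed = TRUE)[[1]]
      mut <- which(runif(length(res)) < cl$aa_divergence)
      mut <- mut[mut > 1L]
      res[mut] <- vapply(res[mut], function(a)
        sample(setdiff(aa_pool, a), 1L), character(1))
      body <- pick_codons(res[-1L])
      stopc <- sample(STOP_CODONS, 1L, prob = c(0.3, 0.25, 0.45))
      cds <- paste(c(genes$start_codon[gi], body, stopc), collapse = "")
      strand <- genes$strand[gi]
      err <- "none"; ext <- ""
      off <- 0L
      if (runif(1) < cl$subject_start_error_rate) {
        if (runif(1) < cl$too_long_frac) {
          err <- "too_long"
          off <- sample(5:20, 1L)
          ext <- paste(c("ATG", random_sense_codons(off - 1L, gc)),
                       collapse = "")
        } else {
          err <- "too_short"
          off <- -sample(5:20, 1L)
          k <- -off + 1L  # residue index of the annotated (wrong) start
          res_k <- res
          res_k[k] <- "M"
          body <- pick_codons(res_k[-1L])
          body[k - 1L] <- "ATG"
          cds <- paste(c(genes$start_codon[gi], body, stopc), collapse = "")
        }
      }
      spacer <- random_bases(
        sample(config$intergenic_range[1]:config$intergenic_range[2], 1L),
        gc)
      pieces <- c(pieces, spacer)
      pos <- pos + nchar(spacer)
      block <- paste0(ext, cds)
      a <- pos + 1L
      b <- pos + nchar(block)
      if (strand == 1L) {
        pieces <- c(pieces, block)
        true_start <- a + nchar(ext)
        stop_coord <- b
      } else {
        pieces <- c(pieces, revcomp(block))
        true_start <- b - nchar(ext)
        stop_coord <- a
      }
      pos <- pos + nchar(block)
      ann_start <- if (err == "too_long") {
        true_start - strand * nchar(ext)
      } else if (err == "too_short") {
        true_start + strand * 3L * (-off)
      } else true_start
      tag <- sprintf("%s_%s", sname, genes$gene_id[gi])
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        locus_tag = tag, replicon_id = sname,
        start_coord = ann_start, stop_coord = stop_coord,
        product = NA_character_, source = "original",
        stringsAsFactors = FALSE)
      ledger[[length(ledger) + 1L]] <- data.frame(
        subject = sname, gene_id = genes$gene_id[gi], subject_locus = tag,
        error = err, true_start = true_start, annotated_start = ann_start,
        offset_codons = if (err == "too_long") as.integer(nchar(ext) / 3L)
                        else as.integer(off),
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, random_bases(200L, gc))
    g <- genome_record(sname, paste(pieces, collapse = ""))
    ann <- new_annotation_set(do.call(rbind, ann_rows),
                              genome_ref = sname)
    subjects[[sname]] <- list(genomes = setNames(list(g), sname),
                              annotation = ann)
  }
  list(subjects = subjects,
       ledger_clade = do.call(rbind, ledger))
}

#' Score pipeline calls against the simulation ground truth
#'
#' Computes per-category recall and precision of the refinement calls
#' against the planted errors. Novel-gene calls are matched at locus level
#' (same replicon and stop coordinate); start corrections must propose the
#' exact true start; replacements must name the planted fake locus;
#' sequencing-error calls must propose a correction interval containing
#' the true inserted base.
#'
#' @param result Output of [refine_annotation()].
#' @param ledger The `sim_ledger` from [plant_errors()].
#' @return Data frame `category`, `n_truth`, `n_called`, `tp`, `recall`,
#'   `precision`, plus attribute `insertion_containment` (fraction of
#'   base-insertion truths whose interval contains the inserted base).
#' @export
score_recovery <- function(result, ledger) {
  calls <- result$calls
  genes <- ledger$genes
  err <- ledger$errors
  key <- function(rep, stop) paste(rep, stop)
  truth_stop <- function(ids) {
    gi <- match(ids, genes$gene_id)
    key(genes$replicon_id[gi], genes$stop_coord[gi])
  }

  # novel genes: planted missed genes plus transcribed one-hit genes
  novel_truth <- truth_stop(c(
    err$gene_id[err$category == "missed_gene"],
    intersect(ledger$transcribed_one_hit,
              err$gene_id[err$category == "one_hit"])))
  novel_called <- calls[calls$category == "novel_cds", , drop = FALSE]
  novel_pred <- key(novel_called$replicon_id, novel_called$new_stop)

  # start corrections: exact proposed start
  st_err <- err[err$category %in% c("wrong_start_long",
                                    "wrong_start_short"), , drop = FALSE]
  start_truth <- paste(genes$replicon_id[match(st_err$gene_id,
                                               genes$gene_id)],
                       st_err$true_start)
  st_called <- calls[calls$category %in% c("start_corrected",
                                           "nterm_extension") &
                       !is.na(calls$new_start), , drop = FALSE]
  start_pred <- unique(paste(st_called$replicon_id, st_called$new_start))

  # replacements: must displace the planted fake locus
  sp_err <- err[err$category == "spurious_cds", , drop = FALSE]
  repl_truth <- if (nrow(sp_err) > 0) sp_err$fake_tag else character(0)
  repl_called <- calls[calls$category == "wrong_cds_replacement", ,
                       drop = FALSE]
  repl_pred <- unlist(strsplit(repl_called$displaced_locus[
    !is.na(repl_called$displaced_locus)], ","))

  # sequencing errors: one event per candidate pair; an event matches a
  # planted insertion when any of its equivalent deletion intervals
  # contains the inserted base
  ins_err <- err[err$category == "base_insertion", , drop = FALSE]
  events <- result$seq_errors
  event_matches <- function(ev, repl, pos) {
    ev$replicon_id == repl && any(vapply(ev$calls, function(sc) {
      sc$mode == "deletion" && sc$interval[1] <= pos &&
        sc$interval[2] >= pos
    }, logical(1)))
  }
  contained <- vapply(seq_len(nrow(ins_err)), function(i) {
    repl <- genes$replicon_id[match(ins_err$gene_id[i], genes$gene_id)]
    any(vapply(events, event_matches, logical(1),
               repl = repl, pos = ins_err$inserted_pos[i]))
  }, logical(1))

  prf <- function(truth, pred) {
    tp <- length(intersect(truth, pred))
    data.frame(n_truth = length(truth), n_called = length(pred), tp = tp,
               recall = if (length(truth) == 0) NA_real_
                        else tp / length(truth),
               precision = if (length(pred) == 0) NA_real_
                           else tp / length(pred))
  }
  out <- rbind(
    cbind(category = "novel_cds", prf(novel_truth, unique(novel_pred))),
    cbind(category = "start_corrected", prf(start_truth, start_pred)),
    cbind(category = "wrong_cds_replacement",
          prf(repl_truth, unique(repl_pred))),
    cbind(category = "sequence_error",
          data.frame(n_truth = nrow(ins_err), n_called = length(events),
                     tp = sum(contained),
                     recall = if (nrow(ins_err) == 0) NA_real_
                              else mean(contained),
                     precision = if (length(events) == 0) NA_real_
                                 else sum(contained) / length(events)))
  )
  attr(out, "insertion_containment") <-
    if (nrow(ins_err) == 0) NA_real_ else mean(contained)
  out
}
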