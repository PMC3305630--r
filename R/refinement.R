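#' Pipeline thresholds
#'
#' Houses the numeric thresholds used throughout the refinement stage:
#' the minimum ORF size of the six-frame database (41 residues), the
#' two-distinct-peptide validation rule, the stricter p-value bound
#' (3.2e-5) applied to one-hit wonders, the general PSM identity threshold
#' (p < 0.005, rank 1), the canonical bacterial initiation codons
#' (ATG/GTG/TTG), the maximum nucleotide gap between the peptide-supported
#' spans of two reading frames considered as one frameshift candidate, and
#' the E-value cutoffs of the clade-extension stage (1e-20 for novel-gene
#' propagation, 1e-30 for N-terminus propagation).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_orf_aa = 41L,
    min_peptides_validate = 2L,
    one_hit_p_max = 3.2e-5,
    psm_p_max = 0.005,
    canonical_starts = c("ATG", "GTG", "TTG"),
    frame_gap_max_nt = 600L,
    evalue_novel = 1e-20,
    evalue_nterm = 1e-30,
    max_missed = 1L,
    pep_min_len = 6L,
    pep_max_len = 40L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

empty_calls <- function() {
  data.frame(category = character(), orf_id = character(),
             locus_tag = character(), replicon_id = character(),
             new_start = integer(), new_stop = integer(),
             displaced_locus = character(), nterm_category = character(),
             start_codon = character(), n_peptides = integer(),
             best_p = numeric(), note = character(),
             stringsAsFactors = FALSE)
}

call_row <- function(category, orf_id = NA_character_,
                     locus_tag = NA_character_,
                     replicon_id = NA_character_, new_start = NA_integer_,
                     new_stop = NA_integer_,
                     displaced_locus = NA_character_,
                     nterm_category = "none",
                     start_codon = NA_character_, n_peptides = NA_integer_,
                     best_p = NA_real_, note = NA_character_) {
  data.frame(category = category, orf_id = orf_id, locus_tag = locus_tag,
             replicon_id = replicon_id,
             new_start = as.integer(new_start),
             new_stop = as.integer(new_stop),
             displaced_locus = displaced_locus,
             nterm_category = nterm_category, start_codon = start_codon,
             n_peptides = as.integer(n_peptides), best_p = best_p,
             note = note, stringsAsFactors = FALSE)
}

rbind_calls <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0) return(empty_calls())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Codon (forward-genetic reading) at 1-based residue index k of an ORF.
orf_codon_at <- function(genome, orf, k) {
  if (orf$frame > 0) {
    pos <- orf$span_start + 3L * (k - 1L)
    substr(genome$sequence, pos, pos + 2L)
  } else {
    pos <- orf$span_start - 3L * (k - 1L)
    revcomp(substr(genome$sequence, pos - 2L, pos))
  }
}

# Genomic coordinate (reading direction) of the first base of ORF residue k.
orf_residue_pos <- function(orf, k) {
  if (orf$frame > 0) orf$span_start + 3L * (k - 1L)
  else orf$span_start - 3L * (k - 1L)
}

# Reading-direction stop coordinate of a CDS ending at the ORF's bounding
# stop codon (the span includes the stop triplet when it exists within the
# replicon; otherwise the ORF end itself is used and a note is warranted).
orf_cds_stop <- function(orf, replicon_len) {
  if (orf$frame > 0) {
    if (orf$span_end + 3L <= replicon_len) orf$span_end + 3L else orf$span_end
  } else {
    if (orf$span_end - 3L >= 1L) orf$span_end - 3L else orf$span_end
  }
}

#' Nearest upstream canonical start for an ORF position
#'
#' Scans in-frame codons from the residue that must be covered towards the
#' ORF's upstream bounding stop and returns the genomic coordinate of the
#' first (i.e. nearest) canonical initiation codon found. Picking the
#' nearest rather than the furthest codon avoids the longest-ORF bias of
#' ab-initio gene callers.
#'
#' @param orf One-row ORF data frame slice.
#' @param must_cover_aa_offset 1-based residue index that the chosen start
#'   must lie at or upstream of.
#' @param genomes Named list of genome records.
#' @param config A [pipeline_config()].
#' @return Genomic coordinate of the start codon's first base (reading
#'   direction), or `NA_integer_` when no canonical codon is available.
#' @export
choose_start <- function(orf, must_cover_aa_offset, genomes,
                         config = pipeline_config()) {
  g <- genomes[[orf$replicon_id]]
  k <- as.integer(must_cover_aa_offset)
  stopifnot(k >= 1L, k <= nchar(orf$aa))
  while (k >= 1L) {
    if (orf_codon_at(g, orf, k) %in% config$canonical_starts) {
      return(as.integer(orf_residue_pos(orf, k)))
    }
    k <- k - 1L
  }
  NA_integer_
}

# Forward-coordinate [lo, hi] of the peptide-supported span of each ORF.
supported_spans <- function(mapped) {
  if (nrow(mapped) == 0) {
    return(data.frame(orf_id = character(), replicon_id = character(),
                      frame = integer(), lo = integer(), hi = integer(),
                      min_off = integer(), stringsAsFactors = FALSE))
  }
  lo <- pmin(mapped$genomic_start, mapped$genomic_end)
  hi <- pmax(mapped$genomic_start, mapped$genomic_end)
  agg_lo <- tapply(lo, mapped$orf_id, min)
  agg_hi <- tapply(hi, mapped$orf_id, max)
  agg_off <- tapply(mapped$aa_offset0, mapped$orf_id, min)
  ids <- names(agg_lo)
  idx <- match(ids, mapped$orf_id)
  data.frame(orf_id = ids, replicon_id = mapped$replicon_id[idx],
             frame = mapped$frame[idx],
             lo = as.integer(agg_lo), hi = as.integer(agg_hi),
             min_off = as.integer(agg_off),
             stringsAsFactors = FALSE, row.names = NULL)
}

overlaps_interval <- function(lo1, hi1, lo2, hi2) {
  lo1 <= hi2 & hi1 >= lo2
}

#' Genomic spans of proteomically detected genes
#'
#' Returns the forward-coordinate spans of (i) annotated CDSs whose
#' containing ORF is validated by at least two distinct peptides and (ii)
#' validated ORFs with no annotated CDS (their peptide-supported spans).
#' Used for overlap guards ("no overlap with other proteomic-detected
#' genes").
#'
#' @param evidence Output of [aggregate_to_proteins()].
#' @param mapped Output of [map_psms()].
#' @param annotation An `annotation_set`.
#' @param db An `orf_db`.
#' @param genomes Named list of genome records.
#' @return Data frame `replicon_id`, `lo`, `hi`, `locus_tag` (NA for
#'   unannotated ORFs), `orf_id`.
#' @export
detected_gene_spans <- function(evidence, mapped, annotation, db, genomes) {
  validated <- evidence$orf_id[evidence$status == "validated"]
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  det_ann <- which(ann_orfs %in% validated)
  spans <- supported_spans(mapped)
  out <- list()
  if (length(det_ann) > 0) {
    a <- annotation[det_ann, ]
    out[[1]] <- data.frame(replicon_id = a$replicon_id,
                           lo = pmin(a$start_coord, a$stop_coord),
                           hi = pmax(a$start_coord, a$stop_coord),
                           locus_tag = a$locus_tag,
                           orf_id = ann_orfs[det_ann],
                           stringsAsFactors = FALSE)
  }
  novel <- setdiff(validated, stats::na.omit(ann_orfs))
  sp <- spans[spans$orf_id %in% novel, , drop = FALSE]
  if (nrow(sp) > 0) {
    out[[length(out) + 1L]] <- data.frame(replicon_id = sp$replicon_id,
                                          lo = sp$lo, hi = sp$hi,
                                          locus_tag = NA_character_,
                                          orf_id = sp$orf_id,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(replicon_id = character(), lo = integer(),
                      hi = integer(), locus_tag = character(),
                      orf_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify validated ORFs against the existing annotation
#'
#' Every validated ORF with no annotated CDS in the same frame becomes
#' either a novel gene call (its peptide-supported span overlaps no
#' annotated CDS on either strand), a wrong-CDS replacement (it overlaps
#' only annotated CDSs that were not detected and have no credible
#' homology support; the displaced loci are recorded), or a reported,
#' uncalled conflict (it overlaps a detected or homology-supported CDS).
#' Proposed coordinates run from the nearest canonical start covering the
#' most upstream supporting peptide to the ORF's stop codon.
#'
#' @param evidence Output of [aggregate_to_proteins()].
#' @param mapped Output of [map_psms()].
#' @param annotation An `annotation_set`.
#' @param db An `orf_db`.
#' @param genomes Named list of genome records.
#' @param homology_support Named logical vector by locus_tag marking
#'   annotated CDSs with credible homologs (default: none).
#' @param config A [pipeline_config()].
#' @param exclude_orfs ORF ids to leave out (e.g. members of frameshift
#'   pairs already explained by a sequencing-error call).
#' @return Calls data frame (categories `novel_cds`,
#'   `wrong_cds_replacement`, `conflict`).
#' @export
classify_detected_orfs <- function(evidence, mapped, annotation, db, genomes,
                                   homology_support = NULL,
                                   config = pipeline_config(),
                                   exclude_orfs = character()) {
  validated <- evidence$orf_id[evidence$status == "validated"]
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  detected_loci <- annotation$locus_tag[ann_orfs %in% validated]
  spans <- supported_spans(mapped)
  lens <- vapply(genomes, function(g) nchar(g$sequence), integer(1))
  hs <- function(tag) {
    !is.null(homology_support) && isTRUE(unname(homology_support[tag]))
  }
  todo <- setdiff(validated, c(stats::na.omit(ann_orfs), exclude_orfs))
  todo <- todo[!startsWith(todo, "CONTAM_")]
  calls <- lapply(todo, function(oid) {
    orf <- db$orfs[db$orfs$orf_id == oid, ]
    sp <- spans[spans$orf_id == oid, ]
    ev <- evidence[evidence$orf_id == oid, ]
    ov <- annotation$replicon_id == orf$replicon_id &
      overlaps_interval(pmin(annotation$start_coord, annotation$stop_coord),
                        pmax(annotation$start_coord, annotation$stop_coord),
                        sp$lo, sp$hi)
    ov_loci <- annotation$locus_tag[ov]
    ns <- choose_start(orf, sp$min_off + 1L, genomes, config)
    codon <- if (!is.na(ns)) {
      orf_codon_at(genomes[[orf$replicon_id]], orf,
                   (abs(ns - orf$span_start)) %/% 3L + 1L)
    } else NA_character_
    stop_pos <- orf_cds_stop(orf, lens[[orf$replicon_id]])
    if (length(ov_loci) == 0) {
      call_row("novel_cds", orf_id = oid, replicon_id = orf$replicon_id,
               new_start = ns, new_stop = stop_pos, start_codon = codon,
               n_peptides = ev$n_peptides, best_p = ev$best_p_value)
    } else {
      blocked <- ov_loci[ov_loci %in% detected_loci |
                           vapply(ov_loci, hs, logical(1))]
      if (length(blocked) > 0) {
        call_row("conflict", orf_id = oid, replicon_id = orf$replicon_id,
                 n_peptides = ev$n_peptides, best_p = ev$best_p_value,
                 new_start = ns, new_stop = stop_pos, start_codon = codon,
                 note = paste("overlaps detected/homology-supported:",
                              paste(blocked, collapse = ",")))
      } else {
        call_row("wrong_cds_replacement", orf_id = oid,
                 replicon_id = orf$replicon_id, new_start = ns,
                 new_stop = stop_pos, start_codon = codon,
                 displaced_locus = paste(ov_loci, collapse = ","),
                 n_peptides = ev$n_peptides, best_p = ev$best_p_value)
      }
    }
  })
  rbind_calls(calls)
}

#' One-hit-wonder candidate selection
#'
#' An ORF supported by exactly one distinct peptide is retained as a
#' candidate novel gene only when that peptide's p-value is strictly below
#' the one-hit threshold (default 3.2e-5) and the ORF's supported span has
#' zero nucleotide overlap with any proteomically detected gene on either
#' strand. Candidates await orthogonal (e.g. transcription) evidence.
#'
#' @inheritParams classify_detected_orfs
#' @param detected_spans Output of [detected_gene_spans()].
#' @return Calls data frame (category `one_hit_candidate`).
#' @export
one_hit_wonder_candidates <- function(evidence, mapped, annotation, db,
                                      genomes, detected_spans,
                                      config = pipeline_config(),
                                      exclude_orfs = character()) {
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  spans <- supported_spans(mapped)
  lens <- vapply(genomes, function(g) nchar(g$sequence), integer(1))
  onehit <- evidence[evidence$status == "one_hit", , drop = FALSE]
  onehit <- onehit[!onehit$orf_id %in% c(stats::na.omit(ann_orfs),
                                         exclude_orfs) &
                     !startsWith(onehit$orf_id, "CONTAM_"), , drop = FALSE]
  calls <- lapply(seq_len(nrow(onehit)), function(i) {
    ev <- onehit[i, ]
    if (!(ev$best_p_value < config$one_hit_p_max)) return(NULL)
    sp <- spans[spans$orf_id == ev$orf_id, ]
    ov <- detected_spans$replicon_id == sp$replicon_id &
      detected_spans$orf_id != ev$orf_id &
      overlaps_interval(detected_spans$lo, detected_spans$hi, sp$lo, sp$hi)
    if (any(ov)) return(NULL)
    orf <- db$orfs[db$orfs$orf_id == ev$orf_id, ]
    ns <- choose_start(orf, sp$min_off + 1L, genomes, config)
    codon <- if (!is.na(ns)) {
      orf_codon_at(genomes[[orf$replicon_id]], orf,
                   (abs(ns - orf$span_start)) %/% 3L + 1L)
    } else NA_character_
    call_row("one_hit_candidate", orf_id = ev$orf_id,
             replicon_id = sp$replicon_id, new_start = ns,
             new_stop = orf_cds_stop(orf, lens[[orf$replicon_id]]),
             start_codon = codon, n_peptides = 1L,
             best_p = ev$best_p_value)
  })
  rbind_calls(calls)
}

#' Promote one-hit candidates with transcription evidence
#'
#' Candidates whose locus shows transcription (e.g. by RT-PCR) are promoted
#' to novel gene calls; the others remain candidates.
#'
#' @param candidates Calls data frame from [one_hit_wonder_candidates()].
#' @param transcription_evidence Named logical vector by `orf_id` (or a
#'   data frame with columns `orf_id`, `transcribed`). Missing ids default
#'   to `FALSE`.
#' @return Calls data frame with promoted rows recategorised as
#'   `novel_cds` (note records the promotion).
#' @export
accept_with_transcription <- function(candidates, transcription_evidence) {
  if (is.data.frame(transcription_evidence)) {
    transcription_evidence <- setNames(
      as.logical(transcription_evidence$transcribed),
      transcription_evidence$orf_id)
  }
  unknown <- setdiff(names(transcription_evidence), candidates$orf_id)
  if (length(unknown) > 0) {
    warning("transcription evidence for unknown orf_id(s): ",
            paste(head(unknown, 5), collapse = ", "))
  }
  if (nrow(candidates) == 0) return(candidates)
  promoted <- candidates$orf_id %in%
    names(transcription_evidence)[transcription_evidence %in% TRUE]
  candidates$category[promoted] <- "novel_cds"
  candidates$note[promoted] <- "promoted by transcription evidence"
  candidates
}

#' Scan for N-terminal extensions from strictly tryptic peptides
#'
#' For each annotated CDS, fully tryptic peptides mapping in-frame upstream
#' of its annotated start (including peptides that span the start) within
#' the same stop-to-stop ORF indicate a too-short annotation. The proposed
#' new start is the nearest canonical codon at or upstream of the most
#' upstream such peptide; a call is withheld (report-only row with no
#' coordinates) when no canonical codon exists, and skipped when the
#' extension would overlap an upstream detected gene.
#'
#' @inheritParams classify_detected_orfs
#' @param detected_spans Output of [detected_gene_spans()].
#' @return Calls data frame (category `nterm_extension`).
#' @export
nterm_extension_scan <- function(mapped, annotation, db, genomes,
                                 detected_spans = NULL,
                                 config = pipeline_config()) {
  full <- mapped[mapped$tryptic_status == "full", , drop = FALSE]
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  calls <- lapply(seq_len(nrow(annotation)), function(i) {
    oid <- ann_orfs[i]
    if (is.na(oid)) return(NULL)
    cds <- annotation[i, ]
    orf <- db$orfs[db$orfs$orf_id == oid, ]
    k_cds <- abs(cds$start_coord - orf$span_start) %/% 3L + 1L
    m <- full[full$orf_id == oid, , drop = FALSE]
    up <- m[m$aa_offset0 + 1L < k_cds, , drop = FALSE]
    if (nrow(up) == 0) return(NULL)
    k_pep <- min(up$aa_offset0) + 1L
    ns <- choose_start(orf, k_pep, genomes, config)
    if (is.na(ns)) {
      return(call_row("nterm_extension", orf_id = oid,
                      locus_tag = cds$locus_tag,
                      replicon_id = cds$replicon_id,
                      n_peptides = nrow(up),
                      note = "no canonical start upstream; report only"))
    }
    if (!is.null(detected_spans) && nrow(detected_spans) > 0) {
      ext_lo <- min(ns, cds$start_coord)
      ext_hi <- max(ns, cds$start_coord)
      ov <- detected_spans$replicon_id == cds$replicon_id &
        !(detected_spans$locus_tag %in% cds$locus_tag) &
        detected_spans$orf_id != oid &
        overlaps_interval(detected_spans$lo, detected_spans$hi,
                          ext_lo, ext_hi)
      if (any(ov)) {
        return(call_row("nterm_extension", orf_id = oid,
                        locus_tag = cds$locus_tag,
                        replicon_id = cds$replicon_id,
                        n_peptides = nrow(up),
                        note = "extension overlaps detected gene; withheld"))
      }
    }
    codon <- orf_codon_at(genomes[[cds$replicon_id]], orf,
                          abs(ns - orf$span_start) %/% 3L + 1L)
    call_row("nterm_extension", orf_id = oid, locus_tag = cds$locus_tag,
             replicon_id = cds$replicon_id, new_start = ns,
             new_stop = cds$stop_coord, start_codon = codon,
             n_peptides = nrow(up))
  })
  rbind_calls(calls)
}

#' Validate or correct start codons from semi-tryptic N-terminal peptides
#'
#' Each mapped semi-tryptic N-terminal peptide is interpreted as either an
#' intact initiator (peptide begins with Met over an ATG or GTG codon) or a
#' methionine-excised N-terminus (the codon immediately upstream of the
#' peptide is canonical), yielding one of the categories
#' `ATG_met_retained`, `ATG_met_removed`, `GTG_met_retained`,
#' `GTG_met_removed`, `TTG_met_removed`. When the implied start equals the
#' annotated start the call is `start_confirmed`; otherwise
#' `start_corrected` with the new coordinates. Peptides implying a start at
#' a non-canonical codon are rejected with a reason.
#'
#' @inheritParams classify_detected_orfs
#' @return Calls data frame (categories `start_confirmed`,
#'   `start_corrected`, plus `rejected` report rows).
#' @export
validate_starts_semitryptic <- function(mapped, annotation, db, genomes,
                                        config = pipeline_config()) {
  semi <- mapped[mapped$tryptic_status == "semi_N", , drop = FALSE]
  if (nrow(semi) == 0) return(empty_calls())
  ann_orfs <- suppressWarnings(containing_orf(annotation, db, genomes))
  rows <- lapply(seq_len(nrow(semi)), function(i) {
    mp <- semi[i, ]
    ann_i <- which(ann_orfs == mp$orf_id)
    if (length(ann_i) == 0) return(NULL)   # unannotated ORF: handled by the
    cds <- annotation[ann_i[1], ]          # novel-gene route
    orf <- db$orfs[db$orfs$orf_id == mp$orf_id, ]
    g <- genomes[[orf$replicon_id]]
    o1 <- mp$aa_offset0 + 1L               # residue index of peptide start
    pep1 <- substr(mp$peptide, 1, 1)
    codon_here <- orf_codon_at(g, orf, o1)
    # both readings of the peptide N-terminus can be chemically plausible
    # (e.g. a Met-Met start); prefer the one consistent with the annotated
    # start, then an intact initiator
    hyps <- list()
    if (pep1 == "M" && codon_here %in% c("ATG", "GTG")) {
      hyps[[length(hyps) + 1L]] <- list(k = o1,
                                        cat = paste0(codon_here,
                                                     "_met_retained"))
    }
    if (o1 >= 2L) {
      codon_prev <- orf_codon_at(g, orf, o1 - 1L)
      if (codon_prev %in% config$canonical_starts) {
        hyps[[length(hyps) + 1L]] <- list(k = o1 - 1L,
                                          cat = paste0(codon_prev,
                                                       "_met_removed"))
      }
    }
    interp <- NULL
    if (length(hyps) > 0) {
      matches_ann <- vapply(hyps, function(h) {
        orf_residue_pos(orf, h$k) == cds$start_coord
      }, logical(1))
      interp <- if (any(matches_ann)) hyps[[which(matches_ann)[1]]]
                else hyps[[1]]
    }
    if (is.null(interp)) {
      return(call_row("rejected", orf_id = mp$orf_id,
                      locus_tag = cds$locus_tag,
                      replicon_id = orf$replicon_id,
                      note = paste0("no canonical start consistent with ",
                                    "semi-tryptic peptide ", mp$peptide)))
    }
    if (endsWith(interp$cat, "met_removed") &&
        !interp$cat %in% c("ATG_met_removed", "GTG_met_removed",
                           "TTG_met_removed")) {
      return(call_row("rejected", orf_id = mp$orf_id,
                      locus_tag = cds$locus_tag,
                      replicon_id = orf$replicon_id,
                      note = paste("unsupported initiator category",
                                   interp$cat)))
    }
    implied <- orf_residue_pos(orf, interp$k)
    codon <- orf_codon_at(g, orf, interp$k)
    if (implied == cds$start_coord) {
      call_row("start_confirmed", orf_id = mp$orf_id,
               locus_tag = cds$locus_tag, replicon_id = orf$replicon_id,
               nterm_category = interp$cat, start_codon = codon,
               n_peptides = 1L)
    } else {
      call_row("start_corrected", orf_id = mp$orf_id,
               locus_tag = cds$locus_tag, replicon_id = orf$replicon_id,
               new_start = implied, new_stop = cds$stop_coord,
               nterm_category = interp$cat, start_codon = codon,
               n_peptides = 1L)
    }
  })
  calls <- rbind_calls(rows)
  if (nrow(calls) == 0) return(calls)
  # one verdict per locus: prefer a confirmation, then the implied start
  # closest to the annotated one
  keep <- unlist(lapply(split(seq_len(nrow(calls)), calls$locus_tag),
                        function(idx) {
    sub <- calls[idx, ]
    if (any(sub$category == "start_confirmed")) {
      idx[which(sub$category == "start_confirmed")[1]]
    } else if (any(sub$category == "start_corrected")) {
      cand <- idx[sub$category == "start_corrected"]
      ann_start <- annotation$start_coord[
        match(sub$locus_tag[1], annotation$locus_tag)]
      cand[which.min(abs(calls$new_start[cand] - ann_start))]
    } else idx[1]
  }), use.names = FALSE)
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Start-codon usage of confirmed and corrected starts
#'
#' @param calls Calls data frame containing `start_confirmed` /
#'   `start_corrected` rows with a `start_codon` column.
#' @return Data frame `codon`, `count`, `percent` over ATG/GTG/TTG
#'   (percentages of their total); zero rows for empty input.
#' @export
start_codon_usage <- function(calls) {
  sub <- calls[calls$category %in% c("start_confirmed", "start_corrected") &
                 !is.na(calls$start_codon), , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(codon = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  counts <- table(factor(sub$start_codon, levels = c("ATG", "GTG", "TTG")))
  data.frame(codon = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / sum(counts),
             stringsAsFactors = FALSE)
}
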