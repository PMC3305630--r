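# Frame-split detection and single-base sequencing-error resolution.
#
# A single inserted (or deleted) base splits one true coding region across
# two apparent reading frames on the same strand. The signature in peptide
# evidence is a pair of peptide-bearing ORFs, same strand, different
# frames, whose supported spans are collinear and close; the resolution is
# an exhaustive single-base edit search over the interval between the
# innermost peptides, accepting an edit iff re-translation places every
# supporting peptide in one stop-to-stop ORF.

#' Detect frameshift candidate ORF pairs
#'
#' Returns pairs of peptide-bearing ORFs on the same strand of the same
#' replicon but in different frames, whose peptide-supported spans are
#' collinear (disjoint, in reading order) and separated by at most
#' `frame_gap_max_nt` nucleotides. Each pair carries the genomic search
#' interval between the innermost peptides. Pairs in which either ORF
#' matches a detected annotated CDS are not candidates: adjacent real genes
#' in different frames are the common genomic arrangement, not a frameshift
#' signature, and fusing a healthy detected gene is never proposed.
#'
#' Single-peptide members are only credible at the stringent one-hit
#' confidence threshold (when protein-level `evidence` is supplied), and
#' the search interval must not cross an unrelated proteomically detected
#' gene -- both guards keep sporadic random matches from pairing healthy
#' loci into spurious frameshifts.
#'
#' @param mapped Output of [map_psms()].
#' @param db An `orf_db`.
#' @param config A [pipeline_config()].
#' @param annotated_orfs `orf_id`s that contain an annotated CDS (used for
#'   the adjacent-real-genes guard); default none.
#' @param evidence Optional output of [aggregate_to_proteins()]; enables
#'   the single-peptide credibility guard.
#' @param detected_spans Optional output of [detected_gene_spans()];
#'   enables the interval guard.
#' @return A list of candidate lists with elements `orf_up`, `orf_down`
#'   (reading order), `replicon_id`, `strand`, `interval_lo`,
#'   `interval_hi` (forward coordinates), `peptides`.
#' @export
detect_frame_split_candidates <- function(mapped, db,
                                          config = pipeline_config(),
                                          annotated_orfs = character(),
                                          evidence = NULL,
                                          detected_spans = NULL) {
  # shared peptides (multiple ORFs) do not count as frame-split support,
  # by the same parsimony rule that excludes them from validation
  mapped <- mapped[!mapped$shared, , drop = FALSE]
  spans <- supported_spans(mapped)
  spans <- spans[!startsWith(spans$orf_id, "CONTAM_"), , drop = FALSE]
  if (!is.null(evidence)) {
    credible <- evidence$orf_id[evidence$n_peptides_all >= 2L |
                                  evidence$best_p_value <
                                    config$one_hit_p_max]
    spans <- spans[spans$orf_id %in% credible, , drop = FALSE]
  }
  out <- list()
  if (nrow(spans) < 2) return(out)
  for (i in seq_len(nrow(spans) - 1L)) {
    for (j in (i + 1L):nrow(spans)) {
      a <- spans[i, ]; b <- spans[j, ]
      if (a$replicon_id != b$replicon_id) next
      if (sign(a$frame) != sign(b$frame) || a$frame == b$frame) next
      if (a$orf_id %in% annotated_orfs || b$orf_id %in% annotated_orfs) next
      # forward-coordinate order; reading order follows strand
      left <- if (a$lo <= b$lo) a else b
      right <- if (a$lo <= b$lo) b else a
      gap <- right$lo - left$hi - 1L
      if (gap < 1L || gap > config$frame_gap_max_nt) next
      if (!is.null(detected_spans) && nrow(detected_spans) > 0) {
        cross <- detected_spans$replicon_id == a$replicon_id &
          !(detected_spans$orf_id %in% c(a$orf_id, b$orf_id)) &
          overlaps_interval(detected_spans$lo, detected_spans$hi,
                            left$hi + 1L, right$lo - 1L)
        if (any(cross)) next
      }
      strand <- sign(a$frame)
      up <- if (strand > 0) left else right
      down <- if (strand > 0) right else left
      peps <- unique(mapped$peptide[mapped$orf_id %in% c(a$orf_id,
                                                         b$orf_id)])
      out[[length(out) + 1L]] <- list(
        orf_up = up$orf_id, orf_down = down$orf_id,
        replicon_id = a$replicon_id, strand = strand,
        interval_lo = left$hi + 1L, interval_hi = right$lo - 1L,
        peptides = peps)
    }
  }
  out
}

# Translate, in reading coordinates, the stop-to-stop segment anchored at
# `anchor_read` of the (edited) reading-strand string, returning the protein
# up to (not including) the first stop, plus the 1-based codon index of that
# stop (NA if none within the window).
translate_anchored <- function(rs_window) {
  n <- 3L * (nchar(rs_window) %/% 3L)
  if (n == 0) return(list(protein = "", stop_codon_idx = NA_integer_))
  aa <- translate_str(substr(rs_window, 1L, n))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0) {
    list(protein = substr(aa, 1L, star - 1L),
         stop_codon_idx = as.integer(star))
  } else {
    list(protein = aa, stop_codon_idx = NA_integer_)
  }
}

#' Resolve a frameshift candidate by exhaustive single-base edits
#'
#' For every position in the candidate's search interval the base is
#' tentatively deleted, the fused region is re-translated stop-to-stop from
#' the upstream ORF's first codon, and the deletion is accepted iff every
#' supporting peptide occurs in the resulting single ORF with no
#' intervening stop. Accepted positions are collapsed into maximal
#' intervals of equivalent deletions, which naturally span homopolymer
#' runs. Single-base insertions (each of the four bases at each position)
#' are attempted as a secondary mode only when no deletion reconciles the
#' frames. Deletions are tried first because a frame split caused by one
#' extra base in the reported sequence is resolved by removing it.
#'
#' @param candidate One candidate from [detect_frame_split_candidates()].
#' @param genomes Named list of genome records.
#' @param supporting_peptides Peptide sequences that must all occur in the
#'   corrected protein (defaults to the candidate's peptides).
#' @param config A [pipeline_config()].
#' @return `NULL` when no single-base edit reconciles the frames; otherwise
#'   a list of `seq_error_call` lists (usually one), ranked by corrected
#'   protein length, each with `replicon_id`, `mode` (`"deletion"` or
#'   `"insertion"`), `interval` (inclusive genomic interval of equivalent
#'   edits), `inserted_base` (insertion mode only), `corrected_protein`,
#'   `stop_pos` (genomic coordinate, original sequence, of the first base
#'   in reading direction of the terminating stop codon), `frames`,
#'   `peptides`.
#' @export
resolve_sequence_error <- function(candidate, genomes,
                                   supporting_peptides = NULL,
                                   config = pipeline_config()) {
  if (is.null(supporting_peptides)) supporting_peptides <- candidate$peptides
  g <- genomes[[candidate$replicon_id]]
  L <- nchar(g$sequence)
  strand <- candidate$strand
  rs <- if (strand > 0) g$sequence else revcomp(g$sequence)
  to_read <- function(p) if (strand > 0) p else L - p + 1L
  from_read <- function(q) if (strand > 0) q else L - q + 1L
  orf_up <- parse_orf_id(candidate$orf_up)
  orf_down <- parse_orf_id(candidate$orf_down)
  anchor <- to_read(orf_up$span_start)
  win_end <- min(L, to_read(orf_down$span_end) + 200L)
  win <- substr(rs, anchor, win_end)
  qs <- sort(vapply(candidate$interval_lo:candidate$interval_hi, to_read,
                    numeric(1)))
  wq <- as.integer(qs) - anchor + 1L
  wq <- wq[wq >= 1L & wq <= nchar(win)]
  if (length(wq) == 0) return(NULL)

  check_edit <- function(edited) {
    tr <- translate_anchored(edited)
    if (all(vapply(supporting_peptides, grepl, logical(1), x = tr$protein,
                   fixed = TRUE))) tr else NULL
  }
  accept_mode <- function(mode, base = NA_character_) {
    acc <- integer(); prot <- character(); stop_idx <- integer()
    for (w in wq) {
      edited <- if (mode == "deletion") {
        paste0(substr(win, 1L, w - 1L), substr(win, w + 1L, nchar(win)))
      } else {
        paste0(substr(win, 1L, w - 1L), base, substr(win, w, nchar(win)))
      }
      tr <- check_edit(edited)
      if (!is.null(tr)) {
        acc <- c(acc, w)
        prot <- c(prot, tr$protein)
        stop_idx <- c(stop_idx, tr$stop_codon_idx)
      }
    }
    if (length(acc) == 0) return(list())
    # collapse consecutive accepted window positions into runs
    runs <- split(seq_along(acc), cumsum(c(1L, diff(acc) != 1L)))
    lapply(runs, function(r) {
      w_lo <- acc[r[1]]; w_hi <- acc[r[length(r)]]
      # stop codon position in ORIGINAL coordinates: the edit is at or
      # before the stop, so a deletion shifts it forward by one, an
      # insertion backwards by one, in edited window coordinates
      si <- stop_idx[r[1]]
      stop_read <- if (is.na(si)) NA_integer_ else {
        e <- anchor + 3L * (si - 1L)
        if (e >= anchor + w_lo - 1L) {
          e + if (mode == "deletion") 1L else -1L
        } else e
      }
      p_lo <- from_read(w_lo + anchor - 1L)
      p_hi <- from_read(w_hi + anchor - 1L)
      iv <- c(min(p_lo, p_hi), max(p_lo, p_hi))
      if (mode == "deletion") {
        # deleting any base of one homopolymer run yields an identical
        # sequence, so the equivalence interval extends through the runs
        # at both ends even beyond the searched window
        iv[1] <- homopolymer_run(g$sequence, iv[1])[1]
        iv[2] <- homopolymer_run(g$sequence, iv[2])[2]
      }
      structure(list(replicon_id = candidate$replicon_id, mode = mode,
                     interval = iv,
                     inserted_base = base,
                     corrected_protein = prot[r[1]],
                     stop_pos = if (is.na(stop_read)) NA_integer_
                                else from_read(stop_read),
                     frames = c(orf_up$frame, orf_down$frame),
                     peptides = supporting_peptides),
                class = "seq_error_call")
    })
  }

  calls <- accept_mode("deletion")
  if (length(calls) == 0) {
    for (b in c("A", "C", "G", "T")) {
      calls <- c(calls, accept_mode("insertion", b))
    }
  }
  if (length(calls) == 0) return(NULL)
  calls <- calls[order(-vapply(calls, function(x)
    nchar(x$corrected_protein), numeric(1)))]
  names(calls) <- NULL
  if (length(calls) > 1) {
    message("multiple non-equivalent single-base edits reconcile the ",
            "frames (", length(calls), "); returning all, ranked")
  }
  calls
}

# Parse an orf_id of the form {replicon}:{+frame}:{start}-{end}.
parse_orf_id <- function(orf_id) {
  m <- regmatches(orf_id,
                  regexec("^(.*):([+-][0-9]):([0-9]+)-([0-9]+)$", orf_id))[[1]]
  if (length(m) != 5) stop("malformed orf_id: ", orf_id)
  list(replicon_id = m[2], frame = as.integer(m[3]),
       span_start = as.integer(m[4]), span_end = as.integer(m[5]))
}

#' Shorten a detected CDS to resolve an overlap conflict
#'
#' When a validated novel ORF overlaps the 5' region of a detected
#' annotated CDS, the annotated gene may simply be shorter than annotated:
#' a new start is sought that still covers every one of the gene's own
#' peptides while eliminating the overlap. When both constraints cannot
#' hold the conflict stands and is reported.
#'
#' @param detected_locus The locus_tag of the detected annotated CDS.
#' @param conflicting_call One-row calls slice whose proposed span overlaps
#'   the CDS (`new_start`/`new_stop` used as the conflict region).
#' @param mapped Output of [map_psms()].
#' @param annotation An `annotation_set`.
#' @param db An `orf_db`.
#' @param genomes Named list of genome records.
#' @param config A [pipeline_config()].
#' @return One-row calls data frame: `start_corrected` for the old locus on
#'   success, or a `conflict` report row.
#' @export
shorten_conflicting_cds <- function(detected_locus, conflicting_call, mapped,
                                    annotation, db, genomes,
                                    config = pipeline_config()) {
  cds <- annotation[annotation$locus_tag == detected_locus, ]
  stopifnot(nrow(cds) == 1)
  oid <- suppressWarnings(containing_orf(cds, db, genomes))
  if (is.na(oid)) {
    return(call_row("conflict", locus_tag = detected_locus,
                    replicon_id = cds$replicon_id,
                    note = "detected CDS has no containing ORF"))
  }
  orf <- db$orfs[db$orfs$orf_id == oid, ]
  own <- mapped[mapped$orf_id == oid & mapped$tryptic_status == "full", ,
                drop = FALSE]
  if (nrow(own) == 0) {
    return(call_row("conflict", locus_tag = detected_locus,
                    replicon_id = cds$replicon_id,
                    note = "no peptides to constrain a shorter start"))
  }
  k_pep <- min(own$aa_offset0) + 1L
  conf_lo <- min(conflicting_call$new_start, conflicting_call$new_stop)
  conf_hi <- max(conflicting_call$new_start, conflicting_call$new_stop)
  ns <- choose_start(orf, k_pep, genomes, config)
  ok <- FALSE
  if (!is.na(ns)) {
    new_lo <- min(ns, cds$stop_coord)
    new_hi <- max(ns, cds$stop_coord)
    ok <- !overlaps_interval(new_lo, new_hi, conf_lo, conf_hi)
  }
  if (!ok) {
    return(call_row("conflict", orf_id = oid, locus_tag = detected_locus,
                    replicon_id = cds$replicon_id,
                    note = paste("shortening cannot both cover peptides and",
                                 "remove the overlap")))
  }
  codon <- orf_codon_at(genomes[[cds$replicon_id]], orf,
                        abs(ns - orf$span_start) %/% 3L + 1L)
  call_row("start_corrected", orf_id = oid, locus_tag = detected_locus,
           replicon_id = cds$replicon_id, new_start = ns,
           new_stop = cds$stop_coord, start_codon = codon,
           n_peptides = nrow(own),
           note = paste("shortened to resolve overlap with",
                        conflicting_call$orf_id))
}
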