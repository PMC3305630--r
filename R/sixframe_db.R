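#' Enumerate stop-to-stop ORFs in all six reading frames
#'
#' Each replicon is conceptually translated in the three frames of both
#' strands; every frame is partitioned at stop codons and every maximal
#' inter-stop segment of at least `min_length_aa` residues becomes one ORF.
#' Replicon ends act as virtual stop codons, so partial terminal segments
#' are eligible unless `require_both_stops = TRUE`; trailing incomplete
#' codons (fewer than three bases) at frame ends are discarded silently.
#' Circular topology is not wrapped.
#'
#' Frames are labelled `+1, +2, +3` (forward strand, first codon starting
#' at base 1, 2, 3) and `-1, -2, -3` (reverse complement, first codon
#' starting at base 1, 2, 3 of the reverse-complemented sequence).
#' `span_start`/`span_end` are 1-based genomic coordinates of the first and
#' last translated base in reading direction, so `span_start > span_end` on
#' minus frames.
#'
#' @param genomes Named list of [genome_record()]s.
#' @param min_length_aa Minimum ORF length in residues (default 41, i.e.
#'   "more than forty residues").
#' @param require_both_stops If `TRUE`, keep only segments bounded by real
#'   stop codons on both sides (drops partial terminal segments).
#' @param table Genetic code id (default bacterial, `"11"`).
#' @return A data frame with columns `orf_id`, `replicon_id`, `frame`
#'   (integer in `c(1,2,3,-1,-2,-3)`), `span_start`, `span_end`, `aa`,
#'   sorted by (replicon, frame, span position). `orf_id` is
#'   `{replicon}:{+frame}:{span_start}-{span_end}`.
#' @export
enumerate_orfs <- function(genomes, min_length_aa = 41L,
                           require_both_stops = FALSE, table = "11") {
  stopifnot(length(genomes) > 0)
  out <- list()
  for (g in genomes) {
    L <- nchar(g$sequence)
    for (strand in c(1L, -1L)) {
      seqstr <- if (strand == 1L) g$sequence else revcomp(g$sequence)
      for (off in 1:3) {
        n_cod <- (nchar(seqstr) - off + 1L) %/% 3L
        if (n_cod < 1) next
        aa <- translate_str(substr(seqstr, off, off + 3L * n_cod - 1L), table)
        seg <- orf_segments(aa, min_length_aa, require_both_stops)
        if (nrow(seg) == 0) next
        # reading-strand base coordinates of each segment
        b1 <- off + 3L * (seg$first - 1L)
        b2 <- off + 3L * seg$last - 1L
        if (strand == 1L) {
          s_start <- b1; s_end <- b2
        } else {
          s_start <- L - b1 + 1L; s_end <- L - b2 + 1L
        }
        frame <- strand * off
        out[[length(out) + 1L]] <- data.frame(
          orf_id = sprintf("%s:%+d:%d-%d", g$replicon_id, frame,
                           s_start, s_end),
          replicon_id = g$replicon_id,
          frame = frame,
          span_start = s_start,
          span_end = s_end,
          aa = seg$aa,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orf_id = character(), replicon_id = character(),
                      frame = integer(), span_start = integer(),
                      span_end = integer(), aa = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon_id, res$frame, pmin(res$span_start,
                                                    res$span_end)), ]
  rownames(res) <- NULL
  res
}

# Split a frame translation at stops; return codon index ranges of kept
# segments. `first`/`last` are 1-based codon indices within the frame.
orf_segments <- function(aa, min_length_aa, require_both_stops) {
  n <- nchar(aa)
  empty <- data.frame(first = integer(), last = integer(), aa = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
  bounds_lo <- c(1L, stops + 1L)
  bounds_hi <- c(stops - 1L, n)
  has_stop_before <- c(FALSE, rep(TRUE, length(stops)))
  has_stop_after <- c(rep(TRUE, length(stops)), FALSE)
  keep <- (bounds_hi - bounds_lo + 1L) >= min_length_aa
  if (require_both_stops) keep <- keep & has_stop_before & has_stop_after
  if (!any(keep)) return(empty)
  lo <- bounds_lo[keep]; hi <- bounds_hi[keep]
  data.frame(first = lo, last = hi,
             aa = substring(aa, lo, hi),
             stringsAsFactors = FALSE)
}

#' Build the protein search database from enumerated ORFs
#'
#' Writes the database FASTA with headers that encode genomic placement
#' (`orf_id|replicon|frame|span_start|span_end`), so coordinates are
#' recoverable from the header alone. Contaminant proteins (e.g. trypsin,
#' keratins) are appended with a `CONTAM_` id prefix.
#'
#' @param orfs ORF data frame from [enumerate_orfs()].
#' @param contaminant_path Optional FASTA of contaminant proteins.
#' @param out Optional output FASTA path.
#' @param min_length_aa Recorded threshold (metadata only).
#' @return A list of class `orf_db` with elements `orfs`, `contaminants`
#'   (data frame `id`, `aa`) and `min_length_aa`.
#' @export
build_search_db <- function(orfs, contaminant_path = NULL, out = NULL,
                            min_length_aa = 41L) {
  if (anyDuplicated(orfs$orf_id)) {
    stop("duplicate orf_ids: ",
         paste(unique(orfs$orf_id[duplicated(orfs$orf_id)]), collapse = ", "))
  }
  contaminants <- data.frame(id = character(), aa = character(),
                             stringsAsFactors = FALSE)
  if (!is.null(contaminant_path)) {
    cset <- Biostrings::readAAStringSet(contaminant_path)
    ids <- vapply(strsplit(names(cset), "\\s+"), `[`, character(1), 1L)
    contaminants <- data.frame(id = paste0("CONTAM_", ids),
                               aa = as.character(cset),
                               stringsAsFactors = FALSE)
  }
  db <- structure(list(orfs = orfs, contaminants = contaminants,
                       min_length_aa = as.integer(min_length_aa)),
                  class = "orf_db")
  if (!is.null(out)) write_search_db(db, out)
  db
}

#' Write an ORF database as FASTA
#' @param db An `orf_db`.
#' @param path Output FASTA path (60-character wrapped).
#' @return `path`, invisibly.
#' @export
write_search_db <- function(db, path) {
  orfs <- db$orfs
  seqs <- c(orfs$aa, db$contaminants$aa)
  hdrs <- c(sprintf("%s|%s|%+d|%d|%d", orfs$orf_id, orfs$replicon_id,
                    orfs$frame, orfs$span_start, orfs$span_end),
            db$contaminants$id)
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an ORF database FASTA written by [write_search_db()]
#' @param path FASTA path.
#' @param min_length_aa Threshold to record in the returned object.
#' @return An `orf_db`.
#' @export
read_search_db <- function(path, min_length_aa = 41L) {
  set <- Biostrings::readAAStringSet(path)
  hdr <- names(set)
  is_contam <- startsWith(hdr, "CONTAM_")
  parts <- strsplit(hdr[!is_contam], "|", fixed = TRUE)
  if (any(lengths(parts) != 5L)) {
    stop("malformed ORF database headers in ", path)
  }
  orfs <- data.frame(
    orf_id = vapply(parts, `[`, character(1), 1L),
    replicon_id = vapply(parts, `[`, character(1), 2L),
    frame = as.integer(vapply(parts, `[`, character(1), 3L)),
    span_start = as.integer(vapply(parts, `[`, character(1), 4L)),
    span_end = as.integer(vapply(parts, `[`, character(1), 5L)),
    aa = as.character(set[!is_contam]),
    stringsAsFactors = FALSE
  )
  contaminants <- data.frame(id = hdr[is_contam],
                             aa = as.character(set[is_contam]),
                             stringsAsFactors = FALSE)
  structure(list(orfs = orfs, contaminants = contaminants,
                 min_length_aa = as.integer(min_length_aa)),
            class = "orf_db")
}

# Strand (+1/-1) implied by a CDS or ORF reading-direction span.
span_strand <- function(start_coord, stop_coord) {
  ifelse(start_coord > stop_coord, -1L, 1L)
}

# Reading frame (as in enumerate_orfs) of an in-frame position on a strand.
# `pos` is the genomic coordinate of a codon's first base in reading
# direction.
position_frame <- function(pos, strand, replicon_len) {
  off <- ifelse(strand == 1L, (pos - 1L) %% 3L + 1L,
                (replicon_len - pos) %% 3L + 1L)
  strand * off
}

#' Find the stop-to-stop ORF containing an annotated CDS
#'
#' A CDS is contained in the ORF on the same replicon and frame whose span
#' covers it. Returns the matching `orf_id`s (NA where no ORF contains the
#' CDS, e.g. because the CDS is shorter than the database threshold or
#' interrupted by an in-frame stop).
#'
#' @param ann An `annotation_set`.
#' @param db An `orf_db`.
#' @param genomes Named list of genome records (for frame arithmetic).
#' @return Character vector of `orf_id` (or `NA`) parallel to `ann` rows.
#' @export
containing_orf <- function(ann, db, genomes) {
  if (nrow(ann) == 0) return(character(0))
  orfs <- db$orfs
  lens <- vapply(genomes, function(g) nchar(g$sequence), integer(1))
  vapply(seq_len(nrow(ann)), function(i) {
    cds <- ann[i, ]
    strand <- span_strand(cds$start_coord, cds$stop_coord)
    frame <- position_frame(cds$start_coord, strand, lens[[cds$replicon_id]])
    lo <- min(cds$start_coord, cds$stop_coord)
    hi <- max(cds$start_coord, cds$stop_coord)
    cand <- orfs$replicon_id == cds$replicon_id & orfs$frame == frame &
      pmin(orfs$span_start, orfs$span_end) <= lo &
      pmax(orfs$span_start, orfs$span_end) >= hi
    # the annotated span may include the terminal stop codon, which lies
    # just beyond the ORF's translated span
    if (!any(cand)) {
      hi2 <- hi - ifelse(strand == 1L, 3L, 0L)
      lo2 <- lo + ifelse(strand == 1L, 0L, 3L)
      cand <- orfs$replicon_id == cds$replicon_id & orfs$frame == frame &
        pmin(orfs$span_start, orfs$span_end) <= lo2 &
        pmax(orfs$span_start, orfs$span_end) >= hi2
    }
    if (!any(cand)) NA_character_ else orfs$orf_id[which(cand)[1]]
  }, character(1))
}

#' Build the restricted second-pass database
#'
#' The restricted database is the union of (i) the stop-to-stop ORFs that
#' contain an annotated CDS in the same frame and (ii) the ORFs pointed to
#' by the first search pass. Annotated CDSs with no containing ORF are
#' reported in a warning.
#'
#' @param db Full `orf_db`.
#' @param annotation An `annotation_set`.
#' @param first_pass_hits Character vector of `orf_id`s from the first pass.
#' @param genomes Named list of genome records.
#' @return An `orf_db` restricted to the union, contaminants retained.
#' @export
build_restricted_db <- function(db, annotation, first_pass_hits = character(),
                                genomes) {
  if (!all(first_pass_hits %in% db$orfs$orf_id)) {
    stop("first_pass_hits contains unknown orf_ids: ",
         paste(head(setdiff(first_pass_hits, db$orfs$orf_id), 5),
               collapse = ", "))
  }
  ann_orfs <- containing_orf(annotation, db, genomes)
  if (anyNA(ann_orfs)) {
    warning("annotated CDS with no containing ORF: ",
            paste(annotation$locus_tag[is.na(ann_orfs)], collapse = ", "))
  }
  keep <- union(stats::na.omit(ann_orfs), first_pass_hits)
  res <- db
  res$orfs <- db$orfs[db$orfs$orf_id %in% keep, , drop = FALSE]
  rownames(res$orfs) <- NULL
  res
}
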