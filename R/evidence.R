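PSM_COLUMNS <- c("peptide", "orf_id", "p_value", "rank", "spectral_count",
                 "condition", "tryptic_status")

#' Read a peptide-spectrum-match table
#'
#' The evidence interchange format is a tab-separated table with a header
#' row and columns `peptide`, `orf_id`, `p_value`, `rank`,
#' `spectral_count`, `condition`, `tryptic_status`. Isoleucine/leucine are
#' kept distinct as written. Malformed rows (non-positive or >1 p-values,
#' rank < 1, spectral count < 1, empty peptide) are rejected with a warning
#' listing their line numbers.
#'
#' @param path TSV path.
#' @return Data frame of PSM records.
#' @export
read_psm_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(PSM_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("PSM table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, PSM_COLUMNS, drop = FALSE]
  tab$peptide <- as.character(tab$peptide)
  tab$orf_id <- as.character(tab$orf_id)
  tab$p_value <- as.numeric(tab$p_value)
  tab$rank <- as.integer(tab$rank)
  tab$spectral_count <- as.integer(tab$spectral_count)
  bad <- is.na(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1 |
    is.na(tab$rank) | tab$rank < 1L |
    is.na(tab$spectral_count) | tab$spectral_count < 1L |
    is.na(tab$peptide) | nchar(tab$peptide) == 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed PSM row(s) at line(s): ",
            paste(head(which(bad) + 1L, 20), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a PSM table
#' @param psms PSM data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms[, PSM_COLUMNS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter PSMs on identity threshold and rank
#'
#' Retains rank-1 matches whose p-value is strictly below the threshold
#' (a record at exactly the threshold is removed).
#'
#' @param psms PSM data frame.
#' @param p_threshold Identity threshold (default 0.005).
#' @return Filtered PSM data frame.
#' @export
filter_psms <- function(psms, p_threshold = 0.005) {
  out <- psms[psms$rank == 1L & psms$p_value < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a reversed decoy database
#'
#' Each ORF (and contaminant) sequence is reversed in full; decoy ids carry
#' a `DECOY_` prefix.
#'
#' @param db An `orf_db`.
#' @return An `orf_db` of reversed sequences.
#' @export
make_decoy_db <- function(db) {
  rev_str <- function(x) {
    vapply(lapply(strsplit(x, "", fixed = TRUE), rev), paste,
           character(1), collapse = "")
  }
  res <- db
  res$orfs$aa <- rev_str(db$orfs$aa)
  res$orfs$orf_id <- paste0("DECOY_", db$orfs$orf_id)
  if (nrow(res$contaminants) > 0) {
    res$contaminants$aa <- rev_str(db$contaminants$aa)
    res$contaminants$id <- paste0("DECOY_", db$contaminants$id)
  }
  res
}

#' Decoy-based false discovery rate
#'
#' FDR = (number of decoy identifications) / (number of target
#' identifications), counting distinct peptide sequences (`"peptide"`),
#' distinct ORF ids (`"protein"`), or assigned spectra (`"spectrum"`) --
#' distinct-sequence and spectrum accounting can differ, so both are
#' available and labelled. Returned as a fraction; reports multiply
#' by 100.
#'
#' @param target_psms,decoy_psms PSM data frames (already filtered).
#' @param level `"peptide"`, `"protein"` or `"spectrum"`.
#' @return FDR fraction; `NA_real_` (with a warning) when there are no
#'   target identifications, a case in which the rate is undefined.
#' @export
decoy_fdr <- function(target_psms, decoy_psms, level = c("peptide",
                                                         "protein",
                                                         "spectrum")) {
  level <- match.arg(level)
  if (level == "spectrum") {
    n_target <- sum(target_psms$spectral_count)
    n_decoy <- sum(decoy_psms$spectral_count)
  } else {
    key <- if (level == "peptide") "peptide" else "orf_id"
    n_target <- length(unique(target_psms[[key]]))
    n_decoy <- length(unique(decoy_psms[[key]]))
  }
  if (n_target == 0) {
    warning("no target identifications; decoy FDR undefined")
    return(NA_real_)
  }
  n_decoy / n_target
}

# Locate every occurrence of each distinct peptide across all DB sequences.
# Returns a data frame (peptide, orf_id, aa_offset0) where aa_offset0 is the
# 0-based residue offset within the ORF. Contaminants are searched too and
# reported with their CONTAM_ id and offset; they carry no coordinates.
peptide_db_hits <- function(peptides, db) {
  seqs <- c(db$orfs$aa, db$contaminants$aa)
  ids <- c(db$orfs$orf_id, db$contaminants$id)
  if (length(seqs) == 0 || length(peptides) == 0) {
    return(data.frame(peptide = character(), orf_id = character(),
                      aa_offset0 = integer(), stringsAsFactors = FALSE))
  }
  big <- paste(seqs, collapse = "#")
  starts <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]
  out <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    hit <- gregexpr(pep, big, fixed = TRUE)[[1]]
    if (hit[1] == -1L) next
    idx <- findInterval(hit, starts)
    off <- hit - starts[idx]
    # a fixed-string match can never span the '#' separator because
    # peptides contain no '#'
    out[[i]] <- data.frame(peptide = pep, orf_id = ids[idx],
                           aa_offset0 = as.integer(off),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(peptide = character(), orf_id = character(),
                      aa_offset0 = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Convert a 0-based aa offset within an ORF to genomic coordinates of the
# peptide span (reading direction).
orf_offset_to_genomic <- function(orf, aa_offset0, pep_len) {
  if (orf$frame > 0) {
    gs <- orf$span_start + 3L * aa_offset0
    ge <- gs + 3L * pep_len - 1L
  } else {
    gs <- orf$span_start - 3L * aa_offset0
    ge <- gs - 3L * pep_len + 1L
  }
  c(gs, ge)
}

# Hits for semi-tryptic N-terminal peptides whose retained initiator Met
# is encoded by GTG/TTG: the six-frame translation shows Val/Leu at that
# residue, so the peptide is located by its tail and anchored one residue
# upstream (the dedicated initiator-Met search mode of engine searches).
semi_retained_hits <- function(peptides, db) {
  peps <- unique(peptides)
  peps <- peps[startsWith(peps, "M") & nchar(peps) >= 2L]
  if (length(peps) == 0) {
    return(data.frame(peptide = character(), orf_id = character(),
                      aa_offset0 = integer(), stringsAsFactors = FALSE))
  }
  th <- peptide_db_hits(substring(peps, 2L), db)
  th <- th[th$aa_offset0 >= 1L, , drop = FALSE]
  idx <- match(th$peptide, substring(peps, 2L))
  prev <- substring(vapply(match(th$orf_id, c(db$orfs$orf_id,
                                              db$contaminants$id)),
                           function(i) c(db$orfs$aa,
                                         db$contaminants$aa)[i],
                           character(1)),
                    th$aa_offset0, th$aa_offset0)
  keep <- prev %in% c("V", "L")   # GTG/TTG translation product
  data.frame(peptide = peps[idx][keep], orf_id = th$orf_id[keep],
             aa_offset0 = th$aa_offset0[keep] - 1L,
             stringsAsFactors = FALSE)
}

#' Map peptides onto genome coordinates
#'
#' Each distinct peptide sequence is located in every database ORF it
#' occurs in; residue offsets are converted to genomic coordinates via the
#' ORF's frame and span, and (when `genomes` is supplied) each placement is
#' verified by re-translating the genomic span. Peptides occurring in more
#' than one ORF are mapped to all of them and flagged `shared`; a PSM whose
#' claimed ORF does not contain its peptide is a mapping error.
#'
#' @param psms Filtered PSM data frame.
#' @param db An `orf_db`.
#' @param genomes Named list of genome records; when supplied, the
#'   re-translation round trip is asserted for every mapping.
#' @return Data frame of mapped peptides: `peptide`, `orf_id`,
#'   `replicon_id`, `frame`, `aa_offset0`, `genomic_start`, `genomic_end`,
#'   `tryptic_status`, `shared`.
#' @export
map_psms <- function(psms, db, genomes = NULL) {
  peps <- unique(psms$peptide)
  hits <- peptide_db_hits(peps, db)
  semi_peps <- unique(psms$peptide[psms$tryptic_status == "semi_N"])
  semi_peps <- setdiff(semi_peps, hits$peptide)
  if (length(semi_peps) > 0) {
    hits <- rbind(hits, semi_retained_hits(semi_peps, db))
  }
  hits <- hits[!startsWith(hits$orf_id, "CONTAM_"), , drop = FALSE]
  n_orfs_hit <- tapply(hits$orf_id, hits$peptide,
                       function(x) length(unique(x)))
  claimed <- unique(psms[, c("peptide", "orf_id"), drop = FALSE])
  bad <- !paste(claimed$peptide, claimed$orf_id) %in%
    paste(hits$peptide, hits$orf_id)
  bad <- bad & !startsWith(claimed$orf_id, "CONTAM_")
  if (any(bad)) {
    stop("PSM peptide(s) not found in their claimed ORF (corrupt evidence): ",
         paste(head(claimed$peptide[bad], 5), collapse = ", "))
  }
  if (nrow(hits) == 0) {
    return(data.frame(peptide = character(), orf_id = character(),
                      replicon_id = character(), frame = integer(),
                      aa_offset0 = integer(), genomic_start = integer(),
                      genomic_end = integer(), tryptic_status = character(),
                      shared = logical(), stringsAsFactors = FALSE))
  }
  orfs <- db$orfs
  oi <- match(hits$orf_id, orfs$orf_id)
  pl <- nchar(hits$peptide)
  plus <- orfs$frame[oi] > 0
  gs <- ifelse(plus, orfs$span_start[oi] + 3L * hits$aa_offset0,
               orfs$span_start[oi] - 3L * hits$aa_offset0)
  ge <- ifelse(plus, gs + 3L * pl - 1L, gs - 3L * pl + 1L)
  mapped <- data.frame(
    peptide = hits$peptide,
    orf_id = hits$orf_id,
    replicon_id = orfs$replicon_id[oi],
    frame = orfs$frame[oi],
    aa_offset0 = hits$aa_offset0,
    genomic_start = as.integer(gs),
    genomic_end = as.integer(ge),
    shared = unname(n_orfs_hit[hits$peptide] > 1L),
    stringsAsFactors = FALSE
  )
  # a peptide sequence can be reported both as a fully tryptic match and
  # as a semi-tryptic N-terminal match; keep one mapped row per status
  status_pairs <- unique(psms[, c("peptide", "tryptic_status")])
  mapped <- merge(mapped, status_pairs, by = "peptide", sort = FALSE)
  if (!is.null(genomes)) {
    for (i in seq_len(nrow(mapped))) {
      g <- genomes[[mapped$replicon_id[i]]]
      dna <- span_sequence(g, mapped$genomic_start[i],
                           mapped$genomic_end[i])
      aa <- translate_str(dna)
      ok <- aa == mapped$peptide[i] ||
        # retained initiator Met over a GTG/TTG codon
        (startsWith(mapped$peptide[i], "M") &&
           substr(dna, 1, 3) %in% c("GTG", "TTG") &&
           substring(aa, 2) == substring(mapped$peptide[i], 2))
      if (!ok) {
        stop("re-translation mismatch for peptide ", mapped$peptide[i],
             " at ", mapped$genomic_start[i], "-", mapped$genomic_end[i])
      }
    }
  }
  mapped
}

#' Aggregate mapped peptides into protein-level evidence
#'
#' Groups by ORF: distinct peptide sequences are counted (shared peptides,
#' i.e. those occurring in several ORFs, do not count towards validation),
#' spectral counts are summed and the best p-value retained. An ORF with at
#' least two distinct unshared peptides is `validated`; with exactly one it
#' is a `one_hit`; spectra do not substitute for distinct peptides.
#'
#' @param mapped Output of [map_psms()].
#' @param psms The filtered PSM data frame (for spectral counts and
#'   p-values).
#' @return Data frame `orf_id`, `n_peptides` (distinct unshared),
#'   `n_peptides_all`, `total_spectra`, `best_p_value`, `status`
#'   (`validated` / `one_hit` / `unsupported`).
#' @export
aggregate_to_proteins <- function(mapped, psms) {
  if (nrow(mapped) == 0) {
    return(data.frame(orf_id = character(), n_peptides = integer(),
                      n_peptides_all = integer(), total_spectra = integer(),
                      best_p_value = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  u <- unique(mapped[, c("peptide", "orf_id", "shared")])
  per_pep <- psms[!duplicated(psms$peptide), ]
  spectra <- tapply(psms$spectral_count, psms$peptide, sum)
  bestp <- tapply(psms$p_value, psms$peptide, min)
  split_idx <- split(seq_len(nrow(u)), u$orf_id)
  res <- lapply(names(split_idx), function(oid) {
    rows <- split_idx[[oid]]
    peps <- u$peptide[rows]
    n_uns <- sum(!u$shared[rows][!duplicated(peps)])
    n_all <- length(unique(peps))
    data.frame(orf_id = oid,
               n_peptides = as.integer(n_uns),
               n_peptides_all = as.integer(n_all),
               total_spectra = as.integer(sum(spectra[unique(peps)])),
               best_p_value = min(bestp[unique(peps)]),
               status = if (n_uns >= 2L) "validated"
                        else if (n_uns == 1L) "one_hit" else "unsupported",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
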