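# Clade extension: a desk-scale translated homology search (local
# Smith-Waterman under BLOSUM62 with affine gaps and a Karlin-Altschul
# E-value scale) plus start-consensus logic, used to propagate novel genes
# and certified N-termini to related genomes. A k-mer seed prefilter keeps
# the all-against-all searches tractable; an import path for standard
# 12-column tabular hit files lets real-genome runs use an external search
# engine instead.

#' Alignment parameters
#'
#' BLOSUM62 with affine gap penalties (open 11, extend 1) and published
#' gapped Karlin-Altschul parameters (K = 0.041, lambda = 0.267), which
#' reproduce the E-value scale of standard protein searches. E-values are
#' approximate; threshold behaviour, not engine-exact E-values, is what the
#' package asserts.
#'
#' @param ... Named overrides (`gap_open`, `gap_extend`, `karlin_k`,
#'   `karlin_lambda`, `seed_word_aa`).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(...) {
  p <- list(matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L,
            karlin_k = 0.041, karlin_lambda = 0.267, seed_word_aa = 3L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown alignment_params field(s): ",
         paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  structure(p, class = "alignment_params")
}

.matrix_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (is.null(.matrix_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .matrix_cache[[name]] <- get(name, envir = e)
  }
  .matrix_cache[[name]]
}

#' Optimal local alignment score and coordinates
#'
#' Smith-Waterman local alignment under the configured substitution matrix
#' and affine gap penalties (a gap of length k costs
#' `gap_open + k * gap_extend`). A pair with no positive-scoring local
#' alignment returns score 0 and an empty alignment.
#'
#' @param query_aa,subject_aa Protein strings.
#' @param params An [alignment_params()].
#' @param score_only If `TRUE`, skip traceback and return only the score
#'   (faster for bulk screening).
#' @return A list with `score` and (unless `score_only`) `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `query_aligned`,
#'   `subject_aligned`.
#' @export
smith_waterman <- function(query_aa, subject_aa,
                           params = alignment_params(),
                           score_only = FALSE) {
  stopifnot(nchar(query_aa) > 0, nchar(subject_aa) > 0)
  if (score_only) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = query_aa, subject = subject_aa, type = "local",
      substitutionMatrix = substitution_matrix(params$matrix),
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    return(list(score = max(0, sc)))
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = query_aa, subject = subject_aa, type = "local",
    substitutionMatrix = substitution_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = 0, query_start = NA_integer_,
                query_end = NA_integer_, subject_start = NA_integer_,
                subject_end = NA_integer_, query_aligned = "",
                subject_aligned = ""))
  }
  pat <- Biostrings::alignedPattern(al)[[1]]
  sub <- Biostrings::alignedSubject(al)[[1]]
  list(score = sc,
       query_start = al@pattern@range@start,
       query_end = al@pattern@range@start + al@pattern@range@width - 1L,
       subject_start = al@subject@range@start,
       subject_end = al@subject@range@start + al@subject@range@width - 1L,
       query_aligned = as.character(pat),
       subject_aligned = as.character(sub))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` with m the query length and n the
#' database residue count.
#'
#' @param raw_score Alignment raw score S (vectorised).
#' @param query_len Query length m.
#' @param db_residues Total database residues n.
#' @param params An [alignment_params()].
#' @return Numeric E-value(s).
#' @export
evalue <- function(raw_score, query_len, db_residues,
                   params = alignment_params()) {
  stopifnot(query_len > 0, db_residues > 0)
  params$karlin_k * query_len * db_residues *
    exp(-params$karlin_lambda * raw_score)
}

# Element-wise batched local alignment of paired sequence vectors; one
# engine call amortises the per-call construction overhead.
sw_batch <- function(queries, subjects, params = alignment_params(),
                     score_only = FALSE) {
  stopifnot(length(queries) == length(subjects))
  if (length(queries) == 0) {
    return(data.frame(score = numeric(), qstart = integer(),
                      qend = integer(), sstart = integer(),
                      send = integer()))
  }
  mat <- substitution_matrix(params$matrix)
  if (score_only) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(queries),
      subject = Biostrings::AAStringSet(subjects), type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
    return(data.frame(score = pmax(0, sc), qstart = NA_integer_,
                      qend = NA_integer_, sstart = NA_integer_,
                      send = NA_integer_))
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAStringSet(subjects), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  pr <- al@pattern@range
  sr <- al@subject@range
  data.frame(score = Biostrings::score(al),
             qstart = IRanges::start(pr), qend = IRanges::end(pr),
             sstart = IRanges::start(sr), send = IRanges::end(sr))
}

# Indices of subject sequences sharing at least `min_hits` exact k-mer
# words with the query (the two-hit seed heuristic of word-based search).
seed_candidates <- function(query, subjects, k = 3L, min_hits = 2L) {
  seed_lookup(query, seed_index(subjects, k), length(subjects), k,
              min_hits)
}

kmer_set <- function(s, k) {
  if (nchar(s) < k) return(character())
  unique(substring(s, seq_len(nchar(s) - k + 1L),
                   seq_len(nchar(s) - k + 1L) + k - 1L))
}

# inverted k-mer index: word -> subject indices (computed once per
# subject set, then shared across queries)
seed_index <- function(subjects, k = 3L) {
  words <- lapply(subjects, kmer_set, k = k)
  split(rep(seq_along(subjects), lengths(words)), unlist(words))
}

seed_lookup <- function(query, index, n_subjects, k = 3L, min_hits = 2L) {
  qk <- kmer_set(query, k)
  hit <- unlist(index[qk], use.names = FALSE)
  if (is.null(hit)) return(integer())
  counts <- tabulate(hit, nbins = n_subjects)
  which(counts >= min_hits)
}

#' Search for unannotated homologous regions in subject genomes
#'
#' Each novel protein is searched against the six-frame stop-to-stop ORFs
#' of each subject genome (translated-search stand-in); hits below the
#' novel-gene E-value cutoff are kept, and hits whose subject span overlaps
#' an annotated CDS are dropped, so only homologous regions not previously
#' annotated as CDSs are reported.
#'
#' @param novel_proteins Named character vector of query proteins.
#' @param subject_genomes Named list (one element per subject) of genome
#'   record lists.
#' @param subject_annotations Named list of `annotation_set`s, parallel to
#'   `subject_genomes`.
#' @param config A [pipeline_config()] (`evalue_novel` used).
#' @param params An [alignment_params()].
#' @return Data frame `query_id`, `subject`, `subject_replicon`,
#'   `subject_start`, `subject_stop` (reading-direction convention),
#'   `score`, `e_value`, `query_from`, `query_to`.
#' @export
find_unannotated_homologs <- function(novel_proteins, subject_genomes,
                                      subject_annotations,
                                      config = pipeline_config(),
                                      params = alignment_params()) {
  out <- list()
  for (sn in names(subject_genomes)) {
    genomes <- subject_genomes[[sn]]
    ann <- subject_annotations[[sn]]
    orfs <- enumerate_orfs(genomes, min_length_aa = config$min_orf_aa)
    nres <- sum(nchar(orfs$aa))
    idx <- seed_index(orfs$aa, params$seed_word_aa)
    pair_q <- integer(); pair_o <- integer()
    for (qi in seq_along(novel_proteins)) {
      cand <- seed_lookup(novel_proteins[[qi]], idx, nrow(orfs),
                          params$seed_word_aa)
      pair_q <- c(pair_q, rep(qi, length(cand)))
      pair_o <- c(pair_o, cand)
    }
    if (length(pair_q) == 0) next
    scr <- sw_batch(unname(novel_proteins)[pair_q], orfs$aa[pair_o],
                    params, score_only = TRUE)$score
    ev <- evalue(scr, nchar(novel_proteins)[pair_q], nres, params)
    keep <- which(scr > 0 & ev < config$evalue_novel)
    if (length(keep) == 0) next
    al <- sw_batch(unname(novel_proteins)[pair_q[keep]],
                   orfs$aa[pair_o[keep]], params)
    for (j in seq_along(keep)) {
      k <- keep[j]
      orf <- orfs[pair_o[k], ]
      hit_start <- orf_residue_pos(orf, al$sstart[j])
      hit_stop <- if (orf$frame > 0) {
        orf_residue_pos(orf, al$send[j]) + 2L
      } else {
        orf_residue_pos(orf, al$send[j]) - 2L
      }
      lo <- min(hit_start, hit_stop); hi <- max(hit_start, hit_stop)
      if (nrow(ann) > 0) {
        ov <- ann$replicon_id == orf$replicon_id &
          overlaps_interval(pmin(ann$start_coord, ann$stop_coord),
                            pmax(ann$start_coord, ann$stop_coord), lo, hi)
        if (any(ov)) next
      }
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(novel_proteins)[pair_q[k]], subject = sn,
        subject_replicon = orf$replicon_id,
        subject_start = hit_start, subject_stop = hit_stop,
        score = al$score[j], e_value = ev[k],
        query_from = al$qstart[j], query_to = al$qend[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_id = character(), subject = character(),
                      subject_replicon = character(),
                      subject_start = integer(), subject_stop = integer(),
                      score = numeric(), e_value = numeric(),
                      query_from = integer(), query_to = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # keep the best hit per (query, subject replicon) region; duplicates can
  # arise when seeds fire on overlapping ORFs
  res <- res[order(res$e_value), ]
  res <- res[!duplicated(paste(res$query_id, res$subject,
                               res$subject_replicon)), ]
  rownames(res) <- NULL
  res
}

#' Propagate certified N-termini to subject proteomes
#'
#' For each query protein whose N-terminus has been certified by peptide
#' evidence, homologous subject proteins (annotated proteome, protein-level
#' search at the N-terminus E-value cutoff) are aligned and the subject
#' residue implied to pair with query residue 1 is computed by trimming the
#' local alignment back to the N-terminus. Offset 0 confirms the subject's
#' annotated start; otherwise a canonical codon at the implied start
#' position in the subject genome is required to propose a correction
#' (positive offsets mean the subject annotation is too long); a subject
#' whose implied start holds no canonical codon stays undecidable and is
#' never force-corrected.
#'
#' @param nterm_proteins Data frame with columns `query_id`, `protein`
#'   (sequence beginning at the certified N-terminal residue).
#' @param subjects Named list; each element a list with `genomes` (named
#'   genome-record list) and `annotation` (an `annotation_set`).
#' @param config A [pipeline_config()] (`evalue_nterm` used).
#' @param params An [alignment_params()].
#' @return A list with `calls` (data frame `query_id`, `subject`,
#'   `subject_locus`, `verdict` in confirmed/corrected/undecidable,
#'   `offset_codons`, `proposed_start`, `e_value`) and `rate` =
#'   corrected / (confirmed + corrected + undecidable).
#' @export
propagate_start_corrections <- function(nterm_proteins, subjects,
                                        config = pipeline_config(),
                                        params = alignment_params()) {
  rows <- list()
  for (sn in names(subjects)) {
    sub <- subjects[[sn]]
    ann <- sub$annotation
    genomes <- sub$genomes
    prots <- vapply(seq_len(nrow(ann)), function(i) {
      extract_and_translate(genomes[[ann$replicon_id[i]]], ann[i, ])
    }, character(1))
    nres <- sum(nchar(prots))
    idx <- seed_index(prots, params$seed_word_aa)
    pair_q <- integer(); pair_s <- integer()
    for (qi in seq_len(nrow(nterm_proteins))) {
      cand <- seed_lookup(nterm_proteins$protein[qi], idx, length(prots),
                          params$seed_word_aa)
      pair_q <- c(pair_q, rep(qi, length(cand)))
      pair_s <- c(pair_s, cand)
    }
    if (length(pair_q) == 0) next
    scr <- sw_batch(nterm_proteins$protein[pair_q], prots[pair_s], params,
                    score_only = TRUE)$score
    # best-scoring homolog per query at the N-terminus E-value cutoff
    best <- vapply(split(seq_along(pair_q), pair_q),
                   function(ii) ii[which.max(scr[ii])], integer(1))
    ev_best <- evalue(scr[best], nchar(nterm_proteins$protein[pair_q[best]]),
                      nres, params)
    best <- best[ev_best < config$evalue_nterm]
    ev_best <- ev_best[ev_best < config$evalue_nterm]
    if (length(best) == 0) next
    als <- sw_batch(nterm_proteins$protein[pair_q[best]],
                    prots[pair_s[best]], params)
    for (j in seq_along(best)) {
      qi <- pair_q[best[j]]
      al <- list(score = als$score[j], query_start = als$qstart[j],
                 subject_start = als$sstart[j])
      ev <- ev_best[j]
      offset <- al$subject_start - al$query_start
      cds <- ann[pair_s[best[j]], ]
      g <- genomes[[cds$replicon_id]]
      dirn <- if (cds$start_coord > cds$stop_coord) -1L else 1L
      if (offset == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = nterm_proteins$query_id[qi], subject = sn,
          subject_locus = cds$locus_tag, verdict = "confirmed",
          offset_codons = 0L, proposed_start = NA_integer_, e_value = ev,
          stringsAsFactors = FALSE)
      } else {
        pos <- cds$start_coord + dirn * 3L * offset
        codon <- codon_at_genomic(g, pos, dirn)
        verdict <- if (!is.na(codon) &&
                       codon %in% config$canonical_starts) "corrected"
                   else "undecidable"
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = nterm_proteins$query_id[qi], subject = sn,
          subject_locus = cds$locus_tag, verdict = verdict,
          offset_codons = as.integer(offset),
          proposed_start = if (verdict == "corrected") as.integer(pos)
                           else NA_integer_,
          e_value = ev, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows) == 0) {
    data.frame(query_id = character(), subject = character(),
               subject_locus = character(), verdict = character(),
               offset_codons = integer(), proposed_start = integer(),
               e_value = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(calls) <- NULL
  n <- nrow(calls)
  rate <- if (n == 0) NA_real_ else sum(calls$verdict == "corrected") / n
  list(calls = calls, rate = rate)
}

# Codon whose first base in reading direction sits at genomic position
# `pos` on the given strand; NA when out of bounds.
codon_at_genomic <- function(genome, pos, strand) {
  L <- nchar(genome$sequence)
  if (strand > 0) {
    if (pos < 1L || pos + 2L > L) return(NA_character_)
    substr(genome$sequence, pos, pos + 2L)
  } else {
    if (pos - 2L < 1L || pos > L) return(NA_character_)
    revcomp(substr(genome$sequence, pos - 2L, pos))
  }
}

#' Read/write BLAST-style 12-column tabular hit files
#'
#' Accepts the standard tab-separated hit format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore) so real-genome runs can substitute an external
#' search engine for the built-in aligner.
#'
#' @param path Tabular hits path.
#' @return Data frame with the twelve standard columns.
#' @export
read_tabular_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12) stop("expected 12 tab-separated columns in ", path)
  names(tab) <- cols
  tab
}
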