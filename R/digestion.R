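#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue is
#' proline (Keil rule, matching the common search-engine "Trypsin"
#' definition), and emits peptides with 0 to `max_missed` internal missed
#' cleavage sites, filtered to a length window. The default 6--40 residue
#' window is the range typically observable by tandem MS; mapping functions
#' accept any supplied peptide regardless of this window.
#'
#' @param protein Protein string (20-letter alphabet, `X` allowed).
#' @param max_missed Maximum internal missed cleavages (default 1).
#' @param min_len,max_len Peptide length window (defaults 6 and 40).
#' @return Data frame with columns `sequence`, `start_offset` (0-based
#'   position in the parent protein), `tryptic_status` (`"full"`),
#'   `missed_cleavages`; ordered by start position then missed cleavages.
#' @export
tryptic_digest <- function(protein, max_missed = 1L, min_len = 6L,
                           max_len = 40L) {
  frags <- tryptic_fragments(protein)
  n <- length(frags$start)
  empty <- data.frame(sequence = character(), start_offset = integer(),
                      tryptic_status = character(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  out <- list()
  for (i in seq_len(n)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n) break
      s <- frags$start[i]
      e <- frags$end[j]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- list(sequence = substr(protein, s, e),
                                      start_offset = s - 1L,
                                      missed_cleavages = m)
    }
  }
  if (length(out) == 0) return(empty)
  data.frame(
    sequence = vapply(out, `[[`, character(1), "sequence"),
    start_offset = vapply(out, function(x) as.integer(x$start_offset),
                          integer(1)),
    tryptic_status = "full",
    missed_cleavages = vapply(out, function(x) as.integer(x$missed_cleavages),
                              integer(1)),
    stringsAsFactors = FALSE
  )
}

# 0-missed-cleavage fragment boundaries (1-based start/end positions).
tryptic_fragments <- function(protein) {
  n <- nchar(protein)
  if (n == 0) return(list(start = integer(), end = integer()))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  list(start = c(1L, sites + 1L), end = c(sites, n))
}

# Tryptic cleavage boundary positions usable as a peptide C-terminus:
# after K/R not before P, plus the protein end.
tryptic_cterm_positions <- function(protein) {
  n <- nchar(protein)
  if (n == 0) return(integer())
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  sort(unique(c(sites, n)))
}

#' Semi-tryptic N-terminal peptide candidates
#'
#' Enumerates the peptides whose C-terminus is a tryptic boundary (or the
#' protein end) but whose N-terminus is unconstrained, restricted to those
#' starting at protein positions 1 or 2 -- the only starts consistent with
#' an intact or methionine-excised N-terminus. These are the "plausible
#' most-N-terminal" peptides a semi-tryptic search can report.
#'
#' @param protein Protein string.
#' @param max_len Maximum peptide length (default 40).
#' @return Data frame as in [tryptic_digest()] with
#'   `tryptic_status = "semi_N"`; `missed_cleavages` counts internal
#'   cleavage sites spanned.
#' @export
semi_tryptic_nterm_candidates <- function(protein, max_len = 40L) {
  empty <- data.frame(sequence = character(), start_offset = integer(),
                      tryptic_status = character(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE)
  n <- nchar(protein)
  if (n < 2) return(empty)
  cterm <- tryptic_cterm_positions(protein)
  out <- list()
  for (s in 1:2) {
    ends <- cterm[cterm >= s & (cterm - s + 1L) <= max_len]
    for (e in ends) {
      inner <- cterm[cterm >= s & cterm < e]
      out[[length(out) + 1L]] <- list(sequence = substr(protein, s, e),
                                      start_offset = s - 1L,
                                      missed = length(inner))
    }
  }
  if (length(out) == 0) return(empty)
  data.frame(
    sequence = vapply(out, `[[`, character(1), "sequence"),
    start_offset = vapply(out, function(x) as.integer(x$start_offset),
                          integer(1)),
    tryptic_status = "semi_N",
    missed_cleavages = vapply(out, function(x) as.integer(x$missed),
                              integer(1)),
    stringsAsFactors = FALSE
  )
}
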