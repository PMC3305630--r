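# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths: the genetic code is
# spelled out, scans are naive per-frame loops, digestion enumerates every
# substring, and the aligner is a plain dynamic program.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(dna, 3L * i - 2L, 3L * i)
    out[i] <- if (codon %in% names(ORACLE_CODE)) ORACLE_CODE[[codon]]
              else "X"
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive six-frame stop-to-stop scan: returns data frame of
# (frame, span_start, span_end, aa) in reading-direction coordinates
oracle_orf_scan <- function(seqstr, min_aa, require_both_stops = FALSE) {
  L <- nchar(seqstr)
  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seqstr else oracle_revcomp(seqstr)
    for (off in 1:3) {
      aa <- oracle_translate(substr(s, off, nchar(s)))
      chars <- strsplit(aa, "")[[1]]
      i <- 1L
      while (i <= length(chars)) {
        if (chars[i] == "*") { i <- i + 1L; next }
        j <- i
        while (j < length(chars) && chars[j + 1L] != "*") j <- j + 1L
        bounded <- i > 1L && j < length(chars)
        if ((j - i + 1L) >= min_aa && (!require_both_stops || bounded)) {
          b1 <- off + 3L * (i - 1L)
          b2 <- off + 3L * j - 1L
          if (strand == 1L) {
            ss <- b1; se <- b2
          } else {
            ss <- L - b1 + 1L; se <- L - b2 + 1L
          }
          res[[length(res) + 1L]] <- data.frame(
            frame = strand * off, span_start = ss, span_end = se,
            aa = paste(chars[i:j], collapse = ""),
            stringsAsFactors = FALSE)
        }
        i <- j + 2L
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(frame = integer(), span_start = integer(),
                      span_end = integer(), aa = character()))
  }
  do.call(rbind, res)
}

# exhaustive substring digestion oracle: every substring whose boundaries
# are tryptic (start = 1 or after K/R-not-P; end = length or K/R-not-P)
# with at most max_missed internal cleavage sites
oracle_digest <- function(protein, max_missed, min_len, max_len) {
  n <- nchar(protein)
  ch <- strsplit(protein, "")[[1]]
  is_site <- function(i) i >= 1 && i < n && ch[i] %in% c("K", "R") &&
    ch[i + 1] != "P"
  out <- list()
  for (i in seq_len(n)) {
    if (!(i == 1 || is_site(i - 1))) next
    for (j in i:n) {
      if (!(j == n || is_site(j))) next
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      internal <- sum(vapply(i:(j - 1L), is_site, logical(1)))
      if (j == i) internal <- 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(protein, i, j), start_offset = i - 1L,
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(), start_offset = integer(),
                      missed_cleavages = integer()))
  }
  do.call(rbind, out)
}

# plain affine-gap local alignment DP (gap of length k costs
# open + k * extend), floored at zero
oracle_sw_score <- function(a, b, mat, open = 11, extend = 1) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

random_dna <- function(n, gc = 0.55) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# one standard simulated study, shared across test files
make_fixture <- function(seed = 7L, ...) {
  cfg <- simulation_config(seed = seed, ...)
  gen <- generate_genome(cfg)
  sim <- plant_errors(gen, cfg)
  db <- build_search_db(enumerate_orfs(sim$genomes))
  ps <- simulate_psms(sim, db, cfg)
  list(cfg = cfg, gen = gen, sim = sim, db = db, ps = ps)
}
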