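# Synthetic genomes with planted annotation errors and simulated peptide
# evidence, with a machine-readable ground-truth ledger. The generator
# emulates the inputs of a bacterial proteogenomic survey: protein-coding
# genes with canonical starts on both strands, a deliberately flawed
# "published" annotation carrying each error class (missed genes, starts
# annotated too long or too short, spurious overlapping CDSs, single-base
# insertions splitting a gene across reading frames), peptide-spectrum
# matches with spectral counts and p-values, and mutated sister genomes
# with planted start-annotation errors.

#' Simulation configuration
#'
#' Defaults describe a compact survey genome: ~60 kb, 40 genes, 60% GC,
#' the usual bacterial initiator mix (ATG 94%, GTG 5%, TTG 1%). Detection
#' is modelled as gene-level and peptide-level Bernoulli draws with
#' negative-binomial spectral counts; genes carrying planted errors are
#' always given the diagnostic evidence that defines their error class
#' (real reported error cases are, by construction, those for which such
#' evidence was observed). True-match p-values are drawn log-uniformly in
#' the interval 1e-9 to 1e-4 and random-match p-values uniformly around the identity
#' threshold, so both the 0.005 and the 3.2e-5 cutoffs are exercised.
#'
#' @param seed Integer seed; all generator stages derive their RNG state
#'   from it.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length_nt = 60000L,
    replicon_id = "synchr1",
    n_genes = 40L,
    gc_content = 0.60,
    start_codon_mix = c(ATG = 0.94, GTG = 0.05, TTG = 0.01),
    protein_len_range = c(90L, 300L),
    intergenic_range = c(80L, 220L),
    error_counts = c(missed_gene = 4L, wrong_start_long = 3L,
                     wrong_start_short = 3L, spurious_cds = 3L,
                     base_insertion = 2L),
    n_one_hit = 2L,
    n_one_hit_transcribed = 1L,
    gene_detect_p = 0.9,
    pep_detect_p = 0.9,
    nterm_detect_p = 0.7,
    met_removed_p = 0.7,
    spectral_size = 2,
    spectral_mu = 6,
    false_psm_rate = 0.01,
    clade = list(n_subjects = 3L, aa_divergence = 0.10,
                 subject_start_error_rate = 0.12, gene_loss_p = 0.05,
                 too_long_frac = 0.7)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown simulation_config field(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  probs <- c(cfg$gene_detect_p, cfg$pep_detect_p, cfg$nterm_detect_p,
             cfg$met_removed_p, cfg$false_psm_rate, cfg$start_codon_mix)
  stopifnot(all(probs >= 0 & probs <= 1), all(cfg$error_counts >= 0))
  structure(cfg, class = "sim_config")
}

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G"), paste0)),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_weights <- function(codons, gc) {
  p <- c(A = (1 - gc) / 2, T = (1 - gc) / 2, G = gc / 2, C = gc / 2)
  vapply(strsplit(codons, "", fixed = TRUE),
         function(b) prod(p[b]), numeric(1))
}

random_bases <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_sense_codons <- function(n, gc) {
  sample(SENSE_CODONS, n, replace = TRUE,
         prob = codon_weights(SENSE_CODONS, gc))
}

#' Generate a synthetic genome and its true annotation
#'
#' Genes are laid out sequentially with random intergenic spacers,
#' alternating strands at random; each gene is a canonical start codon
#' (drawn from the configured mix), stop-free random codons with the
#' configured GC bias, and a stop codon. Coordinates follow the
#' reading-direction convention and the annotated span includes the stop
#' codon. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes` (named list of one [genome_record()]),
#'   `annotation` (the true `annotation_set`) and `ledger` (class
#'   `sim_ledger`), whose `genes` table carries strand, coordinates, start
#'   codon and the true protein of every gene.
#' @export
generate_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  gc <- config$gc_content
  n <- config$n_genes
  lens <- sample(config$protein_len_range[1]:config$protein_len_range[2],
                 n, replace = TRUE)
  strands <- sample(c(1L, -1L), n, replace = TRUE)
  starts <- sample(names(config$start_codon_mix), n, replace = TRUE,
                   prob = config$start_codon_mix)
  gaps <- sample(config$intergenic_range[1]:config$intergenic_range[2],
                 n + 1L, replace = TRUE)
  total <- sum(gaps) + sum(3L * (lens + 1L))
  if (total > config$genome_length_nt) {
    stop("infeasible packing: ", n, " genes need ", total,
         " nt but genome_length_nt is ", config$genome_length_nt)
  }
  pieces <- character(0)
  pos <- 0L
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    spacer <- random_bases(gaps[i], gc)
    pieces <- c(pieces, spacer)
    pos <- pos + gaps[i]
    body <- random_sense_codons(lens[i] - 1L, gc)
    stopc <- sample(STOP_CODONS, 1L, prob = c(0.3, 0.25, 0.45))
    cds <- paste(c(starts[i], body, stopc), collapse = "")
    span <- nchar(cds)
    a <- pos + 1L
    b <- pos + span
    if (strands[i] == 1L) {
      pieces <- c(pieces, cds)
      start_coord <- a; stop_coord <- b
    } else {
      pieces <- c(pieces, revcomp(cds))
      start_coord <- b; stop_coord <- a
    }
    pos <- pos + span
    genes[[i]] <- data.frame(
      gene_id = sprintf("SYN_%04d", i), strand = strands[i],
      start_coord = start_coord, stop_coord = stop_coord,
      start_codon = starts[i], protein = NA_character_,
      stringsAsFactors = FALSE)
  }
  tail_len <- config$genome_length_nt - pos
  pieces <- c(pieces, random_bases(tail_len, gc))
  seqstr <- paste(pieces, collapse = "")
  g <- genome_record(config$replicon_id, seqstr)
  genomes <- setNames(list(g), config$replicon_id)
  genes <- do.call(rbind, genes)
  genes$replicon_id <- config$replicon_id
  genes$protein <- vapply(seq_len(n), function(i) {
    extract_and_translate(g, list(start_coord = genes$start_coord[i],
                                  stop_coord = genes$stop_coord[i]))
  }, character(1))
  genes$category <- "none"
  genes$frameshifted <- FALSE
  ann <- new_annotation_set(data.frame(
    locus_tag = genes$gene_id, replicon_id = genes$replicon_id,
    start_coord = genes$start_coord, stop_coord = genes$stop_coord,
    product = "hypothetical protein", source = "original",
    stringsAsFactors = FALSE), genome_ref = config$replicon_id)
  ledger <- structure(list(genes = genes,
                           errors = data.frame(),
                           transcribed_one_hit = character()),
                      class = "sim_ledger")
  list(genomes = genomes, annotation = ann, ledger = ledger)
}

# in-frame codon at reading-direction codon offset j upstream (j > 0) or
# within (j < 0 unused) of a gene start; returns its genomic coordinate
upstream_codon_pos <- function(start_coord, strand, j) {
  start_coord - strand * 3L * j
}

#' Plant annotation errors into a published annotation
#'
#' Produces the deliberately flawed "published" annotation (plus a mutated
#' genome when single-base insertions are planted):
#' \describe{
#'   \item{missed_gene}{gene removed from the annotation}
#'   \item{wrong_start_long}{annotated start moved upstream to an in-frame
#'     canonical codon (an ab-initio caller's longest-sequence bias);
#'     intervening in-frame stops in the intergenic region are recoded
#'     when no natural candidate exists}
#'   \item{wrong_start_short}{annotated start moved downstream to an
#'     internal in-frame canonical codon}
#'   \item{spurious_cds}{gene removed and replaced by a fake CDS
#'     overlapping its span on the opposite strand}
#'   \item{base_insertion}{one base duplicated inside the gene (extending
#'     a homopolymer run); the gene is dropped from the annotation, as
#'     primary annotation skips frame-broken loci; all downstream
#'     coordinates shift by one}
#' }
#' Error genes are chosen pairwise non-adjacent so the classes stay
#' separable, mirroring the isolated real cases. One-hit-wonder genes
#' (removed from the annotation, later detected by a single peptide) and
#' their transcribed subset are also drawn here.
#'
#' @param sim Output of [generate_genome()].
#' @param config A [simulation_config()].
#' @return List `genomes` (possibly mutated), `annotation_published`,
#'   `annotation_true` (coordinates shifted alongside any insertion),
#'   `ledger` with an `errors` table (gene_id, category, true_start,
#'   published_start, inserted_pos, run_lo, run_hi).
#' @export
plant_errors <- function(sim, config = simulation_config()) {
  set.seed(config$seed + 1L)
  genes <- sim$ledger$genes
  g <- sim$genomes[[1]]
  seqstr <- g$sequence
  n <- nrow(genes)
  counts <- config$error_counts
  need <- sum(counts) + config$n_one_hit
  if (need > floor(n / 2)) {
    stop("error counts infeasible: ", need, " error genes for ", n,
         " genes with the non-adjacency rule")
  }
  # alternate gene indices are pairwise non-adjacent by construction, so
  # drawing from a shuffled set of them can never get stuck
  slots <- sample(seq.int(sample(1:2, 1L), n, by = 2L))
  pick_gene <- function(k, ok = function(i) TRUE) {
    good <- slots[vapply(slots, ok, logical(1))]
    if (length(good) < k) {
      stop("cannot place planted errors non-adjacently")
    }
    out <- good[seq_len(k)]
    slots <<- setdiff(slots, out)
    out
  }
  # an overextended start is only ever reported when the true N-terminal
  # peptide is observable, so it is planted on genes that have one
  has_nterm_pep <- function(i) {
    !is.null(semi_nterm_peptide(genes$protein[i], removed = TRUE)) &&
      !is.null(semi_nterm_peptide(genes$protein[i], removed = FALSE))
  }
  assign <- list()
  for (cat in names(counts)) {
    assign[[cat]] <- pick_gene(counts[[cat]],
                               ok = if (cat == "wrong_start_long")
                                 has_nterm_pep else function(i) TRUE)
  }
  one_hit_idx <- pick_gene(config$n_one_hit)

  errors <- list()
  published <- data.frame(locus_tag = genes$gene_id,
                          replicon_id = genes$replicon_id,
                          start_coord = genes$start_coord,
                          stop_coord = genes$stop_coord,
                          product = "hypothetical protein",
                          source = "original", stringsAsFactors = FALSE)
  drop_loci <- character(0)

  # --- start moved upstream (annotation too long)
  for (i in assign$wrong_start_long) {
    strand <- genes$strand[i]
    sc <- genes$start_coord[i]
    # limit the upstream walk to the intergenic room available
    gap_room <- intergenic_room(genes, i, nchar(seqstr))
    jmax <- min(30L, (gap_room - 3L) %/% 3L)
    pick <- NA_integer_
    for (j in seq_len(max(jmax, 0L))) {
      pos <- upstream_codon_pos(sc, strand, j)
      codon <- codon_at_genomic(g, pos, strand)
      if (is.na(codon)) break
      if (codon %in% STOP_CODONS) break
      if (codon %in% c("ATG", "GTG", "TTG")) { pick <- j; break }
    }
    if (is.na(pick)) {
      pick <- min(10L, max(jmax, 2L))
      seqstr <- engineer_upstream(seqstr, sc, strand, pick)
      g <- genome_record(g$replicon_id, seqstr)
    }
    new_start <- upstream_codon_pos(sc, strand, pick)
    published$start_coord[published$locus_tag == genes$gene_id[i]] <-
      new_start
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "wrong_start_long",
      true_start = sc, published_start = new_start,
      inserted_pos = NA_integer_, run_lo = NA_integer_,
      run_hi = NA_integer_, stringsAsFactors = FALSE)
    genes$category[i] <- "wrong_start_long"
  }

  # --- start moved downstream (annotation too short)
  for (i in assign$wrong_start_short) {
    strand <- genes$strand[i]
    sc <- genes$start_coord[i]
    prot_len <- nchar(genes$protein[i])
    pick <- NA_integer_
    for (j in 8:min(50L, prot_len - 20L)) {
      pos <- sc + strand * 3L * (j - 1L)
      codon <- codon_at_genomic(g, pos, strand)
      if (codon %in% c("ATG", "GTG", "TTG")) { pick <- j; break }
    }
    if (is.na(pick)) {
      pick <- 15L
      pos <- sc + strand * 3L * (pick - 1L)
      seqstr <- write_codon(seqstr, pos, strand, "ATG")
      g <- genome_record(g$replicon_id, seqstr)
    }
    new_start <- sc + strand * 3L * (pick - 1L)
    published$start_coord[published$locus_tag == genes$gene_id[i]] <-
      new_start
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "wrong_start_short",
      true_start = sc, published_start = new_start,
      inserted_pos = NA_integer_, run_lo = NA_integer_,
      run_hi = NA_integer_, stringsAsFactors = FALSE)
    genes$category[i] <- "wrong_start_short"
  }

  # proteins may have changed where a codon was engineered
  genes$protein <- vapply(seq_len(n), function(i) {
    extract_and_translate(g, list(start_coord = genes$start_coord[i],
                                  stop_coord = genes$stop_coord[i]))
  }, character(1))

  # --- genes simply missing from the annotation
  for (i in assign$missed_gene) {
    drop_loci <- c(drop_loci, genes$gene_id[i])
    genes$category[i] <- "missed_gene"
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "missed_gene",
      true_start = genes$start_coord[i], published_start = NA_integer_,
      inserted_pos = NA_integer_, run_lo = NA_integer_,
      run_hi = NA_integer_, stringsAsFactors = FALSE)
  }

  # --- one-hit-wonder genes (also absent from the annotation)
  transcribed <- character(0)
  for (k in seq_along(one_hit_idx)) {
    i <- one_hit_idx[k]
    drop_loci <- c(drop_loci, genes$gene_id[i])
    genes$category[i] <- "one_hit"
    if (k <= config$n_one_hit_transcribed) {
      transcribed <- c(transcribed, genes$gene_id[i])
    }
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "one_hit",
      true_start = genes$start_coord[i], published_start = NA_integer_,
      inserted_pos = NA_integer_, run_lo = NA_integer_,
      run_hi = NA_integer_, stringsAsFactors = FALSE)
  }

  # --- spurious CDS replacing a real gene, on the opposite strand
  fake_n <- 0L
  for (i in assign$spurious_cds) {
    drop_loci <- c(drop_loci, genes$gene_id[i])
    genes$category[i] <- "spurious_cds"
    lo <- min(genes$start_coord[i], genes$stop_coord[i])
    hi <- max(genes$start_coord[i], genes$stop_coord[i])
    flen <- 3L * 45L
    flo <- lo + 6L
    fhi <- min(flo + flen - 1L, hi - 3L)
    fhi <- flo + 3L * ((fhi - flo + 1L) %/% 3L) - 1L
    fake_n <- fake_n + 1L
    fake_tag <- sprintf("FAKE_%03d", fake_n)
    # opposite strand: reading direction reversed relative to the real gene
    if (genes$strand[i] == 1L) {
      fs <- fhi; fe <- flo
    } else {
      fs <- flo; fe <- fhi
    }
    published <- rbind(published, data.frame(
      locus_tag = fake_tag, replicon_id = genes$replicon_id[i],
      start_coord = fs, stop_coord = fe,
      product = "hypothetical protein", source = "original",
      stringsAsFactors = FALSE))
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "spurious_cds",
      true_start = genes$start_coord[i], published_start = NA_integer_,
      inserted_pos = NA_integer_, run_lo = NA_integer_,
      run_hi = NA_integer_, stringsAsFactors = FALSE)
    attr(errors[[length(errors)]], "fake_tag") <- fake_tag
    errors[[length(errors)]]$fake_tag <- fake_tag
  }

  # --- single-base insertions (planted last; they shift coordinates)
  for (i in assign$base_insertion) {
    lo <- min(genes$start_coord[i], genes$stop_coord[i])
    hi <- max(genes$start_coord[i], genes$stop_coord[i])
    margin <- 90L
    p <- sample((lo + margin):(hi - margin), 1L)
    ins_base <- substr(seqstr, p, p)
    seqstr <- paste0(substr(seqstr, 1L, p), ins_base,
                     substr(seqstr, p + 1L, nchar(seqstr)))
    shift <- function(x) ifelse(!is.na(x) & x > p, x + 1L, x)
    genes$start_coord <- shift(genes$start_coord)
    genes$stop_coord <- shift(genes$stop_coord)
    published$start_coord <- shift(published$start_coord)
    published$stop_coord <- shift(published$stop_coord)
    errors <- lapply(errors, function(e) {
      e$true_start <- shift(e$true_start)
      e$published_start <- shift(e$published_start)
      e$inserted_pos <- shift(e$inserted_pos)
      e$run_lo <- shift(e$run_lo); e$run_hi <- shift(e$run_hi)
      e
    })
    g <- genome_record(g$replicon_id, seqstr)
    ins_pos <- p + 1L  # coordinate of the duplicated base in the new genome
    run <- homopolymer_run(seqstr, ins_pos)
    drop_loci <- c(drop_loci, genes$gene_id[i])
    genes$category[i] <- "base_insertion"
    genes$frameshifted[i] <- TRUE
    errors[[length(errors) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], category = "base_insertion",
      true_start = genes$start_coord[i], published_start = NA_integer_,
      inserted_pos = ins_pos, run_lo = run[1], run_hi = run[2],
      stringsAsFactors = FALSE)
  }

  published <- published[!published$locus_tag %in% drop_loci, , drop = FALSE]
  errors_df <- if (length(errors) == 0) data.frame() else {
    for (k in seq_along(errors)) {
      if (is.null(errors[[k]]$fake_tag)) errors[[k]]$fake_tag <- NA_character_
    }
    do.call(rbind, errors)
  }
  genomes <- setNames(list(g), g$replicon_id)
  ann_pub <- suppressWarnings(
    validate_annotation(new_annotation_set(published,
                                           genome_ref = g$replicon_id),
                        genomes))
  ann_true <- new_annotation_set(data.frame(
    locus_tag = genes$gene_id, replicon_id = genes$replicon_id,
    start_coord = genes$start_coord, stop_coord = genes$stop_coord,
    product = "hypothetical protein", source = "original",
    stringsAsFactors = FALSE), genome_ref = g$replicon_id)
  ledger <- structure(list(genes = genes, errors = errors_df,
                           transcribed_one_hit = transcribed),
                      class = "sim_ledger")
  list(genomes = genomes, annotation_published = ann_pub,
       annotation_true = ann_true, ledger = ledger)
}

# available intergenic room (nt) upstream of gene i in reading direction
intergenic_room <- function(genes, i, L) {
  strand <- genes$strand[i]
  sc <- genes$start_coord[i]
  others <- genes[-i, ]
  if (strand == 1L) {
    ends <- pmax(others$start_coord, others$stop_coord)
    prev <- ends[ends < sc]
    sc - (if (length(prev)) max(prev) else 0L) - 1L
  } else {
    starts <- pmin(others$start_coord, others$stop_coord)
    nxt <- starts[starts > sc]
    (if (length(nxt)) min(nxt) else L + 1L) - sc - 1L
  }
}

# overwrite the codon whose first reading-direction base is at `pos`
write_codon <- function(seqstr, pos, strand, codon) {
  if (strand == 1L) {
    substr(seqstr, pos, pos + 2L) <- codon
  } else {
    substr(seqstr, pos - 2L, pos) <- revcomp(codon)
  }
  seqstr
}

# place an ATG j codons upstream of a gene start and recode intervening
# in-frame stop codons so the upstream extension is open
engineer_upstream <- function(seqstr, start_coord, strand, j) {
  g <- genome_record("tmp", seqstr)
  for (jj in seq_len(j - 1L)) {
    pos <- upstream_codon_pos(start_coord, strand, jj)
    codon <- codon_at_genomic(g, pos, strand)
    if (codon %in% STOP_CODONS) {
      seqstr <- write_codon(seqstr, pos, strand, "CAG")
      g <- genome_record("tmp", seqstr)
    }
  }
  write_codon(seqstr, upstream_codon_pos(start_coord, strand, j),
              strand, "ATG")
}

# maximal run of identical bases containing position p (forward coords)
homopolymer_run <- function(seqstr, p) {
  b <- substr(seqstr, p, p)
  lo <- p
  while (lo > 1L && substr(seqstr, lo - 1L, lo - 1L) == b) lo <- lo - 1L
  hi <- p
  L <- nchar(seqstr)
  while (hi < L && substr(seqstr, hi + 1L, hi + 1L) == b) hi <- hi + 1L
  c(lo, hi)
}
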