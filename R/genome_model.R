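#' @import Biostrings
#' @importFrom stats rbinom rnbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Create a genome record
#'
#' A genome record holds one replicon: its identifier, its sequence as an
#' uppercase character string, and its topology. Coordinates throughout the
#' package are 1-based and inclusive; a minus-strand feature is encoded by a
#' start coordinate greater than its stop coordinate (reading-direction
#' convention).
#'
#' @param replicon_id Replicon identifier (e.g. a chromosome accession).
#' @param sequence DNA sequence, IUPAC characters only; lowercase accepted.
#' @param topology `"linear"` or `"circular"`. Circular topology is stored
#'   but replicons are scanned as linear sequences (ends act as virtual
#'   stop codons).
#' @return A list of class `genome_record`.
#' @export
genome_record <- function(replicon_id, sequence, topology = "linear") {
  stopifnot(is.character(replicon_id), nchar(replicon_id) > 0)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1) {
    stop("genome record '", replicon_id, "' has an empty sequence")
  }
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), IUPAC_DNA)
  if (length(bad) > 0) {
    stop("genome record '", replicon_id, "' contains non-IUPAC characters: ",
         paste(bad, collapse = ", "))
  }
  topology <- match.arg(topology, c("linear", "circular"))
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 topology = topology),
            class = "genome_record")
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named list of [genome_record()]s, order preserved, sequences
#'   uppercased. Names are the first whitespace-delimited token of each
#'   header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read raw, then validate the alphabet ourselves so the error can name
  # the offending record
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate replicon ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' @param genomes Named list of [genome_record()]s.
#' @param path Output path. Sequences are wrapped at 60 characters.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1),
                                         "sequence"))
  names(set) <- vapply(genomes, `[[`, character(1), "replicon_id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

new_annotation_set <- function(df, genome_ref = character()) {
  need <- c("locus_tag", "replicon_id", "start_coord", "stop_coord",
            "product", "source", "flag")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- if (col == "flag") rep(FALSE, nrow(df))
                 else rep(NA_character_, nrow(df))
  }
  df <- df[, need, drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$locus_tag)) {
    stop("duplicate locus_tags: ",
         paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
  }
  attr(df, "genome_ref") <- genome_ref
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Read a CDS annotation (GFF3 or minimal TSV)
#'
#' GFF3 `CDS` features (1-based, start <= end, strand column) are converted
#' to the internal reading-direction convention in which a minus-strand CDS
#' has `start_coord > stop_coord`. A minimal tab-separated dialect with a
#' header row and columns `locus_tag`, `replicon`, `start`, `stop` (already
#' in reading-direction convention) is also accepted; it is detected by the
#' header line.
#'
#' CDSs that fall outside their replicon or whose span is not divisible by
#' three are kept but flagged (`flag = TRUE`) with a warning, so a malformed
#' published annotation can still be examined.
#'
#' @param path Annotation file path.
#' @param genomes Optional named list of [genome_record()]s used for bounds
#'   checking.
#' @return An `annotation_set` data frame with columns `locus_tag`,
#'   `replicon_id`, `start_coord`, `stop_coord`, `product`, `source`, `flag`.
#' @export
read_annotation <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || grepl("^\\s*$", first)) {
    ann <- new_annotation_set(data.frame(locus_tag = character(),
                                         replicon_id = character(),
                                         start_coord = integer(),
                                         stop_coord = integer()))
    return(validate_annotation(ann, genomes))
  }
  is_gff <- grepl("^##gff-version", first) ||
    grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "CDS"]
    # attribute columns may parse as CharacterList when any value holds
    # commas; flatten to one string per feature
    attr_chr <- function(col) {
      if (!col %in% names(S4Vectors::mcols(gr))) return(NULL)
      v <- S4Vectors::mcols(gr)[[col]]
      if (inherits(v, "List") || is.list(v)) {
        vapply(as.list(v), function(x) {
          if (length(x) == 0 || all(is.na(x))) NA_character_
          else paste(x, collapse = ",")
        }, character(1))
      } else as.character(v)
    }
    tags <- attr_chr("locus_tag")
    if (is.null(tags)) tags <- attr_chr("ID")
    if (length(gr) > 0 && anyNA(tags)) {
      stop("GFF3 CDS features without locus_tag/ID attribute in ", path)
    }
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    df <- data.frame(
      locus_tag   = tags,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start_coord = ifelse(minus, GenomicRanges::end(gr),
                           GenomicRanges::start(gr)),
      stop_coord  = ifelse(minus, GenomicRanges::start(gr),
                           GenomicRanges::end(gr)),
      product     = if (is.null(attr_chr("product"))) {
        rep(NA_character_, length(gr))
      } else attr_chr("product"),
      source      = if (is.null(attr_chr("cds_source"))) {
        rep("original", length(gr))
      } else attr_chr("cds_source"),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("locus_tag", "replicon", "start", "stop")
    if (!all(need %in% names(tab))) {
      stop("TSV annotation must have columns ", paste(need, collapse = ", "))
    }
    df <- data.frame(
      locus_tag   = as.character(tab$locus_tag),
      replicon_id = as.character(tab$replicon),
      start_coord = as.integer(tab$start),
      stop_coord  = as.integer(tab$stop),
      product     = if ("product" %in% names(tab)) {
        as.character(tab$product)
      } else rep(NA_character_, nrow(tab)),
      source      = if ("source" %in% names(tab)) {
        as.character(tab$source)
      } else rep("original", nrow(tab)),
      stringsAsFactors = FALSE
    )
  }
  ann <- new_annotation_set(df, genome_ref = unique(df$replicon_id))
  validate_annotation(ann, genomes)
}

validate_annotation <- function(ann, genomes = NULL) {
  if (nrow(ann) == 0) return(ann)
  if (any(ann$start_coord == ann$stop_coord)) {
    stop("CDS with start_coord == stop_coord: ",
         paste(ann$locus_tag[ann$start_coord == ann$stop_coord],
               collapse = ", "))
  }
  span <- abs(ann$stop_coord - ann$start_coord) + 1L
  bad3 <- span %% 3L != 0L
  oob <- rep(FALSE, nrow(ann))
  if (!is.null(genomes)) {
    lens <- vapply(genomes, function(g) nchar(g$sequence), integer(1))
    known <- ann$replicon_id %in% names(lens)
    if (!all(known)) {
      stop("CDS on unknown replicon: ",
           paste(ann$locus_tag[!known], collapse = ", "))
    }
    lim <- lens[ann$replicon_id]
    oob <- ann$start_coord < 1L | ann$stop_coord < 1L |
      ann$start_coord > lim | ann$stop_coord > lim
    attr(ann, "genome_ref") <- names(lens)
  }
  flag <- bad3 | oob
  if (any(flag)) {
    warning("flagged ", sum(flag), " CDS record(s) (span not divisible by 3",
            " or outside replicon bounds): ",
            paste(head(ann$locus_tag[flag], 10), collapse = ", "))
  }
  ann$flag <- flag
  ann
}

#' Write an annotation set as GFF3
#'
#' The inverse of [read_annotation()]: internal reading-direction coordinates
#' are converted back to GFF3 `start <= end` plus a strand column.
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @param genomes Optional genome records, used to emit `##sequence-region`
#'   pragmas.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, genomes = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(genomes)) {
    lines <- c(lines, vapply(genomes, function(g) {
      sprintf("##sequence-region %s 1 %d", g$replicon_id, nchar(g$sequence))
    }, character(1)))
  }
  if (nrow(ann) > 0) {
    minus <- ann$start_coord > ann$stop_coord
    lo <- pmin(ann$start_coord, ann$stop_coord)
    hi <- pmax(ann$start_coord, ann$stop_coord)
    attrs <- sprintf("ID=%s;locus_tag=%s", ann$locus_tag, ann$locus_tag)
    has_prod <- !is.na(ann$product)
    # commas separate multiple attribute values in GFF3; encode them
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              gsub(",", "%2C", ann$product[has_prod]))
    has_src <- !is.na(ann$source)
    attrs[has_src] <- paste0(attrs[has_src], ";cds_source=",
                             ann$source[has_src])
    lines <- c(lines, sprintf("%s\tproteoseed\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              ann$replicon_id, lo, hi,
                              ifelse(minus, "-", "+"), attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' CDS span length in codons
#'
#' Under the reading-direction coordinate convention, the span covers an
#' exact multiple of three bases; its length in codons is
#' `(|stop - start| + 1) / 3`. When the span includes the terminal stop
#' codon this equals the protein length plus one.
#'
#' @param start_coord,stop_coord 1-based inclusive coordinates; minus strand
#'   iff `start_coord > stop_coord`. Vectorised.
#' @return Integer vector of codon counts.
#' @export
coords_to_length <- function(start_coord, stop_coord) {
  span <- abs(stop_coord - start_coord) + 1L
  if (any(span %% 3L != 0L)) {
    stop("span not divisible by 3 for coordinates (",
         paste(start_coord[span %% 3L != 0L], stop_coord[span %% 3L != 0L],
               sep = ", ", collapse = "), ("), ")")
  }
  as.integer(span %/% 3L)
}

# byte-level reverse complement (IUPAC-aware); sequences are plain ASCII
revcomp <- function(x) {
  chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB",
         rawToChar(rev(charToRaw(x))))
}

.code_cache <- new.env(parent = emptyenv())

genetic_code_table <- function(table = "11") {
  key <- as.character(table)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  }
  .code_cache[[key]]
}

# Translate an in-frame DNA string (character) with bacterial code (table 11
# by default); stops are "*", codons with ambiguity codes become "X".
# Codon-table lookup over the Biostrings genetic code, which keeps the many
# small translations of the scanning stages cheap.
translate_str <- function(dna, table = "11") {
  n <- 3L * (nchar(dna) %/% 3L)
  if (n == 0) return("")
  code <- genetic_code_table(table)
  i <- seq.int(1L, n, 3L)
  aa <- unname(code[substring(dna, i, i + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Extract the reading-direction sequence of a span on a replicon.
span_sequence <- function(genome, start_coord, stop_coord) {
  lo <- min(start_coord, stop_coord)
  hi <- max(start_coord, stop_coord)
  if (lo < 1 || hi > nchar(genome$sequence)) {
    stop("span ", start_coord, "-", stop_coord, " outside replicon ",
         genome$replicon_id)
  }
  s <- substr(genome$sequence, lo, hi)
  if (start_coord > stop_coord) revcomp(s) else s
}

#' Extract and translate a CDS
#'
#' Minus-strand CDSs (encoded as `start_coord > stop_coord`) are
#' reverse-complemented before translation. A GTG or TTG initiator is
#' rendered as methionine at position 1, and a terminal stop codon included
#' in the span is stripped from the protein. An internal stop codon is an
#' error carrying the genomic position of the offending codon's first base
#' in reading direction; this signal is reused by frameshift detection.
#'
#' @param genome A [genome_record()].
#' @param cds One-row `annotation_set` slice, or any list with
#'   `start_coord`/`stop_coord`.
#' @param table NCBI genetic code id (default `"11"`, bacterial).
#' @return Protein string (no stop character).
#' @export
extract_and_translate <- function(genome, cds, table = "11") {
  dna <- span_sequence(genome, cds$start_coord, cds$stop_coord)
  aa <- translate_str(dna, table)
  n <- nchar(aa)
  if (n > 0 && substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
    n <- n - 1L
  }
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0) {
    dirn <- if (cds$start_coord > cds$stop_coord) -1L else 1L
    pos <- cds$start_coord + dirn * 3L * (as.integer(star) - 1L)
    stop("internal stop codon at genomic position ", pos, " (codon ",
         star, ") in CDS ",
         if (!is.null(cds$locus_tag)) cds$locus_tag else "",
         call. = FALSE)
  }
  init <- toupper(substr(dna, 1, 3))
  if (n > 0 && init %in% c("GTG", "TTG")) {
    substr(aa, 1, 1) <- "M"
  }
  aa
}
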