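# Annotated genome records: circular genomes with 1-based inclusive feature
# intervals in the GenBank style. An interval with start > end denotes a
# feature that wraps across the origin of a circular genome.

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "pseudogene", "other")

#' Create a genome feature
#'
#' @param id Unique feature identifier.
#' @param kind One of `"CDS"`, `"rRNA"`, `"tRNA"`, `"pseudogene"`, `"other"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end Integer vectors of equal length giving 1-based inclusive
#'   interval bounds; multiple entries describe a joined (multi-exon style)
#'   feature in coding order. `start > end` marks an origin-wrapping interval
#'   on a circular genome.
#' @param product Free-text product description.
#' @param anticodon For tRNA features, the anticodon written 5'->3' as a
#'   3-letter RNA string (e.g. `"GUU"`). Must be `NA` for other kinds.
#' @param initiator For tRNA features, `TRUE` marks the initiator
#'   (formyl-methionyl) tRNA, which is excluded from elongation decoding.
#' @return An object of class `"mt_feature"`.
#' @export
feature <- function(id, kind, strand, start, end, product = "",
                    anticodon = NA_character_, initiator = FALSE) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(length(id) == 1L, nchar(id) > 0L, strand %in% c("+", "-"),
            length(start) == length(end), length(start) >= 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(start) || anyNA(end) || any(start < 1L) || any(end < 1L))
    stop("feature '", id, "': interval bounds must be positive integers")
  if (kind != "tRNA" && !is.na(anticodon))
    stop("feature '", id, "': only tRNA features may carry an anticodon")
  if (!is.na(anticodon)) {
    anticodon <- toupper(anticodon)
    if (nchar(anticodon) != 3L || grepl("[^ACGU]", anticodon))
      stop("feature '", id, "': malformed anticodon '", anticodon,
           "' (need 3 letters over A/C/G/U)")
  }
  structure(list(id = id, kind = kind, strand = strand,
                 intervals = cbind(start = start, end = end),
                 product = product, anticodon = anticodon,
                 initiator = isTRUE(initiator)),
            class = "mt_feature")
}

#' Create an annotated genome record
#'
#' @param id Record identifier.
#' @param sequence DNA sequence as a single string over `A,C,G,T,N`.
#' @param circular Logical; is the molecule circular?
#' @param features List of [feature()] objects with unique ids.
#' @return An object of class `"genome_record"`.
#' @export
genome_record <- function(id, sequence, circular = TRUE, features = list()) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("empty genome sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  len <- nchar(sequence)
  ids <- vapply(features, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (f in features) {
    iv <- f$intervals
    if (any(iv > len))
      stop("feature '", f$id, "': interval outside [1, ", len, "]")
    if (any(iv[, "start"] > iv[, "end"]) && !circular)
      stop("feature '", f$id, "': origin-wrapping interval on a linear genome")
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  kinds <- table(factor(vapply(x$features, `[[`, character(1), "kind"),
                        levels = FEATURE_KINDS))
  cat("Annotated genome record '", x$id, "'\n", sep = "")
  cat("  ", nchar(x$sequence), " bp, ",
      if (x$circular) "circular" else "linear", "\n", sep = "")
  cat("  features:", paste(names(kinds), kinds, sep = "=", collapse = " "), "\n")
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

# Genome positions covered by one interval row, unwrapped, in 5'->3' order
# along the reference strand.
interval_positions <- function(start, end, len) {
  if (start <= end) start:end else c(start:len, 1:end)
}

# All positions of a feature in coding order on the reference strand
# (interval rows concatenated as listed).
feature_positions <- function(f, len) {
  unlist(lapply(seq_len(nrow(f$intervals)), function(i) {
    interval_positions(f$intervals[i, "start"], f$intervals[i, "end"], len)
  }), use.names = FALSE)
}

# Coding-strand nucleotide sequence of a feature (reverse-complemented for
# minus-strand features, as in GenBank complement(join(...))).
feature_sequence <- function(genome, f) {
  pos <- feature_positions(f, genome_length(genome))
  s <- paste(strsplit(genome$sequence, "")[[1]][pos], collapse = "")
  if (f$strand == "-") revcomp(s) else s
}

#' Read an annotated genome from FASTA plus a feature table
#'
#' The feature table is a tab-separated file with columns
#' `id, kind, strand, start, end, product, anticodon` and an optional eighth
#' column `initiator` (0/1). A feature spanning several intervals is given on
#' several rows sharing an id, in coding order; `product`, `anticodon` and
#' `initiator` are taken from the first row.
#'
#' @param fasta Path to a single-record DNA FASTA file.
#' @param feature_table Path to the feature TSV described above.
#' @param circular Logical; is the molecule circular?
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta, feature_table, circular = TRUE) {
  seqs <- seqinr::read.fasta(fasta, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(seqs) != 1L)
    stop("expected a single-record FASTA, found ", length(seqs), " records")
  tab <- utils::read.delim(feature_table, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "kind", "strand", "start", "end", "product", "anticodon")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  feats <- lapply(split(seq_len(nrow(tab)), factor(tab$id, levels = unique(tab$id))),
                  function(rows) {
    r1 <- rows[1]
    ac <- tab$anticodon[r1]
    if (is.na(ac) || ac == "" || ac == ".") ac <- NA_character_
    init <- if ("initiator" %in% names(tab)) tab$initiator[r1] %in% c("1", "TRUE", "true") else FALSE
    feature(id = tab$id[r1], kind = tab$kind[r1], strand = tab$strand[r1],
            start = as.integer(tab$start[rows]), end = as.integer(tab$end[rows]),
            product = tab$product[r1], anticodon = ac, initiator = init)
  })
  genome_record(id = names(seqs)[1], sequence = as.character(seqs[[1]]),
                circular = circular, features = unname(feats))
}

#' Write a genome record to FASTA plus a feature table
#'
#' @param genome A [genome_record()].
#' @param fasta,feature_table Output paths (see [read_genome()] for the table
#'   format).
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta, feature_table) {
  seqinr::write.fasta(genome$sequence, names = genome$id, file.out = fasta,
                      nbchar = 70)
  rows <- do.call(rbind, lapply(genome$features, function(f) {
    data.frame(id = f$id, kind = f$kind, strand = f$strand,
               start = f$intervals[, "start"], end = f$intervals[, "end"],
               product = f$product,
               anticodon = ifelse(is.na(f$anticodon), "", f$anticodon),
               initiator = as.integer(f$initiator))
  }))
  utils::write.table(rows, feature_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genome)
}
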