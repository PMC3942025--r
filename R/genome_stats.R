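# Summary statistics of an annotated genome: composition, coding fraction,
# physically overlapping gene pairs, codon usage, nonstandard start codons.

# Kinds whose extents count as "coding" sequence for composition purposes.
# Pseudogenes and 'other' features count as noncoding.
CODING_KINDS <- c("CDS", "rRNA", "tRNA")

# Unwrapped IRanges of a feature's base set (reference-strand projection).
feature_ranges <- function(f, len) {
  iv <- f$intervals
  parts <- lapply(seq_len(nrow(iv)), function(i) {
    s <- iv[i, "start"]; e <- iv[i, "end"]
    if (s <= e) cbind(s, e) else rbind(cbind(s, len), cbind(1L, e))
  })
  m <- do.call(rbind, parts)
  IRanges::IRanges(start = m[, 1], end = m[, 2])
}

ranges_positions <- function(r) {
  unlist(Map(seq.int, IRanges::start(r), IRanges::end(r)), use.names = FALSE)
}

#' Summarize composition and coding content of an annotated genome
#'
#' Coding bases are the union of the extents of all CDS, rRNA and tRNA
#' features, projected onto the reference strand; pseudogenes and `other`
#' features count as noncoding. A+T fractions are computed on the reference
#' strand (`N` bases count in the denominators).
#'
#' @param genome A [genome_record()].
#' @return A list of class `"composition_summary"` with fields
#'   `genome_length`, `at_overall`, `at_coding`, `at_noncoding`,
#'   `coding_fraction`, `feature_counts`, and `flags`.
#' @export
summarize_composition <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  len <- genome_length(genome)
  chars <- strsplit(genome$sequence, "")[[1]]
  is_at <- chars %in% c("A", "T")

  coding_feats <- Filter(function(f) f$kind %in% CODING_KINDS, genome$features)
  if (length(coding_feats)) {
    rng <- IRanges::reduce(do.call(c, lapply(coding_feats, feature_ranges, len = len)))
    coding_pos <- ranges_positions(rng)
  } else {
    coding_pos <- integer(0)
  }
  n_coding <- length(coding_pos)
  n_noncoding <- len - n_coding
  coding_mask <- logical(len); coding_mask[coding_pos] <- TRUE

  flags <- character(0)
  at_coding <- if (n_coding > 0) mean(is_at[coding_mask]) else {
    flags <- c(flags, "no_coding_bases"); 0
  }
  at_noncoding <- if (n_noncoding > 0) mean(is_at[!coding_mask]) else {
    flags <- c(flags, "no_noncoding_bases"); 0
  }
  counts <- table(factor(vapply(genome$features, `[[`, character(1), "kind"),
                         levels = FEATURE_KINDS))
  structure(list(genome_length = len,
                 at_overall = mean(is_at),
                 at_coding = at_coding,
                 at_noncoding = at_noncoding,
                 coding_fraction = n_coding / len,
                 coding_bases = n_coding,
                 noncoding_bases = n_noncoding,
                 feature_counts = counts,
                 flags = flags),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Genome composition summary\n")
  cat(sprintf("  length          %d bp\n", x$genome_length))
  cat(sprintf("  A+T overall     %.1f%%\n", 100 * x$at_overall))
  cat(sprintf("  A+T coding      %.1f%%\n", 100 * x$at_coding))
  cat(sprintf("  A+T noncoding   %.1f%%\n", 100 * x$at_noncoding))
  cat(sprintf("  coding fraction %.1f%%\n", 100 * x$coding_fraction))
  cat("  features       ",
      paste(names(x$feature_counts), x$feature_counts, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Find physically overlapping feature pairs
#'
#' Two features overlap when their unwrapped base sets intersect on the
#' reference coordinate axis, regardless of strand. Each unordered pair is
#' reported once, with the size of the intersection in bp.
#'
#' @param genome A [genome_record()].
#' @param kinds Feature kinds to consider (default CDS only).
#' @return A data frame with columns `id1`, `id2`, `overlap_bp`.
#' @export
find_overlapping_pairs <- function(genome, kinds = "CDS") {
  stopifnot(inherits(genome, "genome_record"))
  kinds <- match.arg(kinds, FEATURE_KINDS, several.ok = TRUE)
  len <- genome_length(genome)
  feats <- Filter(function(f) f$kind %in% kinds, genome$features)
  out <- list()
  if (length(feats) >= 2) {
    rngs <- lapply(feats, feature_ranges, len = len)
    for (i in seq_len(length(feats) - 1)) {
      for (j in (i + 1):length(feats)) {
        ov <- sum(IRanges::width(IRanges::intersect(rngs[[i]], rngs[[j]])))
        if (ov > 0)
          out[[length(out) + 1L]] <- data.frame(id1 = feats[[i]]$id,
                                                id2 = feats[[j]]$id,
                                                overlap_bp = ov)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id1 = character(0), id2 = character(0), overlap_bp = integer(0))
}

# URFs (functionally unassigned reading frames) are recognized by id/product.
is_urf <- function(f) {
  grepl("urf", f$id, ignore.case = TRUE) || grepl("urf|unassigned", f$product,
                                                  ignore.case = TRUE)
}

#' Codon usage of annotated protein-coding genes
#'
#' Codons are counted in the annotated reading frame on the coding strand
#' (minus-strand CDS are reverse-complemented first). A CDS whose joined
#' length is not divisible by 3 is skipped with a warning; codons containing
#' ambiguity characters are excluded from the counts. Termination codons are
#' included in `counts` and also tallied separately in `stop_counts`.
#'
#' @param genome A [genome_record()].
#' @param include_urfs Count codons of functionally unassigned reading frames
#'   (features whose id or product contains "URF")?
#' @return A list of class `"codon_usage"` with `counts` (all 64 codons),
#'   `frequencies` (over counted codons, summing to 1), `stop_counts`,
#'   `grouping` (amino acid -> codons), `include_urfs`, `skipped`.
#' @export
codon_usage <- function(genome, include_urfs = TRUE) {
  stopifnot(inherits(genome, "genome_record"))
  code <- standard_genetic_code()
  codons <- all_codons("DNA")
  counts <- stats::setNames(integer(64), codons)
  skipped <- character(0)
  for (f in genome$features) {
    if (f$kind != "CDS") next
    if (!include_urfs && is_urf(f)) next
    s <- feature_sequence(genome, f)
    if (nchar(s) %% 3 != 0) {
      warning("CDS '", f$id, "' length ", nchar(s),
              " not divisible by 3; skipped")
      skipped <- c(skipped, f$id)
      next
    }
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cods <- cods[!grepl("[^ACGT]", cods)]
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else counts * 0
  structure(list(counts = counts,
                 frequencies = freqs,
                 stop_counts = counts[code == "*"],
                 grouping = split(codons, code),
                 include_urfs = include_urfs,
                 skipped = skipped),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("Codon usage (", sum(x$counts), " codons counted",
      if (x$include_urfs) ", URFs included" else ", URFs excluded",
      ")\n", sep = "")
  nz <- x$counts[x$counts > 0]
  print(sort(nz, decreasing = TRUE))
  invisible(x)
}

#' List CDS features with a nonstandard initiation codon
#'
#' @param genome A [genome_record()].
#' @return Data frame with columns `feature_id` and `start_codon`, one row per
#'   CDS whose first in-frame codon on the coding strand is not `ATG`.
#' @export
nonstandard_starts <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  out <- list()
  for (f in genome$features) {
    if (f$kind != "CDS") next
    s <- feature_sequence(genome, f)
    if (nchar(s) < 3) next
    first <- substr(s, 1, 3)
    if (first != "ATG")
      out[[length(out) + 1L]] <- data.frame(feature_id = f$id, start_codon = first)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(feature_id = character(0), start_codon = character(0))
}
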