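# Amino-acid alignment container and file formats.
#
# Alignments are plain uppercase character matrices, taxa as rows (rownames),
# columns as alignment positions. Gaps/missing are "-", "?", "X", ".".

#' Read an amino-acid alignment
#'
#' @param path File path.
#' @param format `"fasta"` (default) or `"phylip"` (relaxed; parsed via
#'   \pkg{phangorn}).
#' @return Character matrix (taxa x sites) with taxon rownames.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) stop("alignment is not rectangular")
    m <- do.call(rbind, lapply(seqs, toupper))
    rownames(m) <- names(seqs)
  } else {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("reading PHYLIP alignments requires the 'phangorn' package")
    dat <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
    m <- toupper(as.character(dat))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate taxon ids in alignment")
  m
}

#' Write an amino-acid alignment to FASTA
#'
#' @param aln Character matrix (taxa x sites).
#' @param path Output path.
#' @return The alignment, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = 60)
  invisible(aln)
}

#' Write a site-rate profile as TSV
#'
#' @param profile A [conditional_mean_rates()] result.
#' @param path Output path.
#' @return The profile, invisibly.
#' @export
write_rate_profile <- function(profile, path) {
  stopifnot(inherits(profile, "site_rate_profile"))
  tab <- data.frame(site = seq_along(profile$rates), rate = profile$rates,
                    loglik = profile$site_loglik)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}
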