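# tRNA decoding coverage under configurable wobble rules.
#
# An anticodon is written 5'->3' (positions 34, 35, 36 of the tRNA). Codon
# positions 1 and 2 pair with anticodon positions 36 and 35 by strict
# Watson-Crick rules; codon position 3 pairs with the wobble position 34
# according to the rule table below.

#' Wobble pairing rules for anticodon position 34
#'
#' Defaults encode common organellar decoding assumptions: G34 reads C and U;
#' U34 reads A and G, extended to all four bases in a family box (four
#' synonymous codons) when `superwobble` is on; C34 reads G only; A34 is
#' treated as inosine, reading U, C and A, when `a34_inosine` is on (otherwise
#' strict Watson-Crick, reading U only).
#'
#' @param superwobble Allow U34 to read all four codons of a family box?
#' @param a34_inosine Treat A34 as inosine (reads U/C/A)?
#' @return A list of class `"wobble_rules"`.
#' @export
wobble_rules <- function(superwobble = TRUE, a34_inosine = TRUE) {
  structure(list(
    G = c("C", "U"),
    U = c("A", "G"),
    C = "G",
    A = if (a34_inosine) c("U", "C", "A") else "U",
    superwobble = isTRUE(superwobble),
    name = paste0("G34:CU U34:AG", if (superwobble) "(+superwobble)" else "",
                  " C34:G A34:", if (a34_inosine) "UCA(inosine)" else "U")
  ), class = "wobble_rules")
}

# Is the codon box sharing the first two bases of `codon12` a family box
# (all four third positions synonymous, none a stop)?
is_family_box <- function(codon12) {
  aas <- translate_rna_codon(paste0(codon12, c("A", "C", "G", "U")))
  length(unique(aas)) == 1L && aas[1] != "*"
}

# RNA codons an anticodon can read under the rule set.
codons_read_by <- function(anticodon, rules) {
  anticodon <- toupper(anticodon)
  if (is.na(anticodon) || nchar(anticodon) != 3L || grepl("[^ACGU]", anticodon))
    stop("malformed anticodon '", anticodon, "'")
  ac <- strsplit(anticodon, "")[[1]]
  codon12 <- paste0(rna_complement(ac[3]), rna_complement(ac[2]))
  third <- rules[[ac[1]]]
  if (ac[1] == "U" && rules$superwobble && is_family_box(codon12))
    third <- c("A", "C", "G", "U")
  paste0(codon12, third)
}

#' Decoding coverage of a tRNA gene set
#'
#' Determines which sense codons can be read by at least one non-initiator
#' tRNA under the given wobble rule set. Termination codons are excluded
#' (there are no tRNAs for stops). AUG is covered for elongation only if a
#' non-initiator CAU anticodon is present.
#'
#' @param trnas List of tRNA [feature()] objects (each must carry an
#'   anticodon), or a character vector of anticodons (all treated as
#'   non-initiator elongators).
#' @param rules A [wobble_rules()] object.
#' @return A list of class `"decoding_report"`: `covered` (named list, sense
#'   codon -> anticodons reading it), `uncovered_codons`,
#'   `uncovered_amino_acids` (one-letter codes of amino acids with at least
#'   one uncovered codon), and `rule_set`.
#' @export
decoding_coverage <- function(trnas, rules = wobble_rules()) {
  stopifnot(inherits(rules, "wobble_rules"))
  if (is.character(trnas)) {
    anticodons <- trnas
    initiator <- rep(FALSE, length(trnas))
    ids <- trnas
  } else {
    ids <- vapply(trnas, `[[`, character(1), "id")
    anticodons <- vapply(trnas, function(f) {
      if (is.na(f$anticodon))
        stop("tRNA feature '", f$id, "' has no anticodon")
      f$anticodon
    }, character(1))
    initiator <- vapply(trnas, function(f) isTRUE(f$initiator), logical(1))
  }
  sense <- sense_codons("RNA")
  covered <- stats::setNames(vector("list", length(sense)), sense)
  for (i in seq_along(anticodons)) {
    if (initiator[i]) next
    reads <- tryCatch(codons_read_by(anticodons[i], rules),
                      error = function(e) stop("feature '", ids[i], "': ",
                                               conditionMessage(e), call. = FALSE))
    for (cd in intersect(reads, sense))
      covered[[cd]] <- c(covered[[cd]], anticodons[i])
  }
  hit <- !vapply(covered, is.null, logical(1))
  uncovered <- sense[!hit]
  aa_uncov <- sort(unique(translate_rna_codon(uncovered)))
  structure(list(covered = covered[hit],
                 uncovered_codons = uncovered,
                 uncovered_amino_acids = aa_uncov,
                 rule_set = rules$name),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat("tRNA decoding coverage (", x$rule_set, ")\n", sep = "")
  cat("  covered sense codons:  ", length(x$covered), " / 61\n", sep = "")
  if (length(x$uncovered_codons))
    cat("  uncovered codons:      ",
        paste(x$uncovered_codons, collapse = " "), "\n", sep = "")
  if (length(x$uncovered_amino_acids))
    cat("  amino acids affected:  ",
        paste(x$uncovered_amino_acids, collapse = " "), "\n", sep = "")
  invisible(x)
}
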