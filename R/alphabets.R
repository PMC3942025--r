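# Shared sequence alphabets and the standard genetic code.

# Amino-acid state order used by all substitution-model code (PAML convention).
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters treated as missing data in amino-acid alignments.
AA_MISSING <- c("-", "?", "X", ".", "*")

.pkg_cache <- new.env(parent = emptyenv())

#' All 64 codons in a fixed lexicographic order
#'
#' @param alphabet "DNA" (ACGT) or "RNA" (ACGU).
#' @return Character vector of 64 codons.
#' @keywords internal
all_codons <- function(alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  b <- if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The standard genetic code (translation table 1)
#'
#' Maps DNA codons to one-letter amino-acid codes, with `"*"` for the three
#' termination codons. Built once via \pkg{seqinr} and cached.
#'
#' @return Named character vector of length 64 (names are DNA codons).
#' @export
standard_genetic_code <- function() {
  if (!is.null(.pkg_cache$code)) return(.pkg_cache$code)
  codons <- all_codons("DNA")
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]], numcode = 1)
  }, character(1))
  .pkg_cache$code <- aa
  aa
}

# DNA reverse complement of a character scalar.
revcomp <- function(s) {
  s <- chartr("ACGTN", "TGCAN", toupper(s))
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

# Watson-Crick complement for single RNA bases.
rna_complement <- function(b) {
  unname(c(A = "U", U = "A", G = "C", C = "G")[b])
}

# Sense (non-stop) codons of the standard code.
sense_codons <- function(alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  code <- standard_genetic_code()
  cods <- names(code)[code != "*"]
  if (alphabet == "RNA") cods <- chartr("T", "U", cods)
  cods
}

# Amino acid encoded by an RNA codon ("*" for stops).
translate_rna_codon <- function(codon) {
  code <- standard_genetic_code()
  unname(code[chartr("U", "T", codon)])
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
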