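# Gene presence/absence matrices and their partition into taxon-sharing
# classes (the Venn decomposition of gene repertoires).

#' Build a presence/absence matrix from per-taxon gene repertoires
#'
#' @param repertoires Named list mapping taxon id to a character vector of
#'   gene ids. Gene ids are case-normalized (lower-cased) and trimmed. An
#'   empty repertoire yields an all-zero row.
#' @return An integer 0/1 matrix, taxa in the given order as rows, genes in
#'   lexicographic order as columns.
#' @export
build_matrix <- function(repertoires) {
  if (length(repertoires) < 2L) stop("need at least two taxa")
  taxa <- names(repertoires)
  if (is.null(taxa) || any(taxa == "")) stop("repertoires must be a named list")
  if (anyDuplicated(taxa)) stop("duplicate taxon id: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  norm <- lapply(repertoires, function(g) unique(trimws(tolower(as.character(g)))))
  genes <- sort(unique(unlist(norm, use.names = FALSE)))
  m <- matrix(0L, nrow = length(taxa), ncol = length(genes),
              dimnames = list(taxa, genes))
  for (t in taxa) m[t, norm[[t]]] <- 1L
  validate_pam(m)
}

#' Validate a presence/absence matrix
#'
#' @param m A 0/1 matrix with taxon rownames and gene colnames.
#' @return The matrix, invisibly unchanged, after checking that ids are
#'   unique, values binary, and every gene is present in at least one taxon.
#' @export
validate_pam <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop("presence/absence matrix needs taxon rownames and gene colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids")
  if (!all(m %in% c(0L, 1L))) stop("matrix values must be 0/1")
  storage.mode(m) <- "integer"
  absent <- colSums(m) == 0L
  if (any(absent))
    stop("genes absent from every taxon: ",
         paste(colnames(m)[absent], collapse = ", "))
  m
}

#' Read / write a presence/absence matrix as TSV
#'
#' The format is a header row of gene ids, a first column `taxon` of taxon
#' ids, and 0/1 cells.
#'
#' @param path File path.
#' @return `read_pam` returns the validated matrix; `write_pam` returns its
#'   input invisibly.
#' @export
read_pam <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  validate_pam(m)
}

#' @param m The matrix to write.
#' @rdname read_pam
#' @export
write_pam <- function(m, path) {
  m <- validate_pam(m)
  tab <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Partition genes by their taxon-sharing pattern
#'
#' Every gene is assigned to exactly one class keyed by the set of taxa (or
#' groups) possessing it; the classes partition the gene set, as in a Venn
#' diagram of repertoires. With `groups`, a gene counts as present in a group
#' if at least one member taxon has it.
#'
#' @param m A presence/absence matrix (see [build_matrix()]).
#' @param groups Optional named character vector mapping taxon -> group id.
#' @param labels Optional named character vector mapping a pattern key (taxa
#'   sorted, joined by `"+"`) to a short class label (e.g. `"B"`).
#' @return A list of class `"pattern_partition"` with `classes` (named list,
#'   pattern key -> sorted gene ids), `sizes`, and `labels`.
#' @export
partition_by_pattern <- function(m, groups = NULL, labels = NULL) {
  m <- validate_pam(m)
  if (!is.null(groups)) {
    miss <- setdiff(rownames(m), names(groups))
    if (length(miss)) stop("taxa without a group: ", paste(miss, collapse = ", "))
    g <- groups[rownames(m)]
    genes <- colnames(m)
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), g), function(i) {
      as.integer(colSums(m[i, , drop = FALSE]) > 0)
    }))
    colnames(m) <- genes
  }
  units <- rownames(m)
  keys <- apply(m, 2, function(col) paste(sort(units[col == 1L]), collapse = "+"))
  classes <- lapply(split(colnames(m), keys), sort)
  structure(list(classes = classes,
                 sizes = vapply(classes, length, integer(1)),
                 labels = labels),
            class = "pattern_partition")
}

#' @export
print.pattern_partition <- function(x, ...) {
  cat("Gene sharing-pattern partition:", sum(x$sizes), "genes in",
      length(x$classes), "classes\n")
  for (k in names(x$classes)) {
    lab <- if (!is.null(x$labels) && k %in% names(x$labels))
      paste0(" [", x$labels[[k]], "]") else ""
    cat(sprintf("  %-40s%s  %d genes\n", k, lab, length(x$classes[[k]])))
  }
  invisible(x)
}

# Look up a class by label.
partition_class <- function(p, label) {
  stopifnot(inherits(p, "pattern_partition"), !is.null(p$labels))
  key <- names(p$labels)[p$labels == label]
  if (length(key) != 1L) stop("no unique class labelled '", label, "'")
  p$classes[[key]]
}
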