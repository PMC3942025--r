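# Bipartition (split) support over tree sets and the conflict screen against
# accepted taxonomic groups.

# Splits of a tree in unrooted semantics: list of tip-label vectors, one per
# edge (child side). Includes trivial single-tip splits.
tree_splits <- function(tree) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  edge_tip_splits(ut)
}

# Does `clade` form one side of the split `side` over taxon set `taxa`?
split_matches <- function(side, clade, taxa) {
  setequal(side, clade) || setequal(side, setdiff(taxa, clade))
}

#' Fraction of trees containing a clade (unrooted bipartition semantics)
#'
#' A tree contains the clade when the clade's taxa form one side of some
#' bipartition of the (unrooted) tree. The result is invariant under
#' re-rooting of the input trees.
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees; every tree
#'   must contain all of the clade's taxa.
#' @param clade Character vector of tip labels (at least one, and a proper
#'   subset of every tree's tips).
#' @param taxa Optional character vector declaring the full taxon set; trees
#'   are pruned to it before testing (taxa outside the set are dropped).
#' @return The fraction of trees (0..1) in which the clade occurs.
#' @export
clade_support <- function(trees, clade, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  if (!length(clade)) stop("empty clade")
  hits <- vapply(trees, function(tr) {
    stopifnot(inherits(tr, "phylo"))
    if (!is.null(taxa)) {
      drop <- setdiff(tr$tip.label, taxa)
      if (length(drop)) tr <- ape::drop.tip(tr, drop)
    }
    tips <- tr$tip.label
    miss <- setdiff(clade, tips)
    if (length(miss)) stop("tree lacks clade taxa: ", paste(miss, collapse = ", "))
    if (length(clade) >= length(tips))
      stop("clade must be a proper subset of the tree's taxa")
    any(vapply(tree_splits(tr), split_matches, logical(1),
               clade = clade, taxa = tips))
  }, logical(1))
  mean(hits)
}

#' Screen trees for well-supported splits conflicting with accepted groups
#'
#' A split X|Y conflicts with an accepted group G (against its complement)
#' when, after restricting to the taxa shared by the tree and the group
#' universe, G and its complement each intersect both sides of the split.
#' Every conflicting split whose support is at least `threshold` is recorded;
#' the candidate offenders are the smaller of the two subsets of G separated
#' by the split (both subsets if tied).
#'
#' @param trees A `multiPhylo` or list of `phylo` trees whose internal node
#'   labels hold numeric support values (e.g. bootstrap percentages).
#' @param accepted_groups Named list of character vectors (taxon subsets).
#' @param threshold Minimum support for a split to be screened (default 70).
#' @return Data frame with one row per (tree, split, group) conflict:
#'   `tree`, `group`, `support`, `split` (tip set of one side), `offenders`.
#' @export
conflict_screen <- function(trees, accepted_groups, threshold = 70) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(names(accepted_groups)))
    names(accepted_groups) <- paste0("group", seq_along(accepted_groups))
  rows <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    stopifnot(inherits(tr, "phylo"))
    # supports are read off the original edges: a node label is the support of
    # the split separating that node's descendants from the rest (unrooted
    # semantics); the two edges at a binary root carry the same split, which
    # is deduplicated below
    ntip <- length(tr$tip.label)
    below <- descendant_tips(tr)
    supports <- node_support_values(tr)
    seen_splits <- character(0)
    for (k in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[k, 2]
      if (ch <= ntip) next                   # terminal edges carry no split support
      sup <- supports[ch - ntip]
      if (is.na(sup) || sup < threshold) next
      X <- tr$tip.label[below[[ch]]]
      Y <- setdiff(tr$tip.label, X)
      canon <- paste(sort(if (min(X) < min(Y)) X else Y), collapse = "+")
      if (canon %in% seen_splits) next
      seen_splits <- c(seen_splits, canon)
      for (g in names(accepted_groups)) {
        G <- intersect(accepted_groups[[g]], tr$tip.label)
        Gc <- setdiff(tr$tip.label, G)
        gx <- intersect(X, G); gy <- intersect(Y, G)
        if (length(gx) && length(gy) &&
            length(intersect(X, Gc)) && length(intersect(Y, Gc))) {
          off <- if (length(gx) < length(gy)) gx
                 else if (length(gy) < length(gx)) gy
                 else sort(union(gx, gy))
          rows[[length(rows) + 1L]] <- data.frame(
            tree = ti, group = g, support = sup,
            split = paste(sort(X), collapse = "+"),
            offenders = paste(sort(off), collapse = ","))
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(tree = integer(0), group = character(0),
                  support = numeric(0), split = character(0),
                  offenders = character(0))
}

# Numeric support values from internal node labels (NA where absent).
node_support_values <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(nl))
}
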