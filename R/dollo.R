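# Loss-only (Dollo) parsimony on a rooted tree.
#
# Under the no-gain assumption, every gene is present at the root and can only
# be lost. The unique loss-only history assigns a gene as present at an
# internal node iff at least one descendant tip possesses it; losses fall on
# the branches where presence switches off, i.e. at the roots of the maximal
# absent subtrees. This reconstruction is forced by the assumption, not
# heuristic.

#' Loss-only (Dollo) ancestral reconstruction of gene content
#'
#' @param m Presence/absence matrix (see [build_matrix()]); rows are taxa.
#' @param tree A rooted `phylo` tree whose tip labels are matrix taxa; its
#'   basal node (which may be multifurcating, e.g. in a star tree) is taken as
#'   the root. Extra matrix rows are ignored; a tip without a matrix row is an
#'   error.
#' @return An object of class `"dollo_reconstruction"`: `node_presence`
#'   (logical matrix, one row per tip/internal node, genes as columns),
#'   `branch_losses` (list keyed `"parent->child"` of gene id vectors, only
#'   branches with losses), `node_labels`, `tree`, `genes`, and
#'   `assumption = "no gene gain"`.
#' @export
dollo_reconstruct <- function(m, tree) {
  m <- validate_pam(m)
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, rownames(m))
  if (length(missing_tips))
    stop("tree tips without a matrix row: ", paste(missing_tips, collapse = ", "))

  genes <- colnames(m)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  keep <- colSums(m[tree$tip.label, , drop = FALSE]) > 0L
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " gene(s) absent from every tree tip")
    genes <- genes[keep]
  }

  pres <- matrix(FALSE, nrow = ntip + nnode, ncol = length(genes))
  colnames(pres) <- genes
  pres[seq_len(ntip), ] <- m[tree$tip.label, genes, drop = FALSE] == 1L

  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    pres[p, ] <- pres[p, ] | pres[ch, ]
  }

  labs <- node_id_labels(tree)
  rownames(pres) <- labs

  losses <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    lost <- genes[pres[p, ] & !pres[ch, ]]
    if (length(lost))
      losses[[paste0(labs[p], "->", labs[ch])]] <- lost
  }

  structure(list(node_presence = pres,
                 branch_losses = losses,
                 node_labels = labs,
                 tree = tree,
                 genes = genes,
                 assumption = "no gene gain"),
            class = "dollo_reconstruction")
}

# Stable labels for all nodes of a phylo tree: tip labels for tips, existing
# node labels for internal nodes, "node_<k>" where absent.
node_id_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl[is.na(nl) | nl == ""] <- paste0("node_", which(is.na(nl) | nl == "") + ntip)
  c(tree$tip.label, nl)
}

#' Repertoire at a node of a Dollo reconstruction
#'
#' @param rec A [dollo_reconstruct()] result.
#' @param node A node label (tip or internal), or a character vector of two
#'   or more tip labels whose most recent common ancestor is taken.
#' @return Character vector of gene ids present at the node.
#' @export
node_repertoire <- function(rec, node) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  if (length(node) > 1L) {
    idx <- ape::getMRCA(rec$tree, node)
  } else {
    idx <- match(node, rec$node_labels)
    if (is.na(idx)) stop("unknown node '", node, "'")
  }
  rec$genes[rec$node_presence[idx, ]]
}

#' Genes lost on the branch ending at a node
#'
#' @inheritParams node_repertoire
#' @return Character vector of gene ids lost on the branch whose child end is
#'   `node` (empty if none).
#' @export
branch_loss <- function(rec, node) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  idx <- if (length(node) > 1L) ape::getMRCA(rec$tree, node)
         else match(node, rec$node_labels)
  if (is.na(idx)) stop("unknown node")
  k <- which(rec$tree$edge[, 2] == idx)
  if (!length(k)) return(character(0))  # root has no parent branch
  p <- rec$tree$edge[k, 1]
  key <- paste0(rec$node_labels[p], "->", rec$node_labels[idx])
  if (is.null(rec$branch_losses[[key]])) character(0) else rec$branch_losses[[key]]
}

#' Tabulate per-branch loss events
#'
#' @param rec A [dollo_reconstruct()] result.
#' @return Data frame with one row per branch carrying at least one loss:
#'   `parent`, `child`, `n_lost`, `genes` (comma-separated ids).
#' @export
branch_loss_table <- function(rec) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  if (!length(rec$branch_losses))
    return(data.frame(parent = character(0), child = character(0),
                      n_lost = integer(0), genes = character(0)))
  keys <- names(rec$branch_losses)
  parts <- strsplit(keys, "->", fixed = TRUE)
  data.frame(parent = vapply(parts, `[`, character(1), 1),
             child = vapply(parts, `[`, character(1), 2),
             n_lost = vapply(rec$branch_losses, length, integer(1)),
             genes = vapply(rec$branch_losses, paste, character(1), collapse = ","),
             row.names = NULL)
}

#' Census of genes lost more than once (parallel losses)
#'
#' @param rec A [dollo_reconstruct()] result.
#' @param partition Optional [partition_by_pattern()] result; when given, a
#'   per-class summary of parallel-lost genes is attached.
#' @param min_count Minimum number of loss branches for a gene to be reported
#'   (default 2, i.e. parallel losses only).
#' @return Named integer vector gene -> number of loss branches, restricted to
#'   genes with at least `min_count` losses. With `partition`, a `by_class`
#'   attribute tabulates these genes by class label (or pattern key).
#' @export
parallel_losses <- function(rec, partition = NULL, min_count = 2L) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  counts <- stats::setNames(integer(length(rec$genes)), rec$genes)
  for (lost in rec$branch_losses) counts[lost] <- counts[lost] + 1L
  out <- counts[counts >= min_count]
  out <- out[order(-out, names(out))]
  if (!is.null(partition)) {
    cls <- rep(NA_character_, length(out))
    for (k in names(partition$classes)) {
      lab <- if (!is.null(partition$labels) && k %in% names(partition$labels))
        partition$labels[[k]] else k
      cls[names(out) %in% partition$classes[[k]]] <- lab
    }
    attr(out, "by_class") <- table(class = cls)
  }
  out
}

#' Total number of loss events in a reconstruction
#'
#' The counting unit is a (gene, branch) pair: a set of k genes lost on one
#' branch counts k events.
#'
#' @param rec A [dollo_reconstruct()] result.
#' @return Integer event count.
#' @export
total_loss_events <- function(rec) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  sum(vapply(rec$branch_losses, length, integer(1)))
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  root <- ntip + 1L
  cat("Loss-only (Dollo) reconstruction; assumption:", x$assumption, "\n")
  cat("  ", length(x$genes), " genes across ", ntip, " tips\n", sep = "")
  cat("  root repertoire: ", sum(x$node_presence[root, ]), " genes\n", sep = "")
  cat("  loss events:     ", total_loss_events(x), " on ",
      length(x$branch_losses), " branches\n", sep = "")
  invisible(x)
}

#' @export
summary.dollo_reconstruction <- function(object, ...) {
  print(object)
  cat("\nPer-branch losses:\n")
  tab <- branch_loss_table(object)
  print(tab[order(-tab$n_lost), c("parent", "child", "n_lost")], row.names = FALSE)
  invisible(branch_loss_table(object))
}

#' Compare loss-event counts under alternative rootings
#'
#' Unroots the topology, re-roots it on each candidate edge, reruns the
#' loss-only reconstruction, and tabulates the total number of loss events,
#' the number of genes lost in parallel (>= 2 loss branches), and the maximum
#' loss multiplicity. Candidates are ranked by total events; the top-ranked
#' rooting is the most parsimonious under the no-gain assumption.
#'
#' @param m Presence/absence matrix.
#' @param tree A `phylo` topology (rooted trees are unrooted first).
#' @param candidate_edges Optional list of character vectors; each identifies
#'   an edge by the set of tip labels on one side of it. Default: every edge.
#' @return A data frame of class `"rooting_comparison"`, one row per candidate
#'   edge (`edge`, `total_loss_events`, `genes_lost_in_parallel`,
#'   `max_multiplicity`), sorted by ascending event count.
#' @export
compare_rootings <- function(m, tree, candidate_edges = NULL) {
  m <- validate_pam(m)
  stopifnot(inherits(tree, "phylo"))
  ut <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    ape::unroot(tree) else tree
  splits <- edge_tip_splits(ut)
  if (!is.null(candidate_edges)) {
    want <- vapply(candidate_edges, function(s) {
      hit <- which(vapply(splits, function(sp)
        setequal(sp, s) || setequal(setdiff(ut$tip.label, sp), s), logical(1)))
      if (!length(hit)) stop("candidate edge not found: ",
                             paste(s, collapse = "+"))
      hit[1]
    }, integer(1))
    splits <- splits[want]
  }
  rows <- lapply(splits, function(side) {
    rooted <- root_on_split(ut, side)
    rec <- dollo_reconstruct(m, rooted)
    counts <- stats::setNames(integer(length(rec$genes)), rec$genes)
    for (lost in rec$branch_losses) counts[lost] <- counts[lost] + 1L
    data.frame(edge = paste(sort(side), collapse = "+"),
               total_loss_events = sum(counts),
               genes_lost_in_parallel = sum(counts >= 2L),
               max_multiplicity = max(counts))
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$edge), , drop = FALSE]
  out <- out[order(out$total_loss_events, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rooting_comparison", "data.frame")
  out
}

#' @export
print.rooting_comparison <- function(x, ...) {
  cat("Loss-event comparison across candidate rootings",
      "(ranked, fewest events first):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Tip sets on the child side of every edge of a phylo tree.
edge_tip_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- descendant_tips(tree)
  lapply(seq_len(nrow(tree$edge)), function(k) {
    tree$tip.label[below[[tree$edge[k, 2]]]]
  })
}

# List: node index -> integer vector of descendant tip indices.
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# Root an unrooted tree on the edge identified by the tip set of one side.
root_on_split <- function(ut, side) {
  tips <- ut$tip.label
  if (length(tips) == 2L) {
    # single edge; both rootings coincide
    return(structure(list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
                          tip.label = tips, Nnode = 1L),
                     class = "phylo"))
  }
  out <- if (length(side) <= length(tips) / 2) side else setdiff(tips, side)
  ape::root(ut, outgroup = out, resolve.root = TRUE)
}
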