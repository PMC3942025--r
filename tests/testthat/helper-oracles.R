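# Independent brute-force oracles used to validate the implementation on
# small instances. These deliberately avoid the package's own algorithms.

# --- Dollo oracle: exhaustive enumeration of loss placements per gene -------
# For every gene, enumerates all subsets of branches as candidate loss sets;
# a subset is consistent when a tip lacks the gene iff at least one branch on
# its root-to-tip path is in the subset. Returns the minimum-event history
# and whether it is unique.
dollo_oracle <- function(m, tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  stopifnot(nedge <= 14)  # 2^nedge enumeration
  # path matrix: tips x edges
  anc <- matrix(0L, nrow = ntip, ncol = nedge)
  for (t in seq_len(ntip)) {
    node <- t
    repeat {
      k <- which(tree$edge[, 2] == node)
      if (!length(k)) break
      anc[t, k] <- 1L
      node <- tree$edge[k, 1]
    }
  }
  nmask <- 2^nedge
  masks <- matrix(0L, nrow = nmask, ncol = nedge)
  for (b in seq_len(nedge)) masks[, b] <- bitwAnd(seq_len(nmask) - 1L, 2^(b - 1L)) > 0
  hit <- (anc %*% t(masks)) > 0          # tips x masks: tip absent under mask?
  sizes <- rowSums(masks)

  genes <- colnames(m)
  losses_per_gene <- vector("list", length(genes))
  unique_min <- logical(length(genes))
  for (gi in seq_along(genes)) {
    absent <- m[tree$tip.label, genes[gi]] == 0L
    ok <- colSums(hit == absent) == ntip   # mask reproduces the pattern
    stopifnot(any(ok))
    mn <- min(sizes[ok])
    best <- which(ok & sizes == mn)
    unique_min[gi] <- length(best) == 1L
    losses_per_gene[[gi]] <- which(masks[best[1], ] == 1L)
  }
  labs <- mtevo:::node_id_labels(tree)
  branch_losses <- list()
  for (gi in seq_along(genes)) {
    for (k in losses_per_gene[[gi]]) {
      key <- paste0(labs[tree$edge[k, 1]], "->", labs[tree$edge[k, 2]])
      branch_losses[[key]] <- c(branch_losses[[key]], genes[gi])
    }
  }
  branch_losses <- lapply(branch_losses, sort)
  list(branch_losses = branch_losses,
       total_events = sum(lengths(losses_per_gene)),
       unique_min = unique_min)
}

# --- likelihood oracle: sum over all internal-state assignments -------------
lik_oracle_site <- function(states_tips, tree, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
    mtevo:::prob_matrix(model, rate * tree$edge.length[k]))
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  root_col <- 1L  # internal node ntip+1 is the first grid column
  total <- numeric(nrow(grid))
  total <- model$frequencies[grid[, root_col]]
  for (k in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    pa_state <- grid[, pa - ntip]
    ch_state <- if (ch <= ntip) rep(states_tips[ch], nrow(grid))
                else grid[, ch - ntip]
    total <- total * Ps[[k]][cbind(pa_state, ch_state)]
  }
  sum(total)
}

# --- overlap oracle: per-base set intersection -------------------------------
overlap_oracle <- function(genome, kinds = "CDS") {
  L <- nchar(genome$sequence)
  feats <- Filter(function(f) f$kind %in% kinds, genome$features)
  base_sets <- lapply(feats, function(f) {
    unique(unlist(lapply(seq_len(nrow(f$intervals)), function(i) {
      s <- f$intervals[i, "start"]; e <- f$intervals[i, "end"]
      if (s <= e) s:e else c(s:L, 1:e)
    })))
  })
  out <- list()
  if (length(feats) >= 2) {
    for (i in seq_len(length(feats) - 1)) for (j in (i + 1):length(feats)) {
      ov <- length(intersect(base_sets[[i]], base_sets[[j]]))
      if (ov > 0)
        out[[length(out) + 1L]] <- data.frame(id1 = feats[[i]]$id,
                                              id2 = feats[[j]]$id,
                                              overlap_bp = ov)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id1 = character(0), id2 = character(0), overlap_bp = integer(0))
}

# --- bipartition oracle: splits via graph components -------------------------
# A taxon subset is a split of the (unrooted) tree iff deleting some edge
# disconnects exactly that subset. Components are found by BFS on the
# remaining edges, independent of the package's traversal code.
tree_splits_oracle <- function(tree) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(ut$tip.label)
  nn <- ntip + ut$Nnode
  splits <- list()
  for (drop in seq_len(nrow(ut$edge))) {
    adj <- ut$edge[-drop, , drop = FALSE]
    seen <- rep(FALSE, nn)
    queue <- ut$edge[drop, 2]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(adj[adj[, 1] == v, 2], adj[adj[, 2] == v, 1])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    splits[[drop]] <- sort(ut$tip.label[which(seen[seq_len(ntip)])])
  }
  splits
}

clade_support_oracle <- function(trees, clade) {
  mean(vapply(trees, function(tr) {
    any(vapply(tree_splits_oracle(tr), function(s)
      setequal(s, clade) || setequal(s, setdiff(tr$tip.label, clade)),
      logical(1)))
  }, logical(1)))
}

# --- random instances --------------------------------------------------------
random_pam <- function(ntaxa, ngenes) {
  repeat {
    m <- matrix(rbinom(ntaxa * ngenes, 1, 0.6), nrow = ntaxa,
                dimnames = list(paste0("t", seq_len(ntaxa)),
                                paste0("g", seq_len(ngenes))))
    if (all(colSums(m) > 0)) return(validate_pam(m))
  }
}

random_rooted_tree <- function(ntip, brlen = TRUE) {
  tr <- ape::rtree(ntip, rooted = TRUE,
                   br = if (brlen) function(n) stats::runif(n, 0.05, 0.5) else NULL)
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

random_alignment <- function(ntaxa, nsites) {
  m <- matrix(sample(mtevo:::AA_STATES, ntaxa * nsites, replace = TRUE),
              nrow = ntaxa,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  m
}
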