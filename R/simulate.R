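# Synthetic-data generators. Each generator returns its ground truth
# alongside the data, so downstream operations can be tested end to end
# without external inputs. All generators are reproducible via `seed`.

#' Simulate a loss-only gene-content history along a rooted tree
#'
#' Every gene starts present at the root and is lost independently on each
#' branch with that branch's loss probability; once lost it is absent from
#' the entire subtree (no regain). Genes that end up absent from all tips are
#' redrawn (rejection), so the resulting matrix is valid; this slightly
#' biases per-branch marginal loss probabilities upward for extreme settings.
#'
#' @param tree Rooted `phylo` tree.
#' @param n_genes Number of genes to simulate.
#' @param loss_prob Per-branch loss probability in `[0, 1)`..`[0, 1]`: a
#'   scalar, or a vector along the rows of `tree$edge`. Probability 1 is
#'   allowed as long as at least one root-to-tip path is loss-free with
#'   positive probability.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return List with `matrix` (taxa x genes presence/absence) and `truth`, a
#'   list holding `node_presence` (logical matrix over all nodes) and
#'   `branch_losses` (list keyed `"parent->child"`), in the same layout as
#'   [dollo_reconstruct()].
#' @export
simulate_loss_history <- function(tree, n_genes, loss_prob, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_genes >= 1)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  nedge <- nrow(tree$edge)
  p <- rep_len(as.numeric(loss_prob), nedge)
  if (any(p < 0 | p > 1)) stop("loss probabilities must lie in [0, 1]")
  ntip <- length(tree$tip.label)
  labs <- node_id_labels(tree)

  # preorder edge sequence (parents before children) and its mapping back to
  # the rows of tree$edge, to which loss_prob is aligned
  post <- ape::reorder.phylo(tree, "postorder")
  pre_rows <- rev(seq_len(nedge))
  edge_key <- function(e) paste(e[, 1], e[, 2])
  emap <- match(edge_key(post$edge), edge_key(tree$edge))

  # certain all-tip absence (every root-to-tip path hits a p == 1 branch)?
  reach <- rep(FALSE, ntip + tree$Nnode)
  reach[ntip + 1L] <- TRUE
  for (k in pre_rows) {
    pa <- post$edge[k, 1]; ch <- post$edge[k, 2]
    reach[ch] <- reach[pa] && p[emap[k]] < 1
  }
  if (!any(reach[seq_len(ntip)]))
    stop("loss probabilities make absence from all tips certain")

  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    pres <- matrix(FALSE, nrow = ntip + tree$Nnode, ncol = n_genes,
                   dimnames = list(labs, genes))
    loss_edge <- matrix(FALSE, nrow = nedge, ncol = n_genes)
    todo <- seq_len(n_genes)
    while (length(todo)) {
      for (g in todo) {
        present <- rep(FALSE, ntip + tree$Nnode)
        present[ntip + 1L] <- TRUE
        lost_on <- rep(FALSE, nedge)
        for (k in pre_rows) {  # preorder down the tree
          pa <- post$edge[k, 1]; ch <- post$edge[k, 2]
          if (present[pa]) {
            if (stats::runif(1) < p[emap[k]]) lost_on[emap[k]] <- TRUE
            else present[ch] <- TRUE
          }
        }
        pres[, g] <- present
        loss_edge[, g] <- lost_on
      }
      todo <- todo[colSums(pres[seq_len(ntip), todo, drop = FALSE]) == 0]
    }
    losses <- list()
    for (k in seq_len(nedge)) {
      lost <- genes[loss_edge[k, ]]
      if (length(lost))
        losses[[paste0(labs[tree$edge[k, 1]], "->", labs[tree$edge[k, 2]])]] <- lost
    }
    m <- matrix(as.integer(pres[seq_len(ntip), , drop = FALSE]), nrow = ntip,
                dimnames = list(labs[seq_len(ntip)], genes))
    list(matrix = validate_pam(m),
         truth = list(node_presence = pres, branch_losses = losses,
                      loss_prob = p))
  })
}

#' Simulate an amino-acid alignment with known per-site rates
#'
#' Root states are drawn from the model's equilibrium frequencies and evolved
#' down each branch with transition matrices `exp(Q * t * r_i)`, where `r_i`
#' is site i's true rate.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param model A [substitution_model()] (its gamma settings are ignored here;
#'   rates come from `site_rates`).
#' @param n_sites Number of alignment columns.
#' @param site_rates True per-site rates: a numeric vector (recycled to
#'   `n_sites`), or `NULL` to draw i.i.d. Gamma(alpha, alpha) rates from the
#'   model's shape.
#' @param seed Optional RNG seed.
#' @return List with `alignment` (character matrix taxa x sites) and
#'   `site_rates` (the true rates used).
#' @export
simulate_alignment <- function(tree, model, n_sites, site_rates = NULL,
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  with_seed(seed, {
    rates <- if (is.null(site_rates))
      stats::rgamma(n_sites, shape = model$alpha, rate = model$alpha)
    else rep_len(as.numeric(site_rates), n_sites)
    if (any(rates <= 0)) stop("site rates must be positive")
    ntip <- length(tree$tip.label)
    states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = n_sites)
    states[ntip + 1L, ] <- sample.int(20, n_sites, replace = TRUE,
                                      prob = model$frequencies)
    pre <- ape::reorder.phylo(tree, "postorder")
    urates <- unique(rates)
    for (k in rev(seq_len(nrow(pre$edge)))) {  # preorder
      pa <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
      t_k <- pre$edge.length[k]
      for (r in urates) {
        P <- prob_matrix(model, r * t_k)
        sites <- which(rates == r)
        for (s0 in split(sites, states[pa, sites])) {
          from <- states[pa, s0[1]]
          states[ch, s0] <- sample.int(20, length(s0), replace = TRUE,
                                       prob = P[from, ])
        }
      }
    }
    aln <- matrix(AA_STATES[states[seq_len(ntip), , drop = FALSE]],
                  nrow = ntip, dimnames = list(tree$tip.label, NULL))
    list(alignment = aln, site_rates = rates)
  })
}

#' Generate an annotated toy genome with known ground truth
#'
#' Plants CDS, rRNA and tRNA features on a random background sequence so that
#' the coding fraction, codon tallies, overlapping pairs, anticodon set,
#' nonstandard start codon and a pseudogene are all known exactly. On a
#' circular genome the layout is rotated so that one CDS wraps the origin.
#' Planted CDS-CDS overlaps are 4 bp (the downstream gene's AUG overlapping
#' the upstream gene's TGA stop, as in gene-dense organellar genomes).
#'
#' @param length Genome length in bp.
#' @param coding_fraction Target fraction of coding bases (union of CDS, rRNA
#'   and tRNA extents); achieved exactly.
#' @param n_cds,n_rrna,n_trna Feature counts per kind. `n_cds` must be at
#'   least `2 * n_overlap_pairs + 1` when any CDS are requested.
#' @param n_overlap_pairs Number of planted overlapping CDS pairs.
#' @param anticodons Character vector of elongator tRNA anticodons (RNA,
#'   5'->3'); recycled/truncated to `n_trna`.
#' @param initiator_cau Add one extra initiator fMet tRNA (anticodon CAU)?
#' @param codon_probs Named probability vector over sense DNA codons for CDS
#'   internal codons (default uniform).
#' @param nonstandard_start Start codon planted on one non-overlapping CDS
#'   (e.g. `"ATA"`; `NULL` for none).
#' @param at_noncoding Target A+T fraction of noncoding background bases.
#' @param circular Circular genome (forces one origin-wrapping CDS)?
#' @param seed Optional RNG seed.
#' @return List with `genome` (a [genome_record()]) and `truth`: composition
#'   numbers, per-codon tallies, the planted overlap table, anticodons, the
#'   nonstandard-start feature id, and the wrapped feature id.
#' @export
make_toy_genome <- function(length = 1000L, coding_fraction = 0.9,
                            n_cds = 8L, n_rrna = 1L, n_trna = 3L,
                            n_overlap_pairs = 1L,
                            anticodons = c("UAC", "GAU", "UGC"),
                            initiator_cau = TRUE,
                            codon_probs = NULL,
                            nonstandard_start = "ATA",
                            at_noncoding = 0.7,
                            circular = TRUE, seed = NULL) {
  L <- as.integer(length)
  stopifnot(L >= 100, coding_fraction >= 0, coding_fraction <= 1)
  n_cds <- as.integer(n_cds); n_rrna <- as.integer(n_rrna)
  n_trna <- as.integer(n_trna); n_pairs <- as.integer(n_overlap_pairs)
  if (n_cds > 0 && n_cds < 2L * n_pairs + (!is.null(nonstandard_start)))
    stop("infeasible packing: need n_cds >= 2*n_overlap_pairs",
         if (!is.null(nonstandard_start)) " + 1 for the nonstandard start")
  if (n_cds == 0 && n_pairs > 0) stop("overlap pairs need CDS features")

  sense <- sense_codons("DNA")
  if (is.null(codon_probs)) {
    codon_probs <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
  } else {
    if (is.null(names(codon_probs)) || !all(names(codon_probs) %in% sense))
      stop("codon_probs must be named by sense DNA codons")
    codon_probs <- codon_probs / sum(codon_probs)
  }

  trna_len <- 72L; rrna_len <- 150L
  n_trna_all <- n_trna + as.integer(initiator_cau)
  C <- round(coding_fraction * L)
  rna_total <- n_trna_all * trna_len + n_rrna * rrna_len
  cds_union <- C - rna_total
  if (n_cds > 0 && cds_union < n_cds * 9L)
    stop("infeasible packing: coding budget too small for ", n_cds, " CDS")
  if (n_cds == 0 && cds_union < 0)
    stop("infeasible packing: RNA genes exceed the coding budget")
  if (n_cds == 0 && cds_union > 0 && rna_total == 0)
    stop("infeasible packing: coding budget but no features to carry it")

  with_seed(seed, {
    # --- allocate CDS lengths (multiples of 3; overlaps add back 4 bp each)
    ov_bp <- 4L
    cds_sum <- if (n_cds > 0) cds_union + ov_bp * n_pairs else 0L
    cds_len <- integer(0)
    slack <- 0L
    if (n_cds > 0) {
      base <- 3L * (cds_sum %/% (3L * n_cds))
      cds_len <- rep(base, n_cds)
      extra <- cds_sum - sum(cds_len)           # 0 .. 3*n_cds - 1
      add3 <- extra %/% 3L
      if (add3 > 0) cds_len[seq_len(add3)] <- cds_len[seq_len(add3)] + 3L
      slack <- extra %% 3L                      # absorbed by a tRNA below
      if (any(cds_len < 9L)) stop("infeasible packing: CDS too short")
    }
    if (n_cds == 0L) slack <- as.integer(cds_union)
    trna_lens <- rep(trna_len, n_trna_all)
    if (slack > 0) {
      if (n_trna_all > 0) trna_lens[1] <- trna_lens[1] + slack
      else if (n_rrna > 0) rrna_len <- rrna_len + slack
      else stop("infeasible packing: cannot absorb length remainder")
    }

    # --- plan blocks left to right; overlapping pairs fused into one block
    # block := list(kind, ids, lengths, overlap)
    blocks <- list()
    pair_members <- integer(0)
    ci <- 0L
    for (i in seq_len(n_pairs)) {
      blocks[[length(blocks) + 1L]] <- list(kind = "cds_pair",
                                            idx = c(ci + 1L, ci + 2L))
      pair_members <- c(pair_members, ci + 1L, ci + 2L)
      ci <- ci + 2L
    }
    while (ci < n_cds) {
      ci <- ci + 1L
      blocks[[length(blocks) + 1L]] <- list(kind = "cds", idx = ci)
    }
    for (i in seq_len(n_rrna)) blocks[[length(blocks) + 1L]] <- list(kind = "rrna", idx = i)
    for (i in seq_len(n_trna_all)) blocks[[length(blocks) + 1L]] <- list(kind = "trna", idx = i)

    block_span <- vapply(blocks, function(b) {
      switch(b$kind,
             cds_pair = sum(cds_len[b$idx]) - ov_bp,
             cds = cds_len[b$idx],
             rrna = rrna_len,
             trna = trna_lens[b$idx])
    }, numeric(1))
    noncoding <- L - sum(block_span)
    stopifnot(noncoding == L - C)
    pseudo_len <- if (noncoding >= 30L) 20L else 0L
    nslots <- length(blocks) + 1L
    gaps <- rep(noncoding %/% nslots, nslots)
    gaps[nslots] <- gaps[nslots] + noncoding %% nslots
    if (pseudo_len > 0 && gaps[nslots] < pseudo_len + 2L) {
      # steal from the other gaps to host the pseudogene at the end
      need <- pseudo_len + 2L - gaps[nslots]
      for (j in seq_len(nslots - 1L)) {
        take <- min(gaps[j], need)
        gaps[j] <- gaps[j] - take; gaps[nslots] <- gaps[nslots] + take
        need <- need - take
        if (need == 0L) break
      }
      if (need > 0L) pseudo_len <- 0L
    }

    # --- lay the sequence down
    chars <- character(L)
    at_bases <- c("A", "T"); gc_bases <- c("G", "C")
    draw_bg <- function(n) ifelse(stats::runif(n) < at_noncoding,
                                  sample(at_bases, n, replace = TRUE),
                                  sample(gc_bases, n, replace = TRUE))
    draw_codons <- function(n) sample(names(codon_probs), n, replace = TRUE,
                                      prob = codon_probs)
    feats <- list()
    mask <- logical(L)
    cur <- 0L
    alt_start_id <- NULL
    overlap_truth <- list()

    write_cds <- function(id, start, len, start_codon, strand, stop_codon = "TAA",
                          last_internal_ends_A = FALSE) {
      n_int <- len / 3L - 2L
      internals <- draw_codons(n_int)
      if (last_internal_ends_A && n_int > 0)
        internals[n_int] <- paste0(substr(internals[n_int], 1, 2), "A")
      cdn <- c(start_codon, internals, stop_codon)
      s <- paste(cdn, collapse = "")
      if (strand == "-") s <- revcomp(s)
      chars[start:(start + len - 1L)] <<- strsplit(s, "")[[1]]
      mask[start:(start + len - 1L)] <<- TRUE
      feats[[length(feats) + 1L]] <<- feature(id, "CDS", strand,
                                              start, start + len - 1L,
                                              product = paste0("toy protein ", id))
    }

    remaining_plain <- setdiff(seq_len(n_cds), pair_members)
    alt_idx <- if (!is.null(nonstandard_start) && length(remaining_plain))
      remaining_plain[1] else 0L
    minus_idx <- if (length(remaining_plain) > 1) remaining_plain[2] else 0L

    for (bi in seq_along(blocks)) {
      if (gaps[bi] > 0L) {
        chars[(cur + 1L):(cur + gaps[bi])] <- draw_bg(gaps[bi])
        cur <- cur + gaps[bi]
      }
      b <- blocks[[bi]]
      if (b$kind == "cds_pair") {
        i1 <- b$idx[1]; i2 <- b$idx[2]
        a_start <- cur + 1L
        # upstream gene: stop TGA, last internal codon ends in A so that the
        # downstream AUG overlaps the stop by 4 bp
        write_cds(sprintf("cds%02d", i1), a_start, cds_len[i1], "ATG", "+",
                  stop_codon = "TGA", last_internal_ends_A = TRUE)
        a_end <- a_start + cds_len[i1] - 1L
        # downstream gene starts at the ATG formed by ..A|TG.. of the
        # upstream tail: codon 1 = chars[a_end-3 .. a_end-1] = "ATG",
        # codon 2 begins with the "A" of the upstream TGA stop
        b_start <- a_end - 3L
        b_end <- b_start + cds_len[i2] - 1L
        n_int2 <- cds_len[i2] %/% 3L - 2L
        internals2 <- draw_codons(n_int2)
        fresh <- paste0(substr(internals2[1], 2, 3),
                        paste(internals2[-1], collapse = ""), "TAA")
        chars[(a_end + 1L):b_end] <- strsplit(fresh, "")[[1]]
        mask[(a_end + 1L):b_end] <- TRUE
        feats[[length(feats) + 1L]] <- feature(sprintf("cds%02d", i2), "CDS", "+",
                                               b_start, b_end,
                                               product = paste0("toy protein cds",
                                                                sprintf("%02d", i2)))
        overlap_truth[[length(overlap_truth) + 1L]] <-
          data.frame(id1 = sprintf("cds%02d", i1), id2 = sprintf("cds%02d", i2),
                     overlap_bp = ov_bp)
        cur <- b_start + cds_len[i2] - 1L
      } else if (b$kind == "cds") {
        i <- b$idx
        sc <- if (i == alt_idx) nonstandard_start else "ATG"
        strand <- if (i == minus_idx) "-" else "+"
        if (i == alt_idx) alt_start_id <- sprintf("cds%02d", i)
        write_cds(sprintf("cds%02d", i), cur + 1L, cds_len[i], sc, strand)
        cur <- cur + cds_len[i]
      } else if (b$kind == "rrna") {
        st <- cur + 1L; en <- cur + rrna_len
        chars[st:en] <- draw_bg(rrna_len)
        mask[st:en] <- TRUE
        feats[[length(feats) + 1L]] <- feature(sprintf("rrna%02d", b$idx), "rRNA",
                                               "+", st, en, product = "toy rRNA")
        cur <- en
      } else {  # trna
        st <- cur + 1L; en <- cur + trna_lens[b$idx]
        chars[st:en] <- draw_bg(trna_lens[b$idx])
        mask[st:en] <- TRUE
        is_init <- initiator_cau && b$idx == n_trna_all
        ac <- if (is_init) "CAU"
              else anticodons[((b$idx - 1L) %% max(1L, length(anticodons))) + 1L]
        feats[[length(feats) + 1L]] <- feature(sprintf("trna%02d", b$idx), "tRNA",
                                               "+", st, en,
                                               product = if (is_init) "initiator fMet tRNA"
                                                         else "toy tRNA",
                                               anticodon = ac, initiator = is_init)
        cur <- en
      }
    }
    # final gap (with pseudogene at its start, if it fits)
    if (cur < L) chars[(cur + 1L):L] <- draw_bg(L - cur)
    if (pseudo_len > 0) {
      ps <- cur + 2L
      feats[[length(feats) + 1L]] <- feature("pseudo01", "pseudogene", "+",
                                             ps, ps + pseudo_len - 1L,
                                             product = "synthetic tRNA pseudogene")
    }
    stopifnot(sum(mask) == C)

    # --- ground truth computed on the linear layout
    codon_truth <- stats::setNames(integer(64), all_codons("DNA"))
    for (f in feats) {
      if (f$kind != "CDS") next
      s <- f$intervals[1, "start"]; e <- f$intervals[1, "end"]
      sq <- paste(chars[s:e], collapse = "")
      if (f$strand == "-") sq <- revcomp(sq)
      cods <- substring(sq, seq(1, nchar(sq), 3), seq(3, nchar(sq), 3))
      tb <- table(cods)
      codon_truth[names(tb)] <- codon_truth[names(tb)] + as.integer(tb)
    }
    is_at <- chars %in% c("A", "T")
    truth <- list(
      genome_length = L,
      coding_bases = sum(mask),
      coding_fraction = sum(mask) / L,
      at_overall = mean(is_at),
      at_coding = if (any(mask)) mean(is_at[mask]) else 0,
      at_noncoding = if (any(!mask)) mean(is_at[!mask]) else 0,
      codon_counts = codon_truth,
      overlaps = if (length(overlap_truth)) do.call(rbind, overlap_truth)
                 else data.frame(id1 = character(0), id2 = character(0),
                                 overlap_bp = integer(0)),
      anticodons = vapply(Filter(function(f) f$kind == "tRNA", feats),
                          `[[`, character(1), "anticodon"),
      nonstandard_start_id = alt_start_id,
      wrapped_feature = NULL
    )

    # --- rotate a circular genome so that the first CDS wraps the origin
    if (circular && n_cds > 0) {
      f1 <- Find(function(f) f$kind == "CDS", feats)
      r <- f1$intervals[1, "start"] + min(10L, f1$intervals[1, "end"] -
                                                f1$intervals[1, "start"] - 1L)
      rot <- function(p) ((p - r - 1L) %% L) + 1L
      chars <- c(chars[(r + 1L):L], chars[seq_len(r)])
      feats <- lapply(feats, function(f) {
        f$intervals[, "start"] <- rot(f$intervals[, "start"])
        f$intervals[, "end"] <- rot(f$intervals[, "end"])
        f
      })
      truth$wrapped_feature <- f1$id
    }

    genome <- genome_record("toy_genome", paste(chars, collapse = ""),
                            circular = circular, features = feats)
    list(genome = genome, truth = truth)
  })
}
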