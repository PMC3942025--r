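# Felsenstein pruning over discrete-gamma rate categories, conditional-mean
# per-site rate estimation, and progressive removal of fast-evolving sites.

# Encode an alignment as per-tip 20 x S indicator ("tip partial") matrices.
# Gap/missing characters contribute all-ones columns; unknown residues error.
encode_alignment <- function(aln) {
  if (!is.matrix(aln) || is.null(rownames(aln)))
    stop("alignment must be a character matrix with taxon rownames")
  aln <- toupper(aln)
  bad <- setdiff(unique(as.vector(aln)), c(AA_STATES, AA_MISSING))
  if (length(bad))
    stop("unknown residue(s) in alignment: ", paste(bad, collapse = " "))
  lapply(seq_len(nrow(aln)), function(i) {
    idx <- match(aln[i, ], AA_STATES)
    out <- matrix(0, nrow = 20, ncol = ncol(aln))
    out[cbind(idx[!is.na(idx)], which(!is.na(idx)))] <- 1
    out[, is.na(idx)] <- 1
    out
  })
}

#' Per-site, per-category log-likelihoods by Felsenstein pruning
#'
#' Computes, for every alignment column and every discrete-gamma rate
#' category, the log-likelihood of the column on the fixed tree under the
#' model, by the pruning algorithm with per-node rescaling. Gap and missing
#' characters contribute all-ones partial vectors.
#'
#' @param aln Character matrix of aligned amino acids (taxa x sites); rownames
#'   must match the tree's tip labels.
#' @param tree A rooted `phylo` tree with nonnegative branch lengths.
#' @param model A [substitution_model()].
#' @return A list of class `"site_lik_table"`: `loglik` (sites x k matrix),
#'   `category_rates`, `alpha`, `k`, and `all_gap` (logical per site).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have nonnegative branch lengths")
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa must match tree tips")
  aln <- aln[tree$tip.label, , drop = FALSE]
  nsite <- ncol(aln)
  ntip <- length(tree$tip.label)
  tips <- encode_alignment(aln)
  all_gap <- vapply(seq_len(nsite),
                    function(s) all(vapply(tips, function(m) all(m[, s] == 1),
                                           logical(1))),
                    logical(1))
  post <- ape::reorder.phylo(tree, "postorder")
  rates <- model$category_rates
  loglik <- matrix(NA_real_, nrow = nsite, ncol = model$k)

  for (cat in seq_len(model$k)) {
    partials <- vector("list", ntip + tree$Nnode)
    partials[seq_len(ntip)] <- tips
    logscale <- numeric(nsite)
    Ps <- lapply(seq_len(nrow(post$edge)),
                 function(k) prob_matrix(model, rates[cat] * post$edge.length[k]))
    for (k in seq_len(nrow(post$edge))) {
      p <- post$edge[k, 1]; ch <- post$edge[k, 2]
      contrib <- Ps[[k]] %*% partials[[ch]]
      if (is.null(partials[[p]])) partials[[p]] <- contrib
      else partials[[p]] <- partials[[p]] * contrib
      # rescale to avoid underflow
      mx <- apply(partials[[p]], 2, max)
      mx[mx <= 0] <- 1
      partials[[p]] <- sweep(partials[[p]], 2, mx, "/")
      logscale <- logscale + log(mx)
    }
    root <- ntip + 1L
    site_lik <- as.numeric(model$frequencies %*% partials[[root]])
    loglik[, cat] <- log(site_lik) + logscale
  }
  structure(list(loglik = loglik, category_rates = rates,
                 alpha = model$alpha, k = model$k, all_gap = all_gap),
            class = "site_lik_table")
}

#' Conditional-mean site rates under a discrete-gamma model
#'
#' The estimated rate of site i is the posterior mean over equiprobable rate
#' categories, r_i = sum_k r_k L_ik / sum_k L_ik. Columns consisting entirely
#' of gaps carry no information; their rate is reported as 1.0 with a warning.
#'
#' @inheritParams site_log_likelihoods
#' @return A list of class `"site_rate_profile"`: `rates` (per-site posterior
#'   mean rate), `posteriors` (sites x k), `site_loglik` (per-site
#'   log-likelihood summed over categories), `category_rates`, `alpha`, `k`.
#' @export
conditional_mean_rates <- function(aln, tree, model) {
  tab <- site_log_likelihoods(aln, tree, model)
  ll <- tab$loglik
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)               # equal prior weight 1/k cancels
  tot <- rowSums(w)
  post <- w / tot
  rates <- as.numeric(post %*% tab$category_rates)
  if (any(tab$all_gap)) {
    warning(sum(tab$all_gap), " all-gap column(s); their rate is set to 1.0")
    rates[tab$all_gap] <- 1.0
    post[tab$all_gap, ] <- 1 / tab$k
  }
  structure(list(rates = rates, posteriors = post,
                 site_loglik = mx + log(tot / tab$k),
                 category_rates = tab$category_rates,
                 alpha = tab$alpha, k = tab$k),
            class = "site_rate_profile")
}

#' @export
print.site_rate_profile <- function(x, ...) {
  cat("Conditional-mean site rates (discrete gamma, alpha = ",
      format(x$alpha), ", ", x$k, " categories)\n", sep = "")
  cat("  ", length(x$rates), " sites; rate range ",
      format(min(x$rates), digits = 4), " .. ",
      format(max(x$rates), digits = 4), "\n", sep = "")
  cat("  total log-likelihood: ", format(sum(x$site_loglik)), "\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood estimate of the gamma shape parameter
#'
#' One-dimensional bounded search (via [stats::optimize()]) of the discrete-
#' gamma shape maximizing the alignment log-likelihood on the fixed tree.
#'
#' @inheritParams site_log_likelihoods
#' @param interval Search interval for alpha.
#' @return List with `alpha`, `loglik`, and `model` (the input model refit
#'   with the estimated shape).
#' @export
estimate_gamma_shape <- function(aln, tree, model, interval = c(0.05, 20)) {
  obj <- function(a) {
    m2 <- substitution_model(if (model$name == "custom") model$exchangeabilities
                             else model$name,
                             frequencies = model$frequencies,
                             alpha = a, k = model$k)
    tab <- site_log_likelihoods(aln, tree, m2)
    mx <- apply(tab$loglik, 1, max)
    sum(mx + log(rowMeans(exp(tab$loglik - mx))))
  }
  opt <- stats::optimize(obj, interval = interval, maximum = TRUE)
  fit <- substitution_model(if (model$name == "custom") model$exchangeabilities
                            else model$name,
                            frequencies = model$frequencies,
                            alpha = opt$maximum, k = model$k)
  list(alpha = opt$maximum, loglik = opt$objective, model = fit)
}

#' Progressive removal of fast-evolving sites
#'
#' Sites are ranked once by decreasing estimated rate (ties broken by
#' original column index, ascending); the k-th alignment of the series drops
#' the k*step highest-ranked sites. The series is nested: sites removed at
#' step k are a subset of those removed at step k+1.
#'
#' @param aln Character matrix of aligned residues (taxa x sites).
#' @param profile A [conditional_mean_rates()] result for `aln` (or any
#'   numeric vector of per-site rates).
#' @param step Number of sites removed per increment (default 1000).
#' @param max_steps Optional cap on the number of alignments returned.
#' @return A list of filtered alignments; element k has attributes
#'   `removed_sites` and `kept_sites` (original column indices).
#' @export
progressive_removal <- function(aln, profile, step = 1000L, max_steps = NULL) {
  rates <- if (inherits(profile, "site_rate_profile")) profile$rates
           else as.numeric(profile)
  if (!is.matrix(aln) || ncol(aln) != length(rates))
    stop("profile length must equal the number of alignment columns")
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  nsite <- ncol(aln)
  if (step >= nsite) {
    warning("step >= alignment length; returning a single empty alignment")
    out <- aln[, 0, drop = FALSE]
    attr(out, "removed_sites") <- seq_len(nsite)
    attr(out, "kept_sites") <- integer(0)
    return(list(out))
  }
  ord <- order(-rates, seq_along(rates))   # fast first, ties by column index
  nsteps <- (nsite - 1L) %/% step
  if (!is.null(max_steps)) nsteps <- min(nsteps, as.integer(max_steps))
  lapply(seq_len(nsteps), function(k) {
    removed <- sort(ord[seq_len(k * step)])
    kept <- setdiff(seq_len(nsite), removed)
    out <- aln[, kept, drop = FALSE]
    attr(out, "removed_sites") <- removed
    attr(out, "kept_sites") <- kept
    out
  })
}
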