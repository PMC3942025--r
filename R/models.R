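# Amino-acid substitution models with discrete-gamma rate variation.
#
# A model is defined by a symmetric exchangeability matrix S and equilibrium
# frequencies pi. The rate matrix Q = S diag(pi), with the diagonal set so
# rows sum to zero, is rescaled to one expected substitution per unit branch
# length. Transition probabilities P(t) = exp(Qt) come from the spectral
# decomposition of the pi-symmetrized generator, which is exact for
# reversible models.

#' Build an amino-acid substitution model
#'
#' @param exchangeabilities `"poisson"` (all equal), `"lg"` (the LG
#'   replacement matrix packaged with \pkg{mtevo}), or a symmetric 20x20
#'   nonnegative matrix in the amino-acid order
#'   `A R N D C Q E G H I L K M F P S T W Y V`.
#' @param frequencies Equilibrium frequencies (length 20, summing to 1), or
#'   `NULL` for the model default (uniform for Poisson, the published LG
#'   frequencies for LG). Use [empirical_frequencies()] for a "+F" model.
#' @param alpha Discrete-gamma shape parameter (> 0).
#' @param k Number of equiprobable gamma categories (>= 1).
#' @return A list of class `"subst_model"` with the rescaled generator, its
#'   spectral decomposition, and the category rates.
#' @export
substitution_model <- function(exchangeabilities = "poisson",
                               frequencies = NULL, alpha = 1, k = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("gamma shape 'alpha' must be a positive number")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")

  if (is.character(exchangeabilities)) {
    name <- match.arg(exchangeabilities, c("poisson", "lg"))
    if (name == "poisson") {
      S <- matrix(1, 20, 20); diag(S) <- 0
      if (is.null(frequencies)) frequencies <- rep(1 / 20, 20)
    } else {
      lg <- load_lg_model()
      S <- lg$S
      if (is.null(frequencies)) frequencies <- lg$freqs
    }
  } else {
    S <- as.matrix(exchangeabilities)
    name <- "custom"
    if (!all(dim(S) == c(20, 20)) || any(S < 0) || any(abs(S - t(S)) > 1e-12))
      stop("exchangeabilities must be a symmetric nonnegative 20x20 matrix")
    if (is.null(frequencies))
      stop("custom exchangeabilities require explicit frequencies")
  }
  pi <- as.numeric(frequencies)
  if (length(pi) != 20L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must be 20 positive values summing to 1")
  pi <- pi / sum(pi)

  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_STATES, AA_STATES)

  # spectral decomposition of the symmetrized generator
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)

  structure(list(name = name, exchangeabilities = S, frequencies = pi,
                 Q = Q, alpha = alpha, k = k,
                 category_rates = discrete_gamma_rates(alpha, k),
                 eig_values = eig$values,
                 left = diag(1 / d) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(d)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Amino-acid substitution model (", x$name, "+G", x$k, ")\n", sep = "")
  cat("  gamma shape alpha =", format(x$alpha), "\n")
  cat("  category rates:", paste(format(x$category_rates, digits = 4),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Mean rates of equiprobable discrete-gamma categories
#'
#' Category k of K covers the (k-1)/K .. k/K quantile slab of a
#' Gamma(alpha, alpha) distribution (mean 1); its rate is the conditional
#' mean within the slab, so the K rates average exactly 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of k rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r)
}

#' Empirical amino-acid frequencies of an alignment ("+F")
#'
#' @param aln Character matrix of aligned residues (taxa x sites).
#' @param pseudocount Added to every residue count to avoid zeros (default 1).
#' @return Length-20 frequency vector in the standard amino-acid order.
#' @export
empirical_frequencies <- function(aln, pseudocount = 1) {
  counts <- table(factor(toupper(as.vector(aln)), levels = AA_STATES))
  f <- as.numeric(counts) + pseudocount
  stats::setNames(f / sum(f), AA_STATES)
}

# Transition probability matrix P(t) for one scaled time t.
prob_matrix <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$left %*% (exp(model$eig_values * t) * model$right)
  # clamp tiny negative values from roundoff
  P[P < 0] <- 0
  P
}

# Parse the packaged plain-text LG model file.
load_lg_model <- function() {
  if (!is.null(.pkg_cache$lg)) return(.pkg_cache$lg)
  path <- system.file("extdata", "lg_model.txt", package = "mtevo",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  S <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  for (i in 2:20) {
    S[i, seq_len(i - 1)] <- vals[[i - 1]]
  }
  S <- S + t(S)
  freqs <- vals[[20]]
  stopifnot(length(freqs) == 20, abs(sum(freqs) - 1) < 1e-3)
  .pkg_cache$lg <- list(S = S, freqs = freqs / sum(freqs))
  .pkg_cache$lg
}
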