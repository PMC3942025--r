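# Pruning likelihoods, conditional-mean site rates and progressive fast-site
# removal, validated against closed forms and an exhaustive summation oracle.

poisson_model <- function(alpha = 1, k = 4)
  substitution_model("poisson", alpha = alpha, k = k)

test_that("zero-length branches with identical residues give log pi", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- matrix(c("A", "A"), 2, dimnames = list(c("a", "b"), NULL))
  tab <- site_log_likelihoods(aln, tr, poisson_model())
  expect_equal(max(abs(tab$loglik - log(1 / 20))), 0, tolerance = 1e-12)
})

test_that("two-taxon likelihoods match the 20-state Poisson closed form", {
  tr <- ape::read.tree(text = "(a:0.13,b:0.27);")
  t_tot <- 0.4
  mod <- poisson_model(alpha = 0.7, k = 4)
  aln <- matrix(c("A", "A", "A", "V"), nrow = 2,
                dimnames = list(c("a", "b"), NULL))
  tab <- site_log_likelihoods(aln, tr, mod)
  same <- vapply(mod$category_rates, function(r)
    (1 / 20) * (1 / 20 + 19 / 20 * exp(-20 * t_tot * r / 19)), numeric(1))
  diff <- vapply(mod$category_rates, function(r)
    (1 / 20) * (1 / 20) * (1 - exp(-20 * t_tot * r / 19)), numeric(1))
  expect_equal(tab$loglik[1, ], log(same), tolerance = 1e-9)
  expect_equal(tab$loglik[2, ], log(diff), tolerance = 1e-9)
})

test_that("pruning equals exhaustive state summation on small trees", {
  set.seed(55)
  for (i in 1:6) {
    ntip <- sample(3:5, 1)
    tr <- random_rooted_tree(ntip)
    aln <- random_alignment(ntip, 4)
    mod <- substitution_model(if (i %% 2) "poisson" else "lg",
                              alpha = runif(1, 0.3, 2), k = 2)
    tab <- site_log_likelihoods(aln, tr, mod)
    states <- match(aln[tr$tip.label, , drop = FALSE], mtevo:::AA_STATES)
    dim(states) <- dim(aln)
    for (s in seq_len(ncol(aln))) {
      for (cat in seq_len(mod$k)) {
        ora <- lik_oracle_site(states[, s], tr, mod, mod$category_rates[cat])
        expect_equal(tab$loglik[s, cat], log(ora), tolerance = 1e-9)
      }
    }
  }
})

test_that("gaps act as missing data in the pruning computation", {
  tr <- ape::read.tree(text = "(a:0.2,(b:0.1,c:0.1):0.1);")
  mod <- poisson_model(k = 2)
  aln_gap <- matrix(c("A", "-", "C"), 3, dimnames = list(c("a", "b", "c"), NULL))
  tab <- site_log_likelihoods(aln_gap, tr, mod)
  # marginalizing b by hand: sum likelihood over all states of b
  total <- 0
  for (x in mtevo:::AA_STATES) {
    aln_x <- matrix(c("A", x, "C"), 3, dimnames = list(c("a", "b", "c"), NULL))
    total <- total + exp(site_log_likelihoods(aln_x, tr, mod)$loglik[1, 1])
  }
  expect_equal(tab$loglik[1, 1], log(total), tolerance = 1e-9)
  expect_error(site_log_likelihoods(
    matrix(c("A", "B", "C"), 3, dimnames = list(c("a", "b", "c"), NULL)),
    tr, mod), "unknown residue")
})

test_that("posteriors sum to one and constant columns get lower rates", {
  set.seed(66)
  tr <- random_rooted_tree(8)
  mod <- poisson_model(alpha = 0.8)
  sim <- simulate_alignment(tr, mod, 30, site_rates = rep(1, 30), seed = 9)
  aln <- sim$alignment
  aln[, 1] <- "A"                                  # constant column
  aln[, 2] <- sample(mtevo:::AA_STATES, nrow(aln)) # saturated column
  prof <- conditional_mean_rates(aln, tr, mod)
  expect_equal(rowSums(prof$posteriors), rep(1, 30), tolerance = 1e-12)
  expect_lt(prof$rates[1], prof$rates[2])
  expect_true(all(prof$rates >= min(mod$category_rates) - 1e-12))
  expect_true(all(prof$rates <= max(mod$category_rates) + 1e-12))
})

test_that("one category or huge alpha force all rates to one", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3);")
  aln <- matrix(c("A", "A", "A", "V"), 2, dimnames = list(c("a", "b"), NULL))
  p1 <- conditional_mean_rates(aln, tr, poisson_model(k = 1))
  expect_equal(p1$rates, c(1, 1))
  pinf <- conditional_mean_rates(aln, tr, poisson_model(alpha = 1e4, k = 4))
  expect_equal(pinf$rates, c(1, 1), tolerance = 1e-2)
})

test_that("all-gap columns get rate 1 with a warning", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3);")
  aln <- matrix(c("A", "V", "-", "-"), 2, dimnames = list(c("a", "b"), NULL))
  expect_warning(prof <- conditional_mean_rates(aln, tr, poisson_model()),
                 "all-gap")
  expect_equal(prof$rates[2], 1.0)
})

test_that("gamma shape estimation recovers the simulating shape roughly", {
  set.seed(77)
  tr <- random_rooted_tree(12)
  mod <- poisson_model(alpha = 0.5, k = 4)
  sim <- simulate_alignment(tr, mod, 400, seed = 10)  # gamma-drawn rates
  fit <- estimate_gamma_shape(sim$alignment, tr, poisson_model(alpha = 1, k = 4))
  expect_gt(fit$alpha, 0.25)
  expect_lt(fit$alpha, 1.0)
})

test_that("planted two-class rates are recovered and fast sites removed first", {
  set.seed(42)
  tree <- random_rooted_tree(16)
  mod <- poisson_model(alpha = 1, k = 4)
  true_rates <- sample(rep(c(0.2, 3.0), times = c(325, 175)))
  sim <- simulate_alignment(tree, mod, 500, site_rates = true_rates, seed = 142)
  prof <- conditional_mean_rates(sim$alignment, tree, mod)
  expect_gte(cor(prof$rates, sim$site_rates, method = "spearman"), 0.8)
  rem <- progressive_removal(sim$alignment, prof, step = 100, max_steps = 1)
  idx <- attr(rem[[1]], "removed_sites")
  frac_block <- mean(sim$site_rates[idx] == 3.0)
  frac_rest <- mean(sim$site_rates[-idx] == 3.0)
  expect_gte(frac_block / frac_rest, 4)
})

test_that("removal series arithmetic, tie-breaking and nesting are exact", {
  # a 41,372-column profile with equal rates: removal follows column order
  n <- 41372L
  aln <- matrix("A", nrow = 2, ncol = n, dimnames = list(c("a", "b"), NULL))
  series <- progressive_removal(aln, rep(1, n), step = 1000L, max_steps = 25)
  expect_length(series, 25L)
  expect_equal(ncol(series[[25]]), 16372L)
  expect_identical(attr(series[[1]], "removed_sites"), 1:1000)

  # nesting on a random profile
  set.seed(5)
  aln2 <- matrix("A", nrow = 2, ncol = 57, dimnames = list(c("a", "b"), NULL))
  s2 <- progressive_removal(aln2, runif(57), step = 10L)
  expect_length(s2, 5L)
  for (k in 2:5)
    expect_true(all(attr(s2[[k - 1]], "removed_sites") %in%
                      attr(s2[[k]], "removed_sites")))

  expect_warning(e <- progressive_removal(aln2, runif(57), step = 100L),
                 "single empty alignment")
  expect_equal(ncol(e[[1]]), 0L)
})
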