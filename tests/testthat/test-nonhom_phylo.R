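test_that("rate matrix has generator structure and T92 limits", {
  for (kappa in c(0.5, 1, 2, 5)) {
    for (theta in c(0.2, 0.5, 0.8)) {
      Q <- rate_matrix(kappa, theta)
      expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
      off <- Q[row(Q) != col(Q)]
      expect_true(all(off >= 0))
      # stationary frequencies annihilate the generator
      pi <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
      expect_equal(max(abs(pi %*% Q)), 0, tolerance = 1e-12)
      # unit expected rate at stationarity
      expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    }
  }
  # kappa = 1, theta = 0.5 collapses to Jukes-Cantor
  Q <- rate_matrix(1, 0.5)
  expect_equal(unname(unique(round(Q[row(Q) != col(Q)], 12))), 1 / 3)
  expect_error(rate_matrix(-1, 0.5), "kappa")
  expect_error(rate_matrix(2, 1.2), "theta")
})

test_that("transition probabilities match a matrix-exponential oracle", {
  expect_equal(transition_probs(2, 0.6, 0), diag(4),
               ignore_attr = TRUE)
  # rows converge to the stationary distribution
  P <- transition_probs(2, 0.7, 500)
  pi <- c(0.15, 0.35, 0.35, 0.15)
  for (i in 1:4) expect_equal(unname(P[i, ]), pi, tolerance = 1e-9)
  # independent scaling-and-squaring oracle
  for (par in list(c(2, 0.6, 0.1), c(0.7, 0.25, 1.3), c(5, 0.9, 0.01))) {
    P <- transition_probs(par[1], par[2], par[3])
    Pref <- as.matrix(Matrix::expm(rate_matrix(par[1], par[2]) * par[3]))
    expect_equal(unname(P), unname(Pref), tolerance = 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  }
  expect_error(transition_probs(2, 0.6, -1), "t must be")
})

test_that("pruning equals the closed-form two-sequence likelihood", {
  tree <- ape::read.tree(text = "(A:0.3,B:0.2)N1;")
  cmap <- c(A = "x", B = "x")
  model <- gc_model(2, c(x = 0.7), 0.6, cmap)
  aln <- c(A = "ACGT", B = "AGGT")
  # root sits at N1: L = prod_s sum_x pi(x) P_a(x->A_s) P_b(x->B_s)
  Pa <- transition_probs(2, 0.7, 0.3)
  Pb <- transition_probs(2, 0.7, 0.2)
  pi <- c(0.2, 0.3, 0.3, 0.2)
  a <- match(strsplit(aln[["A"]], "")[[1]], c("A", "C", "G", "T"))
  b <- match(strsplit(aln[["B"]], "")[[1]], c("A", "C", "G", "T"))
  direct <- sum(vapply(seq_along(a), function(s) {
    log(sum(pi * Pa[, a[s]] * Pb[, b[s]]))
  }, numeric(1)))
  expect_equal(log_likelihood(aln, tree, model), direct, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(42)
  for (rep in 1:25) {
    n_tips <- sample(2:4, 1)
    tree <- random_labelled_tree(n_tips)
    cmap <- uniform_clade_map(tree)
    # split branches into two classes at random
    cmap[] <- sample(c("x", "y"), length(cmap), replace = TRUE)
    model <- gc_model(stats::runif(1, 0.5, 4),
                      c(x = stats::runif(1, 0.1, 0.9),
                        y = stats::runif(1, 0.1, 0.9)),
                      stats::runif(1, 0.1, 0.9), cmap)
    aln <- random_alignment(tree, 3)
    expect_equal(log_likelihood(aln, tree, model),
                 enumeration_loglik(aln, tree, model),
                 tolerance = 1e-9)
  }
})

test_that("site independence: duplicating sites doubles the log-likelihood", {
  tree <- balanced4_tree()
  cmap <- balanced4_map()
  model <- gc_model(2, c(x = 0.8, y = 0.4), 0.5, cmap)
  set.seed(7)
  aln <- random_alignment(tree, 12)
  ll1 <- log_likelihood(aln, tree, model)
  ll2 <- log_likelihood(vapply(aln, function(s) paste0(s, s),
                               character(1)), tree, model)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
  # gaps are missing data: an all-gap column contributes nothing
  aln_gap <- vapply(aln, function(s) paste0(s, "-"), character(1))
  expect_equal(log_likelihood(aln_gap, tree, model), ll1,
               tolerance = 1e-9)
})

test_that("marginal posteriors are proper and match enumeration", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.3)N2:0.25,C:0.4)N1;")
  cmap <- c(A = "x", B = "x", N2 = "y", C = "y")
  model <- gc_model(1.5, c(x = 0.7, y = 0.3), 0.45, cmap)
  aln <- c(A = "AC", B = "AG", C = "GC")
  rec <- reconstruct_marginal(aln, tree, model)
  expect_equal(rec$method_tag, "marginal_ML")
  for (node in names(rec$posteriors)) {
    post <- rec$posteriors[[node]]
    expect_equal(unname(rowSums(post)), rep(1, nrow(post)),
                 tolerance = 1e-9)
    for (s in seq_len(nrow(post))) {
      expect_equal(unname(post[s, ]),
                   enumeration_posterior(aln, tree, model, node, s),
                   tolerance = 1e-10)
    }
    # reconstructed state is the posterior argmax
    states <- strsplit(rec$node_sequences[[node]], "")[[1]]
    expect_equal(states,
                 c("A", "C", "G", "T")[apply(post, 1, which.max)])
  }
})

test_that("identical tips on short branches reconstruct to themselves", {
  tree <- ape::read.tree(text = "((A:0.01,B:0.01)N2:0.01,C:0.01)N1;")
  cmap <- c(A = "x", B = "x", N2 = "x", C = "x")
  model <- gc_model(2, c(x = 0.5), 0.5, cmap)
  aln <- c(A = "ACGT", B = "ACGT", C = "ACGT")
  rec <- reconstruct_marginal(aln, tree, model)
  expect_equal(unname(rec$node_sequences[["N1"]]), "ACGT")
  expect_equal(unname(rec$node_sequences[["N2"]]), "ACGT")
})

test_that("Fitch parsimony matches brute force and known cases", {
  tree <- balanced4_tree()
  aln0 <- c(A = "ACG", B = "ACG", C = "ACG", D = "ACG")
  expect_equal(fitch_parsimony(aln0, tree)$score, 0)
  aln1 <- c(A = "A", B = "A", C = "G", D = "G")
  expect_equal(fitch_parsimony(aln1, tree)$score, 1)
  set.seed(99)
  for (rep in 1:10) {
    n_tips <- sample(3:5, 1)
    tr <- random_labelled_tree(n_tips)
    aln <- random_alignment(tr, 3)
    expect_equal(fitch_parsimony(aln, tr)$score,
                 oracle_parsimony_score(aln, tr))
  }
})

test_that("fitting recovers a single-class null with two free classes", {
  tree <- six_taxon_tree()
  cmap <- six_taxon_map()
  cfg <- sim_config(tree, cmap, kappa = 2,
                    theta = c(bang = 0.6, flor = 0.6), theta_root = 0.6,
                    n_sites = 200, n_families = 10, seed = 5)
  ds <- simulate_dataset(cfg)
  fit <- fit_model(ds$alignments, tree, cmap, n_starts = 1, seed = 2)
  # both class estimates should agree when the data are homogeneous
  expect_lt(abs(fit$model$theta[["bang"]] - fit$model$theta[["flor"]]),
            0.05)
  # fitted likelihood at least as good as the generating parameters
  truth <- gc_model(2, c(bang = 0.6, flor = 0.6), 0.6, cmap)
  expect_gte(fit$report$logLik + 1e-6,
             log_likelihood(ds$alignments, tree, truth))
})

test_that("likelihood input validation catches mismatched ids", {
  tree <- balanced4_tree()
  model <- gc_model(2, c(x = 0.5, y = 0.5), 0.5, balanced4_map())
  expect_error(log_likelihood(c(A = "AC", B = "AC", C = "AC"),
                              tree, model), "missing")
  expect_error(
    log_likelihood(c(A = "AC", B = "AC", C = "AC", D = "A"), tree, model),
    "length")
})
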