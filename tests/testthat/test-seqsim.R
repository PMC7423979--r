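test_that("root sequences follow the requested composition", {
  # degenerate composition: all G/C
  s <- sample_root_sequence(1, 50, seed = 1)
  expect_equal(nchar(s), 150L)
  expect_true(all(strsplit(s, "")[[1]] %in% c("G", "C")))
  # binomial check at theta = 0.5 over 10^4 codons
  s <- sample_root_sequence(0.5, 1e4, seed = 2, coding_mode = FALSE)
  n <- nchar(s)
  gc <- gc_metrics(s)[["gc_total"]]
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n))
  # determinism
  expect_identical(sample_root_sequence(0.7, 100, seed = 9),
                   sample_root_sequence(0.7, 100, seed = 9))
  # coding mode excludes stops
  s <- sample_root_sequence(0.1, 2000, seed = 3)
  expect_false(any(translate_codons(s) == "*"))
  expect_error(sample_root_sequence(1.5, 10), "theta_root")
})

test_that("branch evolution converges to the class equilibrium", {
  set.seed(11)
  start <- sample_root_sequence(0.2, 100, coding_mode = FALSE)
  res <- evolve_branch(start, kappa = 2, theta = 0.9, t = 50,
                       coding_mode = FALSE)
  gc <- gc_metrics(res$seq)[["gc_total"]]
  expect_lt(abs(gc - 0.9), 3 * sqrt(0.9 * 0.1 / 300))
  # t = 0 is the identity with no events
  res0 <- evolve_branch(start, 2, 0.9, 0)
  expect_identical(res0$seq, start)
  expect_equal(nrow(res0$events), 0L)
  expect_error(evolve_branch(start, 2, 0.9, -1), "t must be")
})

test_that("empirical endpoint changes match the analytic P(t)", {
  set.seed(21)
  n <- 24000L
  t <- 0.2
  start <- sample_root_sequence(0.5, n / 3, coding_mode = FALSE)
  res <- evolve_branch(start, kappa = 2, theta = 0.6, t = t,
                       coding_mode = FALSE)
  P <- transition_probs(2, 0.6, t)
  from <- strsplit(start, "")[[1]]
  to <- strsplit(res$seq, "")[[1]]
  for (x in c("A", "C", "G", "T")) {
    sel <- from == x
    n_x <- sum(sel)
    emp <- vapply(c("A", "C", "G", "T"),
                  function(y) mean(to[sel] == y), numeric(1))
    for (y in c("A", "C", "G", "T")) {
      se <- sqrt(P[x, y] * (1 - P[x, y]) / n_x)
      expect_lt(abs(emp[[y]] - P[x, y]), 3.5 * se + 1e-9)
    }
  }
})

test_that("stationarity: evolving at the root composition preserves GC", {
  set.seed(31)
  theta <- 0.65
  start <- sample_root_sequence(theta, 4000, coding_mode = FALSE)
  res <- evolve_branch(start, 2, theta, t = 1, coding_mode = FALSE)
  n <- nchar(start)
  expect_lt(abs(gc_metrics(res$seq)[["gc_total"]] - theta),
            3 * sqrt(theta * (1 - theta) / n))
})

test_that("simulated datasets carry exact ground truth", {
  tree <- balanced4_tree()
  cmap <- balanced4_map("hi", "lo")
  cfg <- sim_config(tree, cmap, kappa = 2, theta = c(hi = 0.85, lo = 0.45),
                    theta_root = 0.45, n_sites = 150, n_families = 4,
                    seed = 13)
  ds <- simulate_dataset(cfg)
  expect_length(ds$alignments, 4L)
  for (f in seq_len(4)) {
    # event-log replay reproduces every node byte for byte
    replayed <- replay_events(ds, f)
    expect_identical(replayed[names(ds$alignments[[f]])],
                     ds$alignments[[f]])
    expect_identical(replayed[names(ds$true_ancestors[[f]])],
                     ds$true_ancestors[[f]])
    # sequences have length 3 * n_sites and are stop-free
    expect_true(all(nchar(ds$alignments[[f]]) == 450L))
    for (s in ds$alignments[[f]]) {
      expect_false(any(translate_codons(s) == "*"))
    }
  }
  # clade with elevated theta ends up GC-richer at the tips
  gc_hi <- mean(vapply(ds$alignments, function(a) {
    mean(vapply(a[c("A", "B")], function(s) gc_metrics(s)[["gc_total"]],
                numeric(1)))
  }, numeric(1)))
  gc_lo <- mean(vapply(ds$alignments, function(a) {
    mean(vapply(a[c("C", "D")], function(s) gc_metrics(s)[["gc_total"]],
                numeric(1)))
  }, numeric(1)))
  expect_gt(gc_hi, gc_lo)
  # determinism under the same config
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$alignments, ds2$alignments)
})

test_that("zero-length branches copy the parent sequence", {
  tree <- ape::read.tree(text = "(A:0,B:0)N1;")
  cmap <- c(A = "x", B = "x")
  cfg <- sim_config(tree, cmap, theta = c(x = 0.5), n_sites = 30, seed = 2)
  ds <- simulate_dataset(cfg)
  root <- ds$true_ancestors[[1]][["N1"]]
  expect_identical(unname(ds$alignments[[1]][["A"]]), root)
  expect_identical(unname(ds$alignments[[1]][["B"]]), root)
})

test_that("config validation rejects inconsistent clade maps", {
  tree <- balanced4_tree()
  bad <- balanced4_map()[-1]  # drop branch A
  expect_error(sim_config(tree, bad), "A")
  extra <- c(balanced4_map(), Z = "x")
  expect_error(sim_config(tree, extra), "Z")
})

test_that("planted expression tables satisfy the phase rules exactly", {
  tab <- simulate_expression_table(1000, c(0.1, 0.1, 0.8), seed = 4)
  expect_equal(as.integer(table(tab$truth)[c("GAM_SPECIFIC",
                                             "SPO_SPECIFIC",
                                             "CONSTITUTIVE")]),
               c(100L, 100L, 800L))
  spo <- tab[tab$truth == "SPO_SPECIFIC", ]
  expect_true(all(spo$fpkm_gam < 5 & spo$fpkm_spo > 25))
  gam <- tab[tab$truth == "GAM_SPECIFIC", ]
  expect_true(all(gam$fpkm_spo < 5 & gam$fpkm_gam > 25))
  # determinism
  tab2 <- simulate_expression_table(1000, c(0.1, 0.1, 0.8), seed = 4)
  expect_identical(tab, tab2)
  expect_error(simulate_expression_table(100, c(-0.1, 0.2, 0.2)),
               "phase_fractions")
})
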