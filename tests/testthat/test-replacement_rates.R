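test_that("site counting partitions three sites per codon", {
  # GGG (Gly, HIGH): G3->A is synonymous (GGA still Gly),
  # G1->A is radical (AGG = Arg, NEUTRAL)
  code <- build_genetic_code()
  grouping <- gc_grouping(code)
  s <- count_sites("GGG", code, grouping)
  expect_equal(sum(s), 3, tolerance = 1e-12)
  expect_true(s[["S"]] > 0)
  expect_true(s[["NR"]] > 0)
  # partition holds over random stop-free sequences
  set.seed(3)
  for (rep in 1:5) {
    seq <- random_coding(40)
    tot <- count_sites(seq, code, grouping)
    # every neighbour of every codon here is classifiable; the only
    # adjustment is the exclusion of mutations to stops from the
    # denominator, which the per-codon renormalisation absorbs
    expect_equal(sum(tot), 3 * 40, tolerance = 1e-9)
  }
  expect_error(count_sites("TAA"), "stop")
})

test_that("difference counting handles known codon pairs", {
  expect_equal(count_differences("GGG", "GGA"), c(nc = 0, nr = 0, ns = 1))
  # Gly (HIGH) -> Glu (NEUTRAL): radical single step
  expect_equal(count_differences("GGG", "GAG"), c(nc = 0, nr = 1, ns = 0))
  # Lys (LOW) -> Gly (HIGH) via Glu or Arg (both NEUTRAL): 2 radical steps
  expect_equal(count_differences("AAA", "GGA"), c(nc = 0, nr = 2, ns = 0))
  expect_equal(count_differences("AAA", "AAA"), c(nc = 0, nr = 0, ns = 0))
  expect_error(count_differences("TAA", "GGG"), "sense")
})

test_that("difference counts are symmetric and sum to the mismatch count", {
  code <- build_genetic_code()
  grouping <- gc_grouping(code)
  codons <- sense_codons(code)
  set.seed(8)
  pairs <- cbind(sample(codons, 80, TRUE), sample(codons, 80, TRUE))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ab <- suppressWarnings(count_differences(a, b, code, grouping))
    ba <- suppressWarnings(count_differences(b, a, code, grouping))
    expect_equal(ab[c("nc", "nr")], ba[c("nc", "nr")], tolerance = 1e-12)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_lte(sum(ab), k + 1e-12)
  }
})

test_that("difference counting matches the pathway-enumeration oracle", {
  code <- build_genetic_code()
  grouping <- gc_grouping(code)
  codons <- sense_codons(code)
  set.seed(12)
  pick <- cbind(sample(codons, 150, TRUE), sample(codons, 150, TRUE))
  for (i in seq_len(nrow(pick))) {
    got <- suppressWarnings(
      count_differences(pick[i, 1], pick[i, 2], code, grouping))
    want <- oracle_count_differences(pick[i, 1], pick[i, 2], code,
                                     grouping)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the distance correction behaves like a Jukes-Cantor transform", {
  expect_equal(correct_distance(0), 0)
  expect_equal(correct_distance(0.05), 0.051744, tolerance = 1e-4)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(correct_distance(p) >= p))
  expect_warning(d <- correct_distance(0.8), "saturated")
  expect_true(is.na(d))
})

test_that("a degenerate one-group partition gives zero radical sites", {
  code <- build_genetic_code()
  one_group <- stats::setNames(rep("ALL", 20),
                               sort(unique(code[code != "*"])))
  set.seed(14)
  a <- random_coding(50)
  b <- random_coding(50)
  # unrelated random sequences can saturate the corrected distance;
  # only the proportions matter here
  r <- suppressWarnings(pairwise_rates(a, b, code, grouping = one_group))
  expect_equal(r$NR, 0)
  expect_equal(r$nr_diff, 0)
  # d_within then reduces to a plain nonsynonymous rate: same pC as
  # counting all nonsynonymous changes over all nonsynonymous sites
  gc_based <- suppressWarnings(pairwise_rates(a, b, code))
  expect_equal(r$pC,
               (gc_based$nc_diff + gc_based$nr_diff) /
                 (gc_based$NC + gc_based$NR),
               tolerance = 1e-9)
})

test_that("pairwise rates are symmetric in their arguments", {
  set.seed(15)
  a <- random_coding(60, gc = 0.7)
  b <- random_coding(60, gc = 0.4)
  r1 <- suppressWarnings(pairwise_rates(a, b))
  r2 <- suppressWarnings(pairwise_rates(b, a))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(pairwise_rates(a, random_coding(10)), "length")
})

test_that("clade comparison reports means, SEMs and a paired test", {
  rts <- data.frame(ratio = c(0.7, 0.8, 0.75, 0.9),
                    d_within = c(0.2, 0.25, 0.22, 0.3),
                    d_between = c(0.14, 0.2, 0.165, 0.27))
  same <- clade_comparison(rts, rts)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # constant paired difference has zero variance: degenerate, untestable
  shifted <- rts
  shifted$ratio <- rts$ratio + 0.1
  deg <- clade_comparison(shifted, rts)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  # undefined ratios are dropped with a warning
  bad <- rts
  bad$ratio[2] <- NA
  expect_warning(cc <- clade_comparison(bad, rts), "dropped")
  expect_equal(cc$n_families, 3L)
})

test_that("a GC-shifted clade has the larger between/within ratio", {
  # branchwise mode: every tip of a clade against the true root, ratios
  # averaged per family within each clade, paired across families
  tree <- six_taxon_tree()
  cmap <- six_taxon_map()
  cfg <- sim_config(tree, cmap, kappa = 2,
                    theta = c(bang = 0.85, flor = 0.5), theta_root = 0.5,
                    n_sites = 300, n_families = 100, seed = 19)
  ds <- simulate_dataset(cfg)
  avg_rates <- function(tips) {
    do.call(rbind, Map(function(aln, anc) {
      rr <- do.call(rbind, lapply(tips, function(tp) {
        pairwise_rates(aln[[tp]], anc[["N1"]])
      }))
      as.data.frame(as.list(colMeans(rr)))
    }, ds$alignments, ds$true_ancestors))
  }
  cc <- clade_comparison(avg_rates(c("A", "B", "C")),
                         avg_rates(c("D", "E", "F")),
                         labels = c("bang", "flor"))
  expect_gt(cc$per_clade$mean_ratio[1], cc$per_clade$mean_ratio[2])
  expect_lt(cc$p_value, 0.05)
  # the drift toward GC also raises both absolute rates in the shifted
  # clade relative to the stationary one
  expect_gt(cc$per_clade$mean_d_between[1], cc$per_clade$mean_d_between[2])
})
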