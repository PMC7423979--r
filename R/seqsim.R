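# Synthetic-data generator: evolves in-frame codon alignments along a rooted
# tree under the clade-structured GC model, by exact per-site Gillespie
# simulation, recording true ancestral sequences and every substitution
# event. Planted ground truth is what lets the flux accounting, replacement
# rates and enrichment tests be validated end to end.

# stop codons as integer triplets over A=1,C=2,G=3,T=4
is_stop_int <- function(codon) {
  codon[1] == 4L &&
    ((codon[2] == 1L && (codon[3] == 1L || codon[3] == 3L)) ||
       (codon[2] == 3L && codon[3] == 1L))
}

#' Simulation configuration
#'
#' Bundles everything the alignment simulator needs. Model classes (e.g.
#' a GC-shifted "bangiales_like" clade versus a stationary
#' "florideophyte_like" clade) are assigned per branch through the clade
#' map; `kappa` and `theta` may be a single value recycled over classes
#' or one value per class.
#'
#' @param tree Rooted `phylo` with branch lengths (expected
#'   substitutions/site).
#' @param clade_map Named character vector: branch (child-node label) ->
#'   class.
#' @param kappa Transition/transversion ratio(s) > 0, scalar or named by
#'   class.
#' @param theta Equilibrium GC content(s) in (0,1), scalar or named by
#'   class.
#' @param theta_root Root GC content in (0,1).
#' @param n_sites Alignment length in codons (>= 1).
#' @param n_families Number of independent gene families.
#' @param seed Integer seed.
#' @param coding_mode If `TRUE` (default) stop codons are excluded: the
#'   root is stop-free and substitutions creating an in-frame stop are
#'   rejected and redrawn.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(tree, clade_map, kappa = 2, theta = 0.5,
                       theta_root = 0.5, n_sites = 100L, n_families = 1L,
                       seed = 1L, coding_mode = TRUE) {
  tree <- ensure_node_labels(tree)
  cmap <- validate_clade_map(tree, clade_map)
  classes <- sort(unique(unname(cmap)))
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(classes)), classes)
    }
    missing <- setdiff(classes, names(x))
    if (length(missing)) {
      stop(what, " missing for class(es): ", paste(missing, collapse = ", "))
    }
    x[classes]
  }
  kappa <- expand(kappa, "kappa")
  theta <- expand(theta, "theta")
  stopifnot(all(kappa > 0), all(theta > 0 & theta < 1),
            theta_root > 0, theta_root < 1, n_sites >= 1,
            all(tree$edge.length >= 0))
  structure(list(tree = tree, clade_map = cmap, kappa = kappa,
                 theta = theta, theta_root = theta_root,
                 n_sites = as.integer(n_sites),
                 n_families = as.integer(n_families),
                 seed = as.integer(seed), coding_mode = coding_mode),
            class = "sim_config")
}

#' Draw a root sequence from a GC-symmetric composition
#'
#' Sites are i.i.d. with P(G) = P(C) = `theta_root`/2 and P(A) = P(T) =
#' (1 - `theta_root`)/2. In coding mode codons that land on a stop are
#' resampled, so the returned sequence is stop-free in frame.
#'
#' @param theta_root Root GC content in (0,1); the degenerate endpoints 0
#'   and 1 are allowed for testing and give pure-AT / pure-GC sequences.
#' @param n_sites Length in codons.
#' @param seed Optional integer; when given, seeds the RNG for
#'   reproducibility.
#' @param coding_mode Exclude stop codons (default `TRUE`).
#' @return Uppercase DNA string of length `3 * n_sites`.
#' @export
sample_root_sequence <- function(theta_root, n_sites, seed = NULL,
                                 coding_mode = TRUE) {
  if (!is.finite(theta_root) || theta_root < 0 || theta_root > 1) {
    stop("theta_root must be in [0,1]")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - theta_root) / 2, theta_root / 2, theta_root / 2,
         (1 - theta_root) / 2)
  draw <- function(n) sample.int(4L, 3L * n, replace = TRUE, prob = p)
  states <- draw(n_sites)
  if (coding_mode) {
    m <- matrix(states, nrow = 3L)
    bad <- which(apply(m, 2, is_stop_int))
    while (length(bad)) {
      m[, bad] <- draw(length(bad))[seq_len(3L * length(bad))]
      bad <- bad[apply(m[, bad, drop = FALSE], 2, is_stop_int)]
    }
    states <- as.vector(m)
  }
  decode_sequence(states)
}

#' Evolve a sequence along one branch by exact Gillespie simulation
#'
#' Each site evolves under the class's T92-style rate matrix; waiting
#' times are exponential in the total leave rate and every realised
#' substitution is recorded in order, so multiple hits at a site are
#' visible in the event log even though they collapse at the endpoints.
#' In coding mode an event that would create an in-frame stop codon is
#' rejected and the event redrawn.
#'
#' @param seq Uppercase DNA string (in frame if `coding_mode`).
#' @param kappa,theta Model-class parameters.
#' @param t Branch length >= 0 (expected substitutions/site).
#' @param coding_mode Reject stop-creating substitutions.
#' @return List with `seq` (child sequence) and `events` (data frame
#'   `site`, `from`, `to`, `time`; 1-based sites, times in branch units).
#' @export
evolve_branch <- function(seq, kappa, theta, t, coding_mode = TRUE) {
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  states <- match(strsplit(toupper(seq), "")[[1]], NUC)
  if (anyNA(states)) stop("sequence contains non-ACGT characters")
  n <- length(states)
  if (coding_mode && n %% 3L != 0L) {
    stop("coding_mode requires length divisible by 3")
  }
  Q <- rate_matrix(kappa, theta)
  leave <- -diag(Q)
  jump <- Q
  diag(jump) <- 0
  jump <- jump / rowSums(jump)

  ev_site <- integer(0); ev_from <- integer(0)
  ev_to <- integer(0); ev_time <- numeric(0)
  if (t > 0 && n > 0) {
    w <- leave[states]
    total <- sum(w)
    now <- 0
    cap <- 256L
    ev_site <- integer(cap); ev_from <- integer(cap)
    ev_to <- integer(cap); ev_time <- numeric(cap)
    k <- 0L
    repeat {
      now <- now + stats::rexp(1L, total)
      if (now > t) break
      repeat {
        site <- sample.int(n, 1L, prob = w)
        from <- states[site]
        to <- sample.int(4L, 1L, prob = jump[from, ])
        if (!coding_mode) break
        ci <- (site - 1L) %/% 3L
        codon <- states[(ci * 3L + 1L):(ci * 3L + 3L)]
        codon[(site - 1L) %% 3L + 1L] <- to
        if (!is_stop_int(codon)) break
      }
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(ev_site) <- cap; length(ev_from) <- cap
        length(ev_to) <- cap; length(ev_time) <- cap
      }
      ev_site[k] <- site; ev_from[k] <- from
      ev_to[k] <- to; ev_time[k] <- now
      states[site] <- to
      total <- total - w[site]
      w[site] <- leave[to]
      total <- total + w[site]
    }
    ev_site <- ev_site[seq_len(k)]; ev_from <- ev_from[seq_len(k)]
    ev_to <- ev_to[seq_len(k)]; ev_time <- ev_time[seq_len(k)]
  }
  list(seq = decode_sequence(states),
       events = data.frame(site = ev_site, from = NUC[ev_from],
                           to = NUC[ev_to], time = ev_time,
                           stringsAsFactors = FALSE))
}

#' Simulate a multi-family dataset with known ancestors and events
#'
#' For each family, draws a root sequence from the root composition and
#' evolves it down every branch under that branch's class parameters.
#' Tip alignments, all true ancestral sequences and the full per-branch
#' event log are returned; replaying the event log from the root
#' reproduces every tip exactly.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: `alignments` (per family, named
#'   character vector over tips), `true_ancestors` (per family, named
#'   character vector over internal nodes), `event_log` (per family, data
#'   frame with `branch` = child-node label, `site`, `from`, `to`,
#'   `time`), `tree`, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  pre_idx <- match(paste(pre$edge[, 1], pre$edge[, 2]), key)

  alignments <- vector("list", config$n_families)
  ancestors <- vector("list", config$n_families)
  event_log <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    seqs <- character(ntip + tree$Nnode)
    seqs[root_node(tree)] <- sample_root_sequence(
      config$theta_root, config$n_sites, seed = NULL,
      coding_mode = config$coding_mode)
    evs <- vector("list", nrow(tree$edge))
    for (k in seq_len(nrow(pre$edge))) {
      parent <- pre$edge[k, 1]
      child <- pre$edge[k, 2]
      e <- pre_idx[k]
      cl <- config$clade_map[[e]]
      res <- evolve_branch(seqs[parent], config$kappa[[cl]],
                           config$theta[[cl]], tree$edge.length[e],
                           coding_mode = config$coding_mode)
      seqs[child] <- res$seq
      if (nrow(res$events)) {
        res$events$branch <- labs[child]
        evs[[e]] <- res$events[, c("branch", "site", "from", "to", "time")]
      }
    }
    names(seqs) <- labs
    alignments[[f]] <- seqs[seq_len(ntip)]
    ancestors[[f]] <- seqs[(ntip + 1L):(ntip + tree$Nnode)]
    ev <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
    if (is.null(ev)) {
      ev <- data.frame(branch = character(0), site = integer(0),
                       from = character(0), to = character(0),
                       time = numeric(0))
    }
    event_log[[f]] <- ev
  }
  names(alignments) <- names(ancestors) <- names(event_log) <-
    paste0("fam", seq_len(config$n_families))
  structure(list(alignments = alignments, true_ancestors = ancestors,
                 event_log = event_log, tree = tree, config = config),
            class = "sim_dataset")
}

#' Replay an event log from the root to recover all node sequences
#'
#' Walks every branch in preorder applying that branch's logged events in
#' time order. Used to verify the simulator's internal consistency: the
#' replayed tips must equal the simulated tips byte for byte.
#'
#' @param dataset A `sim_dataset`.
#' @param family Family name or index.
#' @return Named character vector of sequences for every node.
#' @export
replay_events <- function(dataset, family = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  tree <- dataset$tree
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  log <- dataset$event_log[[family]]
  root_lab <- labs[root_node(tree)]
  seqs <- character(ntip + tree$Nnode)
  names(seqs) <- labs
  seqs[root_lab] <- dataset$true_ancestors[[family]][[root_lab]]
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- labs[pre$edge[k, 1]]
    child <- labs[pre$edge[k, 2]]
    states <- match(strsplit(seqs[[parent]], "")[[1]], NUC)
    ev <- log[log$branch == child, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        states[ev$site[i]] <- match(ev$to[i], NUC)
      }
    }
    seqs[child] <- decode_sequence(states)
  }
  seqs
}

#' Simulate an FPKM table with planted phase-specific genes
#'
#' Plants four gene classes whose mean FPKM values satisfy the
#' phase-classification rules by construction: gametophyte-specific
#' (gam > 25, spo < 5), sporophyte-specific (mirror image), constitutive
#' (both > 5, fold change < 10) and low-expression background (both < 5).
#' Each gene also gets a dehydration/rehydration condition series derived
#' from its control level; gametophyte-specific genes are up-regulated by
#' the multipliers in `dehydration_profile`, emulating the burst of
#' stress-responsive transcription in the desiccating thallus.
#'
#' @param n_genes Total genes.
#' @param phase_fractions Numeric length 3: fractions of gam-specific,
#'   spo-specific and constitutive genes (sum <= 1; the remainder is
#'   low-expression background).
#' @param dehydration_profile Named multipliers for the stress series of
#'   gam-specific genes; default `c(wl20 = 2, wl50 = 4, wl80 = 8,
#'   re80 = 4, re50 = 1)`.
#' @param seed Integer seed.
#' @param noise_sd Log-normal noise sd on the condition series (default
#'   0.05).
#' @return Data frame of class `expression_table`: `gene`, `truth`,
#'   `fpkm_gam`, `fpkm_spo`, and condition columns `ctrl`, `wl20`,
#'   `wl50`, `wl80`, `re80`, `re50`.
#' @export
simulate_expression_table <- function(n_genes,
                                      phase_fractions = c(0.1, 0.1, 0.6),
                                      dehydration_profile = c(wl20 = 2,
                                                              wl50 = 4,
                                                              wl80 = 8,
                                                              re80 = 4,
                                                              re50 = 1),
                                      seed = 1L, noise_sd = 0.05) {
  stopifnot(length(phase_fractions) == 3L, all(phase_fractions >= 0),
            sum(phase_fractions) <= 1, n_genes >= 1)
  set.seed(seed)
  n_gam <- round(phase_fractions[1] * n_genes)
  n_spo <- round(phase_fractions[2] * n_genes)
  n_con <- round(phase_fractions[3] * n_genes)
  n_low <- n_genes - n_gam - n_spo - n_con
  truth <- rep(c("GAM_SPECIFIC", "SPO_SPECIFIC", "CONSTITUTIVE", "OTHER"),
               c(n_gam, n_spo, n_con, n_low))

  hi <- function(n) stats::runif(n, 26, 200)     # clears the > 25 threshold
  lo <- function(n) stats::runif(n, 0, 4.9)      # stays under 5
  gam <- numeric(n_genes)
  spo <- numeric(n_genes)
  gam[truth == "GAM_SPECIFIC"] <- hi(n_gam)
  spo[truth == "GAM_SPECIFIC"] <- lo(n_gam)
  gam[truth == "SPO_SPECIFIC"] <- lo(n_spo)
  spo[truth == "SPO_SPECIFIC"] <- hi(n_spo)
  base <- stats::runif(n_con, 15, 100)
  gam[truth == "CONSTITUTIVE"] <- base
  spo[truth == "CONSTITUTIVE"] <- base * stats::runif(n_con, 0.5, 2)
  gam[truth == "OTHER"] <- lo(n_low)
  spo[truth == "OTHER"] <- lo(n_low)

  conds <- c("ctrl", names(dehydration_profile))
  series <- matrix(0, n_genes, length(conds),
                   dimnames = list(NULL, conds))
  series[, "ctrl"] <- gam
  for (cn in names(dehydration_profile)) {
    m <- ifelse(truth == "GAM_SPECIFIC", dehydration_profile[[cn]], 1)
    series[, cn] <- gam * m *
      exp(stats::rnorm(n_genes, 0, noise_sd))
  }
  out <- data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
                    truth = truth, fpkm_gam = gam, fpkm_spo = spo,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(series))
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Simulate paired codon-usage families for two clades
#'
#' Each family gets one i.i.d. codon sequence per clade drawn from that
#' clade's sense-codon frequency vector — the minimal paired design for
#' validating codon-enrichment and carbon-usage tests against planted
#' shifts.
#'
#' @param n_families Number of paired families.
#' @param n_codons Codons per sequence.
#' @param freq_a,freq_b Numeric length-61 relative frequencies over
#'   [sense_codons()] (normalised internally).
#' @param seed Integer seed.
#' @return List with `clade_a` and `clade_b`: named lists of DNA strings.
#' @export
simulate_codon_usage_families <- function(n_families, n_codons,
                                          freq_a, freq_b, seed = 1L) {
  codons <- sense_codons()
  stopifnot(length(freq_a) == 61L, length(freq_b) == 61L,
            all(freq_a >= 0), all(freq_b >= 0))
  set.seed(seed)
  draw <- function(freq) {
    paste(sample(codons, n_codons, replace = TRUE, prob = freq),
          collapse = "")
  }
  a <- replicate(n_families, draw(freq_a))
  b <- replicate(n_families, draw(freq_b))
  names(a) <- names(b) <- paste0("fam", seq_len(n_families))
  list(clade_a = as.list(a), clade_b = as.list(b))
}
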