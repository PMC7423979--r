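# Shared fixtures: small trees, clade maps, and independent brute-force
# oracles used to validate the fast implementations.

balanced4_tree <- function() {
  ape::read.tree(text = "((A:0.2,B:0.2)N2:0.1,(C:0.2,D:0.2)N3:0.1)N1;")
}

balanced4_map <- function(class_a = "x", class_b = "y") {
  c(A = class_a, B = class_a, N2 = class_a,
    C = class_b, D = class_b, N3 = class_b)
}

# 6-taxon tree with two 3-tip clades hanging off the root
six_taxon_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.2,B:0.2)N2:0.2,C:0.4)N4:0.1,",
    "((D:0.2,E:0.2)N3:0.2,F:0.4)N5:0.1)N1;"))
}

six_taxon_map <- function() {
  c(A = "bang", B = "bang", N2 = "bang", C = "bang", N4 = "bang",
    D = "flor", E = "flor", N3 = "flor", F = "flor", N5 = "flor")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# random stop-free in-frame sequence of n codons
random_coding <- function(n_codons, gc = 0.5) {
  sample_root_sequence(gc, n_codons, coding_mode = TRUE)
}

## ---- brute-force likelihood oracle -------------------------------------
# Sum over all internal-node state assignments of
# pi_root(x_root) * prod_edges P_edge(x_parent -> x_child); per site.
enumeration_loglik <- function(alignment, tree, model) {
  tree <- ensure_node_labels(tree)
  labs <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  cmap <- validate_clade_map(tree, model$clade_map)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probs(model$kappa, model$theta[[cmap[[e]]]],
                     tree$edge.length[e])
  })
  pi0 <- c((1 - model$theta_root) / 2, model$theta_root / 2,
           model$theta_root / 2, (1 - model$theta_root) / 2)
  seqs <- lapply(alignment[tree$tip.label], function(s) {
    match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  })
  S <- length(seqs[[1]])
  root <- ntip + 1L
  total <- 0
  for (s in seq_len(S)) {
    states <- integer(ntip + nnode)
    for (i in seq_len(ntip)) states[i] <- seqs[[i]][s]
    grid <- expand.grid(rep(list(1:4), nnode))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      states[(ntip + 1L):(ntip + nnode)] <- as.integer(grid[g, ])
      term <- pi0[states[root]]
      for (e in seq_len(nrow(tree$edge))) {
        term <- term * Ps[[e]][states[tree$edge[e, 1]],
                               states[tree$edge[e, 2]]]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# marginal posterior of one internal node at one site, by enumeration
enumeration_posterior <- function(alignment, tree, model, node_label,
                                  site) {
  tree <- ensure_node_labels(tree)
  labs <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  v <- match(node_label, labs)
  cmap <- validate_clade_map(tree, model$clade_map)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probs(model$kappa, model$theta[[cmap[[e]]]],
                     tree$edge.length[e])
  })
  pi0 <- c((1 - model$theta_root) / 2, model$theta_root / 2,
           model$theta_root / 2, (1 - model$theta_root) / 2)
  tip_states <- vapply(alignment[tree$tip.label], function(s) {
    match(substr(s, site, site), c("A", "C", "G", "T"))
  }, integer(1))
  states <- integer(ntip + nnode)
  states[seq_len(ntip)] <- tip_states
  grid <- expand.grid(rep(list(1:4), nnode))
  mass <- numeric(4)
  for (g in seq_len(nrow(grid))) {
    states[(ntip + 1L):(ntip + nnode)] <- as.integer(grid[g, ])
    term <- pi0[states[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      term <- term * Ps[[e]][states[tree$edge[e, 1]],
                             states[tree$edge[e, 2]]]
    }
    mass[states[v]] <- mass[states[v]] + term
  }
  mass / sum(mass)
}

## ---- pathway-counting oracle -------------------------------------------
# Expected (conservative, radical, synonymous) step counts between two
# codons: explicit enumeration over orderings via expand.grid of ranks,
# deliberately structured differently from the package implementation.
oracle_count_differences <- function(codon_a, codon_b, code, grouping) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(nc = 0, nr = 0, ns = 0))
  orderings <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1)), function(i) pos[i]))
  step_class <- function(c1, c2) {
    a1 <- code[[c1]]; a2 <- code[[c2]]
    if (a1 == a2) return("ns")
    if (grouping[[a1]] == grouping[[a2]]) "nc" else "nr"
  }
  legal <- list(); all_counts <- list()
  for (ord in orderings) {
    cur <- a
    ok <- TRUE
    cnt <- c(nc = 0, nr = 0, ns = 0)
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (code[[c1]] == "*" || code[[c2]] == "*") {
        ok <- FALSE
      } else {
        cl <- step_class(c1, c2)
        cnt[cl] <- cnt[cl] + 1
      }
      cur <- nxt
    }
    if (ok) legal[[length(legal) + 1]] <- cnt
    all_counts[[length(all_counts) + 1]] <- cnt
  }
  use <- if (length(legal)) legal else all_counts
  Reduce(`+`, use) / length(use)
}

## ---- Fitch oracle -------------------------------------------------------
# minimum number of changes over all internal labelings (per site, summed)
oracle_parsimony_score <- function(alignment, tree) {
  tree <- ensure_node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- lapply(alignment[tree$tip.label], function(s) {
    match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  })
  S <- length(seqs[[1]])
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  for (s in seq_len(S)) {
    states <- integer(ntip + nnode)
    for (i in seq_len(ntip)) states[i] <- seqs[[i]][s]
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      states[(ntip + 1L):(ntip + nnode)] <- grid[g, ]
      ch <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
      if (ch < best) best <- ch
    }
    total <- total + best
  }
  total
}

# random rooted binary tree with n tips, labelled, random branch lengths
random_labelled_tree <- function(n_tips, max_bl = 0.5) {
  tree <- ape::rtree(n_tips, rooted = TRUE,
                     tip.label = LETTERS[seq_len(n_tips)])
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.01, max_bl)
  tree$node.label <- NULL
  ensure_node_labels(tree)
}

random_alignment <- function(tree, n_sites, gc = 0.5) {
  stats::setNames(
    vapply(tree$tip.label, function(i) random_dna(n_sites, gc),
           character(1)),
    tree$tip.label)
}

uniform_clade_map <- function(tree, class = "x") {
  tree <- ensure_node_labels(tree)
  labs <- c(tree$tip.label, tree$node.label)
  children <- labs[tree$edge[, 2]]
  stats::setNames(rep(class, length(children)), children)
}
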