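# Non-stationary nucleotide substitution model: a T92-style generator with
# a single equilibrium-GC parameter theta per branch class and a global
# transition/transversion ratio kappa. Likelihood is computed by Felsenstein
# pruning with per-branch transition matrices; ancestral states by the
# marginal (up-down) recursion; Fitch parsimony serves as a model-free
# cross-check.

#' Construct a clade-structured substitution model
#'
#' The model is Tamura's two-parameter process generalised to a
#' non-stationary setting: one global transition/transversion ratio
#' `kappa`, and one equilibrium GC content `theta` per branch class, so
#' that different clades can be pulled toward different GC levels. The
#' root composition is GC-symmetric with GC fraction `theta_root`.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param theta Named numeric vector of equilibrium GC contents in (0,1),
#'   one per model class.
#' @param theta_root Root GC content in (0,1).
#' @param clade_map Named character vector: branch (child-node label) ->
#'   class; every class used must appear in `names(theta)`.
#' @return Object of class `gc_model`.
#' @export
gc_model <- function(kappa, theta, theta_root, clade_map) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  stopifnot(is.numeric(theta), !is.null(names(theta)),
            all(theta > 0 & theta < 1))
  stopifnot(theta_root > 0, theta_root < 1)
  unknown <- setdiff(unique(clade_map), names(theta))
  if (length(unknown)) {
    stop("clade map uses classes without a theta: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(kappa = kappa, theta = theta, theta_root = theta_root,
                 clade_map = clade_map),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("Non-stationary GC substitution model (T92-style)\n")
  cat("  kappa      :", format(x$kappa, digits = 4), "\n")
  for (cl in names(x$theta)) {
    cat(sprintf("  theta[%s] : %s\n", cl, format(x$theta[[cl]], digits = 4)))
  }
  cat("  theta_root :", format(x$theta_root, digits = 4), "\n")
  invisible(x)
}

# GC-symmetric base frequencies for a given GC content
theta_freqs <- function(theta) {
  stats::setNames(c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2),
                  NUC)
}

#' Instantaneous rate matrix of the T92-style process
#'
#' Rate of change i -> j is proportional to `kappa * pi_j` for transitions
#' (A<->G, C<->T) and `pi_j` for transversions, with `pi` the
#' GC-symmetric frequencies of `theta`. The matrix is scaled so that the
#' expected substitution rate at stationarity is one per site per unit
#' branch length.
#'
#' @param kappa Transition/transversion ratio, > 0.
#' @param theta Equilibrium GC content in (0,1).
#' @return 4x4 matrix over A,C,G,T with zero row sums.
#' @export
rate_matrix <- function(kappa, theta) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.finite(theta) || theta <= 0 || theta >= 1) {
    stop("theta must be in (0,1)")
  }
  pi <- theta_freqs(theta)
  Q <- matrix(rep(pi, each = 4L), 4L, 4L, dimnames = list(NUC, NUC))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  Q[transitions] <- kappa * Q[transitions]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))   # expected rate at stationarity
  Q / mu
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by spectral decomposition of the reversible generator
#' (symmetrised by the stationary frequencies), so large t is exact and
#' cheap.
#'
#' @inheritParams rate_matrix
#' @param t Branch length (expected substitutions per site), >= 0.
#' @return 4x4 stochastic matrix over A,C,G,T.
#' @export
transition_probs <- function(kappa, theta, t) {
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  Q <- rate_matrix(kappa, theta)
  if (t == 0) {
    P0 <- diag(4L)
    dimnames(P0) <- list(NUC, NUC)
    return(P0)
  }
  pi <- theta_freqs(theta)
  s <- sqrt(pi)
  B <- (s %o% (1 / s)) * Q          # similarity transform; symmetric
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- (1 / s) %o% s *
    (eig$vectors %*% (exp(eig$values * t) * t(eig$vectors)))
  P[P < 0] <- 0                      # clamp roundoff
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}

# Per-edge transition matrices for a model on a labelled tree.
# Returns a list indexed by edge row of tree$edge.
edge_matrices <- function(tree, model) {
  cmap <- validate_clade_map(tree, model$clade_map)
  bl <- tree$edge.length
  if (is.null(bl)) stop("tree has no branch lengths")
  lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probs(model$kappa, model$theta[[cmap[e]]], bl[e])
  })
}

# Up (pruning) pass. Returns list(partials = list of 4 x S matrices per
# node index, logscale = per-node numeric vector length S, edge_msg =
# per-edge 4 x S message P_e %*% partial(child), tree = postordered info).
pruning_pass <- function(tipstates, tree, model) {
  tree <- ensure_node_labels(tree)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- ncol(tipstates)
  miss <- setdiff(tree$tip.label, rownames(tipstates))
  if (length(miss)) {
    stop("alignment is missing tree tips: ", paste(miss, collapse = ", "))
  }
  Ps <- edge_matrices(tree, model)
  po <- ape::reorder.phylo(tree, "postorder")
  # map postordered edges back to original edge rows for P lookup
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_idx <- match(paste(po$edge[, 1], po$edge[, 2]), key)

  partials <- vector("list", ntip + nnode)
  logscale <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    st <- tipstates[tree$tip.label[i], ]
    Lp <- matrix(0, 4L, S)
    known <- !is.na(st)
    Lp[cbind(st[known], which(known))] <- 1
    Lp[, !known] <- 1                # missing data: flat partial
    partials[[i]] <- Lp
    logscale[[i]] <- numeric(S)
  }
  edge_msg <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    e <- po_idx[k]
    msg <- Ps[[e]] %*% partials[[child]]
    edge_msg[[e]] <- msg
    if (is.null(partials[[parent]])) {
      partials[[parent]] <- msg
      logscale[[parent]] <- logscale[[child]]
    } else {
      partials[[parent]] <- partials[[parent]] * msg
      logscale[[parent]] <- logscale[[parent]] + logscale[[child]]
    }
    # rescale to guard against underflow on deep trees
    mx <- apply(partials[[parent]], 2, max)
    mx[mx == 0] <- 1
    partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
    logscale[[parent]] <- logscale[[parent]] + log(mx)
  }
  list(partials = partials, logscale = logscale, edge_msg = edge_msg,
       tree = tree, labs = labs, ntip = ntip, S = S, Ps = Ps)
}

#' Log-likelihood of alignment(s) on a tree under a clade-structured model
#'
#' Felsenstein pruning with each branch using the transition matrix of its
#' class; the root state is weighted by the GC-symmetric composition of
#' `theta_root`. Sites are independent; gaps and ambiguity codes are
#' missing data. A list of alignments (gene families) is summed.
#'
#' @param alignment Named character vector of equal-length sequences
#'   covering the tree's tips, or a list of such vectors.
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A [gc_model()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(alignment, tree, model) {
  if (is.list(alignment) && !is.character(alignment)) {
    return(sum(vapply(alignment, log_likelihood, numeric(1),
                      tree = tree, model = model)))
  }
  up <- pruning_pass(encode_sequences(alignment), tree, model)
  root <- root_node(up$tree)
  pi0 <- theta_freqs(model$theta_root)
  site_lik <- colSums(pi0 * up$partials[[root]])
  sum(log(site_lik) + up$logscale[[root]])
}

# Collapse a list of encoded alignments into unique site patterns with
# weights (the tree is shared, so patterns pool across families).
pattern_data <- function(enc_list, tip_labels) {
  cols <- lapply(enc_list, function(m) {
    m <- m[tip_labels, , drop = FALSE]
    m
  })
  big <- do.call(cbind, cols)
  key <- apply(big, 2, paste, collapse = ",")
  idx <- !duplicated(key)
  pats <- big[, idx, drop = FALSE]
  w <- as.numeric(table(key)[key[idx]])
  list(patterns = pats, weights = w)
}

# Precomputed traversal for repeated likelihood evaluations.
traversal_info <- function(tree, clade_map) {
  tree <- ensure_node_labels(tree)
  cmap <- validate_clade_map(tree, clade_map)
  po <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_idx <- match(paste(po$edge[, 1], po$edge[, 2]), key)
  list(tree = tree, cmap = cmap, po_parent = po$edge[, 1],
       po_child = po$edge[, 2], po_edge = po_idx,
       lengths = tree$edge.length, ntip = length(tree$tip.label))
}

# Weighted-pattern pruning likelihood; kappa scalar, theta named by class.
pattern_loglik <- function(pat, info, kappa, theta, theta_root) {
  S <- ncol(pat$patterns)
  ntip <- info$ntip
  Ps <- lapply(seq_along(info$lengths), function(e) {
    transition_probs(kappa, theta[[info$cmap[[e]]]], info$lengths[e])
  })
  partials <- vector("list", ntip + info$tree$Nnode)
  logscale <- vector("list", ntip + info$tree$Nnode)
  for (i in seq_len(ntip)) {
    st <- pat$patterns[i, ]
    Lp <- matrix(0, 4L, S)
    known <- !is.na(st)
    Lp[cbind(st[known], which(known))] <- 1
    Lp[, !known] <- 1
    partials[[i]] <- Lp
    logscale[[i]] <- numeric(S)
  }
  for (k in seq_along(info$po_edge)) {
    parent <- info$po_parent[k]
    child <- info$po_child[k]
    msg <- Ps[[info$po_edge[k]]] %*% partials[[child]]
    if (is.null(partials[[parent]])) {
      partials[[parent]] <- msg
      logscale[[parent]] <- logscale[[child]]
    } else {
      partials[[parent]] <- partials[[parent]] * msg
      logscale[[parent]] <- logscale[[parent]] + logscale[[child]]
      mx <- apply(partials[[parent]], 2, max)
      mx[mx == 0] <- 1
      partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
      logscale[[parent]] <- logscale[[parent]] + log(mx)
    }
  }
  root <- ntip + 1L
  pi0 <- theta_freqs(theta_root)
  site <- log(colSums(pi0 * partials[[root]])) + logscale[[root]]
  sum(pat$weights * site)
}

#' Fit the clade-structured model by maximum likelihood
#'
#' Maximises [log_likelihood()] over `kappa`, one `theta` per class, and
#' `theta_root`, with the tree topology and branch lengths held fixed.
#' Optimisation runs on an unconstrained scale (log kappa, logit theta)
#' from several start points: a neutral start, a start seeded by the
#' observed tip GC of each class, and optionally random jitters.
#'
#' @param alignments Named character vector or list of such (families).
#' @param tree Rooted `phylo` with branch lengths.
#' @param clade_map Named character vector branch -> class.
#' @param n_starts Number of additional randomised starts (default 2).
#' @param seed Integer seed for the randomised starts.
#' @return A `gc_model_fit`: the fitted [gc_model()] plus a report with
#'   the final log-likelihood, convergence codes and all start points.
#' @export
fit_model <- function(alignments, tree, clade_map, n_starts = 2L,
                      seed = 1L) {
  tree <- ensure_node_labels(tree)
  cmap <- validate_clade_map(tree, clade_map)
  classes <- sort(unique(unname(cmap)))
  fams <- if (is.list(alignments) && !is.character(alignments)) {
    alignments
  } else {
    list(alignments)
  }
  enc <- lapply(fams, encode_sequences)

  # observed GC of the tips under each class, as an informed start
  labs <- node_labels(tree)
  tip_class <- cmap[labs[tree$edge[, 2]][tree$edge[, 2] <=
                                           length(tree$tip.label)]]
  names(tip_class) <- labs[tree$edge[, 2]][tree$edge[, 2] <=
                                             length(tree$tip.label)]
  obs_gc <- vapply(classes, function(cl) {
    tips <- names(tip_class)[tip_class == cl]
    if (!length(tips)) return(0.5)
    vals <- unlist(lapply(fams, function(f) {
      s <- f[intersect(tips, names(f))]
      ch <- unlist(strsplit(toupper(s), ""), use.names = FALSE)
      mean(ch %in% c("G", "C"))
    }))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  obs_gc <- pmin(pmax(obs_gc, 0.05), 0.95)

  info <- traversal_info(tree, cmap)
  pat <- pattern_data(enc, tree$tip.label)

  npar <- 2L + length(classes)       # log kappa, logit thetas, logit root
  unpack <- function(par) {
    par <- pmin(pmax(par, -12), 12)  # keep kappa/theta in sane range
    list(kappa = exp(par[1]),
         theta = stats::setNames(
           stats::plogis(par[2:(1 + length(classes))]), classes),
         theta_root = stats::plogis(par[npar]))
  }
  negll <- function(par) {
    p <- unpack(par)
    ll <- tryCatch(
      pattern_loglik(pat, info, p$kappa, p$theta, p$theta_root),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  starts <- list(
    c(log(2), rep(stats::qlogis(0.5), length(classes)), stats::qlogis(0.5)),
    c(log(2), stats::qlogis(obs_gc), stats::qlogis(mean(obs_gc)))
  )
  if (n_starts > 0) {
    set.seed(seed)
    for (i in seq_len(n_starts)) {
      starts[[length(starts) + 1L]] <-
        starts[[2]] + stats::rnorm(npar, 0, 0.5)
    }
  }
  fits <- lapply(starts, function(p0) {
    stats::optim(p0, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- unpack(best$par)
  model <- gc_model(p$kappa, p$theta, p$theta_root, cmap)
  report <- list(
    logLik = -best$value,
    convergence = best$convergence,
    converged = best$convergence == 0L,
    n_starts = length(starts),
    start_logLik = -vapply(fits, `[[`, numeric(1), "value"),
    n_families = length(enc)
  )
  structure(list(model = model, report = report), class = "gc_model_fit")
}

#' @export
print.gc_model_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  logLik %.3f over %d families; converged: %s\n",
              x$report$logLik, x$report$n_families,
              x$report$converged))
  invisible(x)
}

#' Marginal ancestral state reconstruction
#'
#' For every internal node and site, the posterior probability of each
#' nucleotide given all tips, computed by the up-down recursion
#' (pruning partials combined with the likelihood of the data outside the
#' node's subtree). The reconstructed sequence takes the posterior mode;
#' ties break alphabetically A < C < G < T.
#'
#' @param alignment Named character vector of tip sequences.
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A [gc_model()] (fitted or supplied).
#' @return Object of class `ancestral_reconstruction`: `node_sequences`
#'   (named character vector over internal-node labels), `posteriors`
#'   (list of S x 4 matrices), and `method_tag = "marginal_ML"`.
#' @export
reconstruct_marginal <- function(alignment, tree, model) {
  up <- pruning_pass(encode_sequences(alignment), tree, model)
  tree <- up$tree
  ntip <- up$ntip
  S <- up$S
  nn <- ntip + tree$Nnode
  root <- root_node(tree)
  pi0 <- theta_freqs(model$theta_root)

  # children/edge lookup
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  outside <- vector("list", nn)
  outside[[root]] <- matrix(pi0, 4L, S)
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]
    child <- pre$edge[k, 2]
    e_rows <- kids[[as.character(parent)]]
    e <- e_rows[tree$edge[e_rows, 2] == child]
    sib_rows <- setdiff(e_rows, e)
    acc <- outside[[parent]]
    for (se in sib_rows) acc <- acc * up$edge_msg[[se]]
    o <- crossprod(up$Ps[[e]], acc)          # t(P) %*% acc
    cs <- colSums(o)
    cs[cs == 0] <- 1
    outside[[child]] <- sweep(o, 2, cs, "/") # rescale per site
  }

  internal <- (ntip + 1L):nn
  posteriors <- list()
  node_sequences <- character(0)
  for (v in internal) {
    post <- up$partials[[v]] * outside[[v]]
    post <- sweep(post, 2, colSums(post), "/")
    states <- apply(post, 2, which.max)      # first max = alphabetical tie
    lab <- node_labels(tree)[v]
    pm <- t(post)
    colnames(pm) <- NUC
    posteriors[[lab]] <- pm
    node_sequences[lab] <- decode_sequence(states)
  }
  structure(list(node_sequences = node_sequences, posteriors = posteriors,
                 method_tag = "marginal_ML", tree = tree),
            class = "ancestral_reconstruction")
}

#' Fitch parsimony reconstruction and score
#'
#' Classic two-pass Fitch on a rooted binary tree: the up pass builds
#' candidate state sets and counts the changes, the down pass resolves
#' each node to its parent's state when allowed, otherwise to the
#' alphabetically first candidate. A cheap model-free cross-check on the
#' ML reconstruction.
#'
#' @param alignment Named character vector of tip sequences.
#' @param tree Rooted `phylo`.
#' @return `ancestral_reconstruction` with `method_tag = "fitch"` and a
#'   `score` element (minimum number of changes over the tree).
#' @export
fitch_parsimony <- function(alignment, tree) {
  tree <- ensure_node_labels(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ts <- encode_sequences(alignment)
  miss <- setdiff(tree$tip.label, rownames(ts))
  if (length(miss)) {
    stop("alignment is missing tree tips: ", paste(miss, collapse = ", "))
  }
  S <- ncol(ts)
  # state sets as logical 4 x S matrices
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) {
    st <- ts[tree$tip.label[i], ]
    m <- matrix(FALSE, 4L, S)
    known <- !is.na(st)
    m[cbind(st[known], which(known))] <- TRUE
    m[, !known] <- TRUE
    sets[[i]] <- m
  }
  score <- numeric(S)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- sets[[parent]] & sets[[child]]
      empty <- colSums(inter) == 0
      score <- score + empty
      uni <- sets[[parent]] | sets[[child]]
      inter[, empty] <- uni[, empty]
      sets[[parent]] <- inter
    }
  }
  # down pass
  chosen <- matrix(NA_integer_, nn, S)
  root <- root_node(tree)
  chosen[root, ] <- apply(sets[[root]], 2, which.max)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]
    child <- pre$edge[k, 2]
    p_state <- chosen[parent, ]
    in_set <- sets[[child]][cbind(p_state, seq_len(S))]
    pick <- apply(sets[[child]], 2, which.max)
    pick[in_set] <- p_state[in_set]
    chosen[child, ] <- pick
  }
  labs <- node_labels(tree)
  internal <- (ntip + 1L):nn
  node_sequences <- stats::setNames(
    vapply(internal, function(v) decode_sequence(chosen[v, ]), character(1)),
    labs[internal])
  structure(list(node_sequences = node_sequences, posteriors = NULL,
                 method_tag = "fitch", score = sum(score), tree = tree),
            class = "ancestral_reconstruction")
}
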