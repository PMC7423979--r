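# Directional substitution accounting: along each branch, compare parent
# and child sequences and classify every mismatching site as A/T -> G/C,
# G/C -> A/T, within-A/T or within-G/C, overall and restricted to third
# codon positions; then aggregate over the branches of each clade. A
# GC-shifted clade shows an excess of A/T -> G/C changes.

WEAK <- c("A", "T")    # A/T ("weak" pairing)
STRONG <- c("G", "C")  # G/C ("strong" pairing)

#' Directional substitution counts along one branch
#'
#' Every site where parent and child states differ (both unambiguous) is
#' classified into exactly one of four categories by A/T vs G/C
#' membership of the two states. Counts are reported for all sites and
#' for third codon positions; sites with a gap or ambiguity in either
#' sequence are skipped and tallied separately.
#'
#' @param parent_seq,child_seq Equal-length uppercase DNA strings.
#' @param frame_offset 0-based offset of codon position 1 (default 0).
#' @return One-row data frame: `n_AT_to_GC`, `n_GC_to_AT`, `n_within_AT`,
#'   `n_within_GC`, the same four with suffix `_pos3`, and `n_skipped`.
#' @examples
#' branch_flux("GAA", "GAG")  # one A->G change at codon position 3
#' @export
branch_flux <- function(parent_seq, child_seq, frame_offset = 0L) {
  p <- strsplit(toupper(parent_seq), "")[[1]]
  c_ <- strsplit(toupper(child_seq), "")[[1]]
  if (length(p) != length(c_)) {
    stop("parent and child sequences differ in length (",
         length(p), " vs ", length(c_), ")")
  }
  ok <- p %in% NUC & c_ %in% NUC
  diff <- ok & p != c_
  pos3 <- ((seq_along(p) - 1L - frame_offset) %% 3L) == 2L
  p_at <- p %in% WEAK
  c_at <- c_ %in% WEAK
  cat4 <- function(sel) {
    c(n_AT_to_GC = sum(sel & p_at & !c_at),
      n_GC_to_AT = sum(sel & !p_at & c_at),
      n_within_AT = sum(sel & p_at & c_at),
      n_within_GC = sum(sel & !p_at & !c_at))
  }
  out <- c(cat4(diff), stats::setNames(cat4(diff & pos3),
                                       paste0(names(cat4(diff)), "_pos3")))
  as.data.frame(c(as.list(out), list(n_skipped = sum(!ok))))
}

#' Clade-aggregated substitution flux
#'
#' Computes [branch_flux()] on every branch (parent sequence vs child
#' sequence, ancestral sequences taken from a reconstruction or from
#' simulation truth) and sums the counts over the branches of each clade.
#' A branch belongs to the clade of its child node. When per-family
#' reconstructions are supplied, a paired per-family comparison of the
#' A/T -> G/C excess between two clades is reported (paired t-test on
#' `n_AT_to_GC - n_GC_to_AT`).
#'
#' @param node_seqs Named character vector of sequences covering every
#'   node label (tips and internal), or a list of such vectors (one per
#'   family).
#' @param tree Rooted `phylo` with node labels.
#' @param clade_map Named character vector: branch (child label) -> clade.
#' @param compare Optional character vector of two clade names to contrast
#'   per family (requires >= 2 families).
#' @param frame_offset 0-based offset of codon position 1.
#' @return Object of class `flux_table`: `branches` (per-branch counts,
#'   summed over families), `clades` (per-clade totals with
#'   `ratio_AT_GC`), and when requested `comparison` (paired t-test
#'   report).
#' @export
clade_flux <- function(node_seqs, tree, clade_map, compare = NULL,
                       frame_offset = 0L) {
  tree <- ensure_node_labels(tree)
  cmap <- validate_clade_map(tree, clade_map)
  if (is.null(unique(unname(cmap))) || !all(table(cmap) >= 1)) {
    stop("every clade must contain at least one branch")
  }
  fams <- if (is.list(node_seqs)) node_seqs else list(node_seqs)
  labs <- node_labels(tree)
  parent_lab <- labs[tree$edge[, 1]]
  child_lab <- labs[tree$edge[, 2]]

  per_fam <- lapply(fams, function(seqs) {
    miss <- setdiff(c(parent_lab, child_lab), names(seqs))
    if (length(miss)) {
      stop("sequences missing for node(s): ", paste(miss, collapse = ", "))
    }
    rows <- lapply(seq_along(child_lab), function(e) {
      branch_flux(seqs[[parent_lab[e]]], seqs[[child_lab[e]]], frame_offset)
    })
    cbind(data.frame(branch = child_lab, clade = unname(cmap),
                     stringsAsFactors = FALSE),
          do.call(rbind, rows))
  })

  count_cols <- setdiff(names(per_fam[[1]]), c("branch", "clade"))
  branches <- per_fam[[1]]
  if (length(per_fam) > 1L) {
    for (f in per_fam[-1]) {
      branches[count_cols] <- branches[count_cols] + f[count_cols]
    }
  }
  clades <- stats::aggregate(branches[count_cols],
                             by = list(clade = branches$clade), FUN = sum)
  clades$ratio_AT_GC <- ifelse(clades$n_GC_to_AT > 0,
                               clades$n_AT_to_GC / clades$n_GC_to_AT, NA)

  comparison <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    missing_cl <- setdiff(compare, unique(branches$clade))
    if (length(missing_cl)) {
      stop("clade(s) not present: ", paste(missing_cl, collapse = ", "))
    }
    excess <- function(fam, cl) {
      sel <- fam$clade == cl
      sum(fam$n_AT_to_GC[sel]) - sum(fam$n_GC_to_AT[sel])
    }
    ex1 <- vapply(per_fam, excess, numeric(1), cl = compare[1])
    ex2 <- vapply(per_fam, excess, numeric(1), cl = compare[2])
    tt <- if (length(ex1) >= 2 && stats::sd(ex1 - ex2) > 0) {
      stats::t.test(ex1, ex2, paired = TRUE)
    } else {
      NULL
    }
    # one-sample tests: is each clade's excess different from zero?
    one <- function(ex) {
      if (length(ex) >= 2 && stats::sd(ex) > 0) {
        stats::t.test(ex)$p.value
      } else {
        NA_real_
      }
    }
    comparison <- list(
      clades = compare,
      excess_means = c(mean(ex1), mean(ex2)),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_excess_vs_zero = stats::setNames(c(one(ex1), one(ex2)), compare),
      n_families = length(per_fam)
    )
  }
  structure(list(branches = branches, clades = clades,
                 comparison = comparison, frame_offset = frame_offset),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, ...) {
  cat("Directional substitution flux (per-clade totals)\n")
  print(x$clades, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat(sprintf(
      "Paired AT->GC excess, %s vs %s: means %.1f / %.1f, P = %.3g\n",
      x$comparison$clades[1], x$comparison$clades[2],
      x$comparison$excess_means[1], x$comparison$excess_means[2],
      x$comparison$p_value))
  }
  invisible(x)
}

#' GC content of a node's sequence or posterior
#'
#' For a plain sequence, the G+C fraction over unambiguous sites. For a
#' marginal reconstruction, also offers the expected GC: the mean
#' per-site posterior mass on {G, C}, which uses the full posterior
#' rather than the argmax sequence.
#'
#' @param x A DNA string, or an `ancestral_reconstruction`.
#' @param node Node label (required when `x` is a reconstruction).
#' @param posterior_weighted Use posterior mass on {G,C} instead of the
#'   argmax sequence (marginal reconstructions only).
#' @return GC fraction in [0,1].
#' @export
ancestral_gc <- function(x, node = NULL, posterior_weighted = FALSE) {
  if (inherits(x, "ancestral_reconstruction")) {
    if (is.null(node)) stop("node label required")
    if (!node %in% names(x$node_sequences)) {
      stop("unknown node: ", node)
    }
    if (posterior_weighted) {
      if (is.null(x$posteriors)) {
        stop("no posteriors available for method ", x$method_tag)
      }
      post <- x$posteriors[[node]]
      return(mean(post[, "G"] + post[, "C"]))
    }
    x <- x$node_sequences[[node]]
  }
  ch <- strsplit(toupper(x), "")[[1]]
  ch <- ch[ch %in% NUC]
  if (!length(ch)) stop("no unambiguous sites")
  mean(ch %in% STRONG)
}
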