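# Conservative vs radical replacement rates under the GC-based amino-acid
# grouping. A nonsynonymous change is "conservative" when the encoded
# amino acids share a GC group (HIGH/LOW/NEUTRAL at codon positions 1-2)
# and "radical" when they cross groups. Sites and differences are counted
# codon by codon in the Nei-Gojobori pathway style: every single-nucleotide
# mutation classified, multi-step codon differences averaged over all
# orderings of the single steps, pathways through stop codons excluded.

# classification of one sense-codon -> sense-codon single step
classify_step <- function(from, to, code, grouping) {
  a1 <- code[[from]]
  a2 <- code[[to]]
  if (a1 == a2) {
    "syn"
  } else if (grouping[[a1]] == grouping[[a2]]) {
    "conservative"
  } else {
    "radical"
  }
}

# the 9 single-nucleotide neighbours of a codon
codon_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(NUC, ch[pos])) {
      mut <- ch
      mut[pos] <- nt
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Conservative, radical and synonymous site counts of a sequence
#'
#' For each codon, its nine single-nucleotide mutations are classified as
#' synonymous, conservative nonsynonymous (same GC group) or radical
#' nonsynonymous (different group); mutations creating a stop codon are
#' excluded from the denominator. Each codon contributes three sites,
#' split in proportion to the classified mutation fractions, so over a
#' stop-free sequence `NC + NR + S = 3 * n_codons`.
#'
#' @param seq In-frame, stop-free uppercase DNA string.
#' @param code Genetic code.
#' @param grouping Named vector amino acid -> group (default the GC
#'   grouping; any partition of the 20 amino acids works).
#' @return Named numeric vector `c(NC, NR, S)`.
#' @export
count_sites <- function(seq, code = build_genetic_code(),
                        grouping = gc_grouping(code)) {
  codons <- split_codons(seq)
  stops <- which(code[codons] == "*")
  if (length(stops)) {
    stop("in-frame stop codon at codon position ", stops[1])
  }
  if (anyNA(code[codons])) {
    stop("non-ACGT codon at position ", which(is.na(code[codons]))[1])
  }
  totals <- c(NC = 0, NR = 0, S = 0)
  for (codon in codons) {
    nb <- codon_neighbours(codon)
    sense <- nb[code[nb] != "*"]
    if (!length(sense)) next
    cls <- vapply(sense, classify_step, character(1), from = codon,
                  code = code, grouping = grouping)
    totals["S"] <- totals["S"] + 3 * mean(cls == "syn")
    totals["NC"] <- totals["NC"] + 3 * mean(cls == "conservative")
    totals["NR"] <- totals["NR"] + 3 * mean(cls == "radical")
  }
  totals[c("NC", "NR", "S")]
}

#' Pathway-averaged difference counts between two codons
#'
#' For codons differing at k positions, all k! orderings of single
#' nucleotide steps are enumerated; orderings passing through a stop
#' codon are excluded and the step classifications of the remaining
#' pathways are averaged, giving expected conservative, radical and
#' synonymous difference counts that sum to k. If every pathway passes
#' through a stop, the stop-free steps of each pathway are classified and
#' averaged (with a warning), so the counts then sum to less than k.
#'
#' @param codon_a,codon_b Sense codons.
#' @inheritParams count_sites
#' @return Named numeric vector `c(nc, nr, ns)`.
#' @export
count_differences <- function(codon_a, codon_b,
                              code = build_genetic_code(),
                              grouping = gc_grouping(code)) {
  if (is.na(code[codon_a]) || is.na(code[codon_b]) ||
      code[codon_a] == "*" || code[codon_b] == "*") {
    stop("both codons must be sense codons")
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  zero <- c(nc = 0, nr = 0, ns = 0)
  if (k == 0L) return(zero)

  perms <- permutations_of(pos)
  full <- list()    # pathways avoiding stops entirely
  partial <- list() # per-pathway counts over stop-free steps only
  for (ord in perms) {
    cur <- a
    counts <- zero
    legal <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (code[[c2]] == "*" || code[[c1]] == "*") {
        legal <- FALSE
      } else {
        cls <- classify_step(c1, c2, code, grouping)
        counts[[switch(cls, syn = "ns", conservative = "nc",
                       radical = "nr")]] <-
          counts[[switch(cls, syn = "ns", conservative = "nc",
                         radical = "nr")]] + 1
      }
      cur <- nxt
    }
    if (legal) full[[length(full) + 1L]] <- counts
    partial[[length(partial) + 1L]] <- counts
  }
  if (length(full)) {
    colMeans(do.call(rbind, full))
  } else {
    warning("all pathways between ", codon_a, " and ", codon_b,
            " pass through stop codons; classified stop-free steps only")
    colMeans(do.call(rbind, partial))
  }
}

# all permutations of a vector (k <= 3 here)
permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Multiple-hit correction of a proportion of differences
#'
#' The standard proportion-to-distance correction
#' `d = -(3/4) * log(1 - (4/3) p)`, applied to the conservative and
#' radical proportions alike. Saturated proportions (p >= 3/4) have no
#' finite distance and return `NA` with a warning. Set
#' `correction = "none"` in the rate functions to keep p-distances.
#'
#' @param p Proportion(s) of differences, in [0, 3/4).
#' @return Corrected distance(s), `d >= p`.
#' @export
correct_distance <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE))
  d <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  if (anyNA(d[!is.na(p)])) {
    warning("saturated proportion (p >= 3/4): distance undefined")
  }
  d
}

# Memoised per-codon site fractions and per-pair difference counts for a
# given grouping; pairwise_rates over many families hits these tables.
.rates_cache <- new.env(parent = emptyenv())

rate_tables <- function(code = build_genetic_code(),
                        grouping = gc_grouping(code)) {
  key <- paste(names(grouping), grouping, sep = "=", collapse = ";")
  hit <- .rates_cache[[key]]
  if (!is.null(hit)) return(hit)
  codons <- sense_codons(code)
  site <- t(vapply(codons, function(cdn) {
    count_sites(cdn, code, grouping)
  }, numeric(3)))
  diff <- array(0, dim = c(61L, 61L, 3L),
                dimnames = list(codons, codons, c("nc", "nr", "ns")))
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i != j) {
        diff[i, j, ] <- suppressWarnings(
          count_differences(codons[i], codons[j], code, grouping))
      }
    }
  }
  out <- list(site = site, diff = diff)
  .rates_cache[[key]] <- out
  out
}

#' Conservative and radical replacement rates between two sequences
#'
#' Counts sites with [count_sites()] (averaged over the two sequences)
#' and differences with [count_differences()] codon by codon, then forms
#' the proportions `pC = nc/NC`, `pR = nr/NR` and the corrected rates
#' `d_within` (conservative) and `d_between` (radical), plus their ratio
#' `d_between / d_within`. Works equally for two extant orthologs and for
#' a sequence against its reconstructed ancestor: codon positions where
#' either sequence has a stop or an ambiguous codon are masked and
#' tallied in `n_codons_skipped`.
#'
#' @param seq_a,seq_b In-frame, equal-length DNA strings.
#' @inheritParams count_sites
#' @param correction `"proportion"` (default; see [correct_distance()])
#'   or `"none"` for raw p-distances.
#' @return One-row data frame: `NC`, `NR`, `S`, `nc_diff`, `nr_diff`,
#'   `ns_diff`, `pC`, `pR`, `d_within`, `d_between`, `ratio`,
#'   `n_codons_skipped`.
#' @export
pairwise_rates <- function(seq_a, seq_b, code = build_genetic_code(),
                           grouping = gc_grouping(code),
                           correction = c("proportion", "none")) {
  correction <- match.arg(correction)
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) {
    stop("sequences differ in codon length")
  }
  tabs <- rate_tables(code, grouping)
  # codons that are stops or contain gaps/ambiguity (e.g. in
  # reconstructed ancestors) are masked from the comparison
  keep <- !is.na(match(ca, rownames(tabs$site))) &
    !is.na(match(cb, rownames(tabs$site)))
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no comparable sense codons left")
  ca <- ca[keep]
  cb <- cb[keep]
  sites <- (colSums(tabs$site[ca, , drop = FALSE]) +
              colSums(tabs$site[cb, , drop = FALSE])) / 2
  mism <- which(ca != cb)
  diffs <- c(nc = 0, nr = 0, ns = 0)
  if (length(mism)) {
    idx <- cbind(match(ca[mism], rownames(tabs$site)),
                 match(cb[mism], rownames(tabs$site)))
    diffs <- c(nc = sum(tabs$diff[, , "nc"][idx]),
               nr = sum(tabs$diff[, , "nr"][idx]),
               ns = sum(tabs$diff[, , "ns"][idx]))
  }
  pC <- if (sites[["NC"]] > 0) diffs[["nc"]] / sites[["NC"]] else NA_real_
  pR <- if (sites[["NR"]] > 0) diffs[["nr"]] / sites[["NR"]] else NA_real_
  dW <- if (correction == "proportion") correct_distance(pC) else pC
  dB <- if (correction == "proportion") correct_distance(pR) else pR
  data.frame(NC = sites[["NC"]], NR = sites[["NR"]], S = sites[["S"]],
             nc_diff = diffs[["nc"]], nr_diff = diffs[["nr"]],
             ns_diff = diffs[["ns"]], pC = pC, pR = pR,
             d_within = dW, d_between = dB,
             ratio = if (isTRUE(dW > 0)) dB / dW else NA_real_,
             n_codons_skipped = n_skipped)
}

#' Compare d_between/d_within ratios between two clades
#'
#' Takes per-family replacement rates measured in each clade (rows of
#' [pairwise_rates()], paired by family across clades), reports each
#' clade's mean ratio with its standard error and mean `d_within` /
#' `d_between`, and tests the paired difference of ratios with a t-test.
#' Families with zero or non-finite `d_within` in either clade are
#' dropped with a warning; a zero-variance paired difference is reported
#' as degenerate rather than tested.
#'
#' @param rates_a,rates_b Data frames of per-family rates (same families,
#'   same order) for clades A and B.
#' @param labels Length-2 clade names for reporting.
#' @return Object of class `rate_comparison`.
#' @export
clade_comparison <- function(rates_a, rates_b,
                             labels = c("clade_a", "clade_b")) {
  stopifnot(nrow(rates_a) == nrow(rates_b))
  ok <- is.finite(rates_a$ratio) & is.finite(rates_b$ratio)
  if (!all(ok)) {
    warning(sum(!ok), " famil(ies) dropped: undefined ratio")
  }
  ra <- rates_a$ratio[ok]
  rb <- rates_b$ratio[ok]
  if (length(ra) < 2L) stop("need >= 2 families with finite ratios")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  diffs <- ra - rb
  degenerate <- stats::sd(diffs) == 0
  tt <- if (!degenerate) stats::t.test(ra, rb, paired = TRUE) else NULL
  per_clade <- data.frame(
    clade = labels,
    mean_ratio = c(mean(ra), mean(rb)),
    sem_ratio = c(sem(ra), sem(rb)),
    mean_d_within = c(mean(rates_a$d_within[ok]),
                      mean(rates_b$d_within[ok])),
    mean_d_between = c(mean(rates_a$d_between[ok]),
                       mean(rates_b$d_between[ok])),
    stringsAsFactors = FALSE)
  structure(list(
    per_clade = per_clade,
    p_value = if (degenerate) {
      if (all(diffs == 0)) 1 else NA_real_   # identical sets vs constant shift
    } else {
      tt$p.value
    },
    statistic = if (degenerate) {
      if (all(diffs == 0)) 0 else NA_real_
    } else {
      unname(tt$statistic)
    },
    degenerate = degenerate,
    n_families = length(ra)
  ), class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("d_between/d_within comparison over", x$n_families, "families\n")
  print(x$per_clade, row.names = FALSE, digits = 4)
  if (x$degenerate) {
    cat("paired differences have zero variance (degenerate)\n")
  } else {
    cat(sprintf("paired t = %.3f, P = %.3g\n", x$statistic, x$p_value))
  }
  invisible(x)
}
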