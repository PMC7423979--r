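# GC metrics, codon-usage enrichment between clades, and amino-acid
# carbon-economy comparison. All comparisons are paired over ortholog
# families present in both clades.

#' GC content overall and by codon position
#'
#' Fractions of G/C over all unambiguous sites and at each codon
#' position of an in-frame sequence. Gaps and ambiguity characters are
#' skipped; the overall value is the site-weighted mean of the three
#' positional values.
#'
#' @param seq In-frame uppercase DNA string (length divisible by 3 after
#'   the offset).
#' @param frame_offset 0-based offset of codon position 1.
#' @return Named numeric vector `c(gc_total, gc1, gc2, gc3)`.
#' @examples
#' gc_metrics("GGAGGC")  # gc3 = 0.5
#' @export
gc_metrics <- function(seq, frame_offset = 0L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (frame_offset > 0) ch <- ch[-seq_len(frame_offset)]
  if (!length(ch)) stop("empty sequence")
  if (length(ch) %% 3L != 0L) {
    stop("length ", length(ch), " not divisible by 3 after frame offset")
  }
  pos <- rep_len(1:3, length(ch))
  keep <- ch %in% NUC
  if (!any(keep)) stop("no unambiguous sites")
  is_gc <- ch %in% STRONG
  bypos <- vapply(1:3, function(p) {
    sel <- keep & pos == p
    if (any(sel)) mean(is_gc[sel]) else NA_real_
  }, numeric(1))
  c(gc_total = mean(is_gc[keep]), gc1 = bypos[1], gc2 = bypos[2],
    gc3 = bypos[3])
}

# relative sense-codon frequencies (61-vector) of one or more sequences
codon_frequencies <- function(seqs, code = build_genetic_code()) {
  codons <- sense_codons(code)
  counts <- stats::setNames(numeric(61L), codons)
  for (s in seqs) {
    tab <- table(split_codons(s))
    tab <- tab[names(tab) %in% codons]
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  if (sum(counts) == 0) stop("no sense codons found")
  counts / sum(counts)
}

# per-family frequency matrix (families x variables)
family_profile <- function(families, profiler) {
  t(vapply(families, profiler, profiler(families[[1]])))
}

# paired per-variable test with BH adjustment; x/y are families x vars
paired_variable_test <- function(x, y, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (nrow(x) < 3L) stop("need >= 3 families for a paired test")
  d <- x - y
  pvals <- apply(d, 2, function(v) {
    if (stats::sd(v) == 0) return(if (all(v == 0)) 1 else NA_real_)
    if (test == "t") {
      stats::t.test(v)$p.value
    } else {
      stats::wilcox.test(v, exact = FALSE)$p.value
    }
  })
  data.frame(variable = colnames(x),
             mean_a = colMeans(x), mean_b = colMeans(y),
             mean_diff = colMeans(d),
             p_value = pvals,
             p_adjusted = stats::p.adjust(pvals, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Codon-usage enrichment between two clades
#'
#' Per codon, the paired difference of relative sense-codon frequency
#' across ortholog families, tested two-sided (paired t by default,
#' Wilcoxon optional) with Benjamini-Hochberg adjustment over the 61
#' codons. A codon is "enriched" in a clade when its adjusted P is below
#' `alpha` and its mean frequency difference favours that clade. The
#' report also summarises the enriched set's GC content — both the plain
#' mean over the three codon positions and the usage-weighted mean — and
#' the fraction of enriched codons with G/C at position 3.
#'
#' @param families_a,families_b Paired lists (same length/order): each
#'   element the sequence(s) of one ortholog family in that clade.
#' @param code Genetic code.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @param alpha FDR level (default 0.05).
#' @return Object of class `codon_enrichment`: `table` (per-codon), and
#'   `summary` with the enriched-set statistics for each direction.
#' @export
codon_enrichment <- function(families_a, families_b,
                             code = build_genetic_code(),
                             test = c("t", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(families_a) == length(families_b))
  fa <- family_profile(families_a, function(s) codon_frequencies(s, code))
  fb <- family_profile(families_b, function(s) codon_frequencies(s, code))
  tab <- paired_variable_test(fa, fb, test)
  names(tab)[1] <- "codon"
  tab$enriched_in_a <- !is.na(tab$p_adjusted) &
    tab$p_adjusted < alpha & tab$mean_diff > 0
  tab$enriched_in_b <- !is.na(tab$p_adjusted) &
    tab$p_adjusted < alpha & tab$mean_diff < 0
  set_summary <- function(sel, usage) {
    codons <- tab$codon[sel]
    if (!length(codons)) {
      return(list(n = 0L, mean_gc = NA_real_,
                  mean_gc_usage_weighted = NA_real_, frac_gc3 = NA_real_))
    }
    gc_per <- vapply(strsplit(codons, ""),
                     function(x) mean(x %in% STRONG), numeric(1))
    w <- usage[sel] / sum(usage[sel])
    third <- substr(codons, 3L, 3L)
    list(n = length(codons), mean_gc = mean(gc_per),
         mean_gc_usage_weighted = sum(w * gc_per),
         frac_gc3 = mean(third %in% STRONG))
  }
  summary <- list(
    enriched_in_a = set_summary(tab$enriched_in_a, tab$mean_a),
    enriched_in_b = set_summary(tab$enriched_in_b, tab$mean_b),
    test = test, alpha = alpha, n_families = length(families_a))
  structure(list(table = tab, summary = summary),
            class = "codon_enrichment")
}

#' @export
print.codon_enrichment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Codon enrichment (%s test, BH at %.2f, %d families):\n",
    s$test, s$alpha, s$n_families))
  cat(sprintf("  enriched in A: %d codons (mean GC %.3f, GC3 fraction %.2f)\n",
              s$enriched_in_a$n,
              s$enriched_in_a$mean_gc, s$enriched_in_a$frac_gc3))
  cat(sprintf("  enriched in B: %d codons\n", s$enriched_in_b$n))
  invisible(x)
}

#' Amino-acid usage and carbon-economy comparison between clades
#'
#' Translates each family, compares per-amino-acid content across clades
#' with paired t-tests (BH adjusted over the 20 amino acids), and
#' reports the mean carbon atoms per residue of each clade. Amino acids
#' are additionally binned by their total carbon count so the
#' cheap-residue contrast (Gly/Ala at 2-3 carbons) can be set against
#' the carbon-rich bins.
#'
#' @inheritParams codon_enrichment
#' @return Object of class `carbon_report`: `per_aa` (per-amino-acid
#'   table with carbon counts), `per_bin` (paired tests on carbon-count
#'   bins), `mean_carbon` (per-clade mean carbon atoms per residue and
#'   paired P).
#' @export
carbon_usage_comparison <- function(families_a, families_b,
                                    code = build_genetic_code(),
                                    alpha = 0.05) {
  stopifnot(length(families_a) == length(families_b))
  aas <- sort(unique(code[code != "*"]))
  aa_freq <- function(seqs) {
    aa <- unlist(lapply(seqs, translate_codons, code = code))
    aa <- aa[!is.na(aa) & aa != "*"]
    if (!length(aa)) stop("family translates to no residues")
    tab <- table(factor(aa, levels = aas))
    stats::setNames(as.numeric(tab) / sum(tab), aas)
  }
  fa <- family_profile(families_a, aa_freq)
  fb <- family_profile(families_b, aa_freq)
  colnames(fa) <- colnames(fb) <- aas
  per_aa <- paired_variable_test(fa, fb)
  names(per_aa)[1] <- "aa"
  cc <- carbon_counts(per_aa$aa)
  per_aa$carbon_total <- cc$carbon_total
  per_aa$carbon_side_chain <- cc$carbon_side_chain

  bin_of <- cut(per_aa$carbon_total, breaks = c(0, 3, 4, 5, 6, Inf),
                labels = c("2-3", "4", "5", "6", ">=9"))
  bin_a <- t(apply(fa, 1, function(r) tapply(r, bin_of, sum)))
  bin_b <- t(apply(fb, 1, function(r) tapply(r, bin_of, sum)))
  per_bin <- paired_variable_test(bin_a, bin_b)
  names(per_bin)[1] <- "carbon_bin"

  mc_a <- fa %*% per_aa$carbon_total
  mc_b <- fb %*% per_aa$carbon_total
  d <- as.numeric(mc_a - mc_b)
  p_mc <- if (stats::sd(d) == 0) {
    if (all(d == 0)) 1 else NA_real_
  } else {
    stats::t.test(d)$p.value
  }
  structure(list(
    per_aa = per_aa, per_bin = per_bin,
    mean_carbon = list(clade_a = mean(mc_a), clade_b = mean(mc_b),
                       p_value = p_mc),
    alpha = alpha, n_families = length(families_a)
  ), class = "carbon_report")
}

#' @export
print.carbon_report <- function(x, ...) {
  cat(sprintf(
    "Carbon economy over %d families: mean C/residue %.3f (A) vs %.3f (B), P = %.3g\n",
    x$n_families, x$mean_carbon$clade_a, x$mean_carbon$clade_b,
    x$mean_carbon$p_value))
  sig <- x$per_aa[!is.na(x$per_aa$p_adjusted) &
                    x$per_aa$p_adjusted < x$alpha, ]
  if (nrow(sig)) {
    cat("  amino acids with adjusted P <", x$alpha, ":",
        paste(sig$aa, collapse = ", "), "\n")
  }
  invisible(x)
}
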