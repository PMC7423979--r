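# FPKM-threshold classification of life-phase specific expression, and
# the log2 fold-change profiles of the dehydration/rehydration series.
#
# Printed rules, applied with strict inequalities exactly as stated:
#   spo-specific: dually expressed with FPKM < 5 in gam and > 25 in spo,
#                 or a "unique" gene (FPKM 0 in gam) with > 10-fold FPKM
#                 in spo; gam-specific is the mirror image.
#   constitutive: FPKM > 5 in both phases and fold change < 10.
# Zero handling: "unique" means undetected (FPKM 0) in the other phase;
# the unique-gene fold is FPKM_detected / (0 + pseudocount), and the
# detected phase must itself clear the detection threshold, so a gene at
# (0, 3) is not called specific — it is simply barely expressed.

#' Default thresholds of the phase classifier
#'
#' @return List with `abs_low` (5, detection/dual-rule low bound),
#'   `abs_high` (25, dual-rule high bound), `fold` (10) and
#'   `pseudocount` (0.1, used only in fold ratios).
#' @export
phase_thresholds <- function() {
  list(abs_low = 5, abs_high = 25, fold = 10, pseudocount = 0.1)
}

#' Classify one gene's phase specificity from mean FPKM per phase
#'
#' @param fpkm_gam,fpkm_spo Mean FPKM in the gametophyte and sporophyte
#'   phases (non-negative; averaged over replicates upstream).
#' @param thresholds See [phase_thresholds()].
#' @param fold_all_genes If `TRUE`, the >10-fold clause applies to all
#'   genes, not only genes undetected in one phase. Default `FALSE`
#'   (unique-only, the stricter reading).
#' @return List with `label` (one of `GAM_SPECIFIC`, `SPO_SPECIFIC`,
#'   `CONSTITUTIVE`, `OTHER`) and `rule_fired` naming the clause.
#' @examples
#' classify_phase(2, 30)    # SPO_SPECIFIC (dual rule)
#' classify_phase(20, 25)   # CONSTITUTIVE (fold 1.25)
#' classify_phase(0, 3)     # OTHER (undetected vs barely expressed)
#' @export
classify_phase <- function(fpkm_gam, fpkm_spo,
                           thresholds = phase_thresholds(),
                           fold_all_genes = FALSE) {
  if (!is.finite(fpkm_gam) || !is.finite(fpkm_spo) ||
      fpkm_gam < 0 || fpkm_spo < 0) {
    stop("FPKM values must be finite and non-negative")
  }
  th <- thresholds
  eps <- th$pseudocount
  fold_up <- (fpkm_spo + eps) / (fpkm_gam + eps)   # spo over gam

  dual_spo <- fpkm_gam < th$abs_low && fpkm_spo > th$abs_high
  dual_gam <- fpkm_spo < th$abs_low && fpkm_gam > th$abs_high
  unique_spo <- (fold_all_genes || fpkm_gam == 0) &&
    fpkm_spo > th$abs_low && fold_up > th$fold
  unique_gam <- (fold_all_genes || fpkm_spo == 0) &&
    fpkm_gam > th$abs_low && (1 / fold_up) > th$fold
  constitutive <- fpkm_gam > th$abs_low && fpkm_spo > th$abs_low &&
    max(fold_up, 1 / fold_up) < th$fold

  if (dual_spo) {
    list(label = "SPO_SPECIFIC", rule_fired = "dual_threshold")
  } else if (dual_gam) {
    list(label = "GAM_SPECIFIC", rule_fired = "dual_threshold")
  } else if (unique_spo) {
    list(label = "SPO_SPECIFIC", rule_fired = "fold")
  } else if (unique_gam) {
    list(label = "GAM_SPECIFIC", rule_fired = "fold")
  } else if (constitutive) {
    list(label = "CONSTITUTIVE", rule_fired = "constitutive")
  } else {
    list(label = "OTHER", rule_fired = "none")
  }
}

#' Classify every gene of an expression table
#'
#' @param table Data frame with columns `gene`, `fpkm_gam`, `fpkm_spo`
#'   (e.g. from [simulate_expression_table()] or [read_expression_table()]).
#' @inheritParams classify_phase
#' @return The table with `label` and `rule_fired` columns appended.
#' @export
classify_phases <- function(table, thresholds = phase_thresholds(),
                            fold_all_genes = FALSE) {
  stopifnot(all(c("gene", "fpkm_gam", "fpkm_spo") %in% names(table)))
  res <- Map(classify_phase, table$fpkm_gam, table$fpkm_spo,
             MoreArgs = list(thresholds = thresholds,
                             fold_all_genes = fold_all_genes))
  table$label <- vapply(res, `[[`, character(1), "label")
  table$rule_fired <- vapply(res, `[[`, character(1), "rule_fired")
  table
}

#' Log2 fold change with a pseudocount
#'
#' `log2((fpkm_x + eps) / (fpkm_ctrl + eps))`, the transform used for
#' dehydration/rehydration response profiles.
#'
#' @param fpkm_x,fpkm_ctrl Non-negative FPKM values (vectorised).
#' @param pseudocount Added to both numerator and denominator (default
#'   0.1; 0 gives the raw log ratio).
#' @return log2 ratio(s).
#' @export
fold_change <- function(fpkm_x, fpkm_ctrl, pseudocount = 0.1) {
  stopifnot(all(fpkm_x >= 0), all(fpkm_ctrl >= 0), pseudocount >= 0)
  log2((fpkm_x + pseudocount) / (fpkm_ctrl + pseudocount))
}

#' Fold-change matrix of the stress-condition series
#'
#' @param table Expression table with a `ctrl` column and further
#'   condition columns.
#' @param conditions Condition column names (default: every column after
#'   `ctrl` among `wl20, wl50, wl80, re80, re50` that is present).
#' @param pseudocount See [fold_change()].
#' @return Matrix (genes x conditions) of log2 fold changes vs control,
#'   rownames from `table$gene` — heatmap-ready.
#' @export
fold_change_matrix <- function(table,
                               conditions = intersect(
                                 c("wl20", "wl50", "wl80", "re80", "re50"),
                                 names(table)),
                               pseudocount = 0.1) {
  stopifnot("ctrl" %in% names(table), length(conditions) > 0)
  m <- vapply(conditions, function(cn) {
    fold_change(table[[cn]], table$ctrl, pseudocount)
  }, numeric(nrow(table)))
  m <- matrix(m, nrow = nrow(table),
              dimnames = list(table$gene, conditions))
  m
}

#' Summary of phase-specific expression
#'
#' Counts and percentages per label, for the whole table and optionally
#' for a gene subset (e.g. a candidate list such as horizontally
#' transferred genes). Also flags genes whose stress series shows at
#' least a two-fold change (|log2 FC| >= 1) at two or more time points.
#'
#' @param table Classified table (from [classify_phases()]).
#' @param subset Optional character vector of gene ids.
#' @param pseudocount For the stress fold changes.
#' @return Object of class `phase_summary`: `overall` and (optionally)
#'   `subset` data frames of counts/percentages, `phase_specific_pct`
#'   for each, and `stress_responsive` (logical per gene, when condition
#'   columns are present).
#' @export
phase_summary <- function(table, subset = NULL, pseudocount = 0.1) {
  stopifnot("label" %in% names(table))
  levs <- c("GAM_SPECIFIC", "SPO_SPECIFIC", "CONSTITUTIVE", "OTHER")
  tally <- function(tab) {
    cnt <- table(factor(tab$label, levels = levs))
    data.frame(label = levs, n = as.integer(cnt),
               pct = 100 * as.integer(cnt) / nrow(tab),
               stringsAsFactors = FALSE)
  }
  overall <- tally(table)
  spec_pct <- function(t) sum(t$pct[t$label %in% c("GAM_SPECIFIC",
                                                   "SPO_SPECIFIC")])
  out <- list(overall = overall,
              phase_specific_pct = c(overall = spec_pct(overall)))
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty gene subset")
    miss <- setdiff(subset, table$gene)
    if (length(miss)) {
      stop("subset genes not in table: ", paste(miss, collapse = ", "))
    }
    sub <- table[table$gene %in% subset, , drop = FALSE]
    out$subset <- tally(sub)
    out$phase_specific_pct["subset"] <- spec_pct(out$subset)
  }
  conds <- intersect(c("wl20", "wl50", "wl80", "re80", "re50"),
                     names(table))
  if (length(conds) >= 2 && "ctrl" %in% names(table)) {
    fc <- fold_change_matrix(table, conds, pseudocount)
    out$stress_responsive <- stats::setNames(
      rowSums(abs(fc) >= 1) >= 2, table$gene)
  }
  structure(out, class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("Phase-specific expression summary\n")
  print(x$overall, row.names = FALSE, digits = 3)
  cat(sprintf("phase-specific overall: %.1f%%\n",
              x$phase_specific_pct[["overall"]]))
  if (!is.null(x$subset)) {
    cat("subset:\n")
    print(x$subset, row.names = FALSE, digits = 3)
    cat(sprintf("phase-specific in subset: %.1f%%\n",
                x$phase_specific_pct[["subset"]]))
  }
  invisible(x)
}
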