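# Genetic code, GC-based amino-acid grouping, and carbon economy tables.
# All codon-level statistics in the package are anchored on these.

NUC <- c("A", "C", "G", "T")

#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as a named character vector
#' mapping the 64 trinucleotides (DNA alphabet, alphabetical order) to
#' one-letter amino-acid codes, with `"*"` for the three stop codons.
#' Only the standard code is supported.
#'
#' @return Named character vector of length 64; 61 sense codons map to the
#'   20 amino acids and TAA/TAG/TGA map to `"*"`.
#' @examples
#' code <- build_genetic_code()
#' sum(code != "*")   # 61 sense codons
#' code[["ATG"]]      # "M"
#' @export
build_genetic_code <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  # Biostrings orders codons T,C,A,G-major; re-sort alphabetically so the
  # table is a stable coordinate system for downstream vectors.
  code[order(names(code))]
}

#' Sense codons of the standard code
#'
#' @param code Genetic code from [build_genetic_code()].
#' @return Character vector of the 61 codons that encode an amino acid.
#' @export
sense_codons <- function(code = build_genetic_code()) {
  names(code)[code != "*"]
}

#' Mean G+C count at codon positions 1-2 for one amino acid
#'
#' For each codon of the amino acid, counts how many of its first two
#' bases are G or C (0-2), then averages over the codons unweighted.
#' Six-fold degenerate families (Leu, Arg, Ser) mix codon boxes, so the
#' unweighted mean is the deterministic, code-derived summary used here.
#'
#' @param aa One-letter amino-acid code.
#' @param code Genetic code.
#' @return Numeric scalar in [0, 2].
#' @export
gc12_mean <- function(aa, code = build_genetic_code()) {
  stopifnot(length(aa) == 1L)
  codons <- names(code)[code == aa & code != "*"]
  if (length(codons) == 0L) {
    stop("unknown amino acid: ", aa)
  }
  first_two <- substr(codons, 1L, 2L)
  gc <- vapply(strsplit(first_two, ""), function(x) sum(x %in% c("G", "C")),
               numeric(1))
  mean(gc)
}

#' GC group of an amino acid
#'
#' Amino acids are partitioned into three groups by the G+C content at the
#' first two codon positions: `HIGH` if every codon has G/C at both
#' positions (mean count 2), `LOW` if no codon has any (mean count 0), and
#' `NEUTRAL` otherwise. Replacements that stay within a group are
#' "conservative" with respect to GC content; replacements that cross
#' groups are "radical".
#'
#' @inheritParams gc12_mean
#' @return One of `"HIGH"`, `"LOW"`, `"NEUTRAL"`.
#' @examples
#' classify_gc_group("G")  # HIGH: all Gly codons are GGN
#' classify_gc_group("K")  # LOW: AAA/AAG
#' classify_gc_group("L")  # NEUTRAL: TTR + CTN mix
#' @export
classify_gc_group <- function(aa, code = build_genetic_code()) {
  m <- gc12_mean(aa, code)
  if (m == 2) "HIGH" else if (m == 0) "LOW" else "NEUTRAL"
}

# carbon atoms per free amino acid (total); side chain = total - 2
# (the backbone contributes the alpha and carboxyl carbons)
.CARBON_TOTAL <- c(
  A = 3L, R = 6L, N = 4L, D = 4L, C = 3L, Q = 5L, E = 5L, G = 2L,
  H = 6L, I = 6L, L = 6L, K = 6L, M = 5L, F = 9L, P = 5L, S = 3L,
  T = 4L, W = 11L, Y = 9L, V = 5L
)

#' Carbon atom counts of an amino acid
#'
#' Carbon atoms per free amino acid, both for the whole residue and for
#' the side chain alone (total minus the two backbone carbons). The
#' whole-residue count is what the carbon-economy comparison uses: the
#' cheapest residues are Gly (2) and Ala (3).
#'
#' @param aa One-letter amino-acid code (vectorised).
#' @return Data frame with columns `aa`, `carbon_total`, `carbon_side_chain`.
#' @examples
#' carbon_counts(c("G", "A", "W"))
#' @export
carbon_counts <- function(aa) {
  bad <- setdiff(aa, names(.CARBON_TOTAL))
  if (length(bad)) {
    stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  }
  total <- .CARBON_TOTAL[aa]
  data.frame(aa = aa, carbon_total = unname(total),
             carbon_side_chain = unname(total) - 2L,
             stringsAsFactors = FALSE)
}

#' Profile table for the 20 standard amino acids
#'
#' One row per amino acid: carbon economy (total and side-chain carbon
#' atoms) and the GC grouping derived from the genetic code.
#'
#' @param code Genetic code.
#' @return Data frame with columns `aa`, `carbon_total`,
#'   `carbon_side_chain`, `gc12_mean`, `gc_group`.
#' @export
amino_acid_profiles <- function(code = build_genetic_code()) {
  aas <- sort(unique(code[code != "*"]))
  cc <- carbon_counts(aas)
  cc$gc12_mean <- vapply(aas, gc12_mean, numeric(1), code = code)
  cc$gc_group <- vapply(aas, classify_gc_group, character(1), code = code)
  rownames(cc) <- NULL
  cc
}

#' GC grouping as a named lookup vector
#'
#' @param code Genetic code.
#' @return Named character vector: amino acid -> `HIGH`/`LOW`/`NEUTRAL`.
#' @export
gc_grouping <- function(code = build_genetic_code()) {
  prof <- amino_acid_profiles(code)
  stats::setNames(prof$gc_group, prof$aa)
}

#' Translate an in-frame nucleotide sequence
#'
#' @param seq Single uppercase DNA string, length divisible by 3.
#' @param code Genetic code.
#' @return Character vector of one-letter amino acids (`"*"` for stops,
#'   `NA` for codons containing non-ACGT characters).
#' @export
translate_codons <- function(seq, code = build_genetic_code()) {
  codons <- split_codons(seq)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- NA_character_
  aa
}

# split an in-frame sequence string into its codon triplets
split_codons <- function(seq) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
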