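---
title: "Detecting clade-specific GC enrichment in coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clade-specific GC enrichment in coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdrift)
```

## The problem

Some clades — the Bangiales red algae are the motivating example — have
coding sequences that are dramatically GC-richer than those of their
sister lineages. Establishing that this reflects a directional,
clade-specific substitution regime (rather than shared ancestry or
assembly artefacts) requires several coordinated analyses:

1. fit a substitution model in which the equilibrium GC content is
   allowed to differ between clades, on a fixed species tree;
2. reconstruct ancestral sequences under that model and count, branch by
   branch, substitutions from A/T into G/C versus the reverse;
3. ask whether amino-acid replacements preferentially move between
   GC-defined amino-acid classes in the enriched clade
   (conservative/radical replacement rates);
4. characterise the footprint in codon usage and in the carbon cost of
   the encoded proteome;
5. independently, classify life-phase specific expression from FPKM
   tables, since phase-specific transcription is part of the same
   adaptive story in this system.

`gcdrift` implements all five stages plus a simulator that generates
alignments with known ancestors, known substitution events and known
planted expression classes, so that every stage can be validated against
ground truth.

## The substitution model

The model is a non-stationary variant of Tamura's two-parameter (T92)
process over the DNA alphabet. A branch class $c$ has equilibrium
frequencies

$$\pi_G = \pi_C = \theta_c/2, \qquad \pi_A = \pi_T = (1-\theta_c)/2,$$

and the instantaneous rate from state $i$ to $j$ is proportional to
$\kappa \pi_j$ for transitions (A↔G, C↔T) and $\pi_j$ for transversions,
scaled so one unit of branch length is one expected substitution per
site at stationarity. Every branch of the rooted input tree is assigned
to a class by the *clade map* (a branch is identified by its child
node); the quantity of interest is the per-class equilibrium GC content
$\theta_c$, with a single global $\kappa$ and a GC-symmetric root
composition $\theta_{\mathrm{root}}$. This is the minimal model that
exposes clade-specific equilibrium GC as an explicit parameter; whether
one estimates a $\theta$ per clade or per branch is a modelling choice,
and the clade map makes that granularity explicit and user-controlled.

Likelihoods are computed by Felsenstein pruning with per-branch
transition matrices $P(t) = e^{Qt}$ obtained by spectral decomposition
of the reversible within-class generator. Gaps and ambiguity codes are
missing data (flat partial likelihoods). Branch lengths are taken from
the input tree and never re-optimised. Fitting maximises the likelihood
over $(\kappa, \{\theta_c\}, \theta_{\mathrm{root}})$ on an
unconstrained scale (log / logit) by BFGS from several starts: a neutral
start, a start at the observed tip GC of each class, and seeded random
jitters; the reported fit is the best of all starts, with per-start
log-likelihoods kept in the report. Site patterns are pooled across
gene families (which share the tree), so each likelihood evaluation
costs one pruning pass over the unique patterns.

Ancestral states are reconstructed marginally: an up–down recursion
yields, for every internal node and site, the posterior distribution
over A, C, G, T given all tips; the reported sequence is the posterior
mode, with ties broken alphabetically (A < C < G < T) so runs are
reproducible. A two-pass Fitch parsimony reconstruction is included as a
model-free cross-check; its down-pass prefers the parent's state and
otherwise the alphabetically first candidate.

## Directional flux accounting

Given parent and child sequences for every branch (reconstructed, or
true in simulation), each mismatching site falls into exactly one of
four categories by A/T versus G/C membership of the two states:
A/T→G/C, G/C→A/T, within-A/T, within-G/C. Counts are kept overall and
restricted to third codon positions, per branch and summed per clade; a
branch belongs to the clade of its child node. A GC-shifted clade shows
an excess of A/T→G/C changes; the package reports the per-clade ratio
and a paired per-family t-test of the A/T→G/C excess between two
clades, plus one-sample tests of each clade's excess against zero.
Endpoint comparison is blind to multiple hits at a site, so these are
lower bounds on event counts — in simulation the event log gives the
exact counts, and the tests verify that endpoint counts equal event
counts whenever each site was hit at most once.

## Conservative and radical replacement rates

Amino acids are partitioned by the G+C content of the first two codon
positions: HIGH when every codon of the amino acid carries G/C at both
positions (Gly, Ala, Pro), LOW when none does (Lys, Asn, Ile, Met, Phe,
Tyr), NEUTRAL otherwise. Six-fold families that span two codon boxes
(Leu, Arg, Ser) are classified by the unweighted mean over their codons,
which is deterministic and derived entirely from the code; by that rule
Arg (mean 10/6) is NEUTRAL, so exactly three amino acids are HIGH. A
nonsynonymous replacement is *conservative* when the two amino acids
share a group and *radical* when they cross groups.

Sites are counted codon by codon: each of a codon's nine
single-nucleotide mutations is classified synonymous / conservative /
radical, mutations into stop codons are excluded from the denominator,
and the codon's three sites are split proportionally, so
$N_C + N_R + S = 3 \times$ (codons compared). Differences between two
codons at $k$ positions are averaged over all $k!$ single-step
pathways, excluding pathways through stop codons (if every pathway is
excluded, the stop-free steps of each pathway are classified and
averaged, with a warning). The proportions $p_C = n_c/N_C$ and
$p_R = n_r/N_R$ are corrected for multiple hits with
$d = -\tfrac34\log(1-\tfrac43 p)$ — the correction is a configuration
switch (`"none"` keeps p-distances) because corrected and uncorrected
rates answer slightly different questions and the choice should be
auditable. $d_\mathrm{within} \equiv d_C$, $d_\mathrm{between} \equiv
d_R$, and the clade comparison reports per-clade mean ± SEM of
$d_\mathrm{between}/d_\mathrm{within}$ over families with a paired
t-test. Codons containing stops or ambiguity in either sequence (which
can occur in reconstructed ancestors) are masked and tallied.

Two measurement modes are available, and they do not answer the same
question. Comparing two extant orthologs *within* a GC-rich clade
mostly measures composition: GC-rich sequences concentrate in HIGH-group
amino acids, replacements more often stay inside a group, and the
between/within ratio is *depressed*. The directional signal of an
ongoing compositional shift lives in the *branchwise* mode — each tip
against a reconstructed (or true) ancestor that predates the shift —
where replacements crossing groups upward are over-represented. The
package exposes both; the simulation tests use the branchwise mode with
per-family averaging over a clade's tips. Under pure drift the contrast
is real but small, and with reconstructed (rather than true) ancestors
reconstruction bias can mask it at moderate shifts; in real data the
contrast is additionally shaped by selective constraint, which the
neutral simulator deliberately does not model.

## Composition and carbon economy

Per-sequence GC metrics (overall and per codon position, GC3 being the
classic codon-bias indicator) are computed over unambiguous sites.
Codon-usage enrichment between clades is a per-codon paired t-test of
relative sense-codon frequencies across ortholog families, two-sided,
with Benjamini–Hochberg adjustment over the 61 codons at FDR 0.05; a
Wilcoxon alternative is injectable and every report records which test
was used. Frequencies are relative to all sense codons rather than
RSCU — the simpler quantity, and the one under direct compositional
pressure. The enriched set is summarised by its mean GC (both unweighted
over the three codon positions and usage-weighted) and the fraction
with G/C at position 3.

The carbon-economy comparison translates each family, tests per-amino-
acid content the same paired way, and reports mean carbon atoms per
residue per clade. The per-residue carbon table uses the whole free
amino acid (Gly 2, Ala 3, …, Trp 11); side-chain counts
(total − 2 backbone carbons) are exposed alongside, since "carbon in
the side chain" and "carbon in the residue" differ exactly by that
constant and published discussions mix the two conventions. Amino acids
are additionally binned by carbon count (2–3, 4, 5, 6, ≥9) for the
contrast between cheap and expensive residues.

## Expression phases

Phase specificity is classified from mean FPKM per life phase with the
printed thresholds applied as strict inequalities: a gene is
sporophyte-specific when dually expressed with FPKM < 5 in the
gametophyte and > 25 in the sporophyte, or when undetected (FPKM 0) in
the gametophyte with a > 10-fold contrast; gametophyte-specific is the
mirror image; constitutive requires FPKM > 5 in both phases and fold
change < 10; everything else is OTHER, including genes at exactly a
threshold. Zero handling was genuinely open: fold ratios use a
pseudocount (default 0.1), and the unique-gene clause additionally
requires the detected phase to clear the detection threshold (FPKM
> 5) — a gene at (0, 3) is barely expressed, not phase-specific. An
optional flag applies the fold clause to all genes rather than only to
genes undetected in one phase; the default is the stricter unique-only
reading. Specific clauses take precedence over the constitutive clause.
Fold-change profiles over a dehydration/rehydration series are
$\log_2((\mathrm{FPKM}_x + \varepsilon)/(\mathrm{FPKM}_\mathrm{ctrl} +
\varepsilon))$, and the summary flags genes with at least a two-fold
change at two or more stress time points.

## The simulator and what it does (not) emulate

`simulate_dataset()` evolves each gene family independently along the
input tree by exact per-site Gillespie simulation under the branch
class's rate matrix, recording every substitution event with its time,
so multiple hits are part of the ground truth rather than an unknown.
The root sequence is drawn i.i.d. from the GC-symmetric root
composition. In coding mode the root is stop-free and any event that
would create an in-frame stop is rejected and redrawn — a pragmatic
stand-in for purifying selection against nonsense codons, and the only
selection the simulator knows. There is no among-site rate variation,
no indels, no selection on amino acids, and families are exchangeable;
passing tests therefore demonstrate correctness of the machinery and
detectability of planted compositional signals under drift, not that
real data will show effects of the same size. `simulate_expression_table()`
constructs gene classes that satisfy the classification clauses by
construction (specific genes at FPKM 26–200 vs 0–4.9, constitutive
pairs within two-fold above 15, background below 5), which is what makes
the 100%-recovery test meaningful as a consistency check of generator
and classifier rather than a statistical claim.

## Numerical choices and problem sizes

Transition matrices come from the symmetrised eigendecomposition (exact
for all $t$; entries clamped at 0 and rows renormalised against
roundoff). Pruning partials are rescaled per site to avoid underflow on
deep trees. Optimisation runs until BFGS convergence with a relative
tolerance of 1e−10; parameter proposals are clamped to ±12 on the
transformed scale and non-finite likelihoods are treated as rejections.
Ties in posterior modes and Fitch resolutions break alphabetically.
Saturated difference proportions ($p \ge 3/4$) have no finite corrected
distance and are reported as NA with a warning. Degenerate paired tests
(zero-variance differences) are reported as such rather than tested.

The bundled validation experiments use a six-taxon tree (two
three-tip clades, within-clade root-to-tip path 0.5 substitutions/site)
with 100 families of 300 codons for model fitting and flux accounting
(equilibrium GC 0.8 versus 0.5, transition/transversion ratio 2), 100
families of 300 codons at a 0.85 shift for the replacement-rate
contrast, and 50 paired families of 500 codons for codon-usage and
carbon-economy recovery, with a +50% frequency shift on ten GC-rich
codons or on the Gly/Ala codon boxes. At these sizes the full test
suite and the acceptance script each run in a few minutes on a single
core, while estimator error for the class equilibria stays well inside
±0.05.

## Known limitations

* The model fixes one global transition/transversion ratio across
  classes, and branch lengths are trusted as given.
* Endpoint-based flux counting undercounts multiply-hit sites; the
  event-log comparison quantifies the gap only in simulation.
* The replacement-rate contrast between clades is sensitive to the
  measurement mode (see above); reports state which mode produced them.
* Only the standard nuclear genetic code is supported.
* The codon-usage tests assume families are comparable units across
  clades (single-copy orthologs); paralogy would violate the pairing.
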