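---
title: "Models and design choices in wseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in wseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models, the generative assumptions
of the synthetic ZW experiment, and the design decisions that were
genuinely open when the package was written — the things a maintainer
would want explained rather than rediscovered.

## The dimorphism model

Counts for gene $g$ in sample $s$ are modelled as negative binomial,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$ with variance
$\mu_{gs} + \phi_g \mu_{gs}^2$, and a log-linear mean
$$\log \mu_{gs} = \log N_s + \beta_0 + \beta_T T_s + \beta_X X_s +
\beta_{TX} T_s X_s,$$
where $N_s$ is the TMM-corrected library size (an offset), $T_s$
indicates gonad vs blastoderm and $X_s$ female vs male (male is the
reference, so sex coefficients read as log F/M). Fitting is iteratively
reweighted least squares at fixed $\phi_g$ (`glm.fit` with the
negative-binomial family, convergence $|\Delta\mathrm{dev}| < 10^{-8}$,
at most 100 iterations). All tests are 1-df likelihood-ratio tests
between nested fits, with the $\chi^2_1$ reference:

* **sex within blastoderm / gonad** drops the sex effect in that tissue
  while leaving it free in the other (a reparameterised reduced design,
  not a subset fit — all 8 samples always contribute to $\phi$-use and
  offsets);
* **ratio difference** drops the interaction $\beta_{TX}$: significance
  means the female:male ratio differs between tissues, with the sign of
  the interaction giving the direction;
* **tissue average** compares `~ tissue + sex` against `~ sex`, i.e. the
  tissue effect on the sex-averaged mean.

The "ratio difference" construction deserves a note: the study this
package models reports a robust test for the difference in female:male
fold change between tissues without printing its construction. Within a
GLM framework the tissue×sex interaction LRT *is* that test, and that is
what we implement; it is the one place where the statistical reading was
genuinely open.

False discovery rates are Benjamini–Hochberg, applied separately within
each named test — the four tests answer different questions and are
reported as separate analyses. Log2 fold changes are computed
descriptively after adding an offset-scaled pseudo-count of 0.125, so
that structural zeros (W genes in males) give large finite estimates
rather than infinities; test statistics never use the pseudo-count.

## Dispersion estimation

With 8 samples and a 4-parameter model there are 4 residual df — far too
few for stable per-gene dispersions. We therefore:

1. maximise the summed Cox–Reid adjusted profile likelihood
   ($\ell_g(\phi) - \tfrac12 \log\det X^\top W X$, ridge-stabilised for
   structurally zero groups) over a single common $\phi$, profiling the
   means out iteratively;
2. maximise, per gene, the weighted likelihood
   $APL_g(\phi) + w\,\overline{APL}(\phi)$ on a 61-point log-spaced grid
   with quadratic peak refinement, where $\overline{APL}$ is the mean
   per-gene adjusted profile likelihood and $w = 10$ effective prior
   observations;
3. clamp each tagwise value between its raw per-gene MLE and the common
   value (the shrinkage direction is an invariant of the estimator) and
   floor at $10^{-6}$.

No abundance trend is fitted: at 4 residual df a trend is noise, and the
single-prior shrinkage is a deliberate simplification. On simulated data
the common estimate matches an independent reference implementation to
within a few percent, and the three LRTs hold their nominal size
(fraction of null p-values below 0.05 within [0.03, 0.07] on a
2000-gene null simulation).

**Default dispersion prior 0.04 (BCV 0.2).** Controlled inbred lab
animals typically show biological coefficients of variation around 0.2
in bulk RNA-seq. Per-gene dispersions are drawn log-normally around the
prior with $\sigma = 0.5$, giving the spread the moderation step must
shrink. At this dispersion, 2 replicates per cell give ≥ 0.8 power at
$\alpha = 0.05$ for 2-fold dimorphism at mean counts ≥ 100 — the power
regime the factorial design was built for.

## What the generator emulates — and what it does not

`simulate_counts()` produces the study conditions the analyses assume:

* a 2 tissue × 2 sex × 2 replicate design (other replicate numbers are
  accepted for power curves);
* NB counts with FPKM-scaled means
  $\mu_{gs} = F_{gs} \cdot L_g/10^3 \cdot N_s/10^6$, library sizes
  jittered ±20%;
* **incomplete Z dosage compensation**: by default every Z gene has a
  male:female mean ratio of 1.6 — the chromosome-wide average the mean
  ratio estimator should recover; `z_noncompensated_fraction` exists for
  sensitivity runs;
* an **MHM-like locus**: 3 Z genes transcribed only in females;
* **strictly female W expression**: W, W_random and half of the
  Un_random genes (mis-assigned W material) have hard-zero male counts.
  Quantitative leakiness in males is not documented for these genes
  (detection assays show "not detected"), so the hard zero is our
  choice, with `w_leaky = TRUE` providing a 1% male leak for robustness
  tests;
* **tissue-specific autosomal dimorphism**: 50 genes per tissue, 2-fold,
  half female- and half male-biased, dimorphic in exactly one tissue
  (an interaction, which is what the ratio-difference test detects);
* **gene composition**: autosome 5000, Z 500, W 20, W_random 6,
  Un_random 40. The Z share (~9%) matters more than it looks: TMM
  normalisation estimates scaling factors from the bulk of the M-value
  distribution, and if male-biased Z genes made up an unrealistically
  large share of the transcriptome the normalisation itself would absorb
  part of the genuine dosage signal. The composition therefore mirrors
  the real chicken transcriptome's Z fraction.

Sequence-level generators: `simulate_gametologue_pair()` evolves a W
copy from a Z CDS by uniform single-nucleotide proposals accepted with
probability 1 (synonymous) or $\omega$ (nonsynonymous); stop-creating
changes are always rejected, and the start codon and terminal stop are
never mutated (both are under absolute constraint in expressed genes;
allowing start-codon loss artificially truncates ORFs downstream).
`expected_subs_per_codon` is the expected number of *accepted*
substitutions per codon (Poisson-distributed total). No
transition/transversion bias is modelled — the divergence analysis does
not estimate $\kappa$, so the generator does not encode one.
`fragmentize()` tiles a transcript into overlapping pieces with
per-junction gap dropout; `make_retroviral_decoys()` back-translates a
packaged panel of *synthetic* gag/pol-like toy proteins (not real viral
sequences) with ≤ 10% codon noise.

What passing tests on these data do **not** show: real libraries have
GC- and length-dependent biases, unannotated isoforms, multi-mapping
ambiguity, and W repeats far more degenerate than substitution-only
divergence; none of these are modelled. Results on synthetic data
validate the estimators' correctness, not robustness to every artefact
of real sequencing.

## Discovery filters

The female-specificity screen (female FPKM ≥ 1 in at least one tissue,
male FPKM ≤ 0.1 in all) uses thresholds exposed as arguments; the floor
of 1 FPKM is the conventional "expressed" cut-off and the male ceiling
tolerates index-hopping-level noise. The retroviral filter converts
local BLOSUM62 alignment scores (affine gaps 11/1) to e-values with
fixed Karlin–Altschul parameters $\lambda = 0.267$, $K = 0.041$ and
removes candidates with any ORF e-value below $10^{-3}$; panel hits in
practice sit many orders of magnitude from that boundary, so a full
gapped calibration would change nothing. The pseudogene rule (ORF
covering < 50% of the best-matching gametologue protein, or an internal
stop within the aligned span) is our construction — the filter concept
is standard but no quantitative rule is documented — and every removal
is logged with its reason.

## The scaffolder

Placement aligns each fragment locally to the Z cDNA in both
orientations (match +2, mismatch −3, gap open 5, extend 2) and accepts
placements with ≥ 80% identity over ≥ 50 bp — W/Z gametologue cDNAs are
~88–95% identical, so true fragments clear the gate comfortably.
Because gametologue divergence is overwhelmingly substitutional, when a
constant-offset (gapless) interpretation of the best local alignment
also reaches the identity threshold the *full* fragment is placed at
that offset: local alignment clips mismatching terminal bases, and
without the extension those bases would be lost from the consensus ends.
Gapped alignments fall back to column-by-column projection (fragment
insertions relative to the scaffold are dropped — a documented
limitation, irrelevant under substitution-only divergence).

Merging joins adjacent placements overlapping ≥ 40 bp at ≥ 95%
agreement (common overlap-assembler defaults; the source study delegated
this step to an external assembler without printing values), with
majority-vote consensus, per-base depth, and ties broken by source
priority (annotation > genome-guided > de-novo, since annotated exons
are curated) then placement order. Sub-threshold or disagreeing
overlaps leave both sides in separate contigs and are logged as
conflicts. Gaps between contigs are bridged with N-runs sized by the
Z-scaffold distance — gametologue cDNAs are largely collinear, making
scaffold distance a reasonable gap proxy — and completeness is the
non-N fraction of the scaffold's longest plus-frame ORF. Overlapping
contigs (negative inferred gaps, the conflict case) are never force-
joined; the longer chain wins and the rest is reported as secondary.
Coordinates are 0-based half-open internally; printed reports are
1-based inclusive.

## Divergence estimation

dN/dS uses the classical counting estimator: per-codon synonymous site
fractions (changes to stops count as nonsynonymous), observed
differences partitioned by averaging over all equally-weighted minimal
mutational pathways (pathways through stop codons excluded, with an
all-paths fallback if every route is blocked), and the Jukes–Cantor
correction $d = -\tfrac34\ln(1 - \tfrac43 p)$. Codon alignment is
derived from the end-gap-free global protein alignment, back-mapped to
nucleotides with gapped codons dropped. Sentinels follow the catalog's
printing convention: $d_N = 0$ is reported as $\omega = 0.000$
regardless of $d_S$; $d_S = 0$ with $d_N > 0$ is *undefined*, never
infinity; $p \ge 3/4$ is *saturated*. One subtlety of pathway
averaging: a codon that accumulated two synonymous hits can route
through a nonsynonymous intermediate, so purely synonymous evolution
yields $d_N$ near — not exactly — zero; the estimator is kept faithful
rather than patched. Sliding windows default to 50 codons at step 10
(the profile figure this mirrors does not state its parameters; both
are arguments), and sentinel windows are emitted as missing values so
the axis stays complete. Maximum-likelihood codon models and codon-
frequency corrections are out of scope.

The combined-expression comparison sums W and Z counts per sample
(female totals reflect W+Z, male totals the two Z alleles) and applies
the NB sex LRT to the summed counts per tissue, flagged at P < 0.01; the
test behind the original figure's significance stars is unnamed, and
re-using the package's own sex test on summed counts is our choice.
Significance is decided only by that test, never by a fold-change
heuristic.

## Problem sizes and numerical conventions

The test-suite and acceptance computations use the sizes at which the
statistical claims are stable: 2000-gene null simulations for size
calibration, 500 Z genes for dosage recovery, 50 replicate pairs × 300
codons per $\omega$ setting for divergence recovery, 20 genes × 5–9
fragments for assembly round-trips. Seeds are fixed in the generator
configuration (`seed` is a `sim_config` field; per-stage seeds are
derived by hashing the stage name, so any stage reproduces independently
of execution order). Ties in placement are broken by leftmost scaffold
start then plus orientation; all tolerances and thresholds named above
are exposed as function arguments rather than constants.

## Known limitations

* The dispersion moderation has no trend component; experiments with
  strong mean–dispersion trends will over-shrink at the extremes.
* The scaffolder assumes one W gene and its Z partner per invocation; it
  does not model splice graphs, multi-copy families (multi-copy
  expression must be summed upstream), or simultaneous multi-gene
  scaffolding.
* Insertions in W relative to Z are dropped during projection; exact
  recovery is only guaranteed under substitution-only divergence.
* The retroviral e-value calibration is fixed, not estimated from the
  panel; with panels of unusual composition the absolute e-values (not
  the ranking) may shift.
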