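---
title: "Codon usage bias, selection, and effective population size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias, selection, and effective population size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubne)
```

## The scientific question

Synonymous codons are not used at equal frequencies; this codon usage bias
(CUB) is commonly attributed to weak selection, whose efficacy scales with
the effective population size $N_e$ (selection is effective roughly when
$|N_e s| > 1$). The package implements the full analytical toolkit needed
to ask whether $N_e$ predicts CUB: background-corrected bias metrics,
three independent tests for selection on codon usage, and phylogenetically
controlled comparative statistics — together with a simulator that
generates every input under known truth, so each stage can be validated
end to end without genome downloads.

## Quantifying bias: ENC and ENCp

For each synonymous family $a$ with $k_a$ codons, observed within-family
frequencies $p_i$ and family total $n_a$, the homozygosity estimate is

$$\hat F_a = \frac{n_a \sum_i p_i^2 - 1}{n_a - 1},$$

and the effective number of codons combines degeneracy-class means
($\bar F_2$ over the nine twofold families, etc.):

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped to $[20, 61]$: 20 when every amino acid uses a single codon, 61
when every family is uniform. ENC's null assumes equal base frequencies,
so mutational bias alone registers as "bias". ENCp corrects this by
deriving each codon's expected frequency $e_i$ from the local background
base composition (2 kb flanks on each side, or concatenated introns of at
least 1000 bp) as the product of the three positions' base frequencies,
normalized within the family, and replacing $\hat F_a$ with

$$\hat F'_a = \frac{\chi^2_a + n_a - k_a}{k_a\,(n_a - 1)}, \qquad
  \chi^2_a = n_a \sum_i \frac{(p_i - e_i)^2}{e_i}.$$

With a uniform background $\hat F'_a = \hat F_a$ exactly, so ENCp reduces
to ENC (asserted to $10^{-9}$ in the tests). The pooled
$\chi^2 = \sum_a \chi^2_a$ with $df = \sum_a (k_a - 1)$ gives a per-gene
significance test of observed versus expected usage; genes are corrected
across the genome by Benjamini–Hochberg.

Numerical choices: families with $n_a < 2$ are excluded from their class
mean ($\hat F$ is undefined at $n_a = 1$); families with $\hat F \le 0$
(possible at small $n_a$) are excluded as uninformative; a missing
threefold class mean is imputed as the average of the two- and fourfold
means, the standard ENC convention; a class with no usable family and no
imputation path makes the gene's value `NA` rather than a guess. The
$\chi^2$ pool includes only families in which every expected count
$e_i n_a \ge 1$, a small-expectation validity guard. Reported values are
capped, with the uncapped number kept in an attribute, since means of
capped values are biased.

The per-family report uses $1/\hat F'_a$ — the effective number of codons
used within one family ($k_a$ at uniform usage, 1 at single-codon usage) —
capped to $[1, k_a]$.

## Three tests for selection

**Per-gene ENCp significance.** The pooled usage $\chi^2$ above, with BH
correction across genes. On synthetic data this is calibrated (uniform
p-values under the null) and powerful (essentially every 500-codon gene is
detected at $S = 2$).

**FMutSel0 vs FMutSel.** The mutation–selection codon substitution model
assigns each sense codon a fitness $F_j$; single-nucleotide changes
$i \to j$ occur at rate

$$q_{ij} = \kappa^{\mathbb 1[\mathrm{ts}]}\, \pi^*_{b(j)}\, h(S_{ij}),
 \qquad h(S) = \frac{S}{1 - e^{-S}},\ S_{ij} = F_j - F_i,$$

with mutational base frequencies $\pi^*$ and transition/transversion
ratio $\kappa$. The chain is reversible with stationary law
$\pi_j \propto \pi^*_{j1}\pi^*_{j2}\pi^*_{j3} e^{F_j}$. Under FMutSel0
fitnesses are equal within each synonymous family (19 free amino acid
fitnesses), so codon usage evolves by mutation alone; FMutSel frees all 60
codon fitnesses (one fixed at zero for identifiability). Twice the
log-likelihood difference on a pairwise alignment is referred to
$\chi^2_{41}$ (60 − 19 parameters); the 5% critical value is 56.94. Stop
codons are excluded from the state space entirely.

The likelihood engine works on the 61×61 codon-pair count matrix of a
masked alignment, computing $P(t) = e^{Qt}$ through the symmetrized
eigendecomposition $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}\,\pi$), in
compiled code, with an analytic gradient obtained by the spectral
(Daleckii–Krein) derivative of the matrix exponential propagated in
reverse mode — so a full 65-parameter gradient costs about three
likelihood evaluations. Optimization is bounded quasi-Newton (L-BFGS-B)
over log/softmax-transformed parameters from a data-driven start
(empirical base and codon frequencies, raw codon mismatch fraction for
$t$) plus seeded random restarts; the FMutSel fit is warm-started from
the FMutSel0 optimum. Pairwise likelihoods are the core engine, matching
the species-pair analyses the method serves; trees are out of scope.

From an FMutSel fit, $|N_e s|$ for every synonymous single-nucleotide
codon pair is $|S_{ij}|/2$ under the $S = 2 N_e s$ convention (a
configurable switch, since the literature is loose about the factor of
two); the package reports both the usage-weighted and unweighted medians
over pairs because the original analyses do not say which was summarized.

**Polarized McDonald–Kreitman on codon preference.** Within each
synonymous family (sixfold amino acids split into their fourfold and
twofold subfamilies), the genome-wide most-used codon is "preferred" and
the least-used "unpreferred". Third-position variants are polarized
against two outgroups (ancestral = the agreed outgroup base; disagreeing
or triallelic sites are excluded), classified as unpreferred→preferred or
preferred→unpreferred — only transitions between the family's two extreme
codons count; everything else is "other" and excluded, the reading most
consistent with a single preferred and unpreferred codon per family — and
cross-tabulated as polymorphic versus fixed. Independence is tested by
Pearson $\chi^2$ with Yates continuity correction (the printed reference
statistics reproduce only with the correction, which pins down the
original practice), and tables of different size are compared through
$1000 \cdot \chi^2 / N$.

The null control forces intronic variants into the third position of an
"imaginary codon" built from the two preceding bases in coding
orientation (minus-strand genes reverse complemented first), excluding
sites within 20 bp of an exon–intron boundary; the intronic sites then
pass through the identical preference machinery. CpG mis-polarization —
two independent deaminations on the outgroup lineages making a conserved
ingroup state look derived — is flagged on the quintet centred on the
varying base: outgroup `..TG.` with ingroup-derived `..CG.` (coding
strand), or outgroup `.CA..` with ingroup-derived `.CG..` (opposite
strand). Filtering drops flagged sites before counting.

## Phylogenetic comparative layer

PGLS regresses a response on a predictor across tips with residual
covariance $C(\lambda)$: diagonal root-to-tip depths, off-diagonals
$\lambda$ times shared path length. $\lambda$ is profiled on $[0, 1]$ by
restricted maximum likelihood — REML, the convention of `nlme::gls` with
`corPagel`, against which the implementation is cross-checked in the
tests; plain ML is available but is strongly downward-biased for
$\lambda$ at a few dozen tips and would not recover simulated values.
The closed-form GLS fit makes the estimates exactly invariant to tip
input order; `order_robustness()` demonstrates this by refitting under
permuted orders (the historical motivation being that iterative gls
optimizers can be order-sensitive) and reports medians and the spread.
Slope inference uses $t = b/\mathrm{SE}$ with $df = n - 2$, two-sided,
and $r = \mathrm{sign}(b)\sqrt{t^2/(t^2 + df)}$.

Independent contrasts and Brownian ancestral states are delegated to
`ape::pic` and `ape::ace` (with polytomies — e.g. a three-species
trichotomy — resolved to zero-length branches for the contrast
algorithms, while the PGLS covariance handles them natively); the test
suite checks both against brute-force recursions and the GLS generalized
mean. The nonparametric trend test orients each node so the x-contrast is
positive and tests the count of co-directional y-contrasts against 1/2
with a two-sided exact binomial — chosen over a 2×2 Fisher construction,
whose exact original form for this one-sample count is ambiguous.
Compartment comparisons (X vs autosome, centromeric vs telomeric under a
10 Mb boundary window, configurable to 5 or 20) use
`value ~ group + exon_length + intron_length` ANCOVA with untransformed
lengths by default (a log switch exists; the original transformation is
unstated), BH-corrected across species. Bootstrap median intervals are
percentile intervals over 10,000 resamples by default.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions. Defaults: mutational
background $\pi^* = (0.295, 0.205, 0.205, 0.295)$ (~41% GC, the mammalian
genome-wide figure), $\kappa = 4$ (primate-like transition bias),
500-codon genes (the human median is near 470), two introns totalling
1.2 kb (enough to clear the 1000 bp intron-background minimum), 2 kb
flanks, a 100-chromosome ingroup sample (the scale of the Yoruban
resequencing panel; the exact original cutoff is unstated, so it is an
explicit parameter), pairwise branch length 0.05 (a few percent codon
divergence, the human–chimp scale), and a 41-tip tree for trait
simulations. $S = 0$ is the neutral default; selection scenarios set
$S$ per run (the power analyses use $S = 2$, squarely in the weak
selection regime $|N_e s| \sim 1$).

Coding sequence is drawn codon-by-codon from the stationary law
$\pi_j \propto \pi^*_{j1}\pi^*_{j2}\pi^*_{j3}e^{F_j}$ — by construction
the same distribution the substitution model fits, an identity asserted
to $10^{-12}$ — with the preferred (fitness $+S$) codon of each family
being the C-ending one where available, else G-ending, mirroring the
GC-ending optimal codons of mammals and making CpG mis-polarization act
on the unpreferred→preferred row, as in the empirical tables. Introns and
flanks are neutral i.i.d. draws from $\pi^*$. Codons are independent
(no autocorrelation): every downstream statistic is count-based, so
linkage along the sequence would add realism but not change any expected
value. The polymorphism/divergence sampler is a two-allele stationary
scheme — a variant site is polymorphic at rate $\theta_p \mu$ and fixed
at rate $\theta_f \mu h(S)$, with derived allele counts from the neutral
1/k spectrum — rather than a forward simulation: the MK table only needs
correct fixed/polymorphic proportions under $S$. CpG artifacts arise at a
rate proportional to the squared per-lineage deamination rate
(`cpg_base_rate * cpg_multiplier`, one deamination per outgroup lineage),
on outgroup branches only by default, isolating the mis-polarization
mechanism the filter targets.

Passing tests on these data therefore show the statistics are correct
and calibrated under the stated model; they do not show robustness to
features the generator omits: linked selection and demography (no
recombination, no bottlenecks — $N_e$ enters only through $S$ and the
trait model), alignment error, annotation error, selection on intronic
sites, or context-dependent mutation beyond the CpG artifact itself.

## Validation design and problem sizes

The test suite checks every derived value against an independent oracle
(brute-force histograms, textbook-formula transcriptions, `Matrix::expm`,
`chisq.test`, `nlme::gls + corPagel`, recursive contrasts) and runs the
calibration/recovery properties at these sizes, chosen so each suite
completes in a few minutes on one core while retaining asymptotic
validity: MK null calibration at 200 replicates of ~3,000 sites; CpG
rescue at 60 replicates with multiplier 25; LRT null calibration at 200
replicates of 1,000-codon pairwise alignments (pilots showed the
$\chi^2_{41}$ reference is already accurate there; still "reduced" in the
sense that the recovery experiments use 10,000–40,000 codons); PGLS slope
recovery at 500 replicates of 41 tips. Rejection-rate assertions use
two-sided 99.8% binomial bands around the nominal 5% computed with
`qbinom`, fixed in advance. All randomness flows through explicit seeds;
`run_simulate()` is byte-reproducible, asserted by the determinism test.

## Known limitations

* The pairwise likelihood conditions on two sequences; no tree pruning,
  no among-site rate variation, no $\omega$.
* $\hat F$-based metrics have $O(1/n_a)$ finite-sample wobble: a tenfold
  count inflation shifts ENC noticeably below a few hundred counts per
  family, which is why the estimator-consistency check uses large totals
  and why genes under 100 codons are excluded throughout.
* The MK table counts only the extreme codon pair per family; any signal
  carried by middle-ranked codons of fourfold families is deliberately
  ignored.
* Preference designation from genome-wide counts is itself an estimate;
  under weak selection the designated and true preferred codon can
  disagree in nearly-neutral families, which only dilutes the contrast
  (a conservative direction).
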