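---
title: "Ancestral-allele QTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral-allele QTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own method: the models it
fits, the parameters that matter, what the synthetic data generator does
and does not emulate, and the choices made where the design was
genuinely open.

## The two QTL models

A connected multi-cross design crosses a set of inbred parent lines
into biparental families.  The classical connected marker-regression
model gives each parent one additive effect per locus,

$$Y_{dn} = \mu_d + \sum_{l} \sum_{ij} p^l_{dn,ij}\,
  (\alpha^l_i + \alpha^l_j) + \varepsilon_{dn},$$

with $p^l_{dn,ij}$ the multipoint probability of parental-origin
genotype $ij$ given the markers.  Its assumptions: purely additive
allelic effects identical across families (no allele-by-background
interaction), homoscedastic Gaussian residuals, and inbred parents so
that each parent transmits a single haplotype.  Dominance and epistasis
terms, per-family variances and the disconnected (per-family) model are
out of scope here.

The LD model plugs in a per-locus partition $f^l$ of the parents into
ancestral-allele classes and replaces $\alpha^l_i$ by
$\alpha^l_{f^l(i)}$.  Its extra assumption is the ancestral-allele
hypothesis: parents of one class transmit the same allele at that locus.
When every class is a singleton the two models coincide exactly — the
package's tests assert bit-level equality of the two scans in that case.

Within each locus term the class effects carry a sum-to-zero constraint.
Some constraint is needed because class dosages sum to 2 for every
individual (hence are confounded with the family means); sum-to-zero
keeps the effects interpretable as deviations and leaves the F test
invariant to the choice.  Family means are always free parameters.

Because the number of classes — and so the degrees of freedom of the
locus F test — changes along the genome, scan positions are compared on
the $-\log_{10}(p)$ scale of the incremental F test rather than by the
F statistics themselves.  A locus with a single class carries no
testable term; the scan reports $-\log_{10}(p) = 0$ there, and a
rank-deficient locus term is tested at its actual rank.

## The similarity score

At a scan locus $t$ the haplotype pair $(i, j)$ scores

$$s^t_{i,j} = \sum_k w_1(x^t_k)\, I(h_{i_k}, h_{j_k})
  + \sum_{k = l'}^{r'} w_2(x^t_k),$$

the first sum over the markers of the window (alike-in-state indicator
$I$), the second over the longest common segment $[l', r']$.  The score
is normalized by the complete-data self-similarity $s^t_{\mathrm{map}}$,
so it does not grow with window length or marker density, and blended
with a kinship prior:

$$S^t_{i,j} = P^t\, \tilde s^t_{i,j} + (1 - P^t)\, K_{i,j}.$$

Design choices the formulas leave open:

* **Longest common segment.**  Defined here as the maximal run of
  consecutive alike-in-state window markers that contains the marker(s)
  nearest to $t$; if the nearest marker mismatches, the segment is empty.
  When two markers tie for nearest, the better-scoring run among the
  candidates is taken.  This reading makes the segment a local property
  of the window centre, consistent with how the missing-data options
  behave there.
* **No $w_2(0) = 0$ convention.**  The original formulation of the
  score forced the segment weight to vanish at the centre so the term
  resembled a length measure; that constraint serves no purpose here and
  uniform or constant segment weights are the useful defaults, so it is
  dropped.
* **$s_{\mathrm{map}}$ under missing data.**  Computed assuming complete
  data (both sums over all window markers), so the normalizer depends
  only on map geometry — and therefore so does the reliability $P^t$,
  which can be computed once per map rather than per data set.
* **Sparse-window rule.**  Windows with at least `sparse_min` markers
  (default 10) get $P^t = 1$; sparse windows get
  $P^t = s^t_{\mathrm{map}} / s^*_{\mathrm{map}}$ with the maximum taken
  over sparse windows only.  Normalizing over all windows would drive
  $P^t$ toward 0 on any moderately marked region of a genome with one
  very dense stretch.  An empty window has $P^t = 0$: the score falls
  back on the kinship alone.  With no sparse windows every $P^t$ is 1.

### Weight functions

All density-type weights are scaled so the window of length $L$ carries
total mass 0.95 (in cM$^{-1}$ units):

| kind | form on $|x| \le L/2$ | shape rule |
|---|---|---|
| `exponential` | $\lambda e^{-\lambda |x|}$ | $1 - e^{-\lambda L/2} = 0.475$ (0.475 per half-window) |
| `laplace` | $(\lambda/2) e^{-\lambda |x|}$ | $1 - e^{-\lambda L/2} = 0.95$ |
| `gaussian` | $N(0, \sigma^2)$ density | $\sigma = (L/2) / \Phi^{-1}(0.975)$ |
| `uniform_density` | $0.95 / L$ | — |
| `constant0/1` | $0$ / $1$ | — |

The exponential kind is the default for $w_1$ because linkage
disequilibrium decays exponentially per generation; `uniform_density`
is the default for $w_2$ so the segment term reflects segment length.
The Laplace rule is stated loosely in the literature ("fitted to the
window length"); fitting the symmetric window mass to 0.95, like every
other density kind, is the natural reading and the one implemented.
Default window: 20 cM — long windows suit highly related panels that
share long haplotype blocks; unrelated panels warrant shorter ones.

### Missing marker data

Three policies resolve a comparison involving a missing allele:
`true` (counts as a match; the default), `false` (counts as a
mismatch), `non_assigned` (contributes no weight).  For the
alike-in-state sum, `false` and `non_assigned` are identical.  For the
segment, `false` breaks the run anywhere; `non_assigned` also breaks it
— except at the window centre, where missing comparisons are skipped and
the segment starts at the nearest informative marker on each side (both
sides are tried, the better run wins).  Bridging interior gaps was
rejected because it would make isolated missing values behave
differently from the `false` policy away from the centre, which is the
documented equivalence.

### Kinship

The default kinship is the genome-wide alike-in-state proportion over
markers observed in both haplotypes.  A pair with no jointly observed
marker gets $K = 0$ with a warning.  A user kinship matrix (e.g. from a
pedigree) can be supplied instead.  The null samplers always use the
identity kinship, which models the independence of the simulated
haplotypes.

## Clustering

At each locus, edges with $S \ge$ threshold survive and connected
components (transitive closure) form the classes.  Class ids are
canonical — numbered by smallest member index — so partitions can be
compared as label-free set partitions; the clustering-change count
between consecutive loci uses that comparison.

The threshold is the empirical $(1-\alpha)$ quantile (inverse-CDF order
statistic, `quantile(type = 1)`; the estimator had to be pinned down
since an empirical quantile has several conventions) of a pooled null:

* **Equilibrium sampling** draws each marker independently and
  uniformly over the alleles observed at that marker in the panel —
  monomorphic markers stay monomorphic, multi-allelic markers keep
  their allele count.  It is the most entropic null and yields the
  smallest thresholds.
* **Mosaic sampling** rebuilds haplotypes as founder-block mosaics: per
  chromosome, $B \sim \text{Poisson}(N_G L_c)$ breaks ($L_c$ in
  Morgans), uniform break positions, each block copied from a uniformly
  drawn founder.  Break positions are drawn independently for each
  simulated haplotype.  $N_G \approx 500$ generations is enough for the
  threshold to stabilize; the threshold is non-increasing in $N_G$.

Defaults: threshold method with equilibrium sampling, $\alpha = 0.05$,
200 repetitions.

The HMM alternative fits, per haplotype pair, Gaussian-emission HMMs
with 2, 3 and 4 states to the similarity series (one HMM per pair; a
shared fit across pairs would force a common geometry that related and
unrelated pairs do not share), selects the state count by BIC, decodes
by Viterbi and maps only the state with the highest mean to "shared".
Numerical choices: 5 EM restarts seeded from a master seed; emission
variances floored at $\max(10^{-8}, 10^{-4}\,\mathrm{var}(x))$ because
similarity series contain exactly repeated values (runs of 1.0) that
would otherwise collapse a state; a candidate whose best fit still holds
a degenerate state is discarded; if all candidates fail, the error
advises the threshold method.  Series shorter than 10 loci fall back to
the threshold method with a warning, and a constant series is a single
effective state, classified 1 everywhere.  The HMM assumptions
(conditional independence given the state, stationarity) are knowingly
violated by overlapping windows and uneven locus spacing; the fit is
used as a pragmatic smoother, and the package's tests check the
resulting stability claim (fewer clustering changes than the threshold
method) as a tendency, not a theorem.

## Maps, grid and coordinates

Parent lines are genotyped on a dense map; families are mapped on a
consensus map.  Markers shared by name anchor a per-chromosome monotone
piecewise-linear transfer (at least two anchors per chromosome; anchor
order must agree on both maps — "roughly colinear" is enforced strictly
because silently reordering markers would corrupt every window
downstream).  Beyond the terminal anchors the transfer extrapolates
with the nearest segment's slope, which keeps it monotone; transferred
scan loci are clamped to the parent map's marker span so every locus
owns a window.  The scan grid is the union of all consensus marker
positions and a fixed-step ladder (default 1 cM), deduplicated at
$10^{-9}$ cM; positions are real-valued cM from the chromosome start.
Clusterings serialize to a self-describing XML
(`<clustering><locus><class><parent/></class></locus></clustering>`)
with exact round-trip.

## Genotype probabilities

Parental-origin probabilities come from forward–backward over the
ordered union of marker and scan positions, with Haldane transitions
$r(d) = (1 - e^{-2d/100})/2$ — chosen to match the no-interference
Poisson crossover model that the mosaic sampler already assumes.  F2
uses the classical 3-state kernel; BC two states; RIL two absorbing
homozygote states with $r_{\mathrm{RIL}} = 2r/(1+2r)$.  F3 is handled
as a hidden F2 chain with a one-selfing-generation kernel applied at
each locus — both to read the observed F3 genotypes and to report F3
probabilities; this ignores linkage within the selfing generation and
is an explicit approximation of the full two-generation chain.  At a
fully observed marker the reported probabilities are degenerate on the
observation for every family type.  An individual with no observed
marker gets the chain prior, with a warning; a heterozygote code in a
RIL is treated as missing (with a warning) rather than an error.

## Thresholds and QTL detection

Genome-wide thresholds are Doerge–Churchill permutations of the
phenotypes, *within family*: the family means are nuisance parameters
and permuting across families would mix their distributions into the
null.  The threshold is the $(1-\alpha)$ type-1 quantile of the
per-permutation maxima of $-\log_{10}(p)$.

Multiple QTL are found by an iterative-cofactor loop: scan with the
current cofactors, add the genome-wide argmax while it clears the
threshold (loci within half the 10 cM exclusion window of a cofactor
are ineligible, and cofactors that close to the tested locus are
dropped from both models), then reposition each cofactor with the
others fixed, dropping any that no longer clears the threshold; iterate
to a fixed point, at most 20 rounds (non-convergence returns the last
state with a warning).  This is a documented approximation of the
published iterative QTL mapping algorithm, not a claim of equivalence.
The LD model re-reads $f^l$ at every evaluation, so a cofactor's class
structure always matches its current position.

## The synthetic data generator

No public data set accompanies the method — the original panels are
proprietary — so the package ships a generator that emulates their
structure: ancestors with independent equifrequent biallelic markers;
parent lines as founder mosaics (the same Poisson-break process as the
mosaic null, with truth tracks retained); a thinned consensus map;
families simulated by the exact meiosis chains of each family type,
jointly at the markers and the QTL position, so the QTL genotype is an
exact draw from its conditional given the markers — consistent with the
analysis model and deliberately favourable to it.  The phenotype is
$N(0,1)$ noise plus the additive effect times the number of mutated
alleles (0/1/2 — the natural reading of "additive").  The mutated
allele goes to the biggest ancestral-allele class at the QTL locus,
ties broken by a seeded uniform draw.  Markers at which the two family
parents are alike in state are masked to `NA`, since a real cross
carries no origin information there.

What the generator does **not** emulate: genotyping and phasing errors,
marker ascertainment, segregation distortion, missing parent genotypes,
multi-allelic markers, crossover interference, polygenic background,
or selection during line development.  Green tests therefore show that
the implementation is faithful and that the method behaves as claimed
under its own assumptions — not that those assumptions hold in any
particular real panel.

### Benchmark conditions

The default benchmark is one 150 cM chromosome, parent markers every
1 cM, a 5 cM consensus map, 12 parents, 8 F2 families of 60, window
20 cM, scan step 1 cM — a desk-scale design.  Two generator parameters
deserve their rationale:

* **Ancestor count 10.**  Calibrated so the realized mean number of
  ancestral-allele classes (about 5.7 at the default settings) matches
  the level reported for comparable real 12-parent designs (about 5.8).
  Far fewer ancestors put the benchmark in an over-clustered regime
  (mutant class of 10+ parents, few segregating families) that no real
  panel of this kind shows.
* **Mosaic generations 5.**  Gives ancestral blocks long relative to
  the 20 cM window, as in highly related breeding material.

The ancestor-recovery study uses 3 ancestors and a 0.5 cM parent map —
the marker density typical of real parent-line maps — with a mosaic
threshold; recovery is scored as the mean adjusted Rand index between
the per-locus clustering and the ancestor-of-origin truth track.

The power/precision study places one QTL at each of 20 grid positions
spread along the chromosome, 20 replicates each, additive effect 0.25,
and analyses every data set with both models.  Detection thresholds are
*design-level*: one 10% permutation threshold per model, computed once
from a no-QTL data set of the same design with 1000 permutations, as a
real analysis computes one threshold per design.  Precision at
interval $w$ is the share of detecting replicates with a detection
within $w$ cM of the truth (non-detecting replicates excluded); power
is the share of replicates with at least one detection; the two models
are compared by one-sided paired t-tests across the simulated
positions.  These sizes (20 x 20, 200 null replicates for threshold
calibration, 200 sampler repetitions) are the package's chosen desk
scale; the t-test comparisons at this scale are stochastic, and single
components can fall short of significance for an unlucky seed even
though the direction of the means is stable.

## Known limitations

* The ancestral-allele hypothesis is asserted, not tested, at each
  locus; a parent carrying a rare allele inside a big class biases the
  class effect.
* The F3 chain and the iterative-cofactor detection are documented
  approximations.
* Hard 0/1 class membership discards uncertainty; a soft (probability-
  weighted) plug-in would be the natural extension.
* The permutation threshold assumes exchangeability of phenotypes
  within family under the null — violated under variance heterogeneity
  between genotype classes.
* Thresholds, clusterings and scans all condition on the given maps;
  map error propagates unexamined.
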