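---
title: "Estimating B-cell repertoire diversity from replicate-well occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating B-cell repertoire diversity from replicate-well occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repwell)
```

## The measurement problem

Immunosequencing of the immunoglobulin heavy chain (IgH) can enumerate the
*distinct* B-cell clones in a blood sample, but PCR amplification
efficiency varies so wildly between templates that read counts are a poor
estimate of clonal abundance. The replicate-well design sidesteps this:
genomic DNA equivalent to roughly 50,000 B cells is dispensed into each of
W = 188 PCR wells, each well is amplified and sequenced with its own
barcode, and every unique 130 nt IgH sequence (covering the CDR3 and the
3' end of the V gene) is then scored only by its **occupancy** — the
number of wells it appears in, with read counts censored to
presence/absence. A clone carried by a single cell can occupy only one
well; abundant clones seed many wells. Occupancy is therefore a
digital, amplification-robust abundance proxy, and the vector of counts
$n_j$ (clones occupying exactly $j$ wells) is the sufficient statistic
for repertoire diversity.

repwell implements the full computational chain of this design:

1. **synthetic data** — a generator for ground-truth repertoires, the
   urn-style allocation of cells to wells, and error-bearing reads;
2. **consensus** — collapse of sequencing/PCR errors into predominant
   clones and construction of the occupancy spectrum;
3. **diversity** — maximum-likelihood estimation of richness and
   clonality from the spectrum (`fit_diversity()`, the package's central
   model object);
4. **annotation** — germline V/D/J assignment, CDR3 extraction,
   productivity and somatic hypermutation (SHM) calling;
5. **descriptives** — repertoire overlap, V usage, CDR3 length
   distributions, SHM-by-occupancy tables and per-position SHM profiles
   with AID motif annotation.

## The abundance model

Let clone $i$ contribute template cells to the pooled sample with
intensity $\lambda_i$, and let intensities be i.i.d.
$\mathrm{Gamma}(\alpha, \theta)$ (shape/scale). Cells are allocated to
wells uniformly, so conditional on $\lambda$ the per-well counts are
independent $\mathrm{Poisson}(\lambda/W)$ and the clone's occupancy is

$$ J \mid \lambda \;\sim\; \mathrm{Binomial}\!\left(W,\; 1 -
   e^{-\lambda/W}\right). $$

Marginalising over the gamma density with its Laplace transform gives a
closed-form mixture pmf

$$ P(j) = \binom{W}{j} \sum_{m=0}^{j} \binom{j}{m} (-1)^m
   \left(1 + \frac{\theta (W - j + m)}{W}\right)^{-\alpha}. $$

For large richness $S$ the spectrum counts $n_j$, $j \ge 1$, are treated
as independent Poisson with means $S\,P(j)$; occupancy 0 is unobserved.
Up to a constant the log-likelihood is
$\ell = \sum_{j\ge1} [\,n_j \log(S P_j) - S P_j\,]$, and for fixed
$(\alpha, \theta)$ the richness step is analytic:
$\hat S = n_{\mathrm{obs}} / (1 - P_0)$ — the zero-truncation correction.
`fit_diversity()` therefore optimises only $(\log\alpha, \log\theta)$
numerically (Nelder–Mead over the profile likelihood, four fixed starts
spanning dispersed to uniform regimes, convergence tolerance 1e-8 on the
profile deviance) — a tandem analytic/numeric scheme. The $\alpha$–$\theta$
ridge is real: spectra dominated by occupancy 1–3 constrain roughly three
moments, so multi-start matters more than optimiser polish.

**Clonality** summarises abundance uniformity on $[0,1]$:
$1 - H/\log S$, where $H$ is the Shannon entropy of the clone frequency
vector. For the fitted gamma model the expected entropy of $S$ normalised
gamma intensities obeys the large-$S$ identity
$H = \log S + \log\alpha - \psi(\alpha + 1)$, which is scale-free in
$\theta$, exact in the digamma closed form, and is what the default
evaluates; a 64-node generalised Gauss–Laguerre quadrature of
$E[\lambda\log\lambda]$ is retained (`method = "quadrature"`) purely as an
independent numerical route, and the two agree to well under $10^{-6}$
for shapes $\ge 0.5$ (the quadrature, not the closed form, is the less
accurate side at very small shapes, which is why the closed form is the
default). An empirical overload `clonality(p)` computes the same index
from an explicit frequency vector.

## Numerical choices

- **Occupancy combinatorics.** $P(j \mid k, W) = \binom{W}{j}\,
  j!\,S_2(k,j)/W^k$ with Stirling numbers from the two-term recurrence:
  exact integer-valued doubles for $k \le 30$, the same (all-positive)
  recurrence in log space above. The small-$k$ path is tested against
  exhaustive enumeration of all $W^k$ allocations.
- **Mixture pmf stability.** The alternating binomial sum above cancels
  catastrophically for mid-range $j$ once $W$ is large (error
  $\sim \varepsilon \binom{j}{j/2}$). Every entry carries a running
  floating-point error estimate; if any entry is untrustworthy the whole
  vector is recomputed by deterministic quadrature — composite
  Gauss–Legendre in the probability scale $u$ with
  $\lambda = F^{-1}_{\alpha,\theta}(u)$ and panels refined toward both
  tails. Because the binomial pmf sums to one at every node and the
  weights sum to one, the quadrature pmf normalises to machine precision
  by construction; per-entry accuracy is ~5e-9 across the parameter
  ranges the fits visit.
- **Error collapse.** Candidate merge targets are found by hashing the
  130 single-position wildcard masks of each sequence (O(L) exact lookups
  per singleton), never all-pairs distances. Merging is a single
  simultaneous pass from pooled pre-merge counts, which makes the
  operation idempotent; ties on "predominant" go to the higher pooled
  count, then the lexicographically smaller sequence.
- **Alignment scoring.** Ungapped, match +1 / mismatch −1, V anchored to
  the read's 5' end (all gene suffixes scanned), J to the 3' end, D
  scanned inside the junction window with a minimum score of 3. Ungapped
  is deliberate: the assay reads are short and the SHM model is
  substitution-only, so gaps buy nothing. Thresholds (V ≥ 20, J ≥ 10) are
  set so 130 nt random reads essentially never anchor — a tested
  property, not a calibration.

## What the generator emulates — and what it does not

`simulate_well_experiment()` reproduces the *structure* of the study
design: W = 188 wells (50,000 cells per well at full scale), 130 nt reads
ending at the CDR3 end, per-base substitution errors at rate 0.001
(≈ 88% of reads error-free, ≈ 94% of erroneous reads single-error —
exactly the regime that justifies the distance-1 collapse rule),
per-clone lognormal amplification noise, and two cell-type presets:

| preset | gamma shape | SHM rate (V, 3' 100 nt) | N-inserts/side | mean CDR3 |
|---|---|---|---|---|
| naive-like  | 5   | 0     | U{2..8} | 48 nt |
| memory-like | 0.5 | 0.035 | U{2..5} | 45 nt |

The SHM rate makes memory clones carry 3–4 substitutions per 100 nt of V;
the insert ranges set the 3 nt CDR3 length separation between the
compartments; the shape values put the two presets on opposite sides of
the clonality contrast while a shared $\alpha\theta$ keeps expected cell
yield equal. A `contamination` option (5% for a sorted-naive emulation)
mixes in clones drawn with the opposite preset, mimicking sort impurity,
so a "naive" sample shows ~95% zero-substitution clones rather than 100%.
Insert lengths are kept nonzero so the junction always contains
non-templated bases; with zero-length inserts allowed, the few hundred
fully germline V–D–J concatenations would recur identically across
independently generated repertoires and inflate cross-sample overlap far
above what the astronomically large real junction space permits.

The generator does **not** emulate: indel SHM, allele-level polymorphism,
realistic IMGT gene sets (the bundled reference is a labelled synthetic
stand-in with 9 V across 3 families, 4 D, 3 J and the true anchor
anatomy), class-switch structure, primer bias (the wet-lab rebalancing
procedure is out of scope), or quality scores. Green tests therefore
demonstrate the *pipeline's* correctness under its own model, not the
biological fidelity of any particular real dataset.

## Problem sizes used by the tests

Desk-scale runs keep the full 188-well geometry but shrink counts: the
consensus recovery study uses ~10^5 reads (5,000 clones, 10× coverage);
richness recovery fits use $S = 5\times10^4$ with ~30% of clones sampled
(about 15,000 observed); descriptive runs use 60,000-clone naive and
6,000-clone memory repertoires sampled to a few thousand observed clones.
The likelihood machinery itself is scale-free in these choices.

## Design decisions that were genuinely open

- **Gamma mixing.** The abundance distribution family is not dictated by
  the occupancy machinery; gamma was chosen for its closed-form Laplace
  transform (analytic marginal pmf), its clean degenerate limit
  ($\alpha \to \infty$ recovers the fixed-intensity binomial model, used
  as a cross-check), and because one shape parameter spans the
  naive/memory dispersion contrast.
- **Likelihood form.** With the occupancy-0 class unobserved, the
  Poissonized likelihood omits any separate $-S P_0$ penalty; this is
  what makes the analytic step $\hat S = n_{\mathrm{obs}}/(1-P_0)$ the
  exact profile maximiser rather than an approximation.
- **Merged-singleton evidence.** When a singleton merges into a clone it
  *transfers* its well evidence (possibly adding a new well to the
  target's occupancy). The alternative — dropping the singleton's well —
  would discard real template evidence; transfer is also the conservative
  direction for diversity, since it can only reduce the singleton count.
- **"Present multiple times"** is interpreted on read counts pooled over
  all wells (`collapse_errors()` aggregates before merging), matching the
  cross-well consensus described for the assay; a per-well variant would
  merge less and is not the default.
- **CDR3 convention.** Both anchor codons are included: the CDR3 spans
  the first base of the V conserved-cysteine codon through the last base
  of the J conserved-Phe/Trp codon (0-based, half-open). Conventions
  differ on the J side, so this is fixed explicitly and the generator,
  extractor and tests all share it.
- **Allelic-position flagging** (inherited SNPs vs SHM) is exposed as a
  configurable threshold on naive-sample recurrence rather than a fixed
  rule, since the source procedure is descriptive, not algorithmic.

## Known limitations

- Reads carrying ≥ 2 errors (~0.8% at the design error rate) are beyond
  the distance-1 singleton rule by construction; they persist as
  spurious singleton clones (~6–8% of a clone table at 8–10× coverage).
  This is a property of the published rule itself — the rule's authors
  note the error regime that makes it acceptable — and it is why the
  descriptive pattern checks characterising the *sorted populations* run
  on error-free simulations while the consensus module is scored on
  error-bearing ones.
- Occupancy saturates for clones present in nearly all W wells, so
  clonality for highly dominated repertoires is negatively biased (the
  capped-contribution behaviour is deliberate and conservative).
- No confidence intervals yet; the profile-likelihood machinery is in
  place and bootstrap/profile CIs are natural extensions.
- `fit_diversity()` flags estimates from fewer than 100 observed clones
  as unreliable rather than refusing them.

## A worked run

```{r example, eval = FALSE}
ref <- synthetic_germline_reference()
truth <- simulate_well_experiment(ref, richness = 5000, "naive-like",
                                  n_wells = 188, cells_per_well = 12,
                                  coverage = 10, seed = 1)
clones <- collapse_errors(truth$reads)
spectrum <- occupancy_spectrum(clones)
fit <- fit_diversity(spectrum)
summary(fit)
ann <- annotate_clones(clones, ref)
head(v_usage(ann$clones, ref)$family)
```

The same chain is scriptable from a shell via
`inst/cli/repwell-cli.R simulate | analyze | all`.
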