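---
title: "Genotyping and QTL mapping for backcrossed inbred line populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and QTL mapping for backcrossed inbred line populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilqtl)
```

## The population and the problem

A backcrossed inbred line (BIL) population is produced by crossing a
domesticated recurrent parent (here the tomato cultivar M82) to a wild donor
(*Solanum pennellii*), backcrossing the hybrid to the recurrent parent two
or three times, and then selfing for several generations by single-seed
descent. Each line ends up carrying a handful of wild introgressions —
homozygous donor (`PEN`) or residually heterozygous (`HET`) chromosome
segments — in an otherwise recurrent-parent background. Compared to the
classical single-introgression line design, multiple introgressions per line
give finer mapping resolution (more breakpoints) and, crucially, make
two-locus (epistatic) mapping possible.

The raw genotyping data are sparse: reduced-representation sequencing yields
on the order of one read per marker, with many markers unobserved in any
given line, sequencing errors, and occasional nonparental reads. The
package implements the full inference stack from such data:

1. parental polymorphism identification and noise filtering (`varfilter`
   functions),
2. a heterogeneous hidden Markov model that calls genotype blocks
   (`hmm_config()`, `forward_backward()`, `genotype_population()`),
3. population-wide bin construction (`merge_population_boundaries()`,
   `bin_genotype_matrix()`),
4. marginal and MC+-penalized (additive and epistatic) QTL mapping
   (`marginal_scan()`, `sparsenet_qtl()`),
5. discrete-trait fine-mapping and interval confirmation
   (`finemap_discrete()`, `overlap_qtl()`), and
6. permutation enrichment tests (`candidate_gene_enrichment()`,
   `eqtl_epistasis_enrichment()`).

A crossing-scheme simulator (`simulate_pedigree()`, `emit_read_counts()`,
`simulate_traits()`) generates populations with known truth so that every
stage is testable without external data.

## The simulator

Meiosis follows a no-interference model: per chromosome, the crossover
count is Poisson with mean equal to the genetic map length in Morgans and
crossover positions are uniform in cM, mapped to bp through the genome's
genetic map (constant cM/Mb by default, or a piecewise-linear map). This is
exactly the Haldane model; no crossover interference is imposed because the
genotyping model downstream only relies on large-distance behaviour, where
all standard map functions agree. Pedigrees are advanced by single-seed
descent: one offspring carried per generation, matching an inbred-line
population.

Under this scheme a neutral locus is heterozygous with probability
$2^{-(b+s)}$ after $b$ backcrosses and $s$ selfings, and homozygous-donor
with probability $(2^{-b} - 2^{-(b+s)})/2$; `expected_state_fractions()`
evaluates this closed form, and the simulator reproduces it to Monte-Carlo
accuracy. For the classic mixed design (half BC$_2$ selfed five times, half
BC$_3$ selfed four times) the genome-wide expectation is roughly
0.90 : 0.01 : 0.09 for M82 : HET : PEN, close to the 0.88 : 0.02 : 0.10
priors used by the HMM.

Read counts emulate reduced-representation coverage: marker depth is
zero-inflated Poisson (defaults: mean 1 read, 20% dropout), each read
reports the donor allele with probability `seq_error`, `0.5`, or
`1 - seq_error` for M82 / HET / PEN, and a small `other_rate` produces
nonparental reads. Sequence-level artefacts (restriction-site loss, mapping
bias, repeat contamination) are *not* modelled; passing tests therefore
demonstrate correctness of the inference given this generative model, not
robustness to every artefact of real libraries.

Traits are simulated over the bin matrix as a sum of planted additive
effects (on donor-presence indicators), planted pairwise products, a block
random effect, a per-plant effect, and residual noise, mirroring a
randomized-block field design; per-line means over replicates are the
mapping input. `plant_architecture()` draws identifiable architectures:
additive bins are mutually separated (default 5 Mb) so each planted effect
has its own correlation neighbourhood, and planted pairs are
cross-chromosome or well-separated, because a tightly linked pair's product
column is nearly collinear with a single broad locus and no method can
attribute it (the same reasoning motivates the 20 cM reporting filter for
inferred epistatic QTL).

## Polymorphism filtering

Candidate parental markers are sites where the two parents' majority
alleles differ; ties discard a site, and sites where both parents share a
non-reference allele (reference-specific variants) drop out automatically
because the majorities agree. Noise reduction then requires strictly more
than 90% of each parent's reads to match that parent's assigned allele.
Finally a population-level filter, computed from counts pooled over all
lines, keeps sites whose donor-allele ratio lies inside the chromosome-wise
25th–75th percentile window (linear-interpolation quantiles, inclusive
bounds), whose nonparental read fraction is strictly below 0.025, and whose
pooled coverage is at most 2000 reads. The percentile window is estimated
once from the full candidate set and carried on the result, so re-applying
the filter to its own output is a no-op; the window is computed over sites
with at least one pooled read (configurable).

## The heterogeneous HMM

Three hidden states (M82, HET, PEN) with a transition matrix that varies
with the genetic distance $d$ (cM) between adjacent markers:

$$P(\text{stay}) = e^{-d^2 / 2\sigma^2}, \qquad
  P(\text{change to a given other state}) = \frac{1 - e^{-d^2/2\sigma^2}}{2}.$$

This Gaussian kernel matches the Haldane/Kosambi asymptote of one half at
large distances but has zero slope at $d = 0$: at sub-cM marker spacing the
chain is strongly held in its current state, which is what makes the calls
robust to isolated noisy markers at dense spacing. The length scale
defaults to $\sigma = 0.5$ cM. The off-diagonal mass is split equally
between the two alternative states by default (`"prior"`-weighted splitting
is available); equal splitting is the unique symmetric choice and keeps
every row summing to one.

Emissions contract a per-marker genotype-probability triple (binomial
likelihoods of the read counts under each state, normalized — i.e. scaled
likelihoods under a uniform prior; uniform when a marker has no reads) with
a confusion kernel that assumes a 1% genotyping error split evenly between
the two wrong states. Initial state probabilities are 0.88 : 0.02 : 0.10
for M82 : HET : PEN, the rough crossing-scheme expectation. Decoding is
posterior (forward–backward) rather than Viterbi; the scaled recursion runs
in C++ and handles chains of hundreds of thousands of markers without
underflow. Marginal posteriors are turned into calls with a
threshold-and-hysteresis rule: the running call switches state only at a
marker where the new state's posterior reaches 0.95; a sub-threshold
leading stretch is assigned the prior-modal state (M82) and flagged.
Segment boundaries in bp are placed midway between the last marker of the
outgoing state and the first marker of the incoming state, which is
unbiased when markers are uniformly placed; terminal segments extend to
the chromosome ends.

Baum–Welch estimation of $\sigma$ and Viterbi decoding are deliberately out
of scope.

### What recovery tests show

The acceptance suite simulates 120 lines on a three-chromosome 90 Mb
genome with markers every 10 kb at a mean depth of one read and 1%
sequencing error, and requires at least 95% of true donor blocks of 500 kb
or more to be recovered with both boundaries within five times the local
covered-marker spacing (the spacing averaged within 250 kb of the true
boundary — boundary precision is limited by where reads actually landed),
and every heterozygous block of 500 kb or more to be called HET over most
of its span. Two genuine failure modes remain and are counted against the
method: sub-50 kb recurrent-parent slivers between two introgressions can
be invisible at 1x coverage (the blocks merge), and HET-edge boundaries
drift further than homozygous ones because single reads carry much less
evidence against HET than against a homozygous state. Separate stress
fixtures mirror hard real-data cases: high read noise, 0.2x coverage, and
a narrow 300 kb introgression.

## Bins and the genotype matrix

Per line, introgressions are maximal non-M82 runs; blocks supported by
fewer than two markers are treated as residual genotyping error (the
smoother reassigns them to background before bin construction). The sorted
union of all introgression endpoints partitions each chromosome into
sub-bins within which, by construction, no line changes genotype — the
defining bin property, validated when the lines-by-bins genotype matrix
(0 = M82, 1 = HET, 2 = PEN) is read off the segment tilings. Bins not
covered by any introgression are excluded from the mapping set and listed
in a coverage report. An optional refinement pass snaps boundaries closer
than a tolerance to their midpoint (off by default: the original boundary
fine-tuning was human-supervised, and automated snapping is an
approximation). Genes from a GFF3 annotation are attached to every bin
their span overlaps (half-open interval convention internally; 1-based
inclusive at GFF3 and pileup interfaces, with conversion centralized in
the readers).

For mapping, donor presence codes HET and PEN alike as 1 (both are donor
DNA); a dosage coding (0, 0.5, 1) is available.

## QTL mapping

**Marginal scan.** Each bin's presence indicator is regressed on the trait
separately; two-sided slope p-values are Benjamini–Hochberg adjusted across
the testable bins (both presence classes with at least 3 lines) and called
significant below a q-value threshold, 0.001 by default. (The looser 0.01
threshold sometimes used for reporting is a config value, not a different
method.)

**Penalized mapping.** The additive model fits all bins simultaneously; the
epistatic model adds one product predictor for every unordered bin pair
actually observed in the population (at least one line carrying donor DNA
at both bins — unobserved combinations carry no information). Coefficients
are estimated by cyclic coordinate descent under the MC+ penalty family,
whose univariate thresholding operator is zero up to $\alpha$, a relaxed
linear zone up to $\alpha\gamma$, and the identity beyond; $\gamma \to
\infty$ recovers the lasso and $\gamma \to 1^+$ hard thresholding. The
solver standardizes columns to unit mean square (dropping constants and
exact duplicates — coincident bins or coincident pair products carry the
same information and the correlation intervals recover them afterwards),
and traverses a log-spaced $\alpha$ path from the all-zero model downward.
At each $\alpha$ the $\gamma$ sequence is relaxed from most convex to most
concave, each solve warm-started from the previous $\gamma$'s solution at
the same $\alpha$. This double warm start is essential: independently
cold-started concave paths converge to poor local minima in which even
dominant true effects are absent, whereas relaxation keeps the nonconvex
solves on the solution branch reached from the convex end. Convergence is
declared when no coefficient moves more than $10^{-7}$ in a sweep, with a
cap of $10^4$ sweeps (hitting the cap is flagged and the best iterate
kept).

**Tuning.** $(\alpha, \gamma)$ are chosen by ten seeded six-fold
cross-validations; each repetition picks the grid point minimizing mean
held-out squared error (the minimum rule, not the one-standard-error rule),
and the ten selected $\alpha$s and $\gamma$s are arithmetically averaged —
averaging stabilizes an otherwise fold-sensitive choice — then snapped to
the nearest grid points (log scale) for the final full-data refit. The
$\alpha$ path is computed once from the full data so selections are
comparable across folds and repetitions.

**Intervals and reporting.** Because any sparse selector keeps one
representative of a correlated group, the empirical QTL interval of a
selected bin is the set of bins whose presence columns correlate with it at
$r \ge 0.90$. For epistatic reporting, same-chromosome pairs closer than
20 cM (bin midpoints, via the genetic map) are removed — such pairs are
indistinguishable from broad single loci — and the strongest ten pairs by
coefficient magnitude are reported. No per-line random effect is included
in the penalized models; with uneven introgression coverage this is a known
false-positive risk for epistatic terms, documented rather than modelled.

### What the planted-architecture study shows

The acceptance study simulates 200 lines on a four-chromosome 60 Mb
genome, plants five additive effects (magnitude 1 trait SD, mutually
separated) and two interaction effects (magnitude 2: an interaction is
observable only in the co-carrier lines — about 8% of the population at
the eligibility floor — so a power study plants interactions
proportionally larger, as interaction designs conventionally do) on pairs
co-carried by at least 8% of lines, with residual noise of 0.3 on
replicate observations. Reporting works at the QTL level: selected effects
are clustered at effect-column correlation $r \ge 0.90$ (near-collinear
single and product columns are one statistical signal — distinct bin pairs
can share an identical co-carrier set, and a product column can coincide
with a single bin's presence), each cluster is one reported QTL whose
magnitude is the absolute sum of its members' debiased
(ordinary-least-squares refit) coefficients, and clusters below half the
trait SD — the magnitude class the study plants — are not reported. A
planted effect counts as recovered when a reported cluster contains a
column correlated at $r \ge 0.90$ with the planted column; a reported
cluster is a false positive when it matches nothing by column correlation
nor by interval containment of a planted bin. The study sizes were chosen
to finish in minutes on one core; power at a few hundred lines is the
limiting factor for interaction recovery, exactly as in real populations
of this design.

## Fine-mapping and confirmation

For a discrete trait, the candidate region on a chromosome is the
intersection of the donor intervals of all consistently phenotype-positive
lines minus the union of the donor intervals of all consistently negative
lines; inconsistently scored lines are excluded from both sides. The
candidate shrinks monotonically as informative negative lines accrue and
always contains the causal locus in the noise-free dominant model.
`overlap_qtl()` tabulates half-open overlaps between two QTL interval sets
(e.g. a fine-resolution set against a legacy coarse set) with the span and
the narrowing factor.

## Permutation enrichment

Gene-set enrichment inside trait-associated bins draws the same number of
bins uniformly without replacement from the full bin set 10,000 times; the
statistic is the count of gene-set members inside the drawn bins, and the
p-value uses the add-one estimator $(1 + \#\{perm \ge obs\})/(n+1)$, which
cannot return zero and is conservative under ties. The two-locus variant
counts epistatic pairs whose *both* member intervals overlap at least one
eQTL interval (a one-member variant is available), with the null drawn from
the universe of observed bin pairs. Significance is declared below 0.05.

## Numerical and interface conventions

* Coordinates: 0-based half-open internally and in BED-like files; 1-based
  at GFF3 and pileup/count interfaces.
* State order is always (M82, HET, PEN); genotype codes 0/1/2.
* All stochastic functions accept a `seed` and restore the caller's RNG
  state; equal seeds give byte-identical outputs.
* Posterior rows are validated to sum to one within $10^{-9}$; the
  forward–backward oracle agreement is checked to $10^{-12}$ on short
  chains.
* Quantiles are type-7 (linear interpolation); the percentile window is
  boundary-inclusive, the nonparental bound strict, the coverage cap
  inclusive, and parental concordance strict, following the stated rules.

## Known limitations

* The simulator does not model restriction-site structure, mapping bias, or
  segregation distortion; marker panels are regular grids.
* Automated boundary refinement is a stand-in for human review of
  near-coincident boundaries and is off by default.
* The genetic map behind real data is rarely constant-rate; a piecewise map
  should be supplied where available.
* Epistatic recovery at a few hundred lines is power-limited; interactions
  carried by few lines are reported with unstable magnitudes.
* Heterozygous-boundary precision at 1x coverage is intrinsically worse
  than homozygous-boundary precision; downstream analyses that depend on
  exact HET edges should use deeper data.
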