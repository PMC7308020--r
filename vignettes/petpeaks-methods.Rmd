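---
title: "Model-based peak calling for ChIA-PET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based peak calling for ChIA-PET: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petpeaks)
```

## The problem

ChIA-PET interrogates protein-mediated chromatin structure by sequencing
paired-end tags (PETs): pairs of ~20 bp tags joined through barcoded
half-linkers. *Self-ligated* PETs — both tags on one chromosome with a short
span — pile up around protein binding sites (PBSs), with an upstream tag peak
left of the binding position and a downstream peak right of it. petpeaks
calls binding sites from both tags of every self-ligated PET, modelling each
genomic region's PETs as points in the two-dimensional space of ordered tag
coordinates $(x, y)$, $x < y$, instead of collapsing the data to single tag
positions.

The pipeline has three in-scope stages. Stage 0 classifies read pairs by
half-linker combination (A/A and B/B non-chimeric, A/B chimeric, anything
with a missing linker ambiguous), trims non-chimeric pairs to their tags and
drops tags with non-standard residues. Alignment (stage 1) is out of scope:
any paired aligner produces the BAM that `read_pets()` consumes. Stage 2
classifies mapped PETs into self-ligated, intra- and inter-chromosomal and
removes PCR duplicates. Stage 3 segments the self-ligated PETs into regions,
fits a mixture model per region, and tests candidate sites for significance.

## The tag-peak model

Each side of a PBS is a skew generalized t (SGT) distribution with shape
parameters fixed at $p = 2$ (normal-type mode) and $q = 1$ (heavy cubic
tails), leaving mode $\mu$, skewness $\lambda \in (-1,1)$ and scale
$\sigma > 0$:

$$f_{SGT}(x) = \frac{\bigl(1 + \tfrac{(x-\mu)^2}{(1 + \mathrm{sgn}(x-\mu)
\lambda)^2 \sigma^2}\bigr)^{-3/2}}{2\sigma}.$$

The shapes must be fixed for the remaining three parameters to be
estimable; $p=2, q=1$ also makes the CDF and quantile function elementary
(`sgt_cdf()`, `sgt_quantile()`), which the package exploits for interval
construction and inverse-CDF sampling. Because $q = 1$ implies infinite
variance, every summary of SGT draws in the package and its tests uses
quantiles, never moments above the first.

A binding site $g$ is a pair of SGT peaks with parameters
$(\mu_{yg}, k_g, \lambda_{xg}, \lambda_{yg}, \sigma_{xg}, \sigma_{yg})$,
where the reparametrization $\mu_{xg} = \mu_{yg} - k_g$, $k_g > 0$, keeps
the upstream mode left of the downstream one. The joint density of an
ordered PET is

$$f_g(x, y) = \Lambda(\theta_g)\, f_{xg}(x)\, f_{yg}(y) \quad (x < y),
\qquad 0 \ \text{otherwise},$$

with $\Lambda(\theta_g) = \bigl(\int f_{yg}(y) F_{xg}(y)\,dy\bigr)^{-1}$
restoring unit mass after truncation to the ordered half-plane. $\Lambda$ is
always $\ge 1$, equals 2 when the marginals coincide, and tends to 1 as the
peaks separate. Skewness is steered by hierarchical priors
$f_{\lambda_x}(\lambda) = (1+\lambda)(-\lambda)^{\alpha}$ on $(-1, 0]$ and
$f_{\lambda_y}(\lambda) = \lambda^{\alpha}(1-\lambda)$ on $[0, 1)$ with
$\alpha = 39$, whose modes at $\mp \alpha/(\alpha+1) = \mp 0.975$ push the
upstream peak to lean left and the downstream peak to lean right — away from
the binding position, as the library geometry predicts. The binding position
estimate (summit) is $(\mu_x + \mu_y)/2$ and the 95% binding interval runs
from the 5% quantile of the upstream peak to the 95% quantile of the
downstream peak.

## Regions and the mixture

Stage 3 first segments the genome into the connected components of the
interval graph over PET spans $[x, y]$ (`segment_regions()`). Closed spans
are used, so a shared endpoint connects; this is the permissive,
deterministic reading of "overlap". Components with fewer than two PETs are
discarded — a binding event needs at least two overlapping self-ligated
PETs — and each surviving region is modelled independently, which also makes
region processing order irrelevant and trivially parallelizable.

A region with $N$ PETs and span $L$ is modelled as $G$ binding-site
clusters plus one uniform noise cluster with density $1/(2.5V)$ on
$\{x < y\}$, where $V = L^2/2$ is the area of the ordered-coordinate
triangle over the region span. The $2.5$ factor deliberately
under-normalizes the noise component, spreading it over a slightly larger
area than the region itself so that the fit accounts for the noise level
surrounding the region. The region span (not the convex hull of the tags)
defines $L$: it is what the segmentation actually delimits. The penalized
observed log-likelihood adds the log skewness priors of every cluster to
the mixture log-likelihood (`penalized_loglik()`).

## ECME fitting

`ecme_fit()` implements an Expectation/Conditional Maximization Either
scheme:

* **E step** — responsibilities over the $G + 1$ clusters from the current
  parameters.
* **CM step 1** — mixing weights in closed form (mean responsibility).
* **CM step 2** — per cluster, bounded quasi-Newton (L-BFGS-B with numeric
  gradients) on the responsibility-weighted cluster log-density plus that
  cluster's skewness priors, over all six parameters jointly. Box
  constraints: $\mu_y$ inside the region, $k \ge 0.1$ bp, $\sigma \in
  [1, L]$ bp, skewness intervals shrunk by $10^{-6}$ so the prior stays
  finite. Each optimization is warm-started at the current parameters, so a
  CM step can only improve its objective; a failed optimization freezes
  that cluster for the iteration.
* **"Either" monitoring** — convergence is tracked on the observed
  penalized log-likelihood, which this construction makes non-decreasing
  across iterations (a property the tests assert on every fitted
  trajectory). Iteration stops when the relative change drops below
  `tol = 1e-6` or at `max_iter`.

Initialization is deterministic: cluster summits at the
$(g - \tfrac12)/G$ quantiles of the PET midpoints $(x+y)/2$, $k$ from the
mean PET span, per-side scales from the tag spread around the nearest
center (floored at 5 bp), $\lambda = \mp 0.5$, and $p_0 = 0.1$.
Reproducibility therefore needs no RNG at the fitting stage.

$\Lambda$ is included in the fitted density by default (`use_lambda =
TRUE`); fits with $\Lambda \equiv 1$ are exposed as an option and recover
nearly identical summits (asserted within 2 bp on seeded data). Two
quadratures back $\Lambda$: the exported `lambda_norm()` uses adaptive
quadrature on the real line (tolerance $10^{-8}$) in the downstream peak's
standardized coordinates, and is the authoritative value tested against an
independent nested 2-D quadrature; the fitter's inner loop uses a 128-node
Gauss–Legendre rule after a tangent substitution, which agrees with the
adaptive value to about $10^{-3}$ relative or better across the tested
parameter ranges and, crucially, is used consistently in both the CM
objective and the monitored log-likelihood so the ascent property is exact.

## Choosing the number of sites

The exact conditional-maximization partitioning and cluster-count rule of
the original method's supplementary derivation are not reproduced here;
`select_model()` realizes the same contract with a BIC sweep: fit
$G = 0, 1, \dots, \min(G_{\max}, \lfloor N/4 \rfloor)$ (at least $G = 1$ is
attempted even in sparse regions of 2–3 PETs) and keep the fit minimizing
$-2\,\ell_{pen} + 7G \log N$, counting six cluster parameters plus one
weight per cluster. The noise-only model $G = 0$ competes in the sweep, so
pure-noise regions are typically explained without any site cluster.

## Significance

Candidate sites are clusters with positive weight holding at least two
PETs by maximum responsibility. For inference the per-side 95% quantile
intervals are computed from the independent marginals ($\Lambda = 1$);
dependence corrections would require the joint marginals and the estimated
$\Lambda$ is close to 1 for well-separated peaks. The number of upstream
tags (all $x$ coordinates on the chromosome, not only cluster-assigned
ones — counting assigned tags would make the test circular) in the
upstream interval of length $S$ is tested against a Poisson null with
intensity

$$\lambda = \max\bigl(2,\ N_{C}S/S_{C},\ n_{w10}/10,\ n_{w15}/15\bigr),$$

where $N_C$ is the chromosome total, $S_C$ the chromosome size, and
$n_{w10}, n_{w15}$ are counts in windows of 10 and 15 times the peak size
centered at the peak mode (MACS-style local background anchoring; the
source construction does not state the anchor). The floor of 2 demands at
least two tags for significance. The downstream side is tested likewise;
the two counts are independent under the null, so the site p-value is the
product, and one genome-wide Benjamini–Hochberg correction over all
candidates yields q-values, thresholded at FDR 0.05 by default.

## Stage 2 details

The PET length histogram uses 100 bp bins in raw length space spanning the
minimum to maximum length (bins left-closed, last bin closed), displayed
against log10 bin midpoints — a 100-unit bin in log space would be
meaningless. The elbow cut-off scales the (log-midpoint, count) points to
the unit square (making the geometric construction unit-free), draws the
chord from the highest-count bin to the rightmost bin, and returns the
upper edge of the bin with maximal perpendicular distance, restricted to
bins at or right of the peak, ties breaking leftmost. Mixture-model
cut-offs were deliberately not implemented: the elbow is deterministic.

Duplicate removal scans PETs sorted by (chromosome pair, tag points) and
discards a PET when an already-kept PET matches both tag points within
±1 bp; the first-kept PET wins. Deduplication runs *before* the length
histogram and classification: duplicate inflation would otherwise bias the
histogram that determines the cut-off. PETs whose two tag points coincide
after midpoint rounding are dropped (the model density is zero on the
diagonal) with a reported count.

Each tag enters the model as a single coordinate. The default is the
floor-rounded midpoint of the aligned span: the model ignores strand, and
the midpoint is the strand-neutral choice. The 5' end is available as an
option (`point_rule = "five_prime"`).

## Stage 0 details

The read layout is fixed as `[tag][half-linker][rest]`: the MmeI-type
enzyme cuts 20 bp from its restriction site, so the tag precedes the
linker. The barcode is matched at that fixed offset with `max_mismatch = 0`
by default (exact matching is conservative and reproducible); when
mismatches are allowed and both barcodes match, the fewer-mismatch one
wins and exact ties yield "none". Reverse-complement linker matching is
not attempted — reads are assumed in sequencing orientation.

## The simulators

`simulate_library()` plants exact counts of AA/BB/chimeric/ambiguous read
pairs with known tag sequences; ambiguous pairs carry a barcode differing
from both half-linkers at every position. `simulate_chromosome()` emits
binding sites (SGT pairs accepted on $x < y$, so the reciprocal acceptance
rate independently estimates $\Lambda$), noise PETs uniform on the ordered
triangle of declared spans — placed around sites rather than genome-wide so
segmentation produces realistic mixed regions — long-range intra PETs with
lognormal lengths (median 200 kb, a realistic interaction scale orders of
magnitude above self-ligated spans), and inter-chromosomal PETs. Both
return truth tables covering every emitted record and are byte-reproducible
from their seed.

Default study conditions used across tests: sites with $\sigma = 35$ bp,
$k = 200$ bp, $\lambda = \mp 0.9$ (tight transcription-factor-like peaks
with the mode separation of a short self-ligated fragment), 500-PET sites
with 10% triangle noise for single-site recovery, 40-PET noise-only
regions for model selection, and two-chromosome genomes with ten planted
sites plus noise-only spans for end-to-end FDR/recall checks. These sizes
keep a full suite run modest while leaving the statistics
well-identified.

What the simulator does *not* emulate: sequencing errors, mappability and
alignment artifacts, chromatin-state-dependent background inhomogeneity
beyond the declared noise spans, and inter-site interference. Passing
tests therefore demonstrate correctness of the algorithms under the
model's own assumptions, not performance on any real library.

## Numerical choices and degenerate inputs

* Closed-form CDF/quantile everywhere; quadrature oracles live only in
  tests.
* `lambda_norm()` adaptive quadrature tolerance $10^{-8}$; non-convergence
  raises an error carrying the integral estimate.
* Empty inputs: empty PET files yield empty data frames; empty blacklists
  are identities; segmentation of nothing is an empty region list.
* A region PET with zero density under every cluster (impossible while the
  noise cluster has positive weight) aborts the fit with a diagnostic.
* Elbow requires ≥ 3 nonzero bins and a peak left of the rightmost bin;
  otherwise it errors and a manual `--cutoff` can be supplied.
* p-values of exactly 0 are written as the `-log10` cap (330) in
  narrowPeak output.

## Limitations

The package calls binding sites only; interaction calling between sites is
out of scope (the intra/inter partitions are written in a
MANGO-consumable layout). Alignment is delegated to external tools. The
BIC-based cluster-count rule and the ECME step partitioning are this
package's own design, contract-equivalent to but not a line-for-line
reproduction of the original supplementary derivation.
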