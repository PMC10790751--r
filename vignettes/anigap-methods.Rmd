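---
title: "Methods: detecting the intra-species ANI gap and delineating genomovars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the intra-species ANI gap and delineating genomovars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anigap)
```

## The problem

Pairwise average nucleotide identity (ANI) between bacterial genome
assemblies of the same species does not fill the 95--100% range evenly:
large genome collections show a pronounced scarcity of pairs between about
99.2% and 99.8% ANI, with pairs piling up above and below that window. This
discontinuity suggests natural intra-species units and motivates concrete
thresholds for naming them: *genomospecies* (genomes connected at $\ge$ 95%
ANI), *genomovars* ($\ge$ 99.5% ANI, the midpoint of the gap, proposed as a
whole-genome analogue of MLST sequence types), and *strains* ($>$ 99.99%
ANI). `anigap` implements the full analysis chain needed to detect such a
gap and delineate the units -- ANI estimation, gap statistics, threshold
clustering, sequence typing and concordance, and gene-category enrichment --
together with a synthetic species generator that plants known structure, so
every stage can be validated end to end without external genome downloads.

## Fragment-based ANI

`compute_ani()` splits the query genome into consecutive non-overlapping
fragments (default 3,000 bp; the terminal remainder is discarded so that all
fragments share one length). Each fragment is placed on the reference by
exact $k$-mer seeding ($k = 16$, seeds every 25 bp) with candidate offsets
ranked by seed votes, followed by ungapped X-drop extension from the
anchoring seed (+1 match, $-2$ mismatch, drop threshold 20). A mapping is
kept when its identity -- matches over the extension span -- reaches
`min_fragment_identity` (default 80%) *and* the extension covers at least
`min_fragment_coverage` (default 0.8) of the fragment. A kept mapping is
*bidirectional* when the reference fragment containing the mapped midpoint
maps back, by the same procedure, to within half a fragment of where it came
from. Then

$$\mathrm{ANI} = \frac{1}{|B|}\sum_{f \in B} \mathrm{id}(f), \qquad
  \mathrm{shared\ fraction} = \frac{|B|}{\#\ \text{query fragments}},$$

where $B$ is the set of bidirectional fragment mappings. When $B$ is empty
the ANI is reported as missing (never 0), and downstream clustering treats
it as below any threshold.

Two numerical choices deserve comment. First, identity is scored over the
X-drop extension rather than the raw fragment: a fragment that straddles an
accessory-gene indel would otherwise pick up ~25% chance matches across the
breakpoint and report a misleading 85--95% identity; with extension scoring
the aligned part is scored at its true identity and the coverage filter
discards mappings that align less than 80% of the fragment. Without this,
every gene-content difference between two otherwise nearly identical
genomes would drag their ANI down by several tenths of a point, which is
both inaccurate (the true per-site identity of the shared backbone is
unchanged) and fatal to threshold clustering near 99.5%. Second, mapping is
done on the forward strand only: the generator produces co-oriented
assemblies, and strand search would only add runtime. Real data with
inverted contigs would need reverse-complement seeding, which is out of
scope here.

On indel-free pairs the estimator is exact up to fragment sampling: across
planted divergences of 0.1--4% it stays within 0.05 percentage points of
the exact Hamming identity on the ancestral coordinate frame (the package's
acceptance checks verify this bound on every run).

## Gap statistics

`gap_scan()` takes a species' pairwise ANI values above a floor (default
95%) and answers two questions: *is* the distribution multimodal, and
*where* are the valleys?

**Uniform-null deficits.** `expected_uniform()` and `deficit_ratio()`
implement the chance-alone yardstick: $N$ pairs spread uniformly over
$[a,b]$ put $N (r-l)/(b-a)$ pairs into $[l,r]$. With the published totals
(4,280,133 pairs above 96% ANI) this gives 107,003 pairs per 0.1% bin and
642,020 pairs in the 99.2--99.8% window, so an observed count of ~235,000
is a threefold deficit.

**Dip statistic.** `dip_statistic()` computes the sup-norm distance between
the sample ECDF and the closest continuous unimodal CDF -- a CDF convex up
to its mode and concave after it. The computation is exact: bisection on
the distance $d$, with feasibility decided through box corridors at the
distinct sample values. A convex nondecreasing function fits a corridor iff
the monotonised greatest convex minorant of the upper bounds clears the
lower bounds; the concave side is the point reflection of the same test;
and the two sides must agree on a common value at the mode knot, located by
a nested bisection (the mode-value coupling is *not* redundant -- on
clustered samples ignoring it underestimates the dip by up to ~0.01, which
is why the cheap relaxation was rejected). For $n$ distinct points the dip
lies in $[1/(2n), 0.25]$; two points attain 0.25. `dip_brute()` is a
deliberately independent reference implementation (exhaustive minimisation
over piecewise-linear unimodal CDFs on the sample grid, nested bisections
throughout) used to validate the fast path to $10^{-9}$ on random samples.
p-values come from Monte-Carlo calibration against uniform(0,1) samples of
the same size with a $+1/(n_\mathrm{boot}+1)$ continuity correction;
`dip_null()` lets many tests of the same sample size share one null
distribution.

**Valleys.** `find_valleys()` runs a Gaussian KDE on a fixed grid (95--100,
step 0.01) and reports a local minimum as a valley when its density is at
most $\beta$ (default 0.5) times the lower of its two flanking peaks; the
valley extent is the contiguous region below that cutoff and the midpoint
is the density argmin, with plateau minima resolved to the plateau centre
(a wide empty window bottoms out at numerically zero density, where "the"
argmin would otherwise be the arbitrary leftmost grid point). Densities
below $10^{-9}$ of the maximum are clamped to zero first: FFT far-tail
noise at the $10^{-16}$ level otherwise fragments one real valley into
dozens of spurious micro-valleys. The default bandwidth is 0.1 ANI
percentage units -- the same resolution as the 0.1% bins of the
uniform-null analysis -- rather than Silverman's rule: Silverman's
$\hat\sigma n^{-1/5}$ is calibrated for unimodal densities and, on a
bimodal ANI distribution whose overall spread is ~1.5 points, oversmooths
to the point of dragging valley midpoints ~0.5 points away from the actual
empty interval. Both the bandwidth and $\beta$ are exposed as arguments.

**Classification.** A species is `clonal` when all its pairs exceed 99.5%
ANI (nothing to delimit), `gap_99.2_99.8` when a significant valley (dip
$p < 0.05$) has its midpoint inside the window, `shifted_gap` when
significant valleys exist only elsewhere, and `no_gap` otherwise.
`gap_mode()` pools valley midpoints across species into 0.1-wide bins
centred on multiples of 0.1 and returns the fullest bin's centre, ties
toward higher ANI. `subsample_pairs()` implements the control that
re-evaluates species on a common number of genomes.

**Divergence time.** `divergence_time(d, mu, g, k)` is the naive closed
form $d/(k \mu g)$: with $\mu = 4\times10^{-10}$ per site per generation
and 100 generations per year, two lineages need 62,500 years to accumulate
0.5% divergence. This ignores fixation entirely and is therefore a hard
lower bound; literature statements of millions of years for the same
divergence implicitly assume that only a small fraction of mutations fix.
The function implements the closed form only and documents the assumption.

## Units, typing, enrichment

`cluster_by_ani()` builds a graph with an edge for every pair at or above
the threshold and takes connected components (single linkage). Single
linkage is the natural reading of "groups of genomes sharing more than X%
ANI"; because edge sets at nested thresholds are nested, the strain
partition ($>99.99\%$, strictly, following the definition's wording)
refines the genomovar partition ($\ge 99.5\%$), which refines the
genomospecies partition ($\ge 95\%$) -- `nested_units()` returns all three.
Labels are the smallest genome id per component, so partitions are
deterministic and row-order invariant. Missing ANI never makes an edge.

`assign_st()` implements MLST-style typing: an allele is an exact
(case-insensitive, strand-normalised) nucleotide match of a designated
locus; seven identical alleles make an ST; allele and ST numbers count up
from 1 in order of first appearance. Genomes missing a locus are left
unassigned and excluded (with a logged count) from
`pairwise_concordance()`, which scores the ST labels against an ANI
threshold over unordered pairs: TP = same ST and ANI $\ge$ threshold, FP =
same ST below threshold, FN = different ST at or above threshold, giving
precision TP/(TP+FP) and recall TP/(TP+FN). All metrics are defined over
genome *pairs*; published percentages that mix genome- and pair-based
counting cannot be reproduced exactly from their printed form, and the
pair-based definition is the one that admits an exact brute-force oracle.

`enrichment_test()` asks whether the genes *not* shared between very close
pairs (ANI $>$ 99.8%) are enriched in `hypothetical/mobile` categories
relative to genes not shared between divergent pairs (96--99.8%), pooling
non-shared gene occurrences per pair and applying a pooled-variance
two-proportion z-test, $z = (\hat p_A - \hat p_B) / \sqrt{\hat p (1-\hat p)
(1/n_A + 1/n_B)}$, with a two-sided normal p-value. The variant of z-test
is a choice (the pooled form is the textbook default);
`two_proportion_perm()` provides a permutation reference that agrees with
it within Monte-Carlo error. Counting per pair (rather than unique genes)
is also a choice, documented here: the same gene differing across many
pairs is evidence in each of them.

## The synthetic species generator

`simulate_species()` builds a species with known structure so that every
statement above is testable:

* **Planting.** A two-level lineage tree -- genomovar ancestors off the
  species root, genomes off their ancestors -- with branch lengths chosen
  so that within-unit pairwise identities fall in `intra_unit_ani`
  (default 99.85--99.99%) and between-unit identities in `inter_unit_ani`
  (default 96--99.2%). The two shallowest units are anchored at the band
  edge so between-unit pairs genuinely reach 99.2%, making the planted gap
  exactly the 99.2--99.8-ish window rather than something wider. The
  `gapless` control instead puts every genome on its own branch with
  depths uniform in $[0, 2\%]$, so pairwise identities $(v_i + v_j)$ fill
  96--100% smoothly without exclusion; `clonal` keeps everything above
  99.5%; `custom` accepts arbitrary bands.
* **Substitutions.** Sites are drawn uniformly at random but *disjointly*
  across branches (without replacement from the unused-site pool), so the
  realized Hamming divergence between any two genomes on the ancestral
  coordinate frame is exactly additive along the tree and the truth matrix
  is exact rather than an expectation. At the divergences simulated
  ($\le 4\%$) this differs from independent uniform placement only through
  the absence of double hits (an $O(d^2)$ effect), and it is what makes
  the ANI estimator testable against an exact oracle.
* **Gene content.** Core genes are always present; accessory genes flip
  presence per branch with probability `gain_loss_prob` (default 0.02),
  and `hypothetical/mobile` genes flip `mobile_turnover` (default 15)
  times faster, capped at 0.5. Faster turnover of mobile elements is the
  biological mechanism behind the observed enrichment: between close
  pairs, differing genes are dominated by the fast-churning mobile class,
  while between divergent pairs the slow class has caught up. Setting
  `mobile_turnover = 1` gives the category-neutral null used for
  calibration tests.
* **MLST loci.** Seven core genes spread along the genome are designated
  loci. Substitutions land in them at a reduced relative rate (default
  0.05 on terminal branches, 0.5 on unit-ancestor branches), reflecting
  purifying selection on housekeeping genes; without this, a genome-average
  mutation rate gives nearly every genome a private ST and sequence typing
  becomes vacuously fine-grained. The per-branch substitution *count* is
  unchanged -- only placement is reweighted -- so planted identities stay
  exact. Setting the terminal rate to 0 and the unit rate to 1 makes locus
  variation track unit boundaries perfectly (the configuration in which
  concordance is provably 1/1).
* **What it does not emulate.** No recombination or HGT tracts, no indels
  within aligned backbone, no rearrangements or inversions, no codon
  structure, no assembly artefacts, uniform base composition. Passing
  tests on these simulations therefore demonstrate correctness of the
  *statistics and bookkeeping*, and estimator accuracy under an idealized
  substitution-plus-gene-turnover model -- not robustness to everything
  real assemblies can contain.

Default problem sizes are 5 genomovars $\times$ 8 genomes of ~100 kb (780
pairs), the scale at which gap detection, unit recovery, typing and
enrichment all have comfortable signal; validation runs use 20 seeds for
recovery rates and 500 replicates for calibration checks. These sizes are
the package's validation design; all of them are arguments.

## Degenerate inputs and edge behaviour

Single-genome species yield empty pair tables (not errors); genomes
shorter than one fragment raise an explicit "no fragments" error; a pair
with no bidirectional fragment has missing ANI and clusters as singletons;
constant samples are rejected by the dip test (it needs 4 distinct
values); `find_valleys()` returns an empty table below 10 values and
`classify_species()` then falls back to `clonal`/`no_gap`; duplicate pair
rows are tolerated when consistent and rejected when conflicting; ties in
`gap_mode()` resolve toward higher ANI; equal-length genomes take the
lexicographically smaller id as reference so pair tables are reproducible.

## Limitations

The ANI estimator is forward-strand and ungapped by design and should not
be pointed at real draft assemblies with inversions without adding strand
handling. The dip test's Monte-Carlo null assumes exchangeable, effectively
continuous data; heavy ties (many identical ANI values) would need a
different null. Concordance percentages from the literature that were
computed over genomes rather than pairs are related but not identical to
the pair-based metrics here. The divergence-time closed form deliberately
omits fixation dynamics.
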