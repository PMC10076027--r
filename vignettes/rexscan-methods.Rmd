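---
title: "Methods: motif scoring, X:A enrichment, and ChIP signal profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scoring, X:A enrichment, and ChIP signal profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rexscan)
```

# The biological question

Nematode hermaphrodites halve transcription from both X chromosomes via
a condensin-derived dosage compensation complex (DCC). The DCC enters X
at a small number of recruitment elements (*rex* sites) and spreads from
there. What distinguishes a *rex* site is sequence: short motifs (13 bp
MEX, 30 bp MEX II, sharing a CAGGG core) that are (i) far denser on X
than on autosomes and (ii) bound by DCC subunits only when clustered
inside *rex* sites. `rexscan` implements the computational chain that
quantifies both properties, together with the qPCR and peptide-mass
fingerprinting arithmetic used to validate the complex and its binding.

# Motif model and exact ln(P)

A motif is represented by per-position nucleotide counts
$n_{i,b}$ over $N$ aligned instances with background probabilities
$p_b$. Log-weights follow the Patser convention

$$w_{i,b} = \ln\frac{n_{i,b} + p_b}{(N+1)\,p_b},$$

whose background-proportional pseudocount keeps all weights finite. A
plain log-odds rule with an additive pseudocount is available via
`pseudocount = "additive"`. The match score of a word is the sum of its
per-position weights, and its significance is expressed as
$\ln P = \ln \Pr\{S(X) \ge S(w)\}$ for a random background word $X$ —
more negative is a better match, and the per-position-argmax (consensus)
word attains the most negative value the matrix allows
(`max_theoretical_ln_p()`).

The survival probability is computed exactly by dynamic programming:
per-position weights are rounded to a lattice of step `granularity`
(ties rounded half away from zero, fixed) and the pmf of the lattice
score is built by convolving one position at a time. A queried word's
lattice score is the *sum of its per-position lattice weights*, so word
and distribution are discretised identically and the worked
dinucleotide examples in the documentation are lattice-exact.

**Background.** The background model is a free parameter; the default
is uniform 0.25 per base, overridable by genome-derived mononucleotide
frequencies (e.g. from `Biostrings::letterFrequency`). Published ln(P)
values for the MEX/MEX II matrices cannot be pinned down numerically
because neither the matrices nor the background used to score them were
deposited; all quantitative validation here is therefore against exact
enumeration and synthetic ground truth.

**Granularity.** Discretisation can misclassify "near-tie" words whose
exact scores differ by less than the accumulated rounding
($\le k \cdot \text{granularity}/2$ for a $k$-position motif). In the
sparse upper tail of the distribution a single misclassified word can
change $\ln P$ by a non-negligible amount, so the error is controlled
by making the band rare rather than by a smooth derivative bound. Point
queries (`ln_p()`, `score_distribution()`) default to a step of 1e-5,
at which brute-force enumeration of all $4^k$ words for random matrices
up to $k = 8$ agrees with the DP to well under 0.01 (the test suite
asserts this across 50 random matrices and backgrounds). Genome scans
(`scan_genome()`) default to a coarser 1e-4 lattice: the residual ln(P)
error (worst case ~0.02) is irrelevant against any practical scan
threshold, and the distribution builds an order of magnitude faster. A
guard errors out, with guidance, if a requested lattice would exceed
`max_lattice` points.

# Scanning and strand handling

`scan_genome()` scores every offset of every sequence. Windows touching
non-ACGT characters are skipped silently and counted in the
`skipped_windows` attribute. Minus-strand windows are scored with the
reverse-complement matrix; their p-values come from that matrix's
distribution under the complement-swapped background, which equals the
probability that a random background word matches the original matrix
at least as well as the reverse-complement word does. This makes
reverse-complementing the genome map hits exactly — (start, strand)
$\to$ (L − end, opposite strand) with identical ln(P) — for any
background, symmetric or not; the test suite checks the identity on
random sequences.

Threshold comparisons are inclusive ($\ln P \le t$) by default with a
strict mode available, matching the convention of reporting "motifs
with ln(P) below a cutoff". When both strands pass at one offset, the
better strand is reported once (ties to "+"); `collapse = FALSE`
reports both, which is the right setting for strand-symmetry checks and
palindromic motifs. Overlapping hits are all reported — enrichment is a
density statistic and greedy masking would bias it.

# The cumulative X:A enrichment curve

For each threshold $t$ on a grid, hits with $\ln P \le t$ are counted
on X-class chromosomes and on pooled autosomes, converted to per-bp
densities, and the ratio

$$\text{ratio}(t) = \frac{\text{X hits} / \text{X bp}}
                         {\text{autosomal hits} / \text{autosomal bp}}$$

is reported. Autosomes are pooled into a single density (not averaged
per chromosome). Where no autosomal hit passes, the ratio is flagged
undefined rather than reported as infinity. The default grid steps by
0.25 from −9 down to the matrix's maximum theoretical ln(P). Counts
nest along the grid; swapping the class labels inverts the ratio;
jointly scaling lengths and hit counts leaves it unchanged — all tested
as properties.

# ChIP signal

Coverage is held in fixed-step binned tracks, RPKM-normalised:
$\text{RPKM} = c \,/\, ((\text{bin}/1000)(\text{reads}/10^6))$. Tracks
read from bedGraph or wiggle that are not on a uniform grid are
re-binned by length-weighted averaging.

Peak calling is deliberately simple thresholding — maximal runs of bins
at or above a threshold, merged across gaps up to `merge_gap`, dropped
below `min_width`, summit at the maximum bin (leftmost on ties). It
exists to mark high-occupancy sites in synthetic or pre-normalised
tracks; published peak callers are intentionally out of scope. Note
that raising the threshold can in principle split one run into two, so
the peak *count* is only monotone for well-separated sites over a flat
background — the regime the tool is intended for.

`meta_profile()` averages the track at signed offsets from anchor
midpoints (integer floor of the motif interval midpoint; the anchor
convention is a package choice, as is pooling strands). The standard
error is the cross-anchor sample SD divided by $\sqrt{n}$, reported as
0 when a single anchor contributes. Anchors near chromosome ends
contribute only their in-range offsets. Defaults (half-window 5 kb,
50 bp step) match the scale on which *rex*-site occupancy is usually
displayed. *rex* membership is overlap of at least 1 bp with a peak
interval; `annotate_rex()` reports each peak's motifs in positional
order with inter-motif gaps measured end-to-next-start (the convention
in which two adjacent motifs "separated by 33 bp" have
`start(next) − end(previous) = 33`), and motif-free peaks are still
listed. `discovery_windows()` extracts summit-centred windows (default
500 bp, clipped and flagged at chromosome ends) as input for external
motif discovery.

# qPCR and viability arithmetic

Standard curves are ordinary least squares of threshold cycle on
$\log_{10}$(fraction of input), fitted to a 10% standard and three
serial 10-fold dilutions; a perfectly efficient assay has slope
$-1/\log_{10} 2 \approx -3.3219$ cycles per decade. Quantification
inverts the line; the round trip through fit-and-quantify reproduces
noise-free standards to 1e-9. Site levels are normalised per replicate
to the arithmetic mean of an explicit list of control *rex* sites
(never a hard-coded count), which removes any shared per-replicate
scale factor exactly; means ± SD are then taken across replicates.

Viability percentages are `100·observed/(total·expected_fraction)`,
with the XO-viability (expected fraction 1/2) and XO-rescue (1/3 — the
non-rescued XO class is inviable, leaving two viable XX classes per
expected male class) formulas provided as named wrappers.

# Peptide mass fingerprinting

Tryptic digestion cleaves after K or R except before P, enumerating up
to `max_missed` internal missed cleavages. Monoisotopic MH+ is the
residue-mass sum plus water (18.010565 Da) plus one proton
(1.007276 Da); residue masses are the standard monoisotopic values
embedded to ≥5 decimals. Matching reports every peptide/modification
combination within a ppm tolerance (default 25 ppm), ranked by absolute
deviation. The default variable modifications — Met oxidation
(+15.994915), Cys carbamidomethyl (+57.021464), Cys propionamide
(+71.037114) — are the set needed to reconcile typical MALDI-TOF tables
in which the same peptide appears at two masses; the two cysteine
adducts are treated as alternatives on the same residues. Full
precision is kept internally; comparisons to printed tables are made at
2 dp. Printed delta-ppm columns in such tables are generally computed
from unrounded internal masses and cannot be reproduced from the
rounded columns, so ppm values are reported but not asserted against
publications.

# The synthetic-data generator

`simulate_genome()` emulates the structure the analysis assumes and
nothing more: i.i.d. background sequence; motif instances sampled from
the matrix's per-position frequencies; uniform-random non-overlapping
placement (rejection sampling with a retry cap) at a per-class density;
on X, a configurable number of rex-like clusters of 1–4 motifs with
20–120 bp gaps placed first. It does not model repeats, composition
heterogeneity, or mappability — so passing recovery tests demonstrates
correctness of the estimator under the stated sampling model, not
robustness to genomic confounders. `simulate_coverage()` draws per-bin
Poisson counts around a flat background plus Gaussian bumps (default
σ = 400 bp — a fixture choice) at rex summits. `simulate_qpcr()`
applies a shared log-normal per-replicate scale, per-measurement
log-normal noise of a given CV, and converts levels to Ct through a
perfect standard curve. All generators are pure functions of
(configuration, seed).

**Default study conditions.** The desk-scale genome is X 2 Mb plus two
autosomes totalling 4 Mb (roughly a tenfold shrink of a ~20 Mb nematode
genome, keeping scans around ten seconds each). The default planted
matrix is sharp (97:1:1:1 counts per position around a 13 bp
CAGGG-core consensus), putting the consensus ln(P) near −18 — the
strength regime of a real X-enrichment motif — so planted instances
separate cleanly from background matches. Planting densities default to
1500 motifs/Mb on X versus 125/Mb on autosomes (a 12:1 per-bp ratio).
The absolute density was fixed by a binomial power analysis: with
roughly 3000 X and 500 autosomal planted instances, the ratio estimate
has a sampling SE of about 5%, so a ±15% per-seed recovery band sits
near 3 SD. Instances sampled from the sharp matrix occasionally miss a
stringent threshold, but that thinning is class-independent and leaves
the ratio unbiased; background matches, which dilute the ratio toward
1, are held to a handful genome-wide by evaluating recovery at
ln(P) ≤ −14.

**Recovery checks and their problem sizes.** The test suite runs the
full closure — generate, scan, enrich — over 20 seeds at the conditions
above (a few minutes), asserting per-seed recovery of the 12:1 ratio
within ±15% and mean bias under 5%. Meta-profile recovery plants 12
isolated bumps (even spacing with ±5 kb jitter, far beyond 3σ, so each
anchor sees a single bump) on a 2 Mb chromosome and requires the
anchor-point mean within 10% of background + amplitude; the
no-enrichment group is checked at 3 SE at the anchor offset and, to
account for testing ~80 offsets simultaneously, at 4 SE across the
whole profile.

# Known limitations

* Published MEX/MEX II matrices are not deposited, so their
  genome-scale enrichment folds and per-site ln(P) values cannot be
  reproduced numerically; the pipeline is validated on exact oracles
  and synthetic truth instead.
* The scanner handles ungapped mononucleotide-background PWMs only; no
  dinucleotide background, gapped motifs, or co-occurrence scanning.
* Peak calling is threshold-based plumbing, not a statistical caller;
  no input subtraction or IgG differential testing.
* Mass fingerprinting covers singly protonated monoisotopic masses
  only — no isotope envelopes, charge states above 1, or probabilistic
  scoring.
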