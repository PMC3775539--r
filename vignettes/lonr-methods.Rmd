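---
title: "Branch imbalance as a within-clone selection statistic: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch imbalance as a within-clone selection statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonr)
```

## The model

A B-cell clone expands asexually from a single founder while somatic
hypermutation substitutes nucleotides along the way. If a mutation changes
the mean offspring number per generation from μ to μ + Δμ, the ratio of
the two sub-population sizes descending from the mutated and the unmutated
sibling grows like e^(Δμ·T) until one side takes over, where T is the time
from the mutation to sampling. The log offspring number ratio of a
mutation event,

LONR = ln(n_mut) − ln(n_sib),

with `n_mut` and `n_sib` the sampled-leaf counts below the mutated branch
and its sibling, is therefore an (extremely noisy) per-mutation readout of
Δμ·T. A single LONR value is uninterpretable — drift and uneven sampling
produce large branches without selection, and the neutral LONR
distribution is not even centred at zero, because mutations are more
often *placed* by the reconstruction on branches with particular size
configurations. The statistic becomes meaningful only in aggregate, and
only by contrast: synonymous events experience identical drift, sampling
and placement artifacts but no phenotype, so the test for selection in a
region is an unpaired unequal-variance (Welch) t-test between the NS and
S LONR samples of that region. Both artifacts above cancel in this
contrast; nothing in the procedure uses absolute mutation counts, which
is why no baseline mutation model (hotspot motifs, transition bias,
position-dependent rates) is required.

Assumptions worth stating explicitly:

* hypermutation produces substitutions only — every sequence in a clone
  group is handled at equal length, with no indel tolerance;
* the sampled tree is a fair image of the clone: leaf counts are read
  counts (identical reads are collapsed for tree building but their
  multiplicity is restored in the counts, `count_duplicates` behaviour);
* mutations are classified against their *direct ancestor's* codon, not
  the germline or a consensus — each substitution independently, by
  substituting that single position into the ancestral codon. Joint
  classification of two same-codon same-branch substitutions is a known
  open point; the independent rule is deliberate and events carry both
  codons so users can re-classify;
* "log" is the natural log; any other base rescales every LONR equally
  and cannot change signs or t statistics.

## From reads to trees

Germline V and J genes are assigned by exhaustive ungapped sliding
placement, scored as matches over aligned positions, with the V gene's 3′
end and the J gene's 5′ start required to lie on the read (they anchor the
analysis window); ties keep the first gene in library order. This is a
deliberate, dependency-free proxy for the original BLAST-based step — with
no indels, gapped alignment adds nothing at this scale. Reads matching
≤ 0.5 in either segment are dropped. Retained reads are grouped by
(V, J, V–J distance) — clones from one rearrangement necessarily share all
three — and truncated to the last 159 nt of V (53 codons, so the frame is
kept), the junction, and the first 20 nt of J.

Each group gets an artificial germline: truncated V + `N` × junction
length + truncated J. The junction is unknowable from the germline; `N`
positions are excluded from distance counts and from event codons, so no
mutation is ever called against the junction reference. Trees are built
by an internal neighbor joining over Hamming distances (N-skipping),
rooted at the germline leaf — which is then removed, because the germline
is the known ancestor, not a sampled read, and must not inflate leaf
counts. Negative NJ branch lengths are clamped to zero with the deficit
moved to the sibling branch, preserving path lengths. Ancestral sequences
come from Fitch parsimony with two determinism rules: the top-down pass
prefers the parent's state when attainable (ties broken A<C<G<T), and the
root keeps the germline state wherever it is unambiguous. On binary trees
the bottom-up sets are exact (Fitch = Hartigan), so pinning the root to a
set member, or paying one step when the germline state is outside the
set, still attains the constrained minimum — the test suite verifies this
against exhaustive enumeration.

Groups are parsed into clones by cutting tree edges carrying more than 4
mutations (the published cutoff) and taking connected components. The
cutoff is applied to *edges*, not path distances — the wording of the
original procedure is ambiguous; the edge interpretation is the one that
matches a single-linkage intuition on the tree and is what the
connected-components oracle in the tests checks. Clones whose own tree
implies fewer than `min_mutations_per_tree = 10` substitutions are
skipped: the published filter ("sufficient number of mutations") is
unquantified, and 10 is chosen to sit at the bottom of the 10–20
mutations-per-sequence regime where the test is calibrated.

Polytomies in imported Newick trees are resolved into arbitrary
binary cascades with zero-length edges, because LONR is defined on a
two-branch comparison; a mutated child is then implicitly compared
against the pooled remaining siblings.

## The simulator: what it emulates and what it does not

`simulate_pool()` reproduces the published calibration world: a
uniform-random 348-nt founder, exactly two offspring per cell per
generation, two regions (equal 174-nt halves by default — the original
split is unstated) with Poisson-distributed mutations per child at means
0.5 and 1.0 per sequence per generation, positions uniform within the
region, substitutions uniform over the three alternatives. Sampling takes
300 final-generation cells, with the descendants of one randomly chosen
third-generation cell (one of the first eight siblings) weighted twice —
the published sampling-bias scenario. Ten generations (1024 cells) put a
sampled sequence at ~15 expected mutations, inside the stated 10–20
regime. Poisson-per-region is chosen over per-site Bernoulli for exact
means; a `per_site` switch provides the alternative. Back-mutations are
allowed and stop codons are kept — the neutral model has no phenotype.

What the simulator does **not** emulate: hypermutation hotspot motifs,
transition/transversion bias, indels, class-switching, cell death, or
germinal-center population structure. A green calibration therefore
establishes that the *statistic and its test* behave correctly under
neutral growth with biased sampling — not that every property of real
repertoires is captured. The published robustness claims (position-
dependent rates, stronger biases) are reproducible by varying the
configuration but are not asserted by the test suite.

`simulate_with_selection()` adds the minimal selection model consistent
with the μ + Δμ picture: a cell that has ever acquired an NS mutation in
the selected region (classified against its direct parent; the flag is
inherited) draws its offspring count with mean μ + Δμ, by stochastic
rounding. With Δμ = 0 the code path and RNG stream are identical to the
neutral simulator.

## Calibration and power checks

The acceptance suite runs 300 independent neutral replicates through the
entire pipeline and requires the region-level Welch test at p < 0.05 to
fire at a rate inside the exact binomial 99% band around 5% (roughly
2–9% at this replicate count), in the higher-rate region — designated
because it carries the most events per tree; per-replicate p-values for
both regions are returned. The same run backs the symmetry check: the
per-replicate mean(NS LONR) − mean(S LONR) must be centred at zero (sign
test p > 0.01). `scripts/acceptance.R` recomputes the false-positive
rate from scratch at any seed.

The power check deliberately does *not* use the calibration rates. Under
rates (0.5, 1.0) nearly every lineage acquires its first NS mutation in
the selected region within two or three generations, after which further
NS mutations confer no differential advantage — the contrast washes out.
The pilot-calibrated demonstration regime instead makes mutations in the
selected region rare (rate 0.1 per generation, 8 generations, 200
sampled reads, Δμ = 1.0), so that most NS events there are the
selection-toggling first hit. In that regime ~70% of replicates show a
positive NS−S difference in the selected region (asserted as a sign-test
majority over 150 replicates), while the unselected region's
false-positive rate stays at its nominal level. These constants were
fixed from pilot runs before the assertions were frozen and are not
tuned thereafter.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere; FASTA/Newick ids are the
  interchange keys; TSV outputs have stable column order and 6
  significant digits, so identical runs are byte-identical.
* Degenerate bases (anything outside ACGT) are excluded from distances,
  never guessed; events whose ancestral codon contains one are skipped
  and counted in an attribute rather than silently lost.
* Degenerate statistics are flagged (`too_few`, `zero_variance`,
  `constant_input`, `no_mutations`), never returned as zeros.
* Region reports carry both the pooled-events test (the headline) and
  the per-clone-mean difference, because published region summaries can
  be read either way; a Benjamini–Hochberg column is appended for
  convenience but is no part of the original method, which reports raw
  p-values.
* The Welch test wraps `stats::t.test`; NJ and Fitch are internal
  implementations (determinism and the germline-pinned root are not
  available off the shelf) and are tested against `ape::nj`,
  `phangorn::parsimony`, and exhaustive oracles.

## Known limitations

* Germline assignment is allele-blind, indel-intolerant and has no
  D-gene model; it is adequate for the analysis window used here, not a
  general-purpose annotator.
* The V–J junction of the artificial germline is opaque (`N`), so
  mutations on the root branch inside the junction are undetectable by
  construction; CDR3 signal near the root comes from the V/J stubs.
* LONR says nothing about single mutations; all statements are averages
  over a region within or across clones.
* With very small clones (a handful of distinct sequences) most
  statistics are flagged undefined; the pipeline skips such clones
  rather than reporting noise.
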