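---
title: "Optical map assembly and structural-alteration calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical map assembly and structural-alteration calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmapforge)
```

## The measurement and the problem

Optical Mapping measures ordered restriction maps ("Rmaps") from single
surface-stretched DNA molecules: an enzyme (here SwaI, recognition
`ATTTAAAT`, blunt cut after the fourth base) digests the immobilized
molecule, and fluorescence imaging yields the ordered list of fragment
masses, in kb, between observed cut sites. Molecules average several
hundred kb, so a single molecule spans dozens of restriction fragments and
can be located on an in-silico digest of a reference genome by comparing
fragment-size patterns. From a tumor sample at 25--40x coverage one can
then (i) assemble consensus maps per genomic window and call five classes
of optical structural alteration (OSA) against the reference -- extra cuts
(EC), missing cuts (MC), insertions (INS), deletions (DEL) and complex
events (OTHER); (ii) infer copy number from the depth of aligned molecules;
and (iii) separate somatic candidates from polymorphisms by intersection
with normal panels. `rmapforge` implements this entire pipeline together
with a parameterised simulator that provides ground truth.

All coordinates are 0-based half-open base pairs; all masses are kb at
0.001 kb resolution.

## The single-molecule error model

`sim_config()` draws molecules from subclone genomes under five error
processes, each with a configurable rate (defaults in parentheses):

* **molecule length**: gamma with mean 420 kb, shape 8, truncated below
  300 kb -- right-skewed, matching the 300 kb to >500 kb range of surface-
  mounted molecules;
* **partial digestion**: each true site is cut with probability
  `digest_efficiency` (0.8);
* **spurious cuts**: a Poisson process at `false_cut_rate` (5 per Mb),
  modelling random breakage and star activity;
* **sizing noise**: each fragment mass is multiplied by `1 + e`,
  `e ~ N(0, sizing_cv^2)` (`sizing_cv` = 0.06); noise is multiplicative
  because fluorescence-intensity mass estimation scales with fragment
  size;
* **desorption**: fragments below 0.8 kb detach from the surface and are
  lost with probability 0.75.

These rates are not printed in any one place in the literature; they were
chosen once to match the qualitative descriptions of the platform
(~3 kb practical resolution, visible partial digestion and breakage) and
they live in the configuration, never in code. Chimeric molecules are not
modelled.

Molecules are placed by their midpoint, drawn within copy-number regions
in proportion to `subclone fraction x copy x length`, so coverage follows
the (molecule-length-smoothed) copy profile without double-counting at
copy boundaries; regions touching a chromosome end are extended by half a
molecule so that clipped molecules restore full edge coverage. Every
simulated molecule carries its true origin, orientation and slice label.

**Simulated references.** `simulate_reference()` draws i.i.d. bases at a
configurable GC fraction, default 0.40. The default is chosen to
reproduce the *restriction-fragment density* of the real target: the
genome-wide SwaI map of the human reference contains roughly 220,000
fragments (~13 kb mean), far denser than an i.i.d. GC-0.5 model would
give (65.5 kb), because the recognition site is AT-rich. At GC 0.40 the
expected spacing is (0.3)^-8 = 15 kb, so a 420 kb molecule carries ~28
fragments -- the information regime in which the real pipeline operates
and on which all package defaults were validated. An i.i.d. genome lacks
repeats, segmental duplications and isochore structure, so passing tests
here demonstrate correctness of the algorithms under the stated error
model, not performance on real human data.

## Alignment

`align_rmap()` scores a fitting alignment of a molecule against the
reference digest by dynamic programming over fragment *blocks*: a block
matches up to `max_block` (4) consecutive query fragments against up to 4
consecutive reference fragments and costs

    ((q - r) / (sizing_cv * r))^2
      + (n_query - 1) * extra_penalty + (n_ref - 1) * miss_penalty,

i.e. a squared sizing z-score (variance proportional to reference mass,
matching multiplicative noise) plus per-cut penalties (3.0 each) for cuts
consumed inside the block. The two terminal query fragments are unscored
-- molecule ends are random shear points that match partial reference
fragments. Both orientations and all chromosomes are searched; ties break
toward forward orientation, earlier chromosome, leftmost start. The DP is
implemented in C++ (`src/align_dp.cpp`), the package's one hot loop.

**Acceptance.** A placement is accepted when its mean cost per query
fragment is at most `accept_threshold` (2.0). The denominator counts all
query fragments, terminals included. This rule is deliberately strict:
under the default error model the *expected* cost of a correct placement
is itself close to 2.0 per fragment (one unit of chi-squared sizing noise
per block plus 3.0 for each of the ~25% of cuts that are missing, spurious
or desorbed), so roughly a third of genuinely placeable molecules are
rejected on score. We keep the strict default because the alternative --
raising the threshold until recall reaches ~90% -- admits a measurable
fraction of random molecules (the two distributions are separated by only
~3 sigma), and the pipeline's downstream consumers (consensus support
fractions, coverage ratios) are robust to partial recall but not to
misplaced molecules. Accepted placements are correct in location >99% of
the time and orientation accuracy exceeds 99%.

**Recruiting structurally different molecules.** A molecule spanning a
real 30 kb insertion has one block sitting 10--15 sigma from the
reference; no uniform threshold can accept it without accepting noise.
Two mechanisms handle this, both used only *within* assembly:

* `forgive_worst_block`: acceptance is judged on the total cost minus the
  single largest block sizing term, mirroring the idea of an aligner set
  "loose enough" to tolerate one real difference per molecule;
* a winsorized sizing term (`refine_z_cap`, default z = 4): during
  consensus refinement and classification the squared z-score of a block
  is capped at 16, so one enormous but genuine mass difference costs a
  bounded amount and the DP no longer prefers contorted merge/shift
  explanations of a true insertion. The genome-wide aligner never caps.

## Iterative consensus assembly

Chromosomes are partitioned into 1 Mb windows overlapping by 500 kb.
Round 1 aligns every molecule to the reference and bins accepted molecules
into windows by alignment midpoint. Each window is assembled with a 500 kb
flanking margin so that molecules binned by midpoint never overhang their
window's map; calls are later trimmed to the window core, which the
overlap covers from both sides.

A consensus map is refined from its seed (the reference window) by
repeated realign-and-refine rounds:

1. members are realigned to the current consensus (best placement, capped
   sizing, one structural difference forgiven);
2. each fragment's mass is re-estimated as the **median across molecules**
   of exact one-to-one block observations where at least three exist, and
   of apportioned block masses otherwise (each aligned block distributes
   its query mass over the reference fragments it covers in proportion to
   current consensus masses). The median is essential: a *mean* over only
   1:1 blocks is subject to selection bias (molecules whose noisy fragment
   happens to sit near the current consensus get 1:1 blocks, others are
   merged away), which shrinks real insertions and can random-walk over
   rounds; the capped sizing term in step 1 guarantees that molecules
   carrying a large true deviation still present 1:1 blocks, so the
   estimator ratchets to the true mass. At 30x with 6% sizing noise the
   typical (median) fragment-mass error is ~1.5%; no unbiased estimator
   can do much better (the per-fragment sampling sd is ~1.4%);
3. consensus cuts whose concordant/spanning support falls below
   `keep_frac` (0.4) are deleted (requiring >= 2 spanning molecules, so a
   lone molecule cannot delete a cut at a sparse edge);
4. clusters of unmatched molecule cuts (single-linkage, tolerance
   3 sigma of the local fragment) supported by `add_frac` (0.4) of locally
   spanning molecules are added.

Two refinement passes are run per window per global round
(`refine_rounds`): the first corrects masses, the second re-evaluates cut
additions and deletions against the corrected masses -- without the second
pass, the transient coordinate shift around a real indel mints spurious
cuts. `keep_frac`/`add_frac` sit between the digestion efficiency (0.8)
and the false-cut regime, so true cuts survive and spurious clusters do
not. Fragments below 0.4 kb are merged in the final consensus, matching
the resolution at which maps are compared.

Seven further global rounds (8 total) re-try the still-unaligned molecules
against the current consensus of the windows around their best (rejected)
placement, with the forgiving acceptance; newly recruited members trigger
re-assembly of their window. Aligned counts are non-decreasing by
construction. This is how molecules carrying large alterations, rejected
against the plain reference in round 1, are gradually incorporated.

The consensus tracks, for every cut, which seed cut it descends from
("provenance"); novel cuts carry none.

## Calling structural alterations

Because the consensus descends from the reference seed, classification
does not need to re-align: shared cuts (by provenance) partition both maps
into corresponding segments, and differences read off directly.
Reference cuts without a descendant are MCs; novel consensus cuts are ECs
(placed by interpolation between flanking shared cuts); a segment whose
mass deviation reaches `max(0.13 * r, 4.5 kb)` is an INS or DEL when the
segment is otherwise difference-free. Sub-threshold indels are never
emitted -- they surface only as cut differences, which is also why about a
third of real ECs/MCs represent small indels below the platform's ~3 kb
resolution. Any run of >= 2 differences within 3 consecutive reference
fragments collapses into a single OTHER call. Two rescue rules precede
calling: a novel cut within 2.5 kb (mapped coordinates) of a
descendant-less reference cut is re-identified with it, and when a
segment contains equally many novel and descendant-less cuts they are
paired in order -- both patterns are one cut transiently deleted and
re-discovered during refinement, not an EC/MC pair. The indel threshold
is quantized to the 0.001 kb mass grid so the calling boundary is exact.

Inversions are not emitted by this classifier; they are established by
targeted assembly (below) -- matching the workflow in which hypothesis
maps, not consensus-versus-reference comparison, resolve large
rearrangements.

**Support scoring.** Every call receives a p-value from the error model:
EC -- binomial upper tail of observing k concordant cuts out of n spanning
molecules under the spurious-cut rate over the local fragment; MC --
binomial lower tail of k cut sightings out of n under the digestion
efficiency; INS/DEL -- two-sided normal tail of the mean mass deviation
with per-molecule variance `(sizing_cv * r)^2` (requiring >= 5 mass
observations, the same depth the assembler itself requires). Cut
differences flanked by reference fragments below the desorption limit
(0.8 kb) are the expected signature of small-fragment loss and score 1;
likewise the MC null is adjusted by the desorption survival probability
when a flanking fragment is sub-observable. Size calls are not made on a
window's terminal segments (no bounding cut on one side) or on segments
whose reference mass is below the observability floor; and a size call on
a *suspect* segment -- below the ~3 kb platform resolution, or bounded by
a cut flanking a sub-observable fragment, where cut identity is ambiguous
-- must additionally be reproduced by the overlapping neighbor window
(window-private indels at such segments are assembly artifacts). Calls are then thinned by Bonferroni at `alpha = 0.05` over
all tested loci (cuts plus fragments across windows), de-duplicated
across overlapping windows within the class-specific intersection window
(keeping the higher-support record), and an OTHER bundle is dropped when
another window explains the same locus with a specific call.

## Targeted (hypothesis-driven) assembly

`make_hypothesis_map()` builds an in-silico map of
flank + rearranged interval + flank (default flanks 500 kb): an inversion
reflects the interior cuts about the interval (exact for a palindromic
recognition site); a deletion excises the interval's mass.
`targeted_assembly()` runs the same 8-round iterative assembly seeded from
the hypothesis and judges `supported` only if at least `min_bridge` (5)
molecules have aligned blocks crossing *each* breakpoint. A wrong
hypothesis fails to recruit molecules across its breakpoints -- the
assembly "does not grow" -- while the correct one produces a consensus
bridged on both sides.

## Copy number from aligned coverage

Each accepted alignment is summarized by its midpoint. Because alignment
density varies with local restriction-site density, intervals are defined
from a *normal* sample so that each contains exactly `m` normal midpoints;
under no copy change the tumor count per interval is then a single
negative-binomial draw genome-wide. The NB-HMM has integer states 0-4,
emission mean `mu * k / 2` (state 0 floored at `0.05 mu`), dispersion by
method of moments on counts within `0.5 mu .. 1.5 mu`, sticky transitions
(`stay_prob = 1 - 1e-4`, giving mean segment lengths far above the
interval scale, i.e. arm-scale events), and Viterbi decoding in log space.

By construction the counts are negative binomial with `size = m` exactly
(a Poisson rate integrated over a Gamma-distributed interval width), so
the dispersion is floored at `1/m` and estimated from normalized counts
within +/-25% of the anchor only -- a wider estimation window swallows the
half-rate (copy-1) cluster and inflates the dispersion several-fold,
flattening the decode. The per-chromosome remainder interval holds more
than `m` normal midpoints, so emission means scale with each interval's
actual normal count. The diploid anchor itself is chosen from a small
candidate set around the tumor/normal totals ratio, each refined
self-consistently from its diploid-decoded intervals; among anchors whose
decode gives a diploid *majority* (the decode-space analogue of
median-as-diploid, valid while aberrations cover less than half the
genome) the best-fitting one wins. Requiring the majority rather than
maximizing it matters: maximizing the diploid fraction would reward the
degenerate decode that calls everything diploid. The anchor still fails,
by construction, when more than half the genome is aberrant; a warning
flags that regime. The standalone `fit_model()` keeps the simpler
windowed-median anchor for direct use on a count vector.

Per-slice analysis (`per_slice_cnv()`) runs the identical pipeline per
source label on one shared set of normal intervals and reports intervals
whose decoded states differ between labels -- the signature of intra-tumor
heterogeneity, as when two adjacent tumor slices carry different arm
losses.

## Somatic filtering

`intersect_panel()` matches calls to panels of known variation only
within the same type, after expanding the call by a class-specific
window: 100 bp for MCs, 4200 bp for ECs, 0 bp for INS/DEL/OTHER against
optical-map panels; 100/3000 bp against SNP panels; external
(sequence-derived) events route by size -- below 3 kb they are compared to
cut classes (small indels surface as cut differences), at or above 3 kb
to INS/DEL/OTHER with no window. "Window" means symmetric expansion of
the call interval before >= 1 bp overlap testing, with EC/MC represented
as 1 bp intervals at the inferred cut; expansion is symmetric between
query and panel. `filter_somatic()` keeps as somatic candidates exactly
the calls matched in no panel, with per-panel tallies; candidates and
removed calls partition the input, and adding a panel can only shrink the
candidate set.

## Problem sizes used in the test suite

The packaged validation scenarios run on i.i.d. 10-15 Mb genomes at 30x
coverage with 20 simulation seeds per scenario -- large enough that every
window reaches the depth regime of the real datasets while a full suite
completes on a laptop. The five-variant recovery scenario implants 10 kb
INS/DEL, one site gain, one site loss and a 30 kb insertion (the one that
requires iterative recruitment); copy-number scenarios use a 30 Mb
two-state chromosome (copy 1 vs 2) with the breakpoint a third of the way
in, and `m = 60` normal midpoints per interval: the per-interval
discrimination scales as `1 / sqrt(4/lambda + 4/m)`, so both the diploid
rate (~65 here) and `m` must be large for single-interval state calls to
be reliable. The per-slice scenario gives two slices a shared loss and
one slice an extra 10 Mb arm loss, each slice's losses staying under half
its genome so the diploid anchor is valid.

## Known limitations

* Reference-free (de novo) assembly is out of scope; all consensus maps
  are seeded from a reference or hypothesis map.
* One molecule receives one location or none: split/chimeric alignments
  and translocation discovery are not modelled.
* Consensus mass estimates shrink mildly toward the seed for very large
  deviations (the apportioned-median estimator trades a few percent of
  bias for robustness), so size deltas of large insertions are slight
  underestimates; classification thresholds account for typical fragment
  sizes, not this shrinkage.
* Cut differences co-located in one inter-anchor segment are interpreted
  as a cut position shift rather than an EC/MC pair; a true adjacent
  gain-plus-loss within one segment would be reported through the
  segment's mass deviations instead.
* Integer copy states only, no subclonal mixtures within one label; the
  median anchor fails above 50% aberrant genome (warned).
* The simulator emulates fragment-level error processes, not image-level
  artifacts, and i.i.d. reference sequence carries no repeat structure;
  specificity on real genomes will be bounded by segmental duplications
  that these tests cannot probe.
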