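---
title: "Detecting diversity-generating retroelements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversity-generating retroelements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscan)
```

## The biological problem

Diversity-generating retroelements (DGRs) are prokaryotic cassettes that
rewrite a short stretch of a target gene — the variable repeat (VR) — using
an error-prone reverse-transcribed copy of a nearby template repeat (TR).
The copying step is mutagenic in a peculiar, base-specific way: only
positions that are adenine in the TR change, so TR and VR differ exclusively
by A-to-B substitutions (B = C, G or T). A cassette consists of a reverse
transcriptase (RT) gene, one TR, and one or more VRs, each usually inside a
protein-coding target gene.

This signature — two near-identical repeats whose differences sit only at
the adenines of one of them, close to an RT gene — is highly specific and
searchable. `dgrscan` implements that search plus the downstream analyses:
cassette assembly and architecture classification, RT motif annotation,
substitution-spectrum statistics, GenBank annotation output, and a
synthetic-genome generator that makes the whole pipeline verifiable without
any external data.

## The scan algorithm

The detector is anchored on RT genes. For each RT coding sequence (from
GenBank CDS features or a tab-separated anchor table) it extracts the CDS
plus 5 kb to each side, represented on the RT-coding strand — the scan frame
throughout; for a minus-strand RT the region is reverse-complemented.

Within the region, every 50-nt window (step 1) is a TR candidate. A window
matches a placement elsewhere in the region when **all its non-adenine bases
match exactly**; adenine positions are free ("wildcard"). Each seed match is
extended one position at a time — leftward first, then rightward — while the
wildcard match rule holds and neither interval crosses the region boundary
or the other interval; the result is maximal. Because the window-derived
sequence is the one whose adenines are exempt, the window side is the TR and
the matched side the VR; the reversed assignment can never match (a
substituted VR base is non-wildcard and disagrees with the TR's adenine), so
role assignment is intrinsic, not a convention.

Maximal pairs are deduplicated (adjacent seeds collapse to the same maximal
pair; pairs strictly contained in another pair are dropped) and filtered:

* at least **10 adenines** in the extended TR — a TR with 9 mutable
  positions bounds the achievable repertoire below \(4^9 \approx 2.6\times
  10^5\) variants, too small to be a useful diversification substrate;
* at least **7 A→B substitutions** in the extended pair — exact or
  near-exact repeats are recent duplications, not diversified elements.

Both thresholds are exposed; lowering the substitution cutoff to 5 is the
documented sensitivity mode.

### The generalized wildcard and inverted cassettes

Reassigning the wildcard role to T reveals cassettes whose TR, VR and target
gene sit on the **opposite** strand from the RT: an A-specific element on
the other strand appears, in the RT-coding frame, as a repeat pair whose
mismatches sit at T positions. Such hits are reported with
`strand_relation = "inverted"` and minus-strand intervals. The C and G
sweeps are negative controls: genuine DGRs have no C- or G-specific signal.

### Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere — in memory, in tibbles and
  on disk. This is the R/Bioconductor convention (IRanges, GenomicRanges)
  and the native convention of GenBank and the TSV reports, so no
  conversion boundary exists anywhere in the package.
* `N` matches nothing, neither as wildcard nor as target; any compared
  column containing `N` is a mismatch, so `N` columns terminate extension
  and disqualify seeds. Other IUPAC codes are mapped to `N` on input with a
  warning. This is deliberately conservative: inventing partial-match
  semantics for ambiguity codes would manufacture hits from uncertain base
  calls.
* TR and VR intervals must stay disjoint, including during extension
  (extension stops one step before overlap). In a tandem-periodic region a
  matching run can exceed the TR–VR offset; extension is then greedy
  leftward first, then rightward. The spec of the extension is therefore
  deterministic, and the independent test oracle implements the identical
  rule.
* Substitution and adenine counting happen on the *extended* repeat, not
  the seed window: the filters describe properties of repeats, and the
  window is merely the search primitive.
* A window at or beyond the window length consisting of a single base is
  degenerate under that base's wildcard (every position is exempt, so it
  matches any placement). This is a property of the algorithm, not a bug;
  it is why the synthetic decoy set uses a homopolymer tract shorter than
  the window (see below).
* No maximum repeat length is enforced; observed pairs in real data stay
  under ~180 bp, and lengths are simply reported.

## Cassette assembly and classification

Hits from one region whose TR intervals reciprocally overlap by ≥ 90% are
merged into one cassette (union TR, distinct VRs sorted by position). The
threshold is a design choice: near-identical TR intervals from adjacent
seeds must unify, while genuinely different TRs — which in practice are
either disjoint or barely touching — must not.

A VR is assigned to a target ORF only when fully contained in a CDS on that
CDS's strand; partial overlaps and intergenic VRs are flagged
(`unassigned_vr`), not resolved — fused or mispredicted ORFs are reported
rather than guessed at.

Architecture groups follow the relative position of TR and RT evaluated in
RT-coding orientation:

| group | rule |
|-------|------|
| 1 | TR entirely upstream (5′) of the RT CDS |
| 2 | TR entirely downstream |
| 3 | TR overlaps the RT CDS (a TR fully inside is folded into group 3 and flagged `tr_inside_rt`) |
| 4 | TR on the other strand — the strand test takes precedence |

Subgroups encode the VR layout. Each VR is placed into one of four
categories in the RT-coding frame: `U` (before both TR and RT), `B`
(between them), `D` (after both), `O` (overlapping the RT CDS). The
subgroup letter indexes the canonical enumeration of `(n_vr, placement
tuple)`: `n_vr` ascending, placement tuples in lexicographic order over
`U < B < D < O`. Hence for one VR: `U → a`, `B → b`, `D → c`, `O → d`; the
two-VR block starts at `e` (`UU → e`, `UB → f`, …), and letters continue
`z, aa, ab, …` indefinitely. The prototypical VR–TR–RT arrangement is
therefore subgroup **a** of group 1 by construction, and any new
arrangement receives a fresh, reproducible letter. The enumeration is a
deterministic function of the geometry, so permuting the input hit order
can never change a label.

## RT motif annotation

DGR RTs carry three diagnostic features, all annotated from the protein
string alone:

* **YxDD** (domain 5): first N→C match of `[YF]xDD`; the two aspartates are
  invariant in real elements, the first position tolerates F, and the
  variable second position (commonly M or V) is reported.
* **Region-4 heptamer**: `[ILV]Gxxx??` searched within the 100 residues
  preceding YxDD (the nearest candidate to YxDD wins; whole-protein scan if
  YxDD is absent). The terminal dipeptide classifies the motif:
  `SQ` canonical, the named variants `SP, SH, NQ, PA, AQ, VQ`, anything
  else `other`, and no `[ILV]G` heptamer at all `absent` — which is what a
  retroviral-type `QGxxxSP` RT produces. Locating region 4 relative to YxDD
  rather than by multiple alignment keeps the annotator dependency-free; the
  100-residue window is generous for the region-4-to-region-5 spacing in RT
  families.
* **Charge patch**: the 20-residue window from YxDD to the C-terminus
  maximizing the R+K count (ties to the smallest offset; histidine is not
  counted). Ten or more R/K (≥ 50%) sets the `positive_patch` flag.

`X` never matches any pattern position.

## Substitution statistics

`substitution_profile()` counts, per element, the base found at each
TR-adenine position of the VR. Elements are weighted equally in the
aggregate means and standard deviations — each element is one observation of
the mutagenesis process, regardless of its adenine count. Unchanged-A
positions are reported but flagged uninterpretable: an A in the VR can stem
from faithful copying or from random incorporation of A, and the two are
indistinguishable in sequence data.

`chisq_uniform()` tests the three substitution-target totals against equal
expectation (df = 2; for df = 2 the p-value has the closed form
\(e^{-\chi^2/2}\), which the tests exploit as an independent check).
`chisq_proportional()` tests, per target base, whether per-element counts
are proportional to the element's TR adenine content — the no-selectivity
null. The construction pins one defensible recipe: expected count =
total × n_A / Σn_A, cells with expected < 1 pooled (and folded into the
smallest remaining cell if still < 1), df = cells − 1, raw p-values with no
multiple-testing correction. The `diversity()` bound is exact as an integer
up to n = 26 adenines (the 2^53 double limit); beyond that it is the
correctly rounded power.

## The synthetic-genome generator

`make_genome()` assembles a contig from i.i.d. background at a configurable
GC fraction (default 0.40, a moderately AT-rich bacterial contig) with:

* an RT ORF reverse-translated from a `make_rt_protein()` protein embedding
  the requested motif profile (length uniform in 260–527 aa, region-4
  heptamer 60–90 residues upstream of YMDD, an R/K-rich C-terminal window;
  the background is scrubbed of accidental `[YF]xDD` and `[ILV]G` patterns
  so the planted motifs are the ones found);
* a TR with a chosen adenine count (default 110 nt, 33 adenines — 30% A
  matches the background composition; typical real VRs are 100 ± 50 nt);
* one or more VRs, each a TR copy with an exact number of substitutions at
  adenine positions sampled without replacement, targets drawn with weights
  C:G:T = 1:3:2 (G commonest, C rarest, the observed spectrum), each VR
  embedded in its own target CDS;
* decoy repeats: an exact duplication, a 6-substitution repeat, a repeat
  with non-adenine mismatches only, and a 30-nt homopolymer tract;
* arrangement groups 1–4 (group 3 derives its TR from the natural sequence
  straddling the RT start; group 4 plants the reverse complement of the
  element with the target CDS on the minus strand).

Two construction details matter for exact-coordinate validation:

* **Guard bases.** Each planted repeat (and each guarded decoy copy) is
  flanked by a C/G mismatch pair chosen in the scan frame, so maximal
  extension stops exactly at the planted coordinates. Without guards,
  extension walks freely through background adenine columns — and each such
  column with a differing partner base counts as a substitution, so even an
  *exact* duplication flanked by A-rich background can occasionally pass
  both filters. That is faithful algorithm behaviour on unguarded tandem
  duplications, and the generator controls it rather than leaving it to
  chance.
* **Target mixing.** Substitution targets are resampled until no 7
  consecutive substitutions share one target base. A same-target run of
  filter length is, in the parent frame, a coherent repeat under that
  base's wildcard: a strongly G-biased inverted element would otherwise
  occasionally yield a short mirror fragment in the C sweep. Real VR
  spectra are mixed (the cross-wildcard sweeps of genuine elements find
  nothing), so the constraint is part of emulating them.

The truth table records every planted interval (1-based inclusive, the same
convention as the hit reports), strand, substitution positions, and whether
the element is detectable at default thresholds (≥ 10 TR adenines, ≥ 7
substitutions, length ≥ window).

What the generator does **not** emulate: higher-order sequence structure
(the background is i.i.d., with no codon bias, repeats or skew),
mutagenic-homing dynamics over time, sequencing error, or phage/plasmid
context. Passing tests therefore demonstrate correctness of the detector's
semantics on its defining signal and its specificity against the modelled
artefact classes — not performance on the full messiness of real genomic
data (e.g. "sloppy" elements whose repeats contain non-adenine mismatches
are invisible at the chosen stringency by design).

## Problem sizes and verification strategy

The test suite validates the scanner against an independent brute-force
oracle — a pure-R per-shift mismatch-vector enumeration, structurally
unrelated to the C++ seed-and-extend implementation — exactly, on 100
random 2-kb sequences with and without planted elements. Planted-element
recovery and decoy specificity run over 200 synthetic genomes (~16 kb
each); inverted-mode recovery over 10 group-4 genomes under all four
wildcards; the GenBank writer round-trips 50 annotated contigs (one test
additionally cross-checks coordinates in Biopython); chi-square closed-form
agreement uses 1000 random tables and the proportionality test's size is
estimated from 1000 null replicates (multinomial counts proportional to
adenine content, expected cell counts ≥ 4 by design). These sizes give the
properties room to fail while keeping the default test run quick.

## Known limitations

* The scan is O(region² · window) per region; at the default ~11-kb regions
  this is well under a second, but whole-genome (megabase) scans should go
  through `find_distal_targets()`, which searches CDS features only.
* Repeats truncated by contig ends (elements on contigs shorter than the
  cassette) are clipped, not recovered.
* Subgroup letters are canonical to this package's enumeration; they encode
  the same geometry as published diagrams but are not guaranteed to
  coincide with any particular published lettering beyond the pinned
  prototype (group 1a).
* `diversity()` is exact only to n = 26 adenines as an integer.
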