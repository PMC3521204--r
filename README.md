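# dgrscan

Detection and analysis of **diversity-generating retroelements (DGRs)** in
bacterial and phage DNA.

DGRs are cassettes that diversify a target protein by repeatedly rewriting a
short *variable repeat* (VR) inside its gene with an error-prone
reverse-transcribed copy of a nearby *template repeat* (TR). The copying
step mutates **only adenines**: TR and VR are identical except at TR-A
positions, where the VR may carry any base (A→B substitutions, B ∈ {C, G,
T}). A cassette comprises a reverse-transcriptase (RT) gene, one TR and one
or more VRs.

`dgrscan` finds this signature with a sliding-window, wildcard-base repeat
search anchored on RT genes: every 50-nt window of the ±5-kb region around
an RT is matched against every placement where **all non-A bases match
exactly**, matches are maximally extended, and pairs are kept when the
extended TR has ≥ 10 adenines and the pair shows ≥ 7 A→B substitutions.
Formally, a window `w` at offset `i` matches a placement `j` iff

    ∀k : w[k] = A  ∨  w[k] = s[j + k]      (N matches nothing)

and the reported repeat is the maximal extension of that seed under the same
rule. Reassigning the wildcard to T exposes *inverted* cassettes (TR/VR and
target on the opposite strand from the RT). The package is intended for
microbiologists and mobile-element researchers who want to screen contigs or
annotated genomes for DGRs and characterize what they find.

Beyond detection it provides:

* **Cassette assembly and classification** — merging multi-VR hits,
  strand-aware VR→target-ORF assignment, architecture groups 1–4 (TR
  upstream / downstream / overlapping the RT / on the other strand) with
  deterministic subgroup letters (the prototypical VR–TR–RT layout is 1a).
* **RT motif annotation** — the DGR-diagnostic (I/V/L)GxxxSQ region-4
  heptamer and its variants, the YxDD catalytic motif, and the positively
  charged C-terminal patch.
* **Substitution statistics** — per-element base frequencies at TR-adenine
  positions, the 4ⁿ repertoire bound, a χ² test of target-base uniformity
  and a χ² test of proportionality to TR adenine content.
* **GenBank I/O** — reads annotated GenBank or FASTA (+ RT anchor table)
  input and writes Artemis-compatible annotated GenBank output.
* **A synthetic-genome generator** — contigs with planted cassettes
  (groups 1–4, chosen adenine counts and substitution spectra, RT proteins
  with requested motif profiles) and decoy repeats, plus machine-readable
  truth tables, so the whole pipeline is testable offline.

## Worked example

Generate a synthetic contig with a two-VR cassette, scan it, classify the
cassette and profile the substitutions:

```r
library(dgrscan)

out <- tempfile(); dir.create(out)
cmd_synth(plant_spec(seed = 42, n_vr = 2, n_adenines_tr = 30,
                     substitutions_per_vr = 10), out_dir = out)
cfg  <- run_config(input = file.path(out, "genome.gb"), out_dir = out)
hits <- cmd_scan(cfg)
hits[, c("tr_start_parent", "tr_end_parent", "vr_start_parent",
         "vr_end_parent", "length", "n_wildcard_tr", "n_substitutions")]
#>   tr_start_parent tr_end_parent vr_start_parent vr_end_parent length
#> 1             957          1066             242           351    110
#> 2             957          1066             644           753    110
#>   n_wildcard_tr n_substitutions
#> 1            30              10
#> 2            30              10
```

Two hits share one TR (957–1066): a 110-nt template with 30 adenines copied
into two VRs, each differing at exactly 10 adenine positions. Both VRs lie
upstream of the TR, which lies upstream of the RT:

```r
cmd_classify(cfg)[, c("group", "subgroup", "n_vr", "unassigned_vr")]
#>   group subgroup n_vr unassigned_vr
#> 1     1        e    2         FALSE
```

Group 1 (TR upstream of the RT), subgroup `e` (the first two-VR layout in
the canonical enumeration: both VRs upstream of the TR), and every VR
contained in a target ORF. The substitution profile aggregates the base
found at each TR-adenine position of the VRs:

```r
cmd_stats(cfg)$profile
#> <dgr_substitution_profile> 2 element(s)
#>   base  mean_freq sd_freq
#> 1 A         0.667   0
#> 2 C         0       0
#> 3 G         0.183   0.118
#> 4 T         0.15    0.118
```

Two thirds of TR adenines are unchanged in the VRs; among the substituted
positions G outnumbers T, with no C — the planted 1:3:2 C:G:T bias at work
in a small sample. Finally, the diversification capacity of a TR with nine
adenines:

```r
diversity(9)
#> [1] 262144
```

i.e. < 2.6 × 10⁵ possible VR variants — the rationale for the ≥ 10-adenine
filter. `autoplot()` on the profile and `plot_cassette_map()` on classified
cassettes give ggplot2 graphics; a thin command-line wrapper lives in
`inst/cli/dgrscan.R` (`Rscript dgrscan.R scan --input genome.gb --out dir`).

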