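---
title: "Methods: trio de novo variant filtering, confirmation and QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio de novo variant filtering, confirmation and QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodnv)
```

## The problem and the model

A de novo variant (DNV) is present in a child's germline but in neither
parent's. At trio scale the signal is tiny — tens of true events against
millions of inherited variants and a background of genotyping error — so
DNV calling is dominated not by discovery but by filtering. `triodnv`
models the filtering stage: it assumes joint-genotyped multi-sample VCFs
(with per-sample GT, DP, GQ and AD) from **two independent callers** are
already available, and treats agreement between them as the first line of
defence against caller-specific artefacts.

The decision procedure for each candidate is a conjunction of eight rules
(child genotype het/hom-alt; parents hom-ref; cross-caller intersection;
site depth; child GQ; child allele fraction; zero parental alt reads;
region blacklist). The conjunction structure makes auditing natural: each
rule is evaluated independently and its outcome recorded, so every
rejected candidate names the rules that rejected it and
`count(candidates) = count(final) + count(records with ≥ 1 failed rule)`
always reconciles.

### Variant identity

"Intersection of two callsets" is only well defined once both sides agree
on what a variant *is*. Callers spell the same indel differently, so every
record is reduced to a canonical form before any matching:

* multi-allelic records are decomposed, one output record per alternate
  allele, genotypes recoded into that allele's {0, 1} space (other
  alternate alleles map to 0, missing stays missing) and AD collapsed to
  (ref count, this-alt count);
* shared suffix bases are trimmed; indels are shifted left through repeat
  tracts by extending with the preceding reference base until no further
  equivalent spelling exists; the shared prefix is trimmed except for the
  single anchor base an indel retains.

The result is the unique leftmost minimal spelling, and the matching key is
exact equality of `(chrom, pos, ref, alt)` after this normalization. No
fuzzy or position-window matching is attempted: strict identity is the one
interpretation that is reproducible across implementations. The test suite
verifies the canonical form against a brute-force oracle that enumerates
every reference-consistent equivalent spelling of a haplotype change and
checks all of them collapse to a single key.

## Filter parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth` | 10 | reads | below ~10× a heterozygous genotype is statistically unstable |
| `min_gq` | 20 | phred | 1% genotype-error ceiling for the child call |
| `min_child_vaf` | 0.25 | fraction | a germline het should be near 0.5; 0.25 tolerates sampling noise while excluding mosaic/artefact tails |
| `max_parent_alt_reads` | 0 | reads | a single parental alt read is more consistent with an inherited variant or shared artefact than with a DNV |
| `depth_scope` | `all_trio` | — | an undercovered *parent* silently weakens rule 7; see below |
| `numeric_scope` | `both_callers` | — | both callers vouched for the variant, so both evidence sets must clear the bars |

All thresholds on evidence are **inclusive** ("at least"): depth 10 passes,
GQ 20 passes, VAF exactly 0.25 passes. The confirmation stage (below)
deliberately differs.

Two scope choices were genuinely open:

* **Which samples must meet the depth floor?** The rule as usually stated
  names only "the site". Requiring ≥ 10× in all three members is the
  conservative reading — a parent at 3× cannot demonstrate the absence of
  the allele — and is the default; `child_only` is available.
* **Must both callers' numeric evidence pass, or just one?** Since the
  intersection rule already demands both callers emit the variant,
  requiring both evidence sets to pass (`both_callers`) is the consistent
  strict reading; `either_caller` is available for sensitivity-oriented
  runs.

Each rule can also be disabled outright (`rules_enabled`), in which case it
is recorded as `not_evaluated` and excluded from the verdict — useful for
ablation experiments and for auditing what a single rule contributes.

Further fixed conventions: the VAF denominator is `AD_ref + AD_alt`, not
DP, because AD is allele-resolved while DP may count uninformative reads;
missing evidence always *fails* the affected rule (never errors, never
passes); haploid child genotypes (`1` on chrX/Y) count as hom-alt by
default; alleles containing N are carried through normalization but
flagged and never pass.

## WES confidence zones and pileup rescue

Exome capture BEDs are customarily distributed with a flank ("buffer")
already added to each target — assumed 50 bp per side. Coverage decays
toward the flank edges, so calls there are less trustworthy. With
`assumed_buffer = 50` and `margin = 10`, each padded interval `[s, e)` is
split into a high-confidence core `[s+40, e-40)` (the unpadded target
±10 bp) and two 40 bp low-confidence flanks. Intervals too short to hold a
core (`length ≤ 80`) are entirely low-confidence, with a warning. Both
parameters are exposed because capture kits differ.

High-confidence DNVs must additionally pass a pileup **rescue** test: in
samtools-mpileup evidence, counted at *any* base quality, the alternate
allele must appear at least once in the child and never in either parent.
Low-confidence and off-target DNVs keep their labels but are not subjected
to the test — the rescue defines the final *high-confidence* callset and
there is no analogous statement for the low tier, so the package reports
rather than filters there.

Coordinate conventions throughout: VCF and mpileup positions are 1-based;
BED is 0-based half-open; all internal interval arithmetic is 0-based
half-open, converted only at I/O boundaries. Zone queries are point
queries on the variant's position; blacklist queries use the variant's
full reference span (a 5 bp deletion can overlap a blacklisted region its
anchor base does not touch).

## High-coverage confirmation

Given an independent, much deeper sequencing run of the same trio
(emulated at 300×), a DNV is *confirmed* when the child's pileup VAF is
strictly above 25% and both parents' are strictly below 1% — the parent
cutoff matching the typical Illumina per-base error rate. Note the
asymmetry with the calling filter: calling uses `VAF ≥ 0.25` (inclusive),
confirmation uses `VAF > 0.25` (strict). Both are implemented exactly as
stated, per stage; tests pin the boundary at equality on both sides. The
confirmation VAF denominator is the full pileup depth (all covering
reads), not ref+alt, since that is what a pileup naturally reports.
Samples with zero depth yield `no_data`, which is excluded from the
confirmation-rate denominator and reported separately.

## QC metrics

* **Ti/Tv** — transitions (A↔G, C↔T) over transversions, SNVs only; with
  no transversions the ratio is undefined and reported `NA`. Uniformly
  random substitutions give 4/8 = 0.5; germline callsets sit near 2.
* **CpG fraction** — an SNV is at a CpG site iff its reference base is a C
  immediately followed by G or a G immediately preceded by C (the
  dinucleotide on either strand, read from the reference FASTA).
  Contig-edge positions lacking the neighbour are never CpG. Indels are
  excluded from the numerator and, by default, the denominator — both
  statistics are substitution-defined. A CpG-island/window definition
  would need external annotation and is deliberately out of scope.
* **Callset overlap** — for 2–8 named callsets of normalized keys, the
  count of keys in each exact membership pattern (the numbers behind an
  upset plot); counts provably sum to the union size.

## The synthetic trio simulator

Everything above is testable offline because the package generates its own
study conditions. `simulation_config()` defaults encode them: two 100 kb
random contigs (GC 0.40); 50 true DNVs per trio (the scale of a real
genome's DNV count); 100 inherited variants; 5 planted violations per
filter rule, each violating *exactly one* rule; caller discordance 0.2
(each true DNV has a 20% chance of being emitted by only one caller);
per-sample depth ~ NegBin(mean 30, size 8) floored at 12× for clean sites;
child DNV allele fraction ~ Beta(20, 20) truncated to (0.30, 0.70); parent
pileup error rate 0.001. Each caller sees independently jittered DP/GQ/AD
so the `both_callers` scope is genuinely exercised; the jitter is bounded
so a planted clean DNV can never drift across a threshold. A fraction of
inherited variants is emitted as deliberately non-minimal spellings and a
handful as multi-allelic records, so normalization and decomposition run
inside the end-to-end path, not only in unit tests. mpileup text is
synthesized directly with read-start/end markers, strand-cased bases and
`+N`/`-N` indel tokens, so the parser is tested against known counts
without requiring samtools.

What the simulator does **not** emulate — and what passing tests therefore
do not show: alignment and mapping artefacts (the blacklist here is random
rather than repeat-derived), systematic error motifs shared between
parents and child, index hopping or contamination, cell-line artefacts,
and caller-specific biases beyond independent jitter. Recovery of 100% of
planted DNVs on this fixture demonstrates the *filter logic* is faithful,
not that real-data sensitivity is 100%.

Deep confirmation evidence is simulated as Binomial draws: child alt ~
B(300, planted VAF), parent alt ~ B(300, 0.001). At those parameters a
true het DNV is confirmed unless the child draw falls below 75/300
(≈ 10 SD below the mean) or a parent draws ≥ 3 error reads (probability
≈ 0.4% per parent), which is why the acceptance test requires a ≥ 99%
confirmation rate rather than 100%.

## Problem sizes and determinism

The shipped tests run the default simulation (~190 emitted records per
callset), 1,000-record callsets for the intersection oracle, 12,000 draws
for the Ti/Tv Monte-Carlo check, 100 random fixtures for threshold
monotonicity, and 300 sites at 300× for confirmation — sizes chosen so the
whole suite exercises every code path in about a minute while keeping
Monte-Carlo bands narrow. Every stochastic step is seeded; a given seed
reproduces every output file byte for byte (no timestamps are written to
file bodies).

## Known limitations

* Exact-key matching will not pair callers that report the same event as
  different complex spellings (e.g. an MNP versus two SNVs); distance- or
  haplotype-based matching is out of scope.
* Rule 7 uses the callers' AD fields; a parental alt read visible in the
  alignment but absent from AD is only caught later, by the WES rescue or
  confirmation pileups.
* Hemizygous handling is a simple recode of haploid calls; sex-aware
  expectations (X-linked inheritance models) are not implemented.
* The mpileup dialect parsed is the plain text form without base-quality
  filtering; a lone `*` base column is read as zero coverage, and mapping
  quality columns beyond the first three per sample are ignored.
* Phase-of-origin (the ~75% paternal bias of DNVs) is reported nowhere:
  determining it requires read-backed phasing, which no module here
  attempts.
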