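# triodnv

De novo variant (DNV) detection and quality control for parent–child
sequenced trios.

A DNV is a variant present in a child but absent from both parents'
germlines; a typical genome carries on the order of 40–100 of them, with
characteristic signatures (roughly 20% at hypermutable CpG dinucleotides, a
transition/transversion ratio around 2). Reliable DNV calls matter for
studies of sporadic disease and of the germline mutation rate, but they sit
at the detection floor of short-read sequencing: a single misgenotyped
parent read or a low-quality child genotype produces a false DNV. `triodnv`
implements the post-genotyping half of that problem. It consumes two
joint-genotyped multi-sample VCFs for the same trio — one from each of two
independent callers (e.g. a GATK-style and a DeepVariant-style callset) —
and emits an audited DNV callset.

## The filtering model

Every variant is first reduced to a canonical identity: alleles are
trimmed, indels are left-aligned against the reference, and multi-allelic
records are decomposed into biallelic ones, so that the two callers'
records can be matched exactly on `(chrom, pos, ref, alt)`. A candidate is
then kept as a DNV only if it passes all eight of:

1. child genotype is `0/1` or `1/1`;
2. both parents are genotyped `0/0`;
3. the variant is present in **both** callers' callsets (the intersection);
4. read depth `DP ≥ 10` at the site (all three members, configurable);
5. child genotype quality `GQ ≥ 20`;
6. child variant allele fraction `AD_alt / (AD_ref + AD_alt) ≥ 0.25`;
7. zero parental reads carry the alternate allele (`AD_alt = 0` in both
   parents);
8. the site is outside the blacklist of recent repeats, low-complexity
   regions and centromeres.

Each rule's outcome (`pass` / `fail` / `not_evaluated`) is recorded
per variant, so the output table is an audit trail, not just a callset.

For exome (WES) data, capture BED intervals — distributed with an assumed
50 bp buffer per side — are split into a high-confidence core (the capture
target ±10 bp) and low-confidence 40 bp flanks; high-confidence DNVs must
additionally survive an mpileup test (alternate allele absent from both
parents at any base quality, present at least once in the child). An
independent high-coverage run of the same trio can then *confirm* each DNV
(child VAF > 25%, both parent VAFs < 1%, strict inequalities; the 1%
reflects the Illumina base error rate).

QC metrics — DNVs per child, percent at CpG sites, Ti/Tv, n-way callset
overlap counts — are built in, as is a synthetic-trio simulator that
generates a small reference genome, Mendelian-consistent caller pairs with
planted DNVs and per-rule violations, mpileup evidence and a truth table,
so the entire workflow is testable offline.

## Worked example

Simulate a trio, call DNVs, and compute callset metrics — either through R
functions (`simulate_trio()`, `read_trio_vcf()`, `intersect_callsets()`,
`call_dnvs()`, …) or the bundled CLI:

```sh
triodnv simulate --seed 11 --out-dir demo
triodnv call --vcf-a demo/callerA.vcf --vcf-b demo/callerB.vcf \
    --reference demo/reference.fa --blacklist demo/blacklist.bed \
    --child CHILD --father FATHER --mother MOTHER --out demo/dnvs.tsv
triodnv metrics --dnvs demo/dnvs.tsv --reference demo/reference.fa --out demo/metrics.tsv
```

which prints:

```
[read] caller A: 185 records; caller B: 183 records
[blacklist] 9215 bp excluded
[intersect] 178 pairs in both callers; 12 caller-private dropped by rule
[filter] candidates 190 -> final DNVs 43
[filter] rule child_genotype  failed by 5 record(s)
[filter] rule parents_homref  failed by 105 record(s)
...
[metrics] n=43, CpG%=16.27907, Ti/Tv=2.583333
```

Reading this: seed 11 planted 50 true DNVs of which 7 were made
caller-private (emitted by only one caller), so exactly 43 survive the
intersection — and exactly those 43 pass all eight rules. The 100 inherited
variants fail the parental-genotype and parental-read rules (105 counts
each: inherited plus the 5 planted single-rule violations), and each
violation class is rejected by precisely the rule it was built to break.
The final callset's CpG fraction (~16–20%) and Ti/Tv (~2–2.6) sit where
germline DNV callsets are expected to sit.

`triodnv wes-classify` adds capture-zone confidence labels and the pileup
rescue column; `triodnv confirm` adds high-coverage confirmation;
`triodnv compare` tabulates overlap patterns between named callsets.

## Package layout

- `R/` — normalization/decomposition, VCF/BED/FASTA/mpileup I/O,
  intersection, the eight-rule filter, WES confidence zones and rescue,
  confirmation, metrics, the simulator, and the CLI.
- `exec/triodnv` — the installed command-line entry point.
- `vignettes/dnv-filtering-methods.Rmd` — the methods vignette: model,
  parameters, simulator design, numerical conventions, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
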