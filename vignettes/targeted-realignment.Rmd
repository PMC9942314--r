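---
title: "Targeted re-alignment around reference genome errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted re-alignment around reference genome errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refix)
```

## The two error classes

A reference genome can misrepresent segmental duplications in two opposite
ways, and both corrupt short-read analysis in a characteristic, detectable
fashion.

A **false duplication** is an extra, near-identical copy of a locus that
exists in the reference but not in real genomes. Reads from the single real
locus are split between the two reference copies: an aligner finds two
equally good placements, assigns mapping quality (MAPQ) 0 to mark the
ambiguity, and spreads the pairs across both copies. The visible signature
is a region at roughly **half** the expected read depth in which most
records carry MAPQ 0. Variant callers filter on MAPQ, so heterozygous SNVs
in the region are simply lost — recall collapses. Across a cohort the few
variants that do get called show *heterozygote deficiency* (positive
inbreeding coefficients), because reads carrying an alternate allele that
matches the extra copy defect to it.

A **collapsed duplication** is the mirror image: two real, diverged
paralogs are represented by a single reference copy. Reads from both
paralogs pile onto that one copy, giving roughly **double** depth, and at
every *paralogous sequence variant* (PSV — a fixed difference between the
paralogs) the foreign reads masquerade as a ~50% allele-fraction
heterozygous variant in every sample. The cohort signature is an excess of
heterozygotes at these sites: strongly negative inbreeding coefficients,
with F near −1 when every sample is called het.

## The correction

Both errors are fixed by editing the reference and re-aligning only the
affected reads:

1. **Patch the reference** (`patch_plan()`, `apply_patch()`): hard-mask the
   extra copies of false duplications with `N` (hard masking, not lowercase
   soft masking, because aligners treat soft-masked bases as ordinary
   sequence — the point is that the ambiguous placement ceases to exist),
   and append the missing paralogs of collapsed regions as *decoy contigs*.
2. **Extract the affected read pairs** (`extract_reads()`): from the
   existing coordinate-sorted BAM, take every record with at least one base
   of overlap with the regions' *homolog intervals*, excluding records with
   flag bits unmapped / mate-unmapped / secondary / supplementary (the
   combined exclusion mask 2316, used consistently by the extraction, the
   diagnostics and the genotyper; duplicate-flagged and QC-fail records are
   deliberately retained). Records are grouped by read name; only complete,
   uniquely named pairs survive. A singleton whose mate lies outside the
   intervals is rescued by fetching the mate at its recorded position
   (default window 1,000 bp); unrescued singletons are dropped rather than
   emitted unpaired.
3. **Re-align** (`align_pairs()`) the pairs to the patched reference, via
   an external aligner command template or the built-in mapper (below).
4. Either keep the **regional** corrected BAM (the fast path) or
   **splice** the corrected records back into a genome-wide BAM
   (`splice_back()`), removing every record — including supplementary ones
   far from the regions — whose name was extracted, so no orphans remain.

The whole pipeline is `fix_alignments()`, or `refix fix` on the command
line.

## The built-in mapper

Real deployments should pass an external aligner through
`command_aligner()`. The built-in mapper (`builtin_aligner()`) exists so
the full workflow — and its failure modes — can be exercised without
external binaries, and it is deliberately simple:

* exact k-mer seeds (default `k = 21`, sampled every 5 bp of the read),
  diagonal-clustered into candidate loci;
* ungapped extension scoring **match +1, mismatch −4**, soft clips only at
  contig ends (no gapped alignment: indel-bearing reads drop below the
  score threshold and go unmapped — hence the genotyper is SNV-only);
* `MAPQ = min(60, 6 × (best − second best))`, with second best 0 when no
  other candidate exists, and **MAPQ 0 for tied best placements**. The
  constant 6 is a package choice; the only property downstream analysis
  relies on is that multi-locus reads get MAPQ 0 and unique placements get
  a high value.

**Pair handling.** Each end's candidates are first filtered to those that
can participate in a proper pair (same contig, opposite strands, template
length inside the insert window); an end whose individual best is
incompatible is moved only if a compatible candidate lies within one
mismatch of its best score. Each end is then placed *independently* at its
best retained candidate, and MAPQ is recomputed over the retained set: a
tie resolved by pair compatibility regains confidence, while a tie between
two complete copies (both pair-viable) keeps MAPQ 0. This is weaker than a
joint pair-score optimisation, deliberately: with a score-based pair
rescue, an ambiguous read whose mate happens to cover a divergent site
would be promoted to confident, and the MAPQ-0 signature of a false
duplication — the quantity the diagnostics measure — would be erased for
about a third of the tied reads. The cost of this choice is visible in the
collapse experiment (see *Limitations*).

**Tie-breaking.** Deterministic by default (lowest contig index, then
coordinate, then strand), so repeated runs are byte-identical. With
`tie_break = "random"`, each unresolved tie is broken uniformly at random
per read end from R's seeded RNG. Random mode is what reproduces the
realistic half-depth split over a false duplication; deterministic mode
would pile every tied read onto the first copy. Random placement is per
end, not per pair: pair-unit placement would couple each tied end to its
partner's divergence evidence and push the depth ratio to ~0.67 instead of
the observed ~0.55–0.6.

## Diagnostics

`mapq_summary()` reports per region the record count, mean MAPQ, and
MAPQ-0 fraction. For an `error_region_set()` the summary covers the
region's full affected span — target plus mask intervals — because the
tied reads of a false duplication are spread across both copies; after
masking, the extra copy is empty and the summary collapses onto the kept
copy.

`depth_summary()` computes mean per-position pileup depth over each target
and over user-supplied baseline intervals (which must be disjoint from the
error regions), and their ratio. Expected ratios: ~0.5–0.6 over an
unmasked false duplication, ~2 over a collapse, ~1 after a successful fix.

`inbreeding_coefficient()` is the plain single-population estimator
`F = 1 − H_obs / H_exp` from biallelic genotype counts. No small-sample or
population-structure correction is applied — cohort-scale pipelines use
population-adjusted versions whose exact form varies, and the plain
estimator carries the same qualitative signal (positive = het deficiency,
negative = het excess). `F` is undefined (`NA`) at monomorphic sites;
when the collapse experiment summarises "median F over PSV sites", a PSV
site with no called variant in any sample contributes F = 0, read as "no
detectable Hardy–Weinberg departure" — after a successful fix most PSV
sites are exactly that.

`cohort_site_stats()` reduces a multi-sample VCF to per-site mean depth and
F, grouped into region classes versus the rest of the genome, with
Tukey-style summaries (quartiles, whiskers at 1.5 IQR).

## The genotyper and the comparator

`pileup_genotype()` is a desk-scale pileup SNV caller: bases from records
passing the exclusion mask with MAPQ ≥ 20 and base quality ≥ 13 are
counted per position; a site with total passing depth ≥ 4 is called from
the most frequent non-reference base — heterozygous inside the allele
fraction band [0.2, 0.8], homozygous-alternate above it. Masked (`N`)
positions are skipped. It stands in for a production caller so the
experiments close end-to-end; its thresholds are exposed as arguments.

`compare_to_truth()` is an exact-genotype comparator: a truth SNV is a
true positive only when contig, position, both alleles, and genotype all
match; a genotype mismatch costs one FP plus one FN. No haplotype-aware
rescue or allele decomposition is attempted, making it strictly harsher
than production benchmarking tools. Multiallelic truth records are skipped
and counted. Recall, precision and the harmonic-mean F-measure follow,
each undefined when its denominator is zero.

## The simulator

`simulation_config()` / `simulate_bundle()` generate everything the
pipeline needs, deterministically from one seed:

* **FALSE_DUP** — truth has one copy of a 5 kb locus in 2 kb flanks; the
  erroneous reference duplicates the whole span (flanks included, as a
  real duplication artifact copies a region, not a gene boundary) at
  divergence 0.002 — a false duplication is a near-identical artifactual
  copy. The patch masks the extra contig.
* **COLLAPSE** — truth has two paralogs whose 5 kb loci differ at 1% of
  interior positions (PSVs kept ≥ 2 read lengths from the locus edges so
  every PSV is coverable by fully internal pairs; real paralogs are more
  diverged than duplication artifacts, hence the higher default); the
  reference carries only one. The patch appends the missing paralog, with
  its flanks, as a decoy.
* **CLEAN** — truth equals reference; empty patch plan.

Each bundle also carries an unaffected contig of the same size providing
the depth baseline and background variant sites. Per sample, heterozygous
SNVs are planted on one haplotype at 0.001/bp (human-like heterozygosity),
avoiding PSV positions so the truth bookkeeping stays interpretable.
Paired-end reads are drawn uniformly per haplotype with
Normal(350, 50) fragment lengths truncated at the read length, mate 1 from
the forward end, mate 2 reverse-complemented from the other end,
substitution errors at 0.2%/bp, constant Phred-40 base qualities, and pair
counts chosen so the expected diploid depth is 40×. The truth bundle
records the sampling coordinates of every pair for oracle checks.

What the simulator does **not** model: indels (the built-in mapper is
ungapped), quality-score error profiles, GC bias, chimeras, long reads and
spliced RNA alignment. Passing tests on these bundles therefore
demonstrates the pipeline's bookkeeping and the direction and rough
magnitude of the signatures, not calling accuracy on real data.

Determinism is per operation, not via one shared stream:
`build_truth_and_reference()` seeds from `config$seed`, and each sample's
reads seed from a value derived from the bundle seed and the sample index,
so any sample can be regenerated independently. Identical configuration
and seed reproduce a written bundle byte for byte; the manifest records
MD5 checksums.

## The built-in experiments

`run_false_duplication_study()` and `run_collapse_study()` run both
scenarios end to end (simulate → align to the erroneous reference with
seeded-random tie-breaking → fix with splice-back → genotype → benchmark)
and return the pre/post metrics. `scripts/acceptance.R` reports exactly
these quantities. Problem sizes — a 5 kb locus with 2 kb flanks, one
40× sample for the duplication scenario, ten for the collapse cohort —
are the package's study conditions; a single run of both experiments takes
a few minutes on one core.

Typical behaviour (the test suite asserts these under a fixed seed):

| quantity | false dup, pre | false dup, post | collapse, pre | collapse, post |
|---|---|---|---|---|
| depth ratio vs baseline | ~0.55 | ~1.0 | ~1.95 | ~1.0 |
| MAPQ-0 fraction / mean MAPQ | ≥ 0.8 | ~0 | high MAPQ | mean MAPQ drops |
| SNV recall | ≤ 0.3 | ~1.0 | ~0.9 | ~0.9 |
| SNV precision | (few calls) | ~1.0 | ~0.07 | ≫ pre |
| PSV sites called het | — | — | ~100% | ~0% |
| median F at PSV sites | — | — | −1 | ~0 |

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open (BED convention);
  conversion to 1-based happens only at the VCF boundary and when talking
  to Bioconductor range classes. One internal convention, no off-by-one
  churn.
* Abutting intervals merge during normalization (masking semantics are
  unaffected); normalization is idempotent and conserves covered bases.
* Empty inputs degrade gracefully: empty region sets produce empty (but
  valid, fully headered) BAMs; empty regions report `NA` summaries with
  `n_records = 0`; a zero denominator makes recall/precision/F `NA` rather
  than 0.
* Region configs are a header-bearing TSV (contig, start, end, label,
  kind, decoy_names) with homolog and mask intervals in label-keyed
  companion BEDs (`homologs.bed`, `masks.bed`) — the mask side-file keeps
  the main table rectangular while letting one region own several mask
  intervals.
* The homolog intervals of each region always contain the target and mask
  intervals (added automatically); how far beyond them to reach for reads
  is a user decision the config must state explicitly — the simulator pads
  by `insert_mean + 4·insert_sd` so that pairs straddling a region edge are
  still gathered.
* MAPQ-0 counts are reported raw alongside fractions; percentage changes
  are left to the reader, since a "percent fewer" headline depends on the
  choice of denominator.

## Limitations

* The collapse fix trades mapping confidence for correctness by design:
  after the decoy is added, reads in PSV-free stretches tie between the
  two paralogs and drop to MAPQ 0, so the mean MAPQ over the target falls
  and het sites farther than a read length from any PSV can lose callable
  depth under the genotyper's MAPQ filter. At 1% divergence this affects
  roughly 13% of sites; it is the price of removing the (much larger)
  false-het burden, and mirrors the behaviour of production aligners on
  decoy-augmented references.
* The pre-fix metrics of both experiments sit on sampling distributions
  whose spread across seeds is comparable to the margin around the
  asserted thresholds; the test suite pins one seed, and the acceptance
  script reports whatever the supplied seed yields.
* Exact-genotype benchmarking under-credits callers relative to
  haplotype-aware comparison; numbers from `compare_to_truth()` should not
  be compared directly against published haplotype-aware benchmarks.
* Single-end and long-read inputs, INDEL calling, and spliced RNA
  alignment are out of scope; the external-backend contract leaves room
  for them but the package provides no built-in support.
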