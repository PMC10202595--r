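---
title: "Models and methods behind sagrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sagrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sagrad` evaluates restriction-site-associated DNA sequencing from single
amplified genomes (SAG-RAD). This vignette is the package's account of its
models: what the simulator emulates and deliberately does not, how each
processing stage is defined, which parameters matter and why their defaults
are what they are, and the numerical and design choices made where the
problem left them open.

## What is being evaluated

Genotyping a single cell requires whole-genome amplification before library
preparation. Multiple displacement amplification (MDA) is accurate at the
base level but amplifies different genomic regions by wildly different
factors, which at RAD-locus resolution produces two failure modes:

* **coverage skew** — some loci receive enormous read depth while others
  fall below the depth needed to assemble them at all;
* **allelic dropout (ADO)** — at a heterozygous locus one allele may fail
  to amplify, so the locus looks homozygous.

The package quantifies both by simulating the full experiment with known
truth and running the conventional processing chain over it.

## The simulator

### Library geometry

The simulated protocol is single-digest RAD with SbfI. Each locus haplotype
begins with the 6-bp remnant `TGCAGG`: SbfI recognises `CCTGCAGG` and
cleaves after the A, so the barcode-adjacent read-through is `TGCAGG`.
Read 1 is a 7-bp inline barcode followed by the haplotype prefix; read 2 is
the reverse complement of the fragment end at the drawn insert length.
Inserts follow a normal distribution centred on 400 bp whose standard
deviation is chosen so that at least 99% of its mass lies within the
size-selection window of 300–600 bp, and draws are clipped to that window.
Reads are 150 bp on both mates.

Two geometric constraints follow and are enforced at configuration time:
`insert_min >= read_length` (mates never read through each other, so no
adapter read-through is simulated) and
`locus_length >= insert_max - barcode_length` (read 2 never runs off the
simulated haplotype). The default `locus_length` is 600 bp.

### Population model

Ancestral locus sequences are uniform random DNA after the fixed remnant.
Each deme derives its own sequence per locus by independent per-site
substitution at probability `divergence`; individuals within a deme share
the deme sequence. Each individual is heterozygous at a Bernoulli
(`het_rate`) subset of loci, the two alleles differing by exactly one
substitution. That substitution is placed uniformly *within the read-1
window* (after the remnant): the assembler only observes read 1, so a
variant outside the window would be invisible by construction and the
recovery tests would conflate simulator geometry with assembler loss.
Divergence substitutions are placed anywhere after the remnant, so only
the fraction falling inside the window is visible downstream — as in real
data, where a locus pair can be identical over the sequenced prefix yet
diverged elsewhere.

Keeping heterozygous alleles one substitution apart keeps their Hamming
distance below the merge distance `M`, guaranteeing that a correctly
sampled heterozygous locus is assemblable into a single two-allele locus.
Multi-SNP alleles are outside the default model.

### Amplification bias

For every single-cell library and locus an amplification factor
`A ~ Lognormal(0, mda_sigma)` is drawn and shared by both alleles (the
bias acts at locus scale, which is what shapes the Lorenz curves of
per-locus depth); at heterozygous loci one allele, chosen at random, is
zeroed with probability `dropout_prob`. Bulk libraries always amplify
uniformly (`sigma = 0`, no dropout), regardless of the configured values.
The lognormal is a modelling choice — the true shape of MDA skew for any
particular organism is not pinned down — but it is the simplest family
that spans "perfectly uniform" to "a few loci dominate" with one
parameter, and the package's uniformity ordering (Gini strictly increasing
in `mda_sigma`) is a property of the pipeline, not of the lognormal
specifically.

### Noise terms

* **Sequencing errors**: independent per-base substitution at
  `seq_error_rate`. Qualities are a constant Q37 except at injected error
  positions, which get Q12 — enough signal for the quality filter to act
  on without modelling instrument-specific profiles.
* **Contamination**: a fraction of read pairs is drawn from an
  independently simulated contaminant genome with no cut-site remnants, so
  the cut-site filter removes almost all of them; residual contaminants
  carrying a spurious remnant (probability about `4^-6` per position) are
  deliberately possible.
* **PCR duplicates**: a binomial fraction of pairs are exact copies of
  another pair of the same library, including its insert length.

Not emulated, and out of scope by design: indels, chimeric MDA products,
GC-dependent amplification, instrument-specific quality profiles, and
adapter read-through. Passing tests therefore demonstrate correctness of
the pipeline's logic under substitution-only noise, not robustness to
every artefact of real instruments.

### Determinism

Every sampling function requires an explicit seed through `sim_config()`;
there is no global-state randomness. The three stochastic stages use
`seed`, `seed + 1` and `seed + 2` (population, amplification weights,
reads), so truth and reads can be regenerated independently. All later
stages are deterministic, which is what makes whole pipeline runs
byte-identical under a fixed configuration.

## Demultiplexing and read filters

Filters run in a fixed order — barcode, cut site, uncalled base, quality,
adapter, contaminant — and each read records at most one discard reason,
the first that fired. This makes the accounting table a partition of the
input (its counts always sum to the input size), at the cost of not
reporting, say, how many barcode failures also had low quality.

* **Barcode**: exact match wins; otherwise the unique barcode within one
  mismatch wins; ties are `ambiguous_barcode`. Rescue trims the corrected
  barcode but never edits other bases. Generated barcode sets keep
  pairwise Hamming distance at least 3, which makes one-mismatch rescue
  unambiguous by construction; user sheets below that distance get a
  warning, not an error.
* **Cut site**: "intact" is read literally — the trimmed read 1 must begin
  with the exact 6-bp remnant. In simulation this is also the main
  contaminant gate.
* **Quality**: a read fails when any sliding window of length
  `ceiling(0.15 * read length)` has mean Phred below 10 on either mate.
  The emulated upstream tool names no threshold; these are its documented
  defaults, and both parameters are exposed.
* **Adapter**: an adapter occurrence with at most 2 substitutions anywhere
  in either mate fails the read; at the 3' end a prefix of the adapter
  counts when at least 8 bases overlap. The simulator never produces
  adapter read-through, so the filter defaults to off in the pipeline
  (`adapter: null`) but is fully implemented and tested.
* **Contaminant screen**: a read pair is contaminant when at least half of
  the k-mers (k = 31) of either mate occur exactly, on either strand, in a
  user-supplied contaminant reference. This is a deliberately simple,
  fully reproducible screen that plays the pipeline role of taxonomic read
  classification without an external database; it makes no attempt at
  taxonomic attribution.

Both mates are filtered throughout. Whether the emulated protocol filtered
read 2 as well is not documented; both-mate filtering is the stricter
choice and is stated here as an assumption.

## Assembly

* **PCR deduplication** keys on (sample, read-1 sequence, insert length)
  and keeps the first pair of each key. Independent molecules of the same
  allele can collide on insert length, so slightly more pairs are removed
  than were labelled duplicates by the generator; this is inherent to
  insert-length deduplication, not an implementation artefact.
* **Stacks** are exact-identity groups of read-1 sequences; groups of
  depth at least `m = 3` are primary (putative alleles), the rest
  secondary. No sub-threshold mismatch collapsing is attempted — the
  merge step below handles near-identical variants, and the recovery
  tests demonstrate the simplification is adequate.
* **Locus merging** connects stacks within Hamming distance `M = 2` and
  takes transitive closure (connected components). Closure is
  deterministic and order-independent, unlike greedy seeded merging, at
  the cost of occasional over-merging through chains. The consensus is the
  deepest allele, ties broken lexicographically — a tie-break that removes
  nondeterminism the emulated tools leave open. SNP offsets are 0-based
  columns at which alleles differ.
* **Secondary absorption** assigns each secondary read to the unique
  nearest allele within 4 substitutions; ties or greater distances drop
  the read. The absorption distance is not documented upstream; 4 (twice
  `M`) is assumed and parameterised, and absorbed depth is included in all
  coverage statistics.
* **Locus filters**: confounded means more than three allele-forming
  stacks; extreme coverage means total depth above `mean + 3 * sd`
  computed per sample over all pre-filter loci. "Sites" is interpreted as
  loci, consistent with per-locus depth accounting. The standard deviation
  is the sample SD (`n - 1` denominator, R's `sd()`); with the toy depth
  vectors used in the tests both SD conventions give identical filter
  outcomes. With fewer than two loci the SD is undefined and the extreme
  filter is skipped with a warning.
* **Catalog and matching**: consensus sequences merge across samples at
  distance `n = 2` (transitive closure again); matching a sample locus
  back requires a unique nearest catalog locus within the same distance,
  and ambiguous multi-matches are excluded from every matched-locus count.
  Reusing `n` as the match distance follows upstream default behaviour;
  no separate matching distance is defined.

## Quality-control metrics

* **Lorenz/Gini** are computed over *loci* (the x-axis is the cumulative
  fraction of loci, not genomic bases), using post-absorption retained
  depths. The Gini coefficient is one minus twice the trapezoidal area
  under the discrete Lorenz curve — exact for a piecewise-linear curve.
  Equal depths give exactly 0; a single covered locus among `L` gives
  `(L-1)/L`.
* **Heterozygosity** is the fraction of retained loci with two or more
  alleles.
* **ADO rate** counts matched loci that are homozygous in the single cell
  while diploid in the bulk catalog, divided by *all* matched loci —
  the definition read literally. The alternative normalisation (divide by
  matched diploid-catalog loci only) is available behind
  `denominator = "diploid"`, off by default. Under the simulator its
  expectation is `het_rate * dropout_prob`, which is what the parameter-
  recovery tests check; at finite depth a small surplus appears because an
  allele sampled below the stack threshold is also an apparent dropout.
* **Sample dropout** removes samples with fewer than 10,000 loci
  (strictly fewer: a sample at exactly the threshold is kept).
* **Sharing tables** count catalog loci by the number of replicates
  recovering them and by exact replicate subset.

## Coancestry and population structure

The population-structure stage is a desk-scale stand-in for full
coancestry model fitting, not a reimplementation of it. Over the catalog
loci present in *every* individual, each individual assigns one unit of
coancestry per locus, split equally among its nearest neighbours — the
individuals whose closest allele (minimum Hamming distance over allele
pairs) is nearest. Rows therefore sum exactly to the number of shared
loci. The directional matrix is symmetrised by averaging, converted to a
dissimilarity (maximum minus value) and clustered by average linkage;
cutting at `k` gives labels scored against the true demes with the
adjusted Rand index. All tie-breaks are deterministic, so clustering needs
no seed.

A desk-scale caveat discovered during development and worth stating: the
"present in all individuals" rule interacts strongly with divergence. At a
per-site divergence of 0.02 only a small percentage of loci merge across
three demes within catalog distance 2 over a 143-bp window, and the loci
that do merge are biased toward windows with little between-deme signal.
With few loci and heavy amplification bias the shared set can end up
uninformative and the clustering arbitrary. The package's
population-recovery evaluation therefore simulates 600 loci at 20x with
moderate bias (`mda_sigma = 0.5`, `dropout_prob = 0.1`) — conditions
chosen once, under which recovery was verified to be stable across seeds —
while divergence (0.02) and the 3 x 4 sample design are fixed by the
evaluation design. The same scarcity affects real sparse datasets, which
is why the upstream method is normally run on tens of thousands of loci.

## Pipeline

`run_pipeline()` chains all stages, writes every artifact (FASTQ, sample
manifest, truth JSON-lines, accounting, per-sample locus tables, catalog
FASTA, match tables, QC and Lorenz tables, coancestry matrix, cluster
labels) under one output directory, and lists each with its MD5 checksum
in `run_manifest.tsv`. All thresholds are configuration defaults, never
hard-coded; unknown configuration keys are rejected with their key path,
and the seed is mandatory. Two runs with the same configuration are
byte-identical, which the test suite asserts on checksums.

## Problem sizes used by the tests and the acceptance script

The package's own evaluation uses sizes chosen to make every statistical
check well-powered while keeping a full run in minutes on one core:
locus recovery at 500 loci and 25x depth; ADO/heterozygosity recovery at
2,000 loci (99% binomial confidence intervals of width about +/-1.3
percentage points) with the dropout monotonicity scan at 400 loci over 10
seeds; the Gini bias ordering at 200 loci over 10 seeds per bias level;
population recovery at 600 loci, 3 demes x 4 individuals. These are the
package's standard evaluation conditions; all of them are plain
`sim_config()` arguments and scale up freely.

## Known limitations

* Substitution-only world: no indels or structural variants, hence no
  gapped alignment anywhere in the assembler.
* Read 1 carries all assembly information; paired reads are used only for
  insert-length deduplication, not contig extension.
* Allele presence is depth-thresholded, not model-based: there are no
  genotype likelihoods, so low-depth alleles are lost rather than called
  with uncertainty.
* The coancestry stage summarises haplotype sharing; it is not an
  admixture or tree model and performs no MCMC.
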