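---
title: "Discovering sex chromosome systems from RADseq presence/absence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex chromosome systems from RADseq presence/absence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

In a species with genetic sex determination, the sex-limited chromosome (Y or
W) carries sequence that the other sex simply does not have. Reduced-
representation sequencing anchored at restriction sites (RADseq) samples the
same loci in every individual, so a Y-hemizygous locus shows up as a tag
present in all males and absent from all females; W-specific sequence shows
the mirror image. `radsexmark` turns that signal into three calls: a list of
confirmed sex-specific markers, a heterogamety call (XX/XY vs ZZ/ZW), and a
synteny assignment of the sex linkage group to a reference chromosome.

The central methodological difficulty is that *absence is an inference, not
an observation*. A locus can look absent in one sex because of the depth
threshold used to call tags, allelic dropout at the restriction site, or
plain undersampling. The pipeline therefore splits marker discovery into a
permissive presence/absence scan followed by a strict raw-read confirmation,
and the package's design revolves around making that second step exact.

## Pipeline model and assumptions

**Demultiplexing.** Reads are `barcode + TGCAGG + tag` (SbfI leaves the
6-base `TGCAGG` remnant). Barcodes are assigned allowing one mismatch;
a prefix within tolerance of two barcodes is dropped, never guessed, which
is why the sample-sheet validator requires barcodes mutually ≥ 2 mismatches
apart. The restriction remnant must match exactly: it anchors every
downstream positional comparison, and a read without it did not come from an
SbfI cut site. The sliding-window quality rule (drop a read if any
15-base window has mean phred < 10) mirrors the long-standing defaults of
RADseq preprocessing tools; both knobs are configuration keys because
published studies rarely state them.

**Tag calling.** A RAD tag is a distinct sequence seen at least `min_depth`
(default 5) times in one individual. Exact-copy counting (no error
correction) is deliberate: sequencing errors at rate ~10⁻³ per base scatter
into singleton sequences that the depth threshold removes, and any
surviving error tag is handled by clustering.

**Locus clustering.** Distinct tags are clustered by single linkage under
Hamming distance ≤ `max_allele_mismatch` (default 3). Because all tags are
the same length and share the restriction-site anchor, positional (Hamming)
comparison is the correct distance — no alignment, no indels. Loci with more
than two alleles overall, or more than two in any one individual, are
excluded: a diploid cannot carry three alleles, so such clusters are
paralogous collapses. The filter is applied in both forms (per locus and
per individual) — the stricter reading of the two-alleles rule — and
excluded loci are kept in the output with a reason string rather than
silently removed.

**Putative markers.** A locus is putatively male-specific when present in at
least `min_carriers` males (default ⌈n_males/2⌉) and zero females, and
symmetrically for females. Absence must be absolute. The carrier minimum
guards against rare artefact tags being "sex-specific" by sparsity; the
error tolerance for the absent sex is supplied by the next step, not by a
looser threshold here.

**Confirmation.** Every allele of every putative marker is searched against
the raw post-demultiplex reads (depth-unfiltered) of each opposite-sex
individual; any full-length match within `max_mismatches` (default 0)
disqualifies the marker, and the disconfirming samples and read counts are
recorded as evidence. This is the step that makes the whole design work:
the canonical false positive is an autosomal locus sequenced just below
`min_depth` in one sex — invisible to tag calling, present in the raw
reads. The package's tests plant exactly this scenario (fixed depth 2 in
females, 20 in males) and require the confirmation step to catch it. Both
alleles of a two-allele marker are searched, since either allele appearing
in the opposite sex breaks sex-linkage.

**System call.** Confirmed male-specific markers with zero female-specific
markers give XY; the mirror gives ZW; both positive or both below
`min_markers` (default 1) give UNRESOLVED. The asymmetric requirement (the
opposite count must be exactly zero) matches the biology: genuine
heterogamety produces markers of one specificity only.

**Synteny.** Markers are chained to reference genes through a related
species' transcriptome using two BLAST tabular files; at each step the best
hit is chosen by lowest e-value, then highest bitscore, then lexicographic
subject id (a deterministic, diffable tie-break), and chains failing
`evalue_max` (default 1e-10) at either step are dropped. Genes hit by
several markers count once — the statistical draws are genes, not markers.
For a chromosome holding `K` of the `N` annotated genes, with `k` of `n`
unique hit genes observed on it, the test is the exact hypergeometric upper
tail `P(X ≥ k)` with expectation `nK/N`. The one-sided ≥ convention matches
the question asked (more genes than expected); raw p-values are reported by
default, with an optional Bonferroni flag across chromosomes.

## The synthetic data generator

`simulate_rad_dataset()` emulates the sampling design the pipeline targets:
two sexes with roughly ten individuals each, single-enzyme SbfI tags,
forward reads only, and four locus classes — autosomal (carried by all),
sex-limited (heterogametic sex only), gametolog pairs (allele 1 in all,
diverged allele 2 in the heterogametic sex), and optional planted
false-positive loci with fixed asymmetric depth. Depth per carried tag is
Poisson (default mean 20), dropout removes a locus from an individual with
probability 0.02, and substitutions hit each post-barcode base at 10⁻³.
Identical parameters and seed give byte-identical FASTQ.

Deliberate simplifications, and what they imply about test coverage:

* **Tag spacing.** Base tags are drawn uniformly with minimum pairwise
  Hamming distance 10, so locus clustering is unambiguous by construction.
  Real genomes contain near-duplicate families; the two-alleles filter is
  the only paralog defence tested.
* **Gametolog divergence is a fixed count**, `round(allele_div ×
  tag_length)` substitutions at random tag positions (never in the
  overhang, which the enzyme conserves), rather than per-base Bernoulli.
  This makes the merge-vs-split behaviour of a gametolog pair at a given
  parameter set deterministic, and the test suite asserts both regimes:
  divergence ≤ `max_allele_mismatch` clusters the pair into one two-allele
  locus, larger divergence splits it into two loci of which the
  heterogametic-sex copy surfaces as a sex-specific marker — the same
  signal a diverged Z/W pair produces in real data.
* **No PCR duplicates, no indels, no quality model.** Qualities are
  constant-high, with an optional corruption switch that plants a 15-base
  phred-2 window in a chosen fraction of reads to exercise the quality
  filter. Depth is Poisson because nothing better is known at desk scale;
  recovery tests are written against carrier counts and thresholds, not
  against the shape of the depth distribution.
* **Forward reads only.** Assembly of reverse reads into longer contigs is
  a downstream, out-of-scope step.

Passing tests on this generator therefore demonstrate the pipeline's logic
— accounting, thresholds, confirmation, determinism — not robustness to
repeat-rich genomes, batch effects, or library-size imbalance.

## Numerical and degenerate-input choices

* The hypergeometric tail is computed in log space from `lchoose`
  (log-factorials) with a log-sum-exp reduction; tails near 10⁻²⁶ retain
  full relative precision, which a naive pmf sum in linear space would
  lose. `k = 0` returns exactly 1, `k > min(K, n)` exactly 0, and the
  implementation is cross-checked in the tests against brute-force
  enumeration of draws and against the distribution's survival function.
* Locus ids are assigned by the lexicographically first allele of each
  cluster, marker tables sort by carrier count descending then locus id,
  and every output table carries a parameter stamp in `#` header lines —
  reports are diffable and auditable.
* Empty inputs: zero reads for a sample is a warning (empty tag set), an
  empty truth table refuses to serialise, a single-sex matrix is a hard
  error in `find_putative()`, and a missing opposite-sex read file is a
  hard error in `confirm_markers()` (skipping it would silently inflate
  confirmation).
* `summary.json` contains the configuration but no absolute paths or
  timestamps, so reruns of the same configuration are byte-identical
  wherever they land.

## Evaluation metrics

`evaluate_run()` matches confirmed markers to truth loci by allele sequence
(cluster ids and truth ids are independent namespaces; matching by content
avoids any id-mapping assumptions). Sensitivity is the fraction of truly
sex-limited loci recovered as confirmed markers of the correct specificity;
specificity is the fraction of autosomal loci *not* reported as confirmed
sex-specific. Gametolog-derived sex-limited alleles are genuinely
sex-linked, so recovering them counts neither for nor against either rate.

## Problem sizes

The package's own test and reproduction runs use desk-scale designs chosen
to exercise every code path while staying comfortably interactive: a ZW
design with 4 females and 11 males over 330 loci (25 W-specific, 5
gametolog pairs), an XY design with 9 + 9 individuals over 121 loci, a
hypergeometric verification grid over all populations up to N = 60, and
property suites over 20 simulation seeds across XY, ZW and no-system
designs. Full-scale RADseq studies call loci in the 10⁵ range; the
pipeline's per-stage costs are linear in read count except locus
clustering, which is quadratic in the number of *distinct* tags and would
need an indexed neighbour search at that scale.

## Known limitations

* Presence/absence logic can only find sex chromosomes with differentiated
  (hemizygous or diverged) regions; homomorphic systems with undifferentiated
  sex chromosomes are invisible to it.
* Marker counts depend strongly on `min_depth` and `max_allele_mismatch`;
  absolute counts are not comparable across parameter settings, which is
  why every output is parameter-stamped.
* The synteny stage starts from BLAST tabular files and an annotation
  table; it does not run BLAST, and its p-values inherit whatever gene
  universe the supplied annotation defines.
* With very few individuals of one sex, absolute absence loses power
  slowly (each homogametic individual is an independent chance to observe
  the locus); the default `min_carriers` of half the specific sex is a
  pragmatic floor, not an optimum.
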