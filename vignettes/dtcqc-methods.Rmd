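---
title: "Quality control of direct-to-consumer genotype data with dtcqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of direct-to-consumer genotype data with dtcqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcqc)
```

## The problem

Millions of people hold raw genotype downloads from direct-to-consumer
(DTC) providers: text files of 0.5--1M SNP-array calls in half a dozen
vendor dialects, produced by different chips across different years,
with no access to the vendors' internal quality control. Before such
files can be pooled for research they need: parsing into one normalized
representation; detection of the genome build; detection and repair of
reverse-strand reporting; separation of genuine NGS VCFs from
array-derived conversions; per-SNP sanity filtering; identification of
the underlying array design; removal of positions whose cohort allele
frequencies are implausible against a reference panel; and detection of
duplicate uploads and close relatives. `dtcqc` implements that pipeline
as a library plus a thin command-line wrapper, together with a seeded
synthetic-data generator so every stage is testable offline.

## Normalized representation

A parsed file becomes a `dtc_genome`: records of (rsid, chromosome,
position, allele1, allele2, no-call flag), sorted by position, with
chromosome labels normalized to `{1..22, X, Y, XY, MT}` (vendor numeric
codes 23--26 map to X, Y, the pseudoautosomal region, and
mitochondria). Calls use the characters `A,C,G,T` plus the vendor
insertion/deletion codes `I`/`D`; recognized no-call spellings are
`--`, `-`, `__`, `_`, `00`, `0` and an empty field. Within one file a
duplicated (chromosome, position) pair keeps its first occurrence; the
rest are counted as rejected records, so at every stage
*kept + removed = input* holds exactly.

Parsing is deliberately two-layered: the parser enforces only line
*structure* (field count, integer position, a 1--2 symbol call) and
rejects the whole file when more than 5% of its body lines are
malformed -- a file that broken is more likely corrupted than merely
dirty. Call-character validity, chromosome validity, and range checks
live in `basic_snp_check()`, so its per-reason exclusion counts remain
meaningful for reporting.

## File sanity checks

**Build detection.** A build statement in the vendor header wins.
Otherwise signature SNPs -- markers whose coordinates differ between
GRCh36/37/38 -- vote: each signature present in the file matches the
build whose coordinate equals the file's reported position, and the
majority wins when at least 3 signatures are informative, otherwise the
file defaults to GRCh37 (by far the most common build in consumer
data). The packaged signature table is synthetic: real signature
coordinates are a data product, not an algorithmic one, and the
generator and detector share the packaged table so the mechanism is
fully tested; users can substitute a real table.

**Reference similarity.** Every called biallelic site covered by a
reference-base lookup is classified as homozygous-reference,
heterozygous, homozygous-alternate, or *reference mismatch* -- a call
in which neither allele equals the reference base or its complement, so
no strand interpretation explains it. Under Hardy--Weinberg equilibrium
(HWE) with alternate-allele frequency $q$ the hom-ref fraction is
$(1-q)^2$; the test suite checks the simulated value against this
closed form. The plausibility gate rejects files outside
$5\times10^4 \le$ records $\le 5\times10^6$ or with a mismatch fraction
above 0.10. The bounds are configurable: real arrays span roughly
0.5--1M positions, and mismatch beyond what hom-alt calls at
non-complementary alternates can explain (about 6% for a uniform
alternate-base choice) indicates corruption.

**Strand check.** Some files report genotypes on the reverse strand. At
probe sites inside genes coded on the reverse strand the forward-strand
allele pair is known; pairs that are their own complement (A/T, C/G)
cannot distinguish strands and are never probes. A probe is informative
when the observed alleles match exactly one of the pair or its
complement; the flip score is the flipped fraction of informative
probes. Files scoring $\le 0.2$ pass, files scoring $> 0.8$ (with at
least 10 informative probes) are repaired by complementing every call
genome-wide -- DTC files are strand-consistent per provider, so the
gene-local probes act as a detector while the repair is global -- and
re-scored; anything that remains in the middle band is a strand
mixture no global complement can repair, and is rejected. Complementing
is an involution, so repair of a genuinely flipped file restores the
original exactly.

**VCF triage.** A variant caller lists (almost) only non-reference
sites with ALT always stated; a VCF converted from an array download
carries the whole array content, mostly homozygous-reference rows, with
ALT frequently blank. A VCF is labelled `genotyping` when strictly more
than 50% of rows are hom-ref *or* strictly more than 50% lack ALT
(either signal alone suffices; they have the same cause), `ngs`
otherwise; below 1,000 rows the file is `undetermined` and passes with
a warning flag rather than risking a decision on noise.

## Array-design fingerprinting

Chips differ mainly in *which* positions they assay, so the set of
reported positions fingerprints the array. The distance between two
files is $\Delta N$, the number of positions not shared (the symmetric
difference of their position sets), computed by a two-pointer merge
over sorted encoded positions in C++. Corpus clustering is
single-linkage agglomeration cut at a threshold -- equivalently,
connected components of the graph joining files at $\Delta N \le$
cutoff. The default cutoff of 200,000 targets real 0.5--1M-position
files and scales linearly with design size in synthetic tests (tests at
100K positions use 20,000).

A cluster is profiled into per-position *prevalence* (the fraction of
members reporting it). The model's reference set keeps positions with
prevalence $\ge$ 0.05 -- file-private junk positions otherwise
accumulate in the union -- and the core set is the positions present in
every member. A new genome is assigned to the model covering the
largest fraction of its positions, provided coverage reaches 0.8
(inclusive: "covers 80%" is read as $\ge$); ties break to the earliest
model, deterministically. Unmatched genomes are labelled rather than
guessed.

## Allele-frequency blacklisting

Within one cluster, the cohort's alternate-allele count at a site is
$k$ out of $2n$ alleles from $n$ calling diploid genomes. Against a
panel frequency $p_0$ the test statistic is the one-sample
binomial-proportion z:

$$ z = \frac{k/(2n) - p_0}{\sqrt{p_0 (1 - p_0) / (2n)}} $$

A site is blacklisted when $|z|$ exceeds the threshold on **both** the
full panel (ALL) and the European subset (EUR) -- open consumer
cohorts over-represent European ancestry relative to the panel, so a
single-panel failure often reflects ancestry composition, not array
error. The default threshold is $z_{crit} = 4$: roughly $6 \times 10^5$
sites are tested per cluster, so the conventional 1.96 would be
swamped by false positives, while 4 keeps the expected false-positive
count per cluster near 40 at real scale. Sites with fewer than 30
calling genomes or a monomorphic panel frequency are untestable and
never blacklisted by z. A site where more than 10% of calls carry
alleles matching neither panel allele is blacklisted independently --
that pattern indicates probe failure, and it is also the only route by
which a monomorphic site can be listed. Every blacklist records its
generation parameters in its serialization header.

Under a null cohort drawn from the panel frequencies themselves the
blacklist rate should approach the two-sided normal tail
$2\Phi(-z_{crit})$; the discreteness and skew of the binomial at small
MAF push the exact rate somewhat above the normal value, which is why
the calibration test budgets three binomial standard errors around it.

## Identity and relatedness

Similarity between two genomes is genotype *concordance*: the fraction
of mutually called positions carrying the identical unordered allele
pair. (Position-set overlap alone cannot separate two different people
on the same chip, so concordance is the meaningful reading of
file-to-file similarity.) Pairs above 0.975 are duplicates -- the same
person or identical twins; observed corpora show an empty band from
0.90 to 0.975, so the boundary is insensitive. Pairs from 0.80 to
0.975 are close relatives (parent/child and siblings are not
distinguished); below is unrelated. A verdict requires at least 10,000
mutually called sites. Corpus mode computes all pairs with an optional
screen -- the first 20,000 shared sites, escalating to a full scan
above concordance 0.6 -- which is a performance device only: clearly
unrelated pairs (concordance near 0.5 under HWE) stop early, while
anything near the relative band is always fully scanned. Distinct
genetic origins are connected components of the duplicate relation.

## The synthetic-data generator

The generator emulates the study conditions end to end: array designs
of configurable size with controlled pairwise overlap (built from
disjoint blocks -- a shared core, per-pair extras, private remainders
-- so requested shared fractions are realized exactly up to rounding);
HWE genotypes from a MAF spectrum defaulting to Uniform(0.05, 0.5), the
common-variant range consumer arrays target; Mendelian parent/child
transmission; and injected pathologies (per-site genotype error,
no-call conversion, global strand complement, invalid records,
truncation), each recorded in a planted-truth manifest that tests
assert against. Positions are drawn without replacement from a virtual
genome of the 22 autosomes plus X with GRCh37 lengths. Panel
frequencies for blacklist tests are the design MAFs themselves (ALL)
with an optionally perturbed EUR copy, so dual-panel behaviour is
controllable. Every operation is a pure function of its arguments and a
seed.

What the generator does *not* emulate: linkage disequilibrium,
population structure and ancestry mixtures, real rsid dictionaries,
real per-chip position lists, and batch effects. Passing tests
therefore demonstrate the pipeline's mechanics -- parsing fidelity,
detection power, calibration, bookkeeping -- on idealized data, not
performance on any particular real corpus.

## Numerical and design choices

* Positions are encoded as `chrom_index * 2^28 + pos` in doubles:
  unique, exactly representable, and ordered by (chromosome, position),
  which makes set operations sorted-merge problems.
* Clustering uses `stats::hclust` single linkage plus a height cut;
  this is provably identical to threshold-graph components, and the
  test suite checks that equivalence against a breadth-first oracle.
* The malformed-line abort threshold (5%), the duplicate-keeps-first
  rule, the zip-with-`[Content_Types].xml`-is-a-Word-document rule, and
  the AncestryDNA 23--26 chromosome codes are behavioural choices where
  vendor practice, not any formal specification, is the authority.
* The reference lookup is a sparse two-column (position, base) table
  rather than a FASTA: the pipeline only ever queries assayed
  positions, and a sparse table keeps the test surface text-only.
  Assembly conversion (liftover) is delegated to external tools via the
  detected-build label; nothing downstream requires it.
* VCF parsing goes through `vcfR`; the writer emits biallelic,
  single-sample VCFs only, which is exactly the shape of array-derived
  consumer VCFs.
* Degenerate inputs: empty genomes serialize to header-only files;
  genomes with no informative strand probes pass flagged
  `strand_unchecked` rather than failing; VCFs under the row minimum
  pass flagged `vcf_small`; an empty blacklist applies as the identity.

## Problem sizes used by the checks

The packaged checks run the planted-cluster recovery at 5 designs of
100,000 positions with 20 members each (cutoff 20,000) over multiple
seeds; blacklist calibration at 100 genomes by 10,000 sites with
identical ALL/EUR panels, and power at a +0.3 frequency shift over
2,000 sites; identity separation on a 50,000-site design. These sizes
were chosen as the smallest at which the between-band separations are
comfortably larger than Monte-Carlo noise.

## Known limitations

Haploid no-calls lose their one-character spelling through the VCF
writer (`GT=.` has no width); multiallelic VCF rows are collapsed to
the first non-reference allele; the off-panel blacklist rule cannot
distinguish probe failure from genuine tri-allelic sites; and the
strand checker deliberately ignores A/T and C/G sites, so a file
consisting only of such calls is `strand_unchecked`. Kinship beyond
the duplicate/close-relative bands (e.g. IBD-based degrees) is out of
scope.
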