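# dtcqc — quality control for direct-to-consumer genotype data

Raw genotype downloads from consumer providers (23andMe, AncestryDNA,
FamilyTreeDNA, MyHeritage, deCODEme, plus VCF exports) are a large,
heterogeneous, and largely untapped resource for genetics research:
0.5–1M SNP-array calls per file, in half a dozen vendor dialects,
produced by different chips over different years, with no access to the
vendors' internal QC. `dtcqc` turns such files into a research-usable,
normalized form and tells you exactly what it rejected and why.

The pipeline:

1. **Parse** — unpack zip/gzip/bzip2 containers (rejecting PDFs, Word
   documents, and multi-member archives), triage the dialect, and parse
   into a normalized record set with chromosome labels in
   `{1..22, X, Y, XY, MT}`.
2. **File sanity** — detect the genome build (header declaration, then
   signature-SNP voting, defaulting to GRCh37), compare calls to a
   reference-base lookup, gate on plausibility, detect reverse-strand
   reporting at probe sites and repair it by global complement (files
   with mixed strands are rejected), and separate genuine NGS VCFs from
   array-derived conversions (a VCF with >50% homozygous-reference rows
   or >50% missing ALT alleles is array-derived).
3. **SNP sanity** — per-record filtering (invalid chromosomes,
   out-of-range positions, invalid call characters, no-calls), array
   fingerprint clustering, and per-cluster blacklists of implausible
   sites.

Two corpus-level methods are the statistical core. Array designs are
fingerprinted by **ΔN**, the number of positions two files do not share
(the symmetric difference of their position sets); single-linkage
clustering at a ΔN cutoff (default 200K) recovers the underlying chip
designs, and a genome joins the cluster whose reference positions cover
≥80% of its own. Within a cluster, each site's cohort alternate-allele
count k over 2n alleles is tested against a reference panel frequency
p₀ with the one-sample z statistic

    z = (k/(2n) − p₀) / sqrt(p₀(1−p₀)/(2n))

and blacklisted only when |z| > 4 on **both** the full reference panel
and its European subset (in real use, 1000 Genomes ALL and EUR).
Finally, pairwise genotype concordance over mutually called sites
separates duplicate uploads (>97.5%) and close relatives (80–97.5%)
from unrelated pairs.

A seeded synthetic-data generator (`make_designs`, `sample_genome`,
`sample_child`, `corrupt_genome`, `write_fixture`) reproduces all the
study conditions — overlapping array designs, Hardy–Weinberg genotypes,
Mendelian families, strand flips, no-calls, invalid records,
array-converted VCFs — so the entire pipeline is testable offline.

## Worked example

```r
library(dtcqc)

# a synthetic 60K-position design standing in for a real chip
d <- make_designs(1, 60000, seed = 42)[[1]]
g <- inject_probe_sites(sample_genome(d, seed = 43, nocall_rate = 0.01),
                        seed = 44)
f <- file.path(tempdir(), "download.txt.gz")
write_fixture(g, f, dialect = "t23andme", container = "gzip")

res <- run_single(f, qc_config(), ref = design_reference_lookup(d))
print(res$report)
#> QC report: /tmp/.../download.txt.gz
#>   source=t23andme build=GRCh37 kind=genotyping cluster=NA
#>   extract          pass (gzip)
#>   triage           pass (t23andme)
#>   parse            pass
#>   build            pass (GRCh37)
#>   reference        pass
#>   sanity_gate      pass
#>   strand           pass (clean)
#>   basic_snp_check  pass
#>   PASSED
```

The report records, stage by stage, what was checked and what was
excluded; every count obeys kept + removed = input. A second upload of
the same person, with 1% simulated genotyping error, is recognized as a
duplicate:

```r
dup <- corrupt_genome(g, genotype_error = 0.01, seed = 45)$genome
pairwise_similarity(g, dup)
#> <dtc_similarity: duplicate (concordance 0.9904 over 59442 shared sites)>
```

A thin command-line wrapper lives at `inst/cli/dtcqc.R`
(`qc <file>`, `corpus <dir>`, `blacklist <dir> --freqs <tsv>`,
`simulate <dir>`).

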