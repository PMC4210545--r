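# vardepot

A relational variant warehouse for next-generation sequencing studies.

Exome and genome experiments routinely produce tens of thousands of variant
calls per sample, and interpreting them requires three things that plain VCF
files do not give you: a persistent store in which the same genomic change is
one record shared across samples, annotations that can be updated when their
sources release new versions *without losing what you previously knew*, and
filtering expressive enough to encode inheritance models, cohort frequencies
and candidate-gene panels. `vardepot` provides all three as an R package
backed by a single-file SQLite database, plus a command-line interface.

## What it does

* **Variant store** — samples, projects with role-based access
  (`read_only < edit < admin`), normalized variants keyed by
  `(build, chrom, pos, ref, alt)`, and one genotype-call row per
  (sample, variant) carrying the GATK quality vector: QUAL, GQ, GT, AD (and
  the derived allelic ratio), QD, MQ, FS, the BaseQ/MQ/ReadPos rank sums and
  the verbatim FILTER string (VQSR tranche labels included).
* **VCF import** — VCF 4.x, plain or gzip; multiallelic sites are split into
  biallelic records with per-allele depth projection; alleles are trimmed to
  a minimal representation (shared suffix first, then prefix); imports are
  atomic and a declared genome build that conflicts with the store is
  rejected before any write.
* **Versioned annotation** — pluggable offline sources (tab-delimited lookup
  tables, transcript gene models in BED12 + CDS FASTA). The engine annotates
  only variants missing a source's annotation, and on a new source release
  re-annotates everything: unchanged values keep their records, superseded
  values are archived (never deleted), every change is logged, and changes
  that newly introduce a high-impact effect (stopgain, frameshift, splicing)
  or a pathogenic clinical class are flagged as putatively interesting.
* **Coding-effect classification** — per-transcript location (exonic / UTR /
  intronic / splicing within 2 bp of a boundary / up- and downstream) and,
  where a CDS sequence is available, codon-level effects
  (synonymous / missense / stopgain / stoploss; frameshift vs inframe for
  indels), on both strands.
* **Filtering** — arbitrarily nested AND/OR trees of atoms over any call or
  annotation field with explicit per-atom missing-value policy; de novo,
  recessive and dominant inheritance models from pedigree links; occurrence
  counts over sample selections; gene mutation burden (distinct carrier
  samples per gene); in-silico gene panels of transcript identifiers with
  private/public sharing. Filter schemes serialize to JSON and reload
  evaluation-equivalent.
* **Reporting** — wide (one row per variant) and compact (per-transcript
  sub-rows) RFC 4180 CSV export, IGV locus links, pagination in batches of
  100, and call-set summaries: Tr/Tv ratio, SNP/indel and known/novel
  partitions, MAF histogram.
* **Liftover** — UCSC chain files parsed into alignment segments; positions
  map through the unique covering segment, with failures (`unmapped`,
  `split_across_blocks`, `strand_flip_unsupported`) queued for manual
  curation; the previous build becomes read-only with its annotations
  frozen.
* **Fixtures** — deterministic generators for trio and cohort VCFs with
  known inheritance/burden truth, gene models with CDS sequences, two-release
  annotation tables with planted changes, and multi-segment chain files.

## Worked example

```r
library(vardepot)

store <- vdb_connect("variants.sqlite")          # fresh hg19 store
trio  <- generate_trio(seed = 1, n_per_class = 5)
load_trio(store, trio)                           # 3 samples, 25 variants

gm    <- generate_gene_model(seed = 2)
genes <- gene_model_source("genes", "v1", gm$models, gm$cds)
register_source(store, genes)
annotate_missing(store, genes)
#> [1] 25

filter_de_novo(store, "CHILD")[, c("chrom", "pos", "ref", "alt", "genotype", "gq")]
#>   chrom   pos ref alt genotype gq
#> 1  chrT  6519   T   A      het 39
#> 2  chrT  8229   C   T      het 69
#> 3  chrT 11571   C   G      het 80
#> 4  chrT 12204   A   T      het 80
#> 5  chrT 13903   C   A      het 95

scheme <- filter_scheme("quality_het",
  filter_and(filter_atom("gq", "ge", 30),
             filter_or(filter_atom("genotype", "eq", "het"),
                       filter_atom("genotype", "eq", "hom_alt"))))
nrow(evaluate_scheme(store, scheme, "CHILD"))
#> [1] 25

s <- compute_summary(get_sample_calls(store, "CHILD"))
sprintf("Tr %d, Tv %d, Tr/Tv %.2f", s$tr_count, s$tv_count, s$trtv_ratio)
#> [1] "Tr 9, Tv 16, Tr/Tv 0.56"
```

The five variants returned by `filter_de_novo()` are exactly the five the
generator planted as de novo (child het, both parents hom_ref); the Tr/Tv of
0.56 reflects the generator's uniform substitution model rather than the
~2–3 expected of real exomes — see the methods vignette for what the
synthetic data does and does not emulate.

The same workflows are available from a shell through the CLI wrapper:

```sh
Rscript inst/cli/vardepot.R fixtures trio --seed 1 --out trio.vcf
Rscript inst/cli/vardepot.R import --db variants.sqlite --vcf trio.vcf --build hg19
Rscript inst/cli/vardepot.R filter --db variants.sqlite --sample CHILD --denovo
```

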