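---
title: "Methods: the vardepot variant warehouse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vardepot variant warehouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vardepot)
```

# The data model

`vardepot` treats a *variant* — the normalized tuple
`(build, chrom, pos, ref, alt)` — as the identity of the whole system.
Observations of that variant in samples are separate *genotype calls*, one
row per (sample, variant), holding the GATK quality vector (QUAL, GQ, GT,
AD, QD, MQ, FS, BaseQRankSum, MQRankSum, ReadPosRankSum, FILTER). This
sample/variant split is what makes a warehouse economical: importing a
variant seen in a thousand samples costs one variant row and a thousand
call rows, and an annotation computed once serves every carrier.

Storage is a single-file SQLite database. Samples belong to exactly one
project; access is governed by per-project role grants ordered
`read_only < edit < admin`, where a higher role implies the lower ones.
Authentication (passwords, sessions) is deliberately out of scope — users
are plain string identifiers, and only the authorization model is
implemented.

The allelic ratio is always derived at read time as
`ad_alt / (ad_ref + ad_alt)` and is undefined (`NA`) when depths are absent
or sum to zero. Absent quality values are stored as SQL nulls, never as
sentinel numbers: a missing QD must remain distinguishable from a QD of 0.

# Import and normalization

Imports accept VCF 4.0–4.3, plain or gzip, and are atomic: a failure rolls
back the whole file. A declared genome build that differs from the store's
current build is a conflict error raised before any write, so a store can
never silently mix coordinate systems.

Two normalization steps give variants a canonical form:

* **Multiallelic splitting.** A record with *k* ALT alleles becomes *k*
  biallelic records. AD is projected per allele to (ref depth, that
  allele's depth), and the genotype is re-expressed relative to the
  retained allele — a `1/2` genotype is het with respect to each of the two
  alternates. Missing AD propagates as missing.
* **Allele trimming.** The shared suffix is trimmed first, then the shared
  prefix with the position advanced, always retaining at least one base per
  allele. For a deletion in a repeat run (`CTT>CT`), suffix-first trimming
  anchors the representation at the original position (`CT>C`). Trimming
  order matters only for the choice among equivalent minimal
  representations; the tests assert minimality and edit-equivalence on an
  embedding sequence rather than one specific anchor.

**A known limitation:** indels are *not* left-aligned against a reference
genome — import requires no FASTA. Two pipelines that place the same indel
at different anchors within a repeat can therefore produce two store
entries. Where cross-cohort indel identity matters, inputs should be
pre-normalized with a reference-aware tool before import.

Half-calls (`./1`) count as het; a haploid `1` (male X) counts as hom_alt —
a documented simplification in place of full ploidy awareness. Hom-ref and
missing-genotype records are skipped by default (`keep_homref = TRUE`
retains them, which makes occurrence counting over explicitly genotyped
cohorts exact).

# Versioned annotation

An annotation source is a named, versioned provider mapping variants to
`(field, value)` pairs. Two provider families are built in: tab-delimited
lookup tables keyed exactly by `(chrom, pos, ref, alt)` (allele-exact: the
same position with a different alternate does not match), and transcript
gene models (BED12 plus a CDS FASTA). Adapters that shell out to live
annotation services would implement the same contract but are not part of
the package; every source here is an offline file, which keeps the engine
fully testable.

The annotation cycle is *annotate-missing-then-store*: each run collects
only the variants without an active record from the source, queries the
provider for exactly those, and stores the results at the source's current
version. Variants the provider knows nothing about receive an explicit
no-hit marker record. The marker is what makes the cycle idempotent — an
immediate re-run queries nothing — at the cost of one internal record per
annotation-free variant; the alternative (re-querying them on every run)
was rejected because it makes every cycle O(store size) regardless of what
is actually new.

On a new source release every variant is re-annotated. Unchanged values
keep their original record and version stamp. A changed or dropped value
has its record *retired* — `active = 0`, `retired_at` set, never deleted —
and the new value inserted; a change-log entry records old and new value
and version. Partial uniqueness (`at most one active record per (variant,
source, field)`) is enforced by an index, not just by convention. Replaying
the change log over the first stored value reproduces the current active
value; this is asserted as a test invariant, and the archive means any
historical claim ("in release r1 this variant's class was benign") remains
answerable.

Per-transcript values posed a design choice: one record per transcript
would break the one-active-record invariant that versioning relies on, so
multi-transcript values are stored as a single record whose value joins the
per-transcript elements with `|` (literal pipes escaped, so the join is
reversible). Filter atoms and exports split the cell back; an atom passes
if *any* element satisfies it, matching the sensitivity-first rationale of
transcript-specific filtering — a stop codon in one transcript of a gene
should surface even if other transcripts are unaffected.

Change flagging ("putatively interesting") uses two declared vocabularies:
effect-type fields changing to `stopgain`, `frameshift` or `splicing`, and
clinical-significance fields changing to `pathogenic` or
`likely_pathogenic`. A change is flagged only when the *new* value
introduces the term — a value that was already high-impact and stays so is
not news. Both vocabularies are arguments of `flag_interesting()` and can
be extended per deployment.

# Coding-effect classification

Per overlapping transcript, a variant's location is one of `exonic`, `utr`,
`intronic`, `splicing`, `upstream`, `downstream` (or `intergenic` when no
transcript is within range). The splicing window is fixed at 2 intronic
bases from an exon boundary — the canonical donor/acceptor dinucleotides —
and is a configurable argument; the up/downstream window is 1 kb.

For exonic CDS SNVs with a CDS sequence available, the affected codon is
located by a strand-aware genomic-to-CDS index mapping (alleles are
reverse-complemented on minus-strand transcripts), mutated, and translated
with the standard genetic code: `synonymous`, `missense`, `stopgain`
(new stop), `stoploss` (lost stop). CDS indels are `frameshift` when the
net length change is not a multiple of 3, else `inframe`. Transcripts
without a CDS sequence still get location-level annotation with effect
`unavailable`; non-coding transcripts report `noncoding`.

The classifier trusts the supplied CDS sequence and does not re-verify the
reference allele against it. The test suite checks the classifier against
an independent oracle that rebuilds the entire mutated CDS, translates both
proteins completely, and classifies from the full protein comparison — 200
random SNVs/indels per run on both strands.

# Filtering

A filter is a tree: atoms at the leaves, AND/OR groups above them, nesting
unbounded, evaluation independent of child order (AND intersects, OR unions
the child result sets). Atoms compare one field — a call/variant builtin or
any registered annotation field, addressed bare or as `source.field` — with
one of `eq, ne, lt, le, gt, ge, contains, in_set, is_missing, not_missing`.
Schemes are validated (group arity, field resolvability) before any
evaluation, serialize to schema-versioned JSON and reload
evaluation-equivalent. Field references are late-bound: a saved scheme
naming a since-removed field loads fine and fails only at evaluation, with
the field named.

**Missing values are the consequential gap** in any annotation-driven
filter language: is a variant with no MAF "rare"? There is no universally
right answer, so the policy is explicit *per atom*: `exclude` (default)
makes a missing value fail the atom, `include` makes it pass. A
rare-variant filter would typically pair `maf le 0.01` with
`missing_policy = "include"` — unseen variants are likely rare — while a
quality filter keeps the default.

Inheritance models operate on pedigree links (parent references validated
and acyclic; sibling links stored symmetrically):

* *de novo*: child het or hom_alt, both parents hom_ref. Strict mode
  requires explicit hom_ref parent calls; the lenient flag also accepts
  absent/missing parent genotypes, trading specificity for sensitivity when
  parental coverage is incomplete.
* *recessive*: child hom_alt, both parents het.
* *dominant*: across the family (child, parents, siblings), every
  *affected* member carries the variant (het/hom_alt, missing calls fail)
  and every unaffected member is hom_ref or uncalled. Affected status is an
  explicit per-sample flag.

Occurrence filtering counts *carrier samples* (het or hom_alt) within a
chosen sample set against optional min/max bounds — carriers, not alleles,
so a homozygote counts once; the allele-counting alternative would double-
weight homozygotes and is intentionally not what "seen in at most N
controls" means here. Gene burden counts *distinct* carrier samples per
gene (a sample with two hits in one gene counts once). Gene panels are sets
of transcript identifiers matched version-insensitively, or through the
gene model by symbol; panels are private to their owner until shared
public.

The filter engine's correctness case is equivalence with a brute-force
evaluator that tests every variant independently against the tree — 200
random trees (depth ≤ 4, ≤ 10 atoms) over a 500-variant annotated store per
run, plus truth-table tests for each inheritance model over all parent
genotype combinations.

# Reporting

Summaries compute the transition/transversion split (A↔G, C↔T vs the
rest, SNVs only), SNP/indel and known/novel partitions (known = carries an
rsID), and a MAF histogram over bins (0, 0.001, 0.01, 0.05, 0.1, 0.5] with
missing MAFs in a separate bin; with zero transversions the ratio is
undefined (`NA`), never infinity. Exports are RFC 4180 CSV in two layouts:
wide (one row per variant, multi-transcript cells pipe-joined, reversible)
and compact (per-transcript sub-rows). IGV locus links span the reference
allele ± 25 bp, clamped at 1. Result lists are paginated in batches of 100;
pages concatenate exactly to the whole.

# Liftover

Chain files are parsed into ungapped alignment segments (0-based half-open
internally, converted at the variant boundary). A position maps through the
unique segment covering it; the failure taxonomy is part of the contract:

* `unmapped` — the position falls in a source gap or outside every chain;
* `split_across_blocks` — the variant's reference span starts and ends in
  different segments; failing these outright was chosen over truncating
  the span, which would silently change the allele;
* `strand_flip_unsupported` — the covering chain targets the minus strand;
  mapping would require reverse-complementing both alleles, and the package
  refuses rather than guesses.

Failures are data, not exceptions: store conversion inserts what maps,
queues what does not for manual curation (resolve with coordinates, or
skip), copies genotype calls to the new build, and flags the old build
read-only with its annotations frozen — retrospective questions against
the retired build keep their answers. Re-annotation under the new build
runs the ordinary annotate-missing cycle with new-build sources.
Correctness is checked against an exhaustive per-base lookup table expanded
from the chain, plus round-trips through the inverted chain.

# The synthetic-data generator

All fixtures flow from one explicitly seeded base-R generator; the same
seed yields byte-identical files, and generation never disturbs the
caller's RNG state. The synthetic contig is `chrT` (100 kb) so fixture
coordinates can never be mistaken for real genome positions.

* **Trios** plant five genotype patterns, `n_per_class` variants each:
  de novo (child het, parents hom_ref), recessive (child hom_alt, parents
  het), dominant (het in the affected child and father, hom_ref in the
  unaffected mother), inherited-benign (het in child and unaffected
  mother), and common (het in all three). The patterns are chosen so each
  inheritance filter recovers exactly its class — the recovery test is
  meaningful because the *other* classes are its designed decoys. GATK-style
  fields carry plausible values (GQ 30–99, depths 20–60, AD consistent with
  genotype).
* **Gene models** provide a plus-strand multi-exon coding transcript, a
  non-coding transcript, and a minus-strand coding transcript overlapping
  the first — enough structure to exercise UTR/intron/splice-window logic,
  strand handling and ANY-transcript semantics. CDS sequences start ATG,
  end in a stop, and are internally stop-free, so planted stopgains are
  unambiguous.
* **Cohorts** plant an exact number of distinct carrier samples in a gene
  (the first carrier gets two variants — the probe for distinct-sample
  burden counting) plus background variants outside the gene's flank.
* **Annotation releases** come in pairs with planted changes covering every
  flagging case: effect→stopgain and clinical→pathogenic (interesting),
  effect→missense, clinical→benign and a small MAF drift (not), and one
  variant dropped entirely (archival/no-hit path).
* **Chains** are multi-segment with both source gaps (unmapped regions) and
  target gaps (offset changes); header totals are derived from the
  segments, so generated chains are internally consistent by construction.

What the generator does *not* emulate: linkage disequilibrium, realistic
site-frequency spectra, sequencing-error profiles, multi-nucleotide or
structural variants, and the transition bias of real genomes (substitutions
are uniform, so fixture Tr/Tv sits near 0.5 rather than an exome's ~2–3).
Passing tests therefore demonstrate the *mechanics* — recovery of planted
truth, invariant preservation, oracle agreement — not calibration against
real cohort data.

# Problem sizes and numerical choices

Test and acceptance runs use a 500-variant store for tree-equivalence (200
random trees), 20 trio seeds × 25 variants for inheritance recovery, 1,000
random positions against the per-base chain table, and 200 random
SNVs/indels against the rebuild-and-translate oracle — sizes at which every
oracle is exhaustive or near-exhaustive while a full run stays in the
minutes range on one CPU. Comparisons of annotation values are exact string
comparisons (sources emit fixed-precision text); numeric filter atoms
compare as doubles with non-numeric elements failing the comparison rather
than erroring. Ties in variant ordering are broken by `(chrom, pos, ref,
alt)` so every listing is deterministic.

# Known limitations

* No reference-FASTA left-alignment at import (above).
* Compound-heterozygote detection is not implemented.
* X-chromosome handling is the hemizygous-as-hom_alt simplification.
* Gene models are read from BED12 only; GFF3 input is not implemented.
* The store targets single-writer use; concurrent multi-writer access is
  not guaranteed beyond SQLite's own locking.
* Liftover is single-hop and refuses strand-flipping chains; reference
  verification on the target build runs only when a target FASTA is
  supplied.
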