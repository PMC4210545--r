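## Deterministic synthetic-data generators: trio and cohort VCFs with known
## ground truth, gene models with CDS sequences, annotation tables with
## planted version-to-version changes, and multi-segment chain files. All
## randomness flows from one explicitly seeded base-R generator; the same
## seed yields byte-identical artifacts. The synthetic contig is named
## "chrT" so coordinates can never collide with a real genome.

FIXTURE_CONTIG <- "chrT"
FIXTURE_CONTIG_LEN <- 100000L

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

random_base <- function(n = 1L) sample(BASES, n, replace = TRUE)

other_base <- function(ref) vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")

vcf_header <- function(sample_ids, build = "hg19") {
  c("##fileformat=VCFv4.2",
    sprintf("##reference=%s", build),
    sprintf("##contig=<ID=%s,length=%d>", FIXTURE_CONTIG, FIXTURE_CONTIG_LEN),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Strand bias Phred\">",
    "##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description=\"Base quality rank sum\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

# GT:AD:GQ cell consistent with a genotype class
format_call <- function(genotype, depth, gq) {
  switch(genotype,
    hom_ref = sprintf("0/0:%d,0:%d", depth, gq),
    het = sprintf("0/1:%d,%d:%d", ceiling(depth / 2), floor(depth / 2), gq),
    hom_alt = sprintf("1/1:0,%d:%d", depth, gq),
    missing = "./.:.:.")
}

vcf_data_line <- function(chrom, pos, ref, alt, qual, genotypes, depths, gqs) {
  info <- sprintf("QD=%.2f;MQ=%.2f;FS=%.3f;BaseQRankSum=%.3f;MQRankSum=%.3f;ReadPosRankSum=%.3f",
                  round(stats::runif(1, 1, 35), 2), round(stats::runif(1, 40, 60), 2),
                  round(stats::runif(1, 0, 8), 3), round(stats::rnorm(1), 3),
                  round(stats::rnorm(1), 3), round(stats::rnorm(1), 3))
  cells <- mapply(format_call, genotypes, depths, gqs)
  paste(c(chrom, pos, ".", ref, alt, sprintf("%.2f", qual), "PASS", info,
          "GT:AD:GQ", cells), collapse = "\t")
}

TRIO_CLASSES <- c("de_novo", "recessive", "dominant", "inherited_benign",
                  "control_common")

# genotype patterns (child, father, mother) realizing each intended class;
# the affected members of the fixture trio are the child and the father
TRIO_PATTERNS <- list(
  de_novo = c("het", "hom_ref", "hom_ref"),
  recessive = c("hom_alt", "het", "het"),
  dominant = c("het", "het", "hom_ref"),
  inherited_benign = c("het", "hom_ref", "het"),
  control_common = c("het", "het", "het"))

#' Generate a trio VCF with planted inheritance classes
#'
#' Emits a three-sample VCF (child, father, mother) on the synthetic contig
#' with `n_per_class` variants realizing each of the five genotype patterns
#' — de novo (child het, parents hom_ref), recessive (child hom_alt,
#' parents het), dominant (het in the affected child and father, hom_ref in
#' the unaffected mother), inherited benign (het in child and mother) and
#' common (het in all three). GATK-style INFO/FORMAT fields carry plausible
#' values (GQ 30-99, AD consistent with genotype). Reproducible: the same
#' seed gives byte-identical text.
#'
#' @param seed Integer seed.
#' @param n_per_class Variants per class.
#' @param sample_ids The three sample names (child, father, mother).
#' @param build Declared build label written into the header.
#' @return List with `vcf` (character lines), `truth` (data.frame of
#'   chrom, pos, ref, alt, class and the three genotypes) and `samples`
#'   (named vector child/father/mother).
#' @export
generate_trio <- function(seed, n_per_class = 5L,
                          sample_ids = c("CHILD", "FATHER", "MOTHER"),
                          build = "hg19") {
  with_rng(seed, {
    n <- n_per_class * length(TRIO_CLASSES)
    pos <- sort(sample.int(FIXTURE_CONTIG_LEN - 10L, n))
    ref <- random_base(n)
    alt <- other_base(ref)
    classes <- rep(TRIO_CLASSES, each = n_per_class)
    lines <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      gts <- TRIO_PATTERNS[[classes[[i]]]]
      depths <- sample(20:60, 3, replace = TRUE)
      gqs <- sample(30:99, 3, replace = TRUE)
      lines[[i]] <- vcf_data_line(FIXTURE_CONTIG, pos[[i]], ref[[i]], alt[[i]],
                                  stats::runif(1, 100, 3000), gts, depths, gqs)
      truth[[i]] <- data.frame(chrom = FIXTURE_CONTIG, pos = pos[[i]],
                               ref = ref[[i]], alt = alt[[i]], class = classes[[i]],
                               gt_child = gts[[1]], gt_father = gts[[2]],
                               gt_mother = gts[[3]], stringsAsFactors = FALSE)
    }
    list(vcf = c(vcf_header(sample_ids, build), lines),
         truth = do.call(rbind, truth),
         samples = stats::setNames(sample_ids, c("child", "father", "mother")))
  })
}

#' Register the fixture trio in a store and import its VCF
#'
#' Convenience wrapper creating a project, the three samples (child and
#' father affected, mother unaffected control semantics off) with family
#' links, writing the VCF to a temp file and importing it.
#'
#' @param store A `vdb_store`.
#' @param trio Result of [generate_trio()].
#' @param project_name Project to create.
#' @return The import summary.
#' @export
load_trio <- function(store, trio, project_name = "trio_project") {
  pid <- add_project(store, project_name)
  s <- trio$samples
  add_sample(store, s[["father"]], pid, gender = "male", affected = TRUE)
  add_sample(store, s[["mother"]], pid, gender = "female", affected = FALSE)
  add_sample(store, s[["child"]], pid, affected = TRUE)
  set_family(store, s[["child"]], father_id = s[["father"]], mother_id = s[["mother"]])
  path <- tempfile(fileext = ".vcf")
  writeLines(trio$vcf, path)
  on.exit(unlink(path))
  import_vcf(store, path, vdb_current_build(store), keep_homref = TRUE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(matrix(sample(BASES, 3L * (n_codons - 2L), replace = TRUE),
                         ncol = 3L), 1L, paste, collapse = "")
  codons[codons %in% STOP_CODONS] <- "TGG"   # keep internal sequence stop-free
  paste(c("ATG", codons, "TAA"), collapse = "")
}

#' Generate synthetic transcript models with CDS sequences
#'
#' Produces three transcripts on the synthetic contig: TXC1, a plus-strand
#' multi-exon coding transcript; TXN1, a non-coding single-exon transcript;
#' and TXC2, a minus-strand coding transcript overlapping TXC1's last exon
#' (so ANY-transcript semantics are exercised). CDS lengths are multiples
#' of 3, starting ATG, ending TAA, internally stop-free.
#'
#' @param seed Integer seed.
#' @return List with `bed` (BED12 lines), `fasta` (CDS FASTA lines),
#'   `models` (parsed `gene_models`) and `cds` (named sequences).
#' @export
generate_gene_model <- function(seed) {
  with_rng(seed, {
    defs <- list(
      list(tx = "NM_0001.2", gene = "GENEA", nom = "refseq", strand = "+",
           exons_s = c(1001L, 2001L, 3001L), exons_e = c(1300L, 2450L, 3300L),
           cds_s = 1101L, cds_e = 3200L),
      list(tx = "NR_0100.1", gene = "GENEB", nom = "refseq", strand = "+",
           exons_s = 5001L, exons_e = 5600L, cds_s = NA, cds_e = NA),
      list(tx = "NM_0002.1", gene = "GENEC", nom = "refseq", strand = "-",
           exons_s = c(3100L, 4001L), exons_e = c(3600L, 4400L),
           cds_s = 3200L, cds_e = 4300L))
    bed <- character(0); fasta <- character(0); cds <- character(0)
    for (d in defs) {
      # trim cds_e so the spliced CDS length is a multiple of 3
      if (!is.na(d$cds_s)) {
        len <- sum(pmin(d$exons_e, d$cds_e) - pmax(d$exons_s, d$cds_s) + 1L)
        d$cds_e <- d$cds_e - (len %% 3L)
        len <- len - (len %% 3L)
        seq <- random_cds(len %/% 3L)
        cds[[d$tx]] <- seq
        fasta <- c(fasta, paste0(">", d$tx), seq)
      }
      sizes <- d$exons_e - d$exons_s + 1L
      offs <- d$exons_s - d$exons_s[[1]]
      bed <- c(bed, paste(c(FIXTURE_CONTIG, d$exons_s[[1]] - 1L,
                            d$exons_e[[length(d$exons_e)]],
                            paste(d$tx, d$gene, d$nom, sep = "|"), "0", d$strand,
                            if (is.na(d$cds_s)) c(d$exons_s[[1]] - 1L, d$exons_s[[1]] - 1L)
                            else c(d$cds_s - 1L, d$cds_e),
                            "0", length(sizes),
                            paste0(paste(sizes, collapse = ","), ","),
                            paste0(paste(offs, collapse = ","), ",")),
                          collapse = "\t"))
    }
    path <- tempfile(fileext = ".bed")
    writeLines(bed, path)
    models <- read_gene_models(path)
    unlink(path)
    list(bed = bed, fasta = fasta, models = models, cds = cds)
  })
}

#' Generate a cohort VCF with a planted gene-burden signal
#'
#' Emits an `n_samples` multi-sample VCF in which exactly `n_carriers`
#' distinct samples carry at least one het variant inside the span of the
#' given gene model; the first carrier receives two distinct variants in
#' the gene (a distinct-sample counting probe). Background variants
#' outside the gene are scattered across all samples.
#'
#' @param seed Integer seed.
#' @param n_samples Cohort size.
#' @param gene_model One-row `gene_models` data.frame defining the gene span.
#' @param n_carriers Number of carrier samples to plant (`<= n_samples`).
#' @param n_background Background variants outside the gene.
#' @return List with `vcf` lines, `truth` (data.frame of variants with
#'   `in_gene` and carrier sample), and `sample_ids`.
#' @export
generate_cohort <- function(seed, n_samples = 6L, gene_model, n_carriers = 3L,
                            n_background = 10L) {
  stopifnot(n_carriers <= n_samples)
  with_rng(seed, {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    g_start <- gene_model$tx_start[[1]]; g_end <- gene_model$tx_end[[1]]
    carriers <- sample_ids[seq_len(n_carriers)]
    planted <- list()
    # first carrier gets two variants in the gene, the rest one each
    n_in_gene <- n_carriers + 1L
    gpos <- sort(sample(seq(g_start, g_end), n_in_gene))
    carrier_of <- c(carriers[[1]], carriers)
    for (i in seq_len(n_in_gene))
      planted[[length(planted) + 1L]] <- list(pos = gpos[[i]], carrier = carrier_of[[i]],
                                              in_gene = TRUE)
    outside <- setdiff(seq_len(FIXTURE_CONTIG_LEN - 10L), seq(g_start - 1000L, g_end + 1000L))
    bpos <- sort(sample(outside, n_background))
    for (i in seq_len(n_background))
      planted[[length(planted) + 1L]] <- list(pos = bpos[[i]],
                                              carrier = sample(sample_ids, 1L),
                                              in_gene = FALSE)
    planted <- planted[order(vapply(planted, `[[`, 0L, "pos"))]
    lines <- character(0); truth <- list()
    for (p in planted) {
      ref <- random_base(); alt <- other_base(ref)
      gts <- ifelse(sample_ids == p$carrier, "het", "hom_ref")
      depths <- sample(20:60, n_samples, replace = TRUE)
      gqs <- sample(30:99, n_samples, replace = TRUE)
      lines <- c(lines, vcf_data_line(FIXTURE_CONTIG, p$pos, ref, alt,
                                      stats::runif(1, 100, 3000), gts, depths, gqs))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = FIXTURE_CONTIG, pos = p$pos, ref = ref, alt = alt,
        carrier = p$carrier, in_gene = p$in_gene, stringsAsFactors = FALSE)
    }
    list(vcf = c(vcf_header(sample_ids), lines), truth = do.call(rbind, truth),
         sample_ids = sample_ids)
  })
}

#' Generate two releases of an annotation table with planted changes
#'
#' Builds a v1 table (fields `maf`, `effect`, `clinical_significance`) over
#' the supplied variants and a v2 release in which specific change kinds
#' are planted, each with its expected flagging outcome: an effect change
#' to stopgain and a clinical change to pathogenic (both putatively
#' interesting), a small MAF drift, an effect change to missense and a
#' clinical change to benign (all three not interesting), plus one variant
#' whose fields are dropped entirely.
#'
#' @param seed Integer seed.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (at least 6
#'   rows).
#' @return List with `v1`, `v2` (annotation tables) and `planted`
#'   (data.frame: variant key, field, old, new, expect_interesting).
#' @export
generate_annotation_tables <- function(seed, variants) {
  stopifnot(nrow(variants) >= 6L)
  with_rng(seed, {
    n <- nrow(variants)
    v1 <- data.frame(chrom = variants$chrom, pos = variants$pos,
                     ref = variants$ref, alt = variants$alt,
                     maf = sprintf("%.4f", stats::runif(n, 0.001, 0.2)),
                     effect = sample(c("synonymous", "missense", "intronic"), n, TRUE),
                     clinical_significance = sample(c("benign", "uncertain"), n, TRUE),
                     stringsAsFactors = FALSE)
    v2 <- v1
    key <- function(i) paste(v1$chrom[[i]], v1$pos[[i]], v1$ref[[i]], v1$alt[[i]])
    planted <- list()
    plant <- function(i, field, new, interesting) {
      old <- v2[[field]][[i]]
      v2[[field]][[i]] <<- new
      planted[[length(planted) + 1L]] <<- data.frame(
        chrom = v1$chrom[[i]], pos = v1$pos[[i]], ref = v1$ref[[i]], alt = v1$alt[[i]],
        field_name = field, old_value = old, new_value = new,
        expect_interesting = interesting, stringsAsFactors = FALSE)
    }
    v1$effect[1:2] <- "synonymous"          # ensure the change is a real change
    v2$effect[1:2] <- "synonymous"
    v1$clinical_significance[3:4] <- "uncertain"
    v2$clinical_significance[3:4] <- "uncertain"
    plant(1L, "effect", "stopgain", TRUE)
    plant(2L, "effect", "missense", FALSE)
    plant(3L, "clinical_significance", "pathogenic", TRUE)
    plant(4L, "clinical_significance", "benign", FALSE)
    old_maf <- v2$maf[[5L]]
    plant(5L, "maf", sprintf("%.4f", as.numeric(old_maf) + 0.001), FALSE)
    # drop variant 6 entirely in v2 (archival + no-hit path)
    dropped <- 6L
    v2 <- v2[-dropped, ]
    list(v1 = v1, v2 = v2, planted = do.call(rbind, planted),
         dropped_key = v1[dropped, c("chrom", "pos", "ref", "alt")])
  })
}

#' Generate a multi-segment chain between two synthetic builds
#'
#' One chain from the fixture contig to a shifted target contig with
#' alternating source gaps (deleted regions, which fail liftover as
#' unmapped) and target gaps (insertions, which change the offset).
#' Segment layout is drawn from the seed; header totals are derived from
#' the segments, so the chain is always internally consistent.
#'
#' @param seed Integer seed.
#' @param n_segments Number of ungapped segments.
#' @param target_chrom Target contig name.
#' @return List with `chain` (file lines) and `parsed` ([parse_chain()]
#'   output).
#' @export
generate_chain <- function(seed, n_segments = 5L, target_chrom = "chrT") {
  with_rng(seed, {
    sizes <- sample(3000:12000, n_segments, replace = TRUE)
    dts <- c(sample(50:500, n_segments - 1L, replace = TRUE), 0L)
    dqs <- c(sample(0:800, n_segments - 1L, replace = TRUE), 0L)
    s_start <- 1000L; t_start <- 4000L
    s_end <- s_start + sum(sizes) + sum(dts)
    t_end <- t_start + sum(sizes) + sum(dqs)
    body <- vapply(seq_len(n_segments), function(i) {
      if (i < n_segments) sprintf("%d %d %d", sizes[[i]], dts[[i]], dqs[[i]])
      else sprintf("%d", sizes[[i]])
    }, "")
    lines <- c(sprintf("chain 1000 %s %d + %d %d %s %d + %d %d 1",
                       FIXTURE_CONTIG, FIXTURE_CONTIG_LEN, s_start, s_end,
                       target_chrom, FIXTURE_CONTIG_LEN + 20000L, t_start, t_end),
               body, "")
    list(chain = lines, parsed = parse_chain(lines))
  })
}

#' Expand parsed chains into an exhaustive per-base lookup table
#'
#' Brute-force oracle for position conversion: every source base of every
#' segment is tabulated with its target position.
#'
#' @param chains Parsed chains.
#' @return data.frame (`chrom`, `pos`, `t_chrom`, `t_pos`), 1-based.
#' @export
chain_lookup_table <- function(chains) {
  rows <- list()
  for (ch in chains) {
    seg <- ch$segments
    for (i in seq_len(nrow(seg))) {
      s <- seq(seg$s_start[[i]], seg$s_end[[i]] - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch$s_chrom, pos = s + 1L, t_chrom = ch$t_chrom,
        t_pos = s - seg$s_start[[i]] + seg$t_start[[i]] + 1L)
    }
  }
  do.call(rbind, rows)
}
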