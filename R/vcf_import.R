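## VCF 4.x import: normalization, multiallelic splitting, GATK field
## extraction. File parsing is delegated to vcfR; everything downstream of
## the parsed matrices is own code.

#' Normalize a variant to its minimal representation
#'
#' Trims the shared suffix first, then the shared prefix (advancing `pos`),
#' always retaining at least one base in each allele. No reference FASTA is
#' used: indels are not left-aligned, only trimmed.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Allele strings (uppercase A/C/G/T; `ref != alt`).
#' @return A list with `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  assert_valid_alleles(ref, alt)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # shared suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # shared prefix, advancing pos
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos),
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# GT string (e.g. "0/1", "1|1", "./1", ".", "1") -> genotype class relative
# to ALT allele index `allele`. Half-calls count as het; fully missing is
# "missing"; a haploid "1" (male X) is treated as hom_alt.
gt_class <- function(gt, allele = 1L) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  parts <- strsplit(gt, "[/|]")[[1]]
  if (all(parts == ".")) return("missing")
  hits <- sum(parts == as.character(allele))
  n_called <- sum(parts != ".")
  if (hits == 0L) {
    "hom_ref"
  } else if (length(parts) == 1L || (hits == n_called && n_called >= 2L)) {
    "hom_alt"
  } else {
    "het"
  }
}

#' Split a multiallelic VCF record into biallelic records
#'
#' Each of the k ALT alleles yields one record; AD is projected to
#' (ref depth, that allele's depth) and the genotype re-expressed relative to
#' the retained allele (other ALT alleles count as non-carrier). Missing AD
#' propagates as missing.
#'
#' @param record A list with `chrom`, `pos`, `ref`, `alt` (comma-separated
#'   ALT string or vector), `gt` (GT string), and optionally `ad`
#'   (comma-separated depths, ref first) plus any other fields, which are
#'   carried through unchanged.
#' @return List of biallelic records, each with `alt_index`, scalar `alt`,
#'   `genotype`, `ad_ref`, `ad_alt`.
#' @export
split_multiallelic <- function(record) {
  alts <- record$alt
  if (length(alts) == 1L) alts <- strsplit(alts, ",", fixed = TRUE)[[1]]
  ad <- rep(NA_integer_, length(alts) + 1L)
  if (!is.null(record$ad) && !is.na(record$ad)) {
    parsed <- suppressWarnings(as.integer(strsplit(record$ad, ",", fixed = TRUE)[[1]]))
    if (length(parsed) == length(alts) + 1L) ad <- parsed
  }
  lapply(seq_along(alts), function(k) {
    out <- record
    out$alt <- alts[[k]]
    out$alt_index <- k
    out$genotype <- gt_class(record$gt, k)
    out$ad_ref <- ad[[1L]]
    out$ad_alt <- ad[[k + 1L]]
    out
  })
}

is_symbolic_allele <- function(alt) {
  grepl("[<>\\[\\]*]", alt) || !grepl("^[ACGTNacgtn]+$", alt)
}

#' Extract the GATK quality vector for one sample of a parsed VCF record
#'
#' QUAL comes from the record; GT/GQ/AD from the sample's FORMAT column;
#' QD, MQ, FS and the BaseQ/MQ/ReadPos rank sums from INFO. The FILTER
#' string (e.g. a VQSR tranche label) is stored verbatim. Unparsable numeric
#' fields become missing with a warning.
#'
#' @param record List with `qual`, `filter`, `info` (named list or raw
#'   `;`-string) and `format`/`sample` columns (raw colon-strings), or
#'   pre-split `gt`, `gq`, `ad`.
#' @return A list of call fields suitable for [store_call()].
#' @export
extract_gatk_fields <- function(record) {
  fmt <- record
  if (!is.null(record$format) && !is.null(record$sample)) {
    keys <- strsplit(record$format, ":", fixed = TRUE)[[1]]
    vals <- strsplit(record$sample, ":", fixed = TRUE)[[1]]
    length(vals) <- length(keys)
    fmt <- as.list(vals)
    names(fmt) <- keys
    fmt$gt <- fmt$GT; fmt$gq <- fmt$GQ; fmt$ad <- fmt$AD
  }
  info <- record$info
  if (is.character(info) && length(info) == 1L) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    info <- stats::setNames(lapply(kv, function(x) if (length(x) > 1L) x[[2]] else TRUE),
                            vapply(kv, `[[`, "", 1L))
  }
  num <- function(x, label) {
    if (is.null(x) || is.na(x) || x == ".") return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) warning("unparsable numeric field ", label, ": ", x, call. = FALSE)
    v
  }
  list(qual = num(record$qual, "QUAL"),
       gq = num(fmt$gq, "GQ"),
       gt = if (is.null(fmt$gt)) NA_character_ else fmt$gt,
       ad = if (is.null(fmt$ad)) NA_character_ else fmt$ad,
       qd = num(info$QD, "QD"), mq = num(info$MQ, "MQ"), fs = num(info$FS, "FS"),
       base_q_rank_sum = num(info$BaseQRankSum, "BaseQRankSum"),
       mq_rank_sum = num(info$MQRankSum, "MQRankSum"),
       read_pos_rank_sum = num(info$ReadPosRankSum, "ReadPosRankSum"),
       filter_status = if (is.null(record$filter) || is.na(record$filter))
         NA_character_ else record$filter)
}

#' Import a VCF file for one or more registered samples
#'
#' Records are multiallelic-split, normalized and stored atomically
#' (all-or-nothing). The declared genome build must match the store's
#' current build, otherwise a build-conflict error is raised before any
#' write. Hom-ref and fully missing genotypes are skipped by default.
#'
#' @param store A `vdb_store`.
#' @param vcf_path Path to a plain or gzip VCF 4.x file.
#' @param declared_build Build label the VCF was called against.
#' @param sample_ids Samples to import; default all samples in the file
#'   (they must already be registered).
#' @param keep_homref Also store hom_ref / missing genotype calls.
#' @param overwrite Overwrite existing calls (makes re-import idempotent).
#' @return An import summary data.frame, one row per sample, with
#'   `n_records_read`, `n_variants_imported`, `n_multiallelic_split`,
#'   `n_skipped` and a `skip_reasons` column.
#' @export
import_vcf <- function(store, vcf_path, declared_build,
                       sample_ids = NULL, keep_homref = FALSE, overwrite = FALSE) {
  current <- vdb_current_build(store)
  if (!identical(declared_build, current))
    vdb_conflict("build conflict: VCF declared as '", declared_build,
                 "' but the store's current build is '", current, "'")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  ad_mat <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)
  gq_mat <- tryCatch(vcfR::extract.gt(vcf, element = "GQ"), error = function(e) NULL)
  file_samples <- colnames(gt_mat)
  if (is.null(sample_ids)) sample_ids <- file_samples
  missing_s <- setdiff(sample_ids, file_samples)
  if (length(missing_s))
    stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "), call. = FALSE)
  for (s in sample_ids)
    if (!sample_exists(store, s)) stop("sample not registered: ", s, call. = FALSE)

  con <- store$con
  dbBegin(con)
  ok <- FALSE
  on.exit(if (!ok) dbRollback(con))
  summaries <- lapply(sample_ids, function(s) {
    n_read <- nrow(fix); n_imported <- 0L; n_split <- 0L
    reasons <- c(symbolic_allele = 0L, `non-variant` = 0L)
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      if (length(alts) > 1L) n_split <- n_split + 1L
      cell_ad <- if (!is.null(ad_mat)) ad_mat[i, s] else NA_character_
      cell_gq <- if (!is.null(gq_mat)) gq_mat[i, s] else NA_character_
      base <- list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                   ref = toupper(fix[i, "REF"]), alt = toupper(alts),
                   qual = fix[i, "QUAL"], filter = fix[i, "FILTER"],
                   info = fix[i, "INFO"], gt = gt_mat[i, s],
                   gq = cell_gq, ad = cell_ad)
      if (any(vapply(alts, is_symbolic_allele, TRUE))) {
        reasons["symbolic_allele"] <- reasons["symbolic_allele"] + 1L
        next
      }
      for (rec in split_multiallelic(base)) {
        if (!keep_homref && rec$genotype %in% c("hom_ref", "missing")) {
          reasons["non-variant"] <- reasons["non-variant"] + 1L
          next
        }
        norm <- normalize_variant(rec$chrom, rec$pos, rec$ref, rec$alt)
        vid <- upsert_variant(store, declared_build, norm$chrom, norm$pos,
                              norm$ref, norm$alt)
        q <- extract_gatk_fields(rec)
        store_call(store, s, vid, rec$genotype, qual = q$qual, gq = q$gq,
                   ad_ref = rec$ad_ref, ad_alt = rec$ad_alt,
                   qd = q$qd, mq = q$mq, fs = q$fs,
                   base_q_rank_sum = q$base_q_rank_sum, mq_rank_sum = q$mq_rank_sum,
                   read_pos_rank_sum = q$read_pos_rank_sum,
                   filter_status = q$filter_status, overwrite = overwrite)
        n_imported <- n_imported + 1L
      }
    }
    data.frame(sample_id = s, n_records_read = n_read,
               n_variants_imported = n_imported, n_multiallelic_split = n_split,
               n_skipped = sum(reasons), build = declared_build,
               skip_reasons = paste(sprintf("%s=%d", names(reasons), reasons),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  dbCommit(con)
  ok <- TRUE
  do.call(rbind, summaries)
}
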