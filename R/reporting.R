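## Result presentation: call-set summary statistics (Tr/Tv, known/novel,
## SNP/indel, MAF distribution), compact/wide CSV export, IGV locus links
## and fixed-size result pagination.

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
MAF_BIN_EDGES <- c(0, 0.001, 0.01, 0.05, 0.1, 0.5)
IGV_WINDOW <- 25L
PAGE_SIZE <- 100L

#' Summary statistics of a variant set
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine SNVs (A<->G,
#' C<->T); transversions the remaining SNVs; indels have differing allele
#' lengths. A variant is "known" when it carries an rsID annotation. The
#' MAF histogram bins the configured frequency values over fixed edges,
#' with missing MAFs counted in a separate bin. With zero transversions the
#' Tr/Tv ratio is reported as `NA`, not infinity.
#'
#' @param variants data.frame with `ref`, `alt` and optionally `rsid` and
#'   `maf` columns (`NA` = absent).
#' @param maf_bin_edges Histogram bin edges (right-closed).
#' @return List with `tr_count`, `tv_count`, `trtv_ratio`, `n_snp`,
#'   `n_indel`, `n_known`, `n_novel`, `maf_histogram`.
#' @export
compute_summary <- function(variants, maf_bin_edges = MAF_BIN_EDGES) {
  is_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  change <- paste0(variants$ref, ">", variants$alt)
  tr <- sum(is_snp & change %in% TRANSITIONS)
  tv <- sum(is_snp) - tr
  rsid <- if ("rsid" %in% names(variants)) variants$rsid else rep(NA, nrow(variants))
  known <- !is.na(rsid) & rsid != ""
  maf <- if ("maf" %in% names(variants)) as.numeric(variants$maf)
         else rep(NA_real_, nrow(variants))
  labels <- paste0("(", utils::head(maf_bin_edges, -1), ",",
                   utils::tail(maf_bin_edges, -1), "]")
  bins <- cut(maf, breaks = maf_bin_edges, include.lowest = TRUE, labels = labels)
  hist <- table(bins, useNA = "no")
  hist <- c(as.list(hist), list(missing = sum(is.na(maf))))
  list(tr_count = tr, tv_count = tv,
       trtv_ratio = if (tv == 0L) NA_real_ else tr / tv,
       n_snp = sum(is_snp), n_indel = sum(!is_snp),
       n_known = sum(known), n_novel = sum(!known),
       maf_histogram = hist)
}

#' IGV locus hyperlink target for a variant
#'
#' A 1-based inclusive `chrom:start-end` window extending 25 bp on each
#' side of the variant's reference span, clamped at position 1.
#'
#' @param variant List/row with `chrom`, `pos`, `ref`.
#' @param window Flank size in bp.
#' @return Locus string, e.g. `"chr1:75-125"`.
#' @export
igv_locus <- function(variant, window = IGV_WINDOW) {
  pos <- as.integer(variant$pos)
  span_end <- pos + nchar(variant$ref) - 1L
  sprintf("%s:%d-%d", variant$chrom, max(1L, pos - window), span_end + window)
}

#' Slice an ordered result list into fixed-size pages
#'
#' Deterministic slicing of the (chrom, pos)-ordered result; the last page
#' may be short and a page beyond the range is empty, not an error.
#'
#' @param results data.frame of results (already ordered).
#' @param page 1-based page number.
#' @param page_size Rows per page (the interface presents batches of 100).
#' @return List with `page` (the slice), `total` (overall row count) and
#'   `n_pages`.
#' @export
paginate <- function(results, page, page_size = PAGE_SIZE) {
  stopifnot(page >= 1L, page_size >= 1L)
  total <- nrow(results)
  from <- (page - 1L) * page_size + 1L
  to <- min(total, page * page_size)
  slice <- if (from > total) results[0, , drop = FALSE]
           else results[from:to, , drop = FALSE]
  list(page = slice, total = total, n_pages = ceiling(total / page_size))
}

rfc4180_cell <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

write_csv_rfc4180 <- function(df, path) {
  lines <- c(paste(rfc4180_cell(names(df)), collapse = ","),
             if (nrow(df)) apply(df, 1L, function(r)
               paste(rfc4180_cell(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Export variants with selected annotations to CSV
#'
#' `wide` layout: one row per variant, five fixed variant columns
#' (chrom, pos, ref, alt, igv_locus) plus one column per selected
#' annotation; multi-transcript values stay pipe-joined in a single cell
#' (reversible via [mv_split()]). `compact` layout: one sub-row per
#' transcript element, variant columns repeated. Output is RFC 4180 CSV.
#'
#' @param store A `vdb_store`.
#' @param variant_ids Variants to export (exported (chrom, pos)-ordered).
#' @param annotation_names Character vector of `source.field` names (or
#'   bare unique field names).
#' @param layout `"wide"` or `"compact"`.
#' @param destination Output file path.
#' @param build Build; default current.
#' @return Invisibly the destination path.
#' @export
export_variants <- function(store, variant_ids, annotation_names,
                            layout = c("wide", "compact"), destination,
                            build = vdb_current_build(store)) {
  layout <- match.arg(layout)
  fields_map <- known_fields(store)
  unknown <- setdiff(annotation_names, names(fields_map))
  if (length(unknown))
    stop("unknown annotation name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vars <- get_variants(store, build)
  vars <- vars[vars$variant_id %in% variant_ids, , drop = FALSE]
  ann <- get_annotations(store, vars$variant_id)
  cell <- function(vid, name) {
    target <- fields_map[[name]]
    hit <- ann$value[ann$variant_id == vid & ann$source_name == target[[1]] &
                       ann$field_name == target[[2]]]
    if (length(hit)) hit[[1]] else NA_character_
  }
  base_cols <- data.frame(chrom = vars$chrom, pos = vars$pos, ref = vars$ref,
                          alt = vars$alt,
                          igv_locus = vapply(seq_len(nrow(vars)), function(i)
                            igv_locus(vars[i, ]), ""),
                          stringsAsFactors = FALSE)
  if (layout == "wide") {
    for (nm in annotation_names)
      base_cols[[nm]] <- vapply(vars$variant_id, cell, "", name = nm)
    return(invisible(write_csv_rfc4180(base_cols, destination)))
  }
  # compact: expand each variant into per-transcript sub-rows
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    vals <- lapply(annotation_names, function(nm) {
      v <- cell(vars$variant_id[[i]], nm)
      if (is.na(v)) NA_character_ else mv_split(v)
    })
    k <- max(1L, vapply(vals, length, 0L))
    sub <- base_cols[rep(i, k), , drop = FALSE]
    sub$subrow <- seq_len(k)
    for (j in seq_along(annotation_names)) {
      v <- vals[[j]]
      sub[[annotation_names[[j]]]] <- if (length(v) == k) v
        else c(v, rep(NA_character_, k - length(v)))
    }
    sub
  })
  out <- do.call(rbind, rows)
  invisible(write_csv_rfc4180(out, destination))
}
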