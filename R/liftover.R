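## Genome-build conversion through UCSC chain files. Chains are parsed into
## per-block alignment segments; positions map through the unique covering
## segment, and failures (unmapped, span split across blocks, strand flip)
## are data, not exceptions — they feed the manual-curation queue.

#' Parse a UCSC chain file
#'
#' Coordinates are kept 0-based half-open internally (as in the format) and
#' converted at the variant boundary. Each chain is expanded into its
#' ungapped alignment segments.
#'
#' @param path Chain file path, or a character vector of lines.
#' @return List of chains; each has the header fields plus a `segments`
#'   data.frame (`s_start`, `s_end`, `t_start` 0-based half-open source
#'   interval and target start per segment).
#' @export
parse_chain <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, "chain "))
      stop("malformed chain header at line ", i, ": ", line, call. = FALSE)
    h <- strsplit(line, "\\s+")[[1]]
    if (length(h) < 12L)
      stop("malformed chain header at line ", i, ": expected 12+ fields", call. = FALSE)
    hdr <- list(score = as.numeric(h[[2]]),
                s_chrom = h[[3]], s_size = as.integer(h[[4]]), s_strand = h[[5]],
                s_start = as.integer(h[[6]]), s_end = as.integer(h[[7]]),
                t_chrom = h[[8]], t_size = as.integer(h[[9]]), t_strand = h[[10]],
                t_start = as.integer(h[[11]]), t_end = as.integer(h[[12]]),
                chain_id = if (length(h) >= 13L) h[[13]] else NA_character_)
    if (hdr$s_strand != "+")
      stop("chain source strand must be '+' at line ", i, call. = FALSE)
    segs <- list(); sp <- hdr$s_start; tp <- hdr$t_start
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("truncated chain block", call. = FALSE)
      ln <- trimws(lines[[i]]); i <- i + 1L
      if (!nzchar(ln)) next
      f <- suppressWarnings(as.integer(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(f)) stop("malformed alignment line ", i - 1L, call. = FALSE)
      size <- f[[1]]
      segs[[length(segs) + 1L]] <- c(sp, sp + size, tp)
      if (length(f) == 1L) break
      sp <- sp + size + f[[2]]
      tp <- tp + size + f[[3]]
    }
    m <- do.call(rbind, segs)
    hdr$segments <- data.frame(s_start = m[, 1], s_end = m[, 2], t_start = m[, 3])
    if (m[nrow(m), 2] > hdr$s_end)
      stop("chain segments overrun the source interval", call. = FALSE)
    chains[[length(chains) + 1L]] <- hdr
  }
  chains
}

#' Map a 1-based position (or short span) through loaded chains
#'
#' The position must fall inside exactly one ungapped alignment segment.
#' Positions inside source gaps are `unmapped`; spans whose end maps to a
#' different segment than their start are `split_across_blocks`; chains to
#' a minus-strand target are `strand_flip_unsupported` (alleles would need
#' reverse-complementing, which is refused rather than guessed).
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param chains Parsed chains from [parse_chain()].
#' @param span Reference-span length in bases (1 for SNVs).
#' @return List with `ok`; on success `chrom` and `pos` (1-based), on
#'   failure `reason`.
#' @export
convert_position <- function(chrom, pos, chains, span = 1L) {
  p0 <- as.integer(pos) - 1L                 # 0-based
  end0 <- p0 + as.integer(span) - 1L         # last base, 0-based
  for (ch in chains) {
    if (ch$s_chrom != chrom) next
    if (p0 < ch$s_start || p0 >= ch$s_end) next
    if (ch$t_strand != "+")
      return(list(ok = FALSE, reason = "strand_flip_unsupported"))
    seg <- ch$segments
    hit <- which(p0 >= seg$s_start & p0 < seg$s_end)
    if (!length(hit)) return(list(ok = FALSE, reason = "unmapped"))
    hit_end <- which(end0 >= seg$s_start & end0 < seg$s_end)
    if (!length(hit_end) || hit_end != hit)
      return(list(ok = FALSE, reason = "split_across_blocks"))
    off <- seg$t_start[[hit]] - seg$s_start[[hit]]
    return(list(ok = TRUE, chrom = ch$t_chrom, pos = p0 + off + 1L))
  }
  list(ok = FALSE, reason = "unmapped")
}

#' Invert a set of chains (swap source and target)
#'
#' Useful to check that mappable positions round-trip to themselves.
#' Only plus-strand chains can be inverted.
#'
#' @param chains Parsed chains.
#' @return Parsed chains mapping target back to source.
#' @export
invert_chains <- function(chains) {
  lapply(chains, function(ch) {
    stopifnot(ch$t_strand == "+")
    segs <- ch$segments
    inv <- ch
    inv[c("s_chrom", "s_size", "s_strand", "s_start", "s_end")] <-
      ch[c("t_chrom", "t_size", "t_strand", "t_start", "t_end")]
    inv[c("t_chrom", "t_size", "t_strand", "t_start", "t_end")] <-
      ch[c("s_chrom", "s_size", "s_strand", "s_start", "s_end")]
    inv$segments <- data.frame(s_start = segs$t_start,
                               s_end = segs$t_start + (segs$s_end - segs$s_start),
                               t_start = segs$s_start)
    inv
  })
}

#' Convert every variant of a build to a new build
#'
#' Converted variants are inserted under `new_build` together with copies
#' of their genotype calls; the old build is flagged read-only (subsequent
#' writes are rejected) and keeps its final annotations frozen. Failures
#' are queued for manual curation with their reason. When annotation
#' sources for the new build are supplied, the annotate-missing cycle runs
#' on the converted variants.
#'
#' @param store A `vdb_store`.
#' @param chains Parsed chains from the old to the new build.
#' @param new_build Target build label.
#' @param sources Optional list of `annotation_source`s valid for the new
#'   build, re-annotated after conversion.
#' @param target_seqs Optional named character vector (or FASTA path) of
#'   target-build chromosome sequences; when supplied, the reference allele
#'   is verified at the converted position and mismatches fail with reason
#'   `ref_changed`. Without it verification is skipped.
#' @param old_build Build to convert; default current.
#' @return A conversion report: list with `n_converted`, `failures`
#'   (data.frame `variant_id`, `chrom`, `pos`, `ref`, `alt`, `reason`) and
#'   `n_total`.
#' @export
convert_store <- function(store, chains, new_build, sources = list(),
                          target_seqs = NULL,
                          old_build = vdb_current_build(store)) {
  if (is.character(target_seqs) && length(target_seqs) == 1L &&
      file.exists(target_seqs))
    target_seqs <- read_cds_fasta(target_seqs)
  if (!length(chains)) stop("no chains supplied; aborting before any write",
                            call. = FALSE)
  con <- store$con
  vars <- get_variants(store, old_build)
  dbExecute(con, "INSERT OR IGNORE INTO builds (build) VALUES (?)",
            params = list(new_build))
  dbExecute(con, "UPDATE builds SET is_current = 0")
  dbExecute(con, "UPDATE builds SET is_current = 1 WHERE build = ?",
            params = list(new_build))
  n_conv <- 0L; failures <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    res <- convert_position(v$chrom, v$pos, chains, span = nchar(v$ref))
    if (res$ok && !is.null(target_seqs) && res$chrom %in% names(target_seqs)) {
      at_target <- substr(target_seqs[[res$chrom]], res$pos,
                          res$pos + nchar(v$ref) - 1L)
      if (!identical(at_target, v$ref))
        res <- list(ok = FALSE, reason = "ref_changed")
    }
    if (!res$ok) {
      failures[[length(failures) + 1L]] <-
        data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                   ref = v$ref, alt = v$alt, reason = res$reason,
                   stringsAsFactors = FALSE)
      dbExecute(con, "INSERT INTO liftover_failures (variant_id, target_build, reason)
                      VALUES (?,?,?)",
                params = list(v$variant_id, new_build, res$reason))
      next
    }
    new_id <- upsert_variant(store, new_build, res$chrom, res$pos, v$ref, v$alt)
    calls <- dbGetQuery(con, "SELECT * FROM genotype_calls WHERE variant_id = ?",
                        params = list(v$variant_id))
    for (j in seq_len(nrow(calls))) {
      cl <- calls[j, ]
      store_call(store, cl$sample_id, new_id, cl$genotype, qual = cl$qual,
                 gq = cl$gq, ad_ref = cl$ad_ref, ad_alt = cl$ad_alt, qd = cl$qd,
                 mq = cl$mq, fs = cl$fs, base_q_rank_sum = cl$base_q_rank_sum,
                 mq_rank_sum = cl$mq_rank_sum,
                 read_pos_rank_sum = cl$read_pos_rank_sum,
                 filter_status = cl$filter_status, overwrite = TRUE)
    }
    n_conv <- n_conv + 1L
  }
  dbExecute(con, "UPDATE builds SET read_only = 1 WHERE build = ?",
            params = list(old_build))
  for (src in sources) {
    register_source(store, src)
    annotate_missing(store, src, new_build)
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(variant_id = integer(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(n_converted = n_conv, failures = failures, n_total = nrow(vars))
}

#' Pending liftover failures awaiting manual curation
#' @param store A `vdb_store`.
#' @param target_build Restrict to one target build.
#' @return data.frame of queue entries.
#' @export
liftover_queue <- function(store, target_build = NULL) {
  sql <- "SELECT f.rowid AS queue_id, f.*, v.chrom, v.pos, v.ref, v.alt
          FROM liftover_failures f JOIN variants v ON v.variant_id = f.variant_id
          WHERE f.resolved = 'pending'"
  params <- list()
  if (!is.null(target_build)) { sql <- paste(sql, "AND f.target_build = ?")
                                params <- list(target_build) }
  if (length(params)) dbGetQuery(store$con, sql, params = params)
  else dbGetQuery(store$con, sql)
}

#' Resolve a queued liftover failure
#'
#' Either skip the variant permanently or supply manually curated target
#' coordinates, which insert it under the target build.
#'
#' @param store A `vdb_store`.
#' @param queue_id Queue entry id from [liftover_queue()].
#' @param action `"skip"` or `"manual"`.
#' @param chrom,pos Manually curated coordinates (action `"manual"`).
#' @export
resolve_liftover_failure <- function(store, queue_id, action = c("skip", "manual"),
                                     chrom = NULL, pos = NULL) {
  action <- match.arg(action)
  q <- dbGetQuery(store$con,
    "SELECT f.rowid AS queue_id, f.* , v.ref, v.alt FROM liftover_failures f
     JOIN variants v ON v.variant_id = f.variant_id WHERE f.rowid = ?",
    params = list(queue_id))
  if (!nrow(q)) stop("unknown queue entry: ", queue_id, call. = FALSE)
  if (action == "manual") {
    stopifnot(!is.null(chrom), !is.null(pos))
    upsert_variant(store, q$target_build, chrom, pos, q$ref, q$alt)
  }
  dbExecute(store$con, "UPDATE liftover_failures SET resolved = ? WHERE rowid = ?",
            params = list(action, queue_id))
  invisible(NULL)
}
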