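## Versioned annotation engine: pluggable offline table-driven sources, the
## annotate-missing-then-store cycle, re-annotation on source updates with
## archival of superseded records, change logging and novelty flagging.

# Per-transcript (multi-)values are stored inside a single active record,
# joined with "|" (literal pipes escaped). This keeps the one-active-record
# invariant per (variant, source, field) while filter atoms and exports can
# split back to per-transcript elements.
MV_SEP <- "|"

mv_escape <- function(x) gsub("|", "\\|", x, fixed = TRUE)
mv_unescape <- function(x) gsub("\\|", "|", x, fixed = TRUE)

#' Join multiple per-transcript values into one stored cell
#' @param values Character vector of element values.
#' @return Single string; literal pipes in elements are escaped.
#' @export
mv_join <- function(values) paste(mv_escape(as.character(values)), collapse = MV_SEP)

#' Split a stored multi-value cell back into its elements
#' @param x Single stored string.
#' @return Character vector of element values.
#' @export
mv_split <- function(x) {
  if (is.na(x)) return(NA_character_)
  parts <- strsplit(x, "(?<!\\\\)\\|", perl = TRUE)[[1]]
  mv_unescape(parts)
}

NO_HIT_FIELD <- ".no_hit"

#' Define an annotation source
#'
#' A source is a named, versioned provider: a function taking a variant
#' data.frame (`variant_id`, `chrom`, `pos`, `ref`, `alt`) and returning a
#' long data.frame (`variant_id`, `field_name`, `value`). Variants absent
#' from the result are recorded as explicit no-hits so they are not
#' re-queried forever.
#'
#' @param source_name Unique source name.
#' @param version_label Release label; updates must use a strictly newer one.
#' @param fields data.frame with `field_name` and `value_kind`
#'   (`number`/`text`/`flag`); field names unique within the source.
#' @param provider The lookup function described above.
#' @return An `annotation_source` object.
#' @export
annotation_source <- function(source_name, version_label, fields, provider) {
  stopifnot(is.function(provider), !anyDuplicated(fields$field_name))
  stopifnot(all(fields$value_kind %in% c("number", "text", "flag")))
  structure(list(source_name = source_name, version_label = version_label,
                 fields = fields, provider = provider),
            class = "annotation_source")
}

#' Build a source from a tab-delimited lookup table
#'
#' The table must carry header columns `chrom`, `pos`, `ref`, `alt`; every
#' remaining column becomes an annotation field. Matching is exact on all
#' four key columns (same position with a different alt does not match).
#'
#' @param source_name,version_label As in [annotation_source()].
#' @param table A data.frame, or a path to a TSV file with header.
#' @param value_kinds Optional named vector overriding the inferred
#'   `value_kind` per field.
#' @return An `annotation_source`.
#' @export
table_source <- function(source_name, version_label, table, value_kinds = NULL) {
  if (is.character(table))
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               colClasses = "character", comment.char = "")
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(table)))
  table$pos <- as.integer(table$pos)
  value_cols <- setdiff(names(table), c("chrom", "pos", "ref", "alt"))
  kinds <- vapply(value_cols, function(f) {
    if (!is.null(value_kinds) && f %in% names(value_kinds)) return(value_kinds[[f]])
    v <- table[[f]][!is.na(table[[f]]) & table[[f]] != ""]
    if (length(v) && !anyNA(suppressWarnings(as.numeric(v)))) "number" else "text"
  }, "")
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  tkey <- key(table)
  provider <- function(variants) {
    hit <- match(key(variants), tkey)
    rows <- which(!is.na(hit))
    out <- lapply(rows, function(i) {
      vals <- as.character(unlist(table[hit[[i]], value_cols]))
      keep <- !is.na(vals) & vals != "" & vals != "."
      data.frame(variant_id = variants$variant_id[[i]],
                 field_name = value_cols[keep], value = vals[keep],
                 stringsAsFactors = FALSE)
    })
    if (!length(out)) return(data.frame(variant_id = integer(0),
                                        field_name = character(0),
                                        value = character(0)))
    do.call(rbind, out)
  }
  annotation_source(source_name, version_label,
                    data.frame(field_name = value_cols, value_kind = kinds,
                               stringsAsFactors = FALSE),
                    provider)
}

#' Register a source (or a new version of one) in the store
#' @param store A `vdb_store`.
#' @param source An `annotation_source`.
#' @export
register_source <- function(store, source) {
  dbExecute(store$con,
    "INSERT INTO annotation_sources (source_name, version_label, registered_at, field_schema)
     VALUES (?,?,?,?) ON CONFLICT (source_name) DO UPDATE SET
       version_label = excluded.version_label, field_schema = excluded.field_schema",
    params = list(source$source_name, source$version_label, vdb_now(),
                  jsonlite::toJSON(source$fields)))
  dbExecute(store$con,
    "INSERT OR IGNORE INTO source_versions VALUES (?,?,?)",
    params = list(source$source_name, source$version_label, vdb_now()))
  invisible(NULL)
}

# current provider output for a set of variants, normalized to character
run_provider <- function(source, variants) {
  res <- source$provider(variants)
  if (!nrow(res)) return(res)
  bad <- setdiff(unique(res$field_name), source$fields$field_name)
  if (length(bad))
    stop("provider of '", source$source_name, "' returned undeclared field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  res$value <- as.character(res$value)
  res
}

#' Annotate variants missing this source's annotation
#'
#' Implements the annotate-missing cycle: collect the variants of the
#' current build without any active record from the source (including the
#' explicit no-hit marker), run the provider on exactly those, store the
#' results as active records at the source's current version. Variants the
#' provider returns nothing for receive a no-hit marker record, which makes
#' an immediate re-run annotate zero variants.
#'
#' @param store A `vdb_store`.
#' @param source A registered `annotation_source`.
#' @param build Build to annotate; default current.
#' @return Number of variants sent to the provider in this run.
#' @export
annotate_missing <- function(store, source, build = vdb_current_build(store)) {
  con <- store$con
  todo <- dbGetQuery(con,
    "SELECT v.variant_id, v.chrom, v.pos, v.ref, v.alt FROM variants v
     WHERE v.build = ? AND NOT EXISTS (
       SELECT 1 FROM annotations a
       WHERE a.variant_id = v.variant_id AND a.source_name = ? AND a.active = 1)
     ORDER BY v.variant_id",
    params = list(build, source$source_name))
  if (!nrow(todo)) return(0L)
  res <- run_provider(source, todo)
  now <- vdb_now()
  dbBegin(con); ok <- FALSE; on.exit(if (!ok) dbRollback(con))
  if (nrow(res))
    for (i in seq_len(nrow(res)))
      dbExecute(con,
        "INSERT INTO annotations (variant_id, source_name, field_name, value,
           source_version, active, created_at) VALUES (?,?,?,?,?,1,?)",
        params = list(res$variant_id[[i]], source$source_name, res$field_name[[i]],
                      res$value[[i]], source$version_label, now))
  no_hit <- setdiff(todo$variant_id, unique(res$variant_id))
  for (vid in no_hit)
    dbExecute(con,
      "INSERT INTO annotations (variant_id, source_name, field_name, value,
         source_version, active, created_at) VALUES (?,?,?,'1',?,1,?)",
      params = list(vid, source$source_name, NO_HIT_FIELD, source$version_label, now))
  dbCommit(con); ok <- TRUE
  nrow(todo)
}

#' Re-annotate every stored variant against a new source release
#'
#' Unchanged values keep their record (and original version stamp); changed
#' or dropped values have the old record retired — archived, never deleted —
#' and the new value inserted; newly appearing fields are inserted. One
#' change-log entry is written per changed (variant, field), and putatively
#' interesting changes (see [flag_interesting()]) are flagged in the log.
#'
#' @param store A `vdb_store`.
#' @param source The source at its new version (same `source_name`, strictly
#'   newer `version_label`).
#' @param build Build to update; default current.
#' @return data.frame of change-log entries emitted by this run.
#' @export
update_source <- function(store, source, build = vdb_current_build(store)) {
  con <- store$con
  prev <- dbGetQuery(con,
    "SELECT version_label FROM annotation_sources WHERE source_name = ?",
    params = list(source$source_name))$version_label
  if (!length(prev))
    stop("source '", source$source_name, "' is not registered", call. = FALSE)
  known <- dbGetQuery(con,
    "SELECT version_label FROM source_versions WHERE source_name = ?",
    params = list(source$source_name))$version_label
  if (source$version_label %in% known)
    stop("version label '", source$version_label, "' is not newer than '",
         prev, "'", call. = FALSE)

  variants <- dbGetQuery(con,
    "SELECT variant_id, chrom, pos, ref, alt FROM variants WHERE build = ?
     ORDER BY variant_id", params = list(build))
  res <- run_provider(source, variants)
  now <- vdb_now()

  old <- dbGetQuery(con,
    "SELECT annotation_id, variant_id, field_name, value, source_version
     FROM annotations WHERE source_name = ? AND active = 1
       AND variant_id IN (SELECT variant_id FROM variants WHERE build = ?)",
    params = list(source$source_name, build))
  key <- function(v, f) paste(v, f, sep = "\r")
  old_k <- key(old$variant_id, old$field_name)
  new_k <- if (nrow(res)) key(res$variant_id, res$field_name) else character(0)

  changes <- list()
  log_change <- function(vid, field, old_value, new_value, old_version) {
    changes[[length(changes) + 1L]] <<- data.frame(
      variant_id = vid, source_name = source$source_name, field_name = field,
      old_value = old_value, new_value = new_value,
      old_version = old_version, new_version = source$version_label,
      timestamp = now, stringsAsFactors = FALSE)
  }
  retire <- function(annotation_id)
    dbExecute(con, "UPDATE annotations SET active = 0, retired_at = ? WHERE annotation_id = ?",
              params = list(now, annotation_id))
  insert_active <- function(vid, field, value)
    dbExecute(con,
      "INSERT INTO annotations (variant_id, source_name, field_name, value,
         source_version, active, created_at) VALUES (?,?,?,?,?,1,?)",
      params = list(vid, source$source_name, field, value, source$version_label, now))

  dbBegin(con); ok <- FALSE; on.exit(if (!ok) dbRollback(con))
  # changed or unchanged existing fields
  if (nrow(res)) for (i in seq_len(nrow(res))) {
    j <- match(new_k[[i]], old_k)
    if (!is.na(j)) {
      if (!identical(old$value[[j]], res$value[[i]])) {
        retire(old$annotation_id[[j]])
        insert_active(res$variant_id[[i]], res$field_name[[i]], res$value[[i]])
        log_change(res$variant_id[[i]], res$field_name[[i]],
                   old$value[[j]], res$value[[i]], old$source_version[[j]])
      }
    } else {
      # newly appearing field; retire a no-hit marker if one is active
      nh <- match(key(res$variant_id[[i]], NO_HIT_FIELD), old_k)
      if (!is.na(nh) && !is.na(old$annotation_id[[nh]])) {
        retire(old$annotation_id[[nh]])
        old$annotation_id[[nh]] <- NA_integer_  # retire once
      }
      insert_active(res$variant_id[[i]], res$field_name[[i]], res$value[[i]])
      log_change(res$variant_id[[i]], res$field_name[[i]],
                 NA_character_, res$value[[i]], NA_character_)
    }
  }
  # fields dropped in the new release
  dropped <- which(!(old_k %in% new_k) & old$field_name != NO_HIT_FIELD)
  for (j in dropped) {
    if (is.na(old$annotation_id[[j]])) next
    retire(old$annotation_id[[j]])
    log_change(old$variant_id[[j]], old$field_name[[j]], old$value[[j]],
               NA_character_, old$source_version[[j]])
    # a variant losing all fields becomes a no-hit under the new release
  }
  if (length(dropped)) {
    still <- dbGetQuery(con,
      "SELECT DISTINCT variant_id FROM annotations
       WHERE source_name = ? AND active = 1", params = list(source$source_name))$variant_id
    for (vid in setdiff(unique(old$variant_id[dropped]), still))
      insert_active(vid, NO_HIT_FIELD, "1")
  }
  changes <- if (length(changes)) do.call(rbind, changes) else data.frame(
    variant_id = integer(0), source_name = character(0), field_name = character(0),
    old_value = character(0), new_value = character(0), old_version = character(0),
    new_version = character(0), timestamp = character(0), stringsAsFactors = FALSE)
  changes$interesting <- flag_interesting(changes)
  if (nrow(changes)) for (i in seq_len(nrow(changes)))
    dbExecute(con,
      "INSERT INTO change_log (variant_id, source_name, field_name, old_value,
         new_value, old_version, new_version, timestamp, interesting)
       VALUES (?,?,?,?,?,?,?,?,?)",
      params = c(unname(as.list(changes[i, c("variant_id", "source_name", "field_name",
                                             "old_value", "new_value", "old_version",
                                             "new_version", "timestamp")])),
                 list(as.integer(changes$interesting[[i]]))))
  dbCommit(con); ok <- TRUE
  register_source(store, source)
  # annotate variants never seen before by this source (e.g. imported later)
  annotate_missing(store, source, build)
  changes
}

HIGH_IMPACT_TERMS <- c("frameshift", "stopgain", "splicing")
PATHOGENIC_CLASSES <- c("pathogenic", "likely_pathogenic")

#' Flag putatively interesting annotation changes
#'
#' A change is flagged when (a) a gene-effect field changes to a high-impact
#' term (frameshift, stopgain, splicing — premature stops and splice
#' disruption), or (b) a clinical-significance field changes to a
#' pathogenic or likely-pathogenic class. Multi-transcript values are
#' flagged if any element is high-impact.
#'
#' @param changes Change data.frame as returned by [update_source()].
#' @param effect_fields Field names treated as gene-effect fields.
#' @param clinical_fields Field names treated as clinical-significance fields.
#' @param high_impact,pathogenic The trigger vocabularies.
#' @return Logical vector along `changes` rows.
#' @export
flag_interesting <- function(changes,
                             effect_fields = c("effect", "coding_effect", "location"),
                             clinical_fields = c("clinical_significance",
                                                 "pathogenic_class", "clnsig"),
                             high_impact = HIGH_IMPACT_TERMS,
                             pathogenic = PATHOGENIC_CLASSES) {
  if (!nrow(changes)) return(logical(0))
  hit_any <- function(value, terms) {
    if (is.na(value)) return(FALSE)
    any(tolower(mv_split(value)) %in% terms)
  }
  vapply(seq_len(nrow(changes)), function(i) {
    f <- changes$field_name[[i]]; new <- changes$new_value[[i]]; old <- changes$old_value[[i]]
    if (f %in% effect_fields)
      return(hit_any(new, high_impact) && !hit_any(old, high_impact))
    if (f %in% clinical_fields)
      return(hit_any(new, tolower(pathogenic)) && !hit_any(old, tolower(pathogenic)))
    FALSE
  }, TRUE)
}

#' Active annotations for variants
#' @param store A `vdb_store`.
#' @param variant_ids Integer ids; `NULL` for all.
#' @param source_name Restrict to one source; `NULL` for all.
#' @param include_no_hit Keep the internal no-hit marker rows.
#' @return Long data.frame (`variant_id`, `source_name`, `field_name`,
#'   `value`, `source_version`).
#' @export
get_annotations <- function(store, variant_ids = NULL, source_name = NULL,
                            include_no_hit = FALSE) {
  sql <- "SELECT variant_id, source_name, field_name, value, source_version
          FROM annotations WHERE active = 1"
  params <- list()
  if (!is.null(source_name)) {
    sql <- paste(sql, "AND source_name = ?"); params <- c(params, source_name)
  }
  df <- if (length(params)) dbGetQuery(store$con, sql, params = params)
        else dbGetQuery(store$con, sql)
  if (!is.null(variant_ids)) df <- df[df$variant_id %in% variant_ids, ]
  if (!include_no_hit) df <- df[df$field_name != NO_HIT_FIELD, ]
  df[order(df$variant_id, df$source_name, df$field_name), , drop = FALSE]
}

#' Full record history for one (variant, source, field)
#' @param store A `vdb_store`.
#' @param variant_id,source_name,field_name Key of the fact.
#' @return All records, active and retired, oldest first.
#' @export
annotation_history <- function(store, variant_id, source_name, field_name) {
  dbGetQuery(store$con,
    "SELECT * FROM annotations WHERE variant_id = ? AND source_name = ?
     AND field_name = ? ORDER BY annotation_id",
    params = list(variant_id, source_name, field_name))
}

#' Change-log entries
#' @param store A `vdb_store`.
#' @param interesting_only Restrict to flagged entries.
#' @return data.frame in emission order.
#' @export
get_change_log <- function(store, interesting_only = FALSE) {
  df <- dbGetQuery(store$con, "SELECT * FROM change_log ORDER BY change_id")
  df$interesting <- df$interesting == 1L
  if (interesting_only) df <- df[df$interesting, , drop = FALSE]
  df
}

#' Exact-allele minor allele frequency lookup
#'
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param frequency_table data.frame keyed by those four columns with one
#'   column per population (e.g. `GLOBAL`, `EUR`) and optionally `rsid`.
#' @return Named list of population MAFs plus `rsid` and `known`; `NULL`
#'   when no exact allele match exists.
#' @export
lookup_frequency <- function(variant, frequency_table) {
  hit <- which(frequency_table$chrom == variant$chrom &
               frequency_table$pos == as.integer(variant$pos) &
               frequency_table$ref == variant$ref &
               frequency_table$alt == variant$alt)
  if (!length(hit)) return(NULL)
  row <- frequency_table[hit[[1]], ]
  pops <- setdiff(names(row), c("chrom", "pos", "ref", "alt", "rsid"))
  out <- lapply(row[pops], as.numeric)
  out$rsid <- if ("rsid" %in% names(row) && !is.na(row$rsid) && nzchar(row$rsid))
    row$rsid else NA_character_
  out$known <- !is.na(out$rsid)
  out
}
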