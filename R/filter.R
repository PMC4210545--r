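## Composable AND/OR filter trees over calls and annotations, plus the
## family-inheritance, cohort-occurrence, gene-burden and gene-panel filters.

BUILTIN_FIELDS <- c("chrom", "pos", "ref", "alt", "genotype", "qual", "gq",
                    "ad_ref", "ad_alt", "allelic_ratio", "qd", "mq", "fs",
                    "base_q_rank_sum", "mq_rank_sum", "read_pos_rank_sum",
                    "filter_status")

FILTER_OPS <- c("eq", "ne", "lt", "le", "gt", "ge", "contains", "in_set",
                "is_missing", "not_missing")

#' Build a filter atom
#'
#' An atom compares one field — a genotype/quality field of the call, a
#' variant coordinate field, or any annotation field (`source.field` or a
#' bare field name unique across sources) — against a value. Transcript-level
#' multi-values pass when ANY element satisfies the comparison. The
#' missing-value policy is explicit per atom: `exclude` (default) makes a
#' missing value fail the atom, `include` makes it pass.
#'
#' @param field Field name.
#' @param op One of `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `contains`,
#'   `in_set`, `is_missing`, `not_missing`.
#' @param value Comparison value (vector for `in_set`; unused for the
#'   missingness operators).
#' @param missing_policy `"exclude"` or `"include"`.
#' @return A `filter_node` of kind `atom`.
#' @export
filter_atom <- function(field, op, value = NULL, missing_policy = "exclude") {
  op <- match.arg(op, FILTER_OPS)
  missing_policy <- match.arg(missing_policy, c("exclude", "include"))
  if (op %in% c("is_missing", "not_missing") && !is.null(value))
    stop("operator '", op, "' takes no value", call. = FALSE)
  if (!op %in% c("is_missing", "not_missing") && is.null(value))
    stop("operator '", op, "' requires a value", call. = FALSE)
  structure(list(kind = "atom", field = field, op = op, value = value,
                 missing_policy = missing_policy), class = "filter_node")
}

filter_group <- function(logic, ...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "filter_node"))
    children <- children[[1]]
  structure(list(kind = "group", logic = logic, children = children),
            class = "filter_node")
}

#' Group filter nodes with AND logic (intersection)
#' @param ... Child `filter_node`s (or a single list of them).
#' @return A `filter_node` of kind `group`.
#' @export
filter_and <- function(...) filter_group("AND", ...)

#' Group filter nodes with OR logic (union)
#' @inheritParams filter_and
#' @return A `filter_node` of kind `group`.
#' @export
filter_or <- function(...) filter_group("OR", ...)

#' Bundle a filter tree into a named scheme
#' @param name Scheme name.
#' @param root Root `filter_node`.
#' @param owner Owning user id.
#' @return A `filter_scheme`.
#' @export
filter_scheme <- function(name, root, owner = NA_character_) {
  structure(list(name = name, owner = owner, root = root,
                 created_at = vdb_now()), class = "filter_scheme")
}

# fields resolvable against a store: builtins plus each registered source's
# schema, addressable bare or as source.field
known_fields <- function(store) {
  srcs <- dbGetQuery(store$con, "SELECT source_name, field_schema FROM annotation_sources")
  ann <- list()
  for (i in seq_len(nrow(srcs))) {
    sch <- jsonlite::fromJSON(srcs$field_schema[[i]])
    for (f in sch$field_name) {
      ann[[paste0(srcs$source_name[[i]], ".", f)]] <- c(srcs$source_name[[i]], f)
      ann[[f]] <- if (f %in% names(ann)) c(ann[[f]], "AMBIGUOUS") else c(srcs$source_name[[i]], f)
    }
  }
  ann
}

#' Validate a filter tree against a store
#'
#' Checks group arity (every group needs at least one child) and that every
#' atom field resolves to a builtin call/variant field or a registered
#' annotation field. Validation runs before any evaluation.
#'
#' @param store A `vdb_store`.
#' @param node Root `filter_node` or a `filter_scheme`.
#' @return Invisibly `TRUE`; errors with the offending field otherwise.
#' @export
validate_scheme <- function(store, node) {
  if (inherits(node, "filter_scheme")) node <- node$root
  fields <- known_fields(store)
  walk <- function(n) {
    if (n$kind == "group") {
      if (!length(n$children)) stop("empty filter group", call. = FALSE)
      for (ch in n$children) walk(ch)
    } else {
      if (!(n$field %in% BUILTIN_FIELDS || n$field %in% names(fields)))
        stop("unknown filter field: ", n$field, call. = FALSE)
      if (!is.null(fields[[n$field]]) && "AMBIGUOUS" %in% fields[[n$field]])
        stop("ambiguous field '", n$field, "'; qualify as source.field", call. = FALSE)
    }
  }
  walk(node)
  invisible(TRUE)
}

# values of `field` for each row of `calls` (list column: possibly several
# elements per variant for transcript-level annotations)
field_values <- function(field, calls, ann, fields_map) {
  if (field %in% BUILTIN_FIELDS)
    return(lapply(calls[[field]], function(v) if (is.na(v)) NULL else v))
  target <- fields_map[[field]]
  sub <- ann[ann$source_name == target[[1]] & ann$field_name == target[[2]], ]
  idx <- match(calls$variant_id, sub$variant_id)
  lapply(idx, function(j) {
    if (is.na(j)) return(NULL)
    vals <- mv_split(sub$value[[j]])
    vals[vals != "."]
  })
}

apply_op <- function(op, elems, value) {
  if (op == "is_missing") return(length(elems) == 0L)
  if (op == "not_missing") return(length(elems) > 0L)
  if (!length(elems)) return(NA)       # missing; resolved by missing_policy
  switch(op,
    eq = any(elems == as.character(value)),
    ne = any(elems != as.character(value)),
    lt = any(suppressWarnings(as.numeric(elems)) < as.numeric(value), na.rm = TRUE),
    le = any(suppressWarnings(as.numeric(elems)) <= as.numeric(value), na.rm = TRUE),
    gt = any(suppressWarnings(as.numeric(elems)) > as.numeric(value), na.rm = TRUE),
    ge = any(suppressWarnings(as.numeric(elems)) >= as.numeric(value), na.rm = TRUE),
    contains = any(grepl(as.character(value), elems, fixed = TRUE)),
    in_set = any(elems %in% as.character(value)))
}

#' Evaluate a filter scheme for one sample
#'
#' AND groups intersect, OR groups union, recursively and independent of
#' child order. Returns exactly the sample's variants satisfying the tree,
#' ordered by (chrom, pos).
#'
#' @param store A `vdb_store`.
#' @param scheme A `filter_scheme` or bare `filter_node`.
#' @param sample_id Sample whose calls are filtered.
#' @param build Build; default current.
#' @return data.frame of passing calls/variants ordered by (chrom, pos).
#' @export
evaluate_scheme <- function(store, scheme, sample_id, build = vdb_current_build(store)) {
  root <- if (inherits(scheme, "filter_scheme")) scheme$root else scheme
  validate_scheme(store, root)
  calls <- get_sample_calls(store, sample_id, build)
  if (!nrow(calls)) return(calls)
  ann <- get_annotations(store, calls$variant_id)
  fields_map <- known_fields(store)
  # set-based evaluation: an atom yields the set of passing variant ids,
  # groups intersect/union those sets
  eval_node <- function(n) {
    if (n$kind == "group") {
      sets <- lapply(n$children, eval_node)
      if (n$logic == "AND") Reduce(intersect, sets) else Reduce(union, sets)
    } else {
      vals <- field_values(n$field, calls, ann, fields_map)
      pass <- vapply(vals, function(e) {
        r <- apply_op(n$op, e, n$value)
        if (is.na(r)) n$missing_policy == "include" else isTRUE(r)
      }, TRUE)
      calls$variant_id[pass]
    }
  }
  ids <- eval_node(root)
  out <- calls[calls$variant_id %in% ids, , drop = FALSE]
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

## ---- inheritance filters ------------------------------------------------

get_parents <- function(store, child_id) {
  s <- dbGetQuery(store$con,
    "SELECT father_id, mother_id FROM samples WHERE sample_id = ?",
    params = list(child_id))
  if (!nrow(s)) stop("unknown sample: ", child_id, call. = FALSE)
  if (is.na(s$father_id) || is.na(s$mother_id))
    stop("family configuration error: sample '", child_id,
         "' needs both parent links for inheritance filtering", call. = FALSE)
  list(father = s$father_id, mother = s$mother_id)
}

genotype_of <- function(calls_by_sample, sample_id, variant_id) {
  df <- calls_by_sample[[sample_id]]
  g <- df$genotype[match(variant_id, df$variant_id)]
  ifelse(is.na(g), "absent", g)
}

family_calls <- function(store, sample_ids, build) {
  stats::setNames(lapply(sample_ids, function(s)
    get_sample_calls(store, s, build)), sample_ids)
}

#' De novo variants of a child
#'
#' Variants called het or hom_alt in the child while both parents are
#' hom_ref. With `require_called_parents = FALSE`, parents with an absent or
#' missing-genotype call also count as non-carriers.
#'
#' @param store A `vdb_store`.
#' @param child_id Child sample (father and mother links must be set).
#' @param require_called_parents Strict mode: both parents must have an
#'   explicit hom_ref call.
#' @param build Build; default current.
#' @return data.frame of the child's passing calls, (chrom, pos)-ordered.
#' @export
filter_de_novo <- function(store, child_id, require_called_parents = TRUE,
                           build = vdb_current_build(store)) {
  p <- get_parents(store, child_id)
  fam <- family_calls(store, c(child_id, p$father, p$mother), build)
  child <- fam[[child_id]]
  if (!nrow(child)) return(child)
  ok_parent <- function(g)
    g == "hom_ref" | (!require_called_parents & g %in% c("absent", "missing"))
  keep <- child$genotype %in% c("het", "hom_alt") &
    ok_parent(genotype_of(fam, p$father, child$variant_id)) &
    ok_parent(genotype_of(fam, p$mother, child$variant_id))
  child[keep, , drop = FALSE]
}

#' Recessive-model variants of a child
#'
#' Homozygous alternate in the child with both parents heterozygous.
#'
#' @inheritParams filter_de_novo
#' @return data.frame of the child's passing calls, (chrom, pos)-ordered.
#' @export
filter_recessive <- function(store, child_id, build = vdb_current_build(store)) {
  p <- get_parents(store, child_id)
  fam <- family_calls(store, c(child_id, p$father, p$mother), build)
  child <- fam[[child_id]]
  if (!nrow(child)) return(child)
  keep <- child$genotype == "hom_alt" &
    genotype_of(fam, p$father, child$variant_id) == "het" &
    genotype_of(fam, p$mother, child$variant_id) == "het"
  child[keep, , drop = FALSE]
}

#' Dominant-model variants co-segregating with affected status
#'
#' The family is the child, its linked parents and siblings. A variant
#' passes when every affected member carries it (het or hom_alt, strict:
#' missing calls fail) and every unaffected member is hom_ref or has no
#' call.
#'
#' @inheritParams filter_de_novo
#' @return data.frame of the child's calls passing co-segregation.
#' @export
filter_dominant <- function(store, child_id, build = vdb_current_build(store)) {
  p <- get_parents(store, child_id)
  sibs <- dbGetQuery(store$con,
    "SELECT sibling_id FROM sample_siblings WHERE sample_id = ?",
    params = list(child_id))$sibling_id
  members <- unique(c(child_id, p$father, p$mother, sibs))
  meta <- dbGetQuery(store$con, sprintf(
    "SELECT sample_id, affected FROM samples WHERE sample_id IN (%s)",
    paste(sprintf("'%s'", members), collapse = ",")))
  affected <- meta$sample_id[meta$affected == 1L]
  unaffected <- setdiff(members, affected)
  if (!length(affected))
    stop("family configuration error: no affected members defined", call. = FALSE)
  fam <- family_calls(store, members, build)
  child <- fam[[child_id]]
  if (!nrow(child)) return(child)
  keep <- rep(TRUE, nrow(child))
  for (m in affected)
    keep <- keep & genotype_of(fam, m, child$variant_id) %in% c("het", "hom_alt")
  for (m in unaffected)
    keep <- keep & genotype_of(fam, m, child$variant_id) %in% c("hom_ref", "absent")
  child[keep, , drop = FALSE]
}

## ---- occurrence / burden / panel ---------------------------------------

#' Filter variants on carrier count within a sample selection
#'
#' A carrier is a sample of `sample_set` whose genotype for the variant is
#' het or hom_alt (carrier samples are counted, not alleles). Either bound
#' may be omitted.
#'
#' @param store A `vdb_store`.
#' @param sample_set Non-empty character vector of sample ids.
#' @param min_count,max_count Inclusive bounds on the carrier count.
#' @param variant_ids Restrict to these variants; default all of the build.
#' @param build Build; default current.
#' @return data.frame (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `n_carriers`) of passing variants, (chrom, pos)-ordered.
#' @export
filter_occurrence <- function(store, sample_set, min_count = NULL, max_count = NULL,
                              variant_ids = NULL, build = vdb_current_build(store)) {
  if (!length(sample_set)) stop("sample_set must be non-empty", call. = FALSE)
  if (!is.null(min_count) && !is.null(max_count) && min_count > max_count)
    stop("min_count must not exceed max_count", call. = FALSE)
  vars <- get_variants(store, build)
  if (!is.null(variant_ids)) vars <- vars[vars$variant_id %in% variant_ids, ]
  counts <- dbGetQuery(store$con, sprintf(
    "SELECT variant_id, COUNT(DISTINCT sample_id) AS n_carriers FROM genotype_calls
     WHERE genotype IN ('het','hom_alt') AND sample_id IN (%s) GROUP BY variant_id",
    paste(sprintf("'%s'", sample_set), collapse = ",")))
  vars$n_carriers <- counts$n_carriers[match(vars$variant_id, counts$variant_id)]
  vars$n_carriers[is.na(vars$n_carriers)] <- 0L
  keep <- rep(TRUE, nrow(vars))
  if (!is.null(min_count)) keep <- keep & vars$n_carriers >= min_count
  if (!is.null(max_count)) keep <- keep & vars$n_carriers <= max_count
  vars[keep, , drop = FALSE]
}

#' Gene mutation-burden filter
#'
#' A gene passes when the number of DISTINCT samples of `sample_set`
#' carrying at least one variant annotated to it lies within the bounds; a
#' sample with several qualifying variants in a gene counts once.
#'
#' @param store A `vdb_store`.
#' @param sample_set Character vector of sample ids.
#' @param source_name Annotation source carrying the gene field.
#' @param gene_field Field holding the (possibly multi-valued) gene symbol.
#' @param min_samples,max_samples Inclusive carrier-sample bounds.
#' @param build Build; default current.
#' @return List with `genes` (data.frame `gene`, `n_samples`) and
#'   `variants` (named list of contributing variant-id vectors per gene).
#' @export
filter_burden <- function(store, sample_set, source_name, gene_field = "gene_symbol",
                          min_samples = NULL, max_samples = NULL,
                          build = vdb_current_build(store)) {
  ann <- get_annotations(store, source_name = source_name)
  ann <- ann[ann$field_name == gene_field, ]
  carriers <- dbGetQuery(store$con, sprintf(
    "SELECT c.variant_id, c.sample_id FROM genotype_calls c
     JOIN variants v ON v.variant_id = c.variant_id
     WHERE v.build = '%s' AND c.genotype IN ('het','hom_alt') AND c.sample_id IN (%s)",
    build, paste(sprintf("'%s'", sample_set), collapse = ",")))
  # variant -> genes (multi-transcript values expand to several genes)
  v2g <- lapply(stats::setNames(ann$value, ann$variant_id),
                function(v) unique(mv_split(v)))
  gene_samples <- list(); gene_variants <- list()
  for (i in seq_len(nrow(carriers))) {
    genes <- v2g[[as.character(carriers$variant_id[[i]])]]
    for (g in genes) {
      if (is.na(g) || g == ".") next
      gene_samples[[g]] <- union(gene_samples[[g]], carriers$sample_id[[i]])
      gene_variants[[g]] <- union(gene_variants[[g]], carriers$variant_id[[i]])
    }
  }
  n <- vapply(gene_samples, length, 0L)
  keep <- rep(TRUE, length(n))
  if (!is.null(min_samples)) keep <- keep & n >= min_samples
  if (!is.null(max_samples)) keep <- keep & n <= max_samples
  genes <- names(gene_samples)[keep]
  list(genes = data.frame(gene = genes, n_samples = unname(n[keep]),
                          stringsAsFactors = FALSE),
       variants = gene_variants[genes])
}

strip_tx_version <- function(x) sub("\\.\\d+$", "", x)

#' Restrict variants to an in-silico gene panel
#'
#' The panel is a set of transcript identifiers (version suffixes ignored).
#' A variant passes when at least one of its transcript annotations matches
#' the panel by transcript id, or by gene symbol resolved through the gene
#' model.
#'
#' @param store A `vdb_store`.
#' @param variant_ids Candidate variant ids.
#' @param panel Non-empty character vector of transcript ids.
#' @param source_name Gene-annotation source to read transcript ids from.
#' @param gene_models Optional `gene_models` used to resolve panel entries
#'   to gene symbols.
#' @return Integer vector of passing variant ids.
#' @export
filter_panel <- function(store, variant_ids, panel, source_name,
                         gene_models = NULL) {
  if (!length(panel)) stop("empty gene panel", call. = FALSE)
  core <- strip_tx_version(panel)
  panel_genes <- character(0)
  if (!is.null(gene_models))
    panel_genes <- gene_models$gene_symbol[
      strip_tx_version(gene_models$transcript_id) %in% core]
  ann <- get_annotations(store, variant_ids, source_name)
  tx <- ann[ann$field_name == "transcript_id", ]
  gs <- ann[ann$field_name == "gene_symbol", ]
  pass <- vapply(variant_ids, function(vid) {
    t_el <- strip_tx_version(mv_split(tx$value[match(vid, tx$variant_id)]))
    g_el <- mv_split(gs$value[match(vid, gs$variant_id)])
    any(t_el %in% core, na.rm = TRUE) || any(g_el %in% panel_genes, na.rm = TRUE)
  }, TRUE)
  variant_ids[pass]
}

## ---- scheme persistence -------------------------------------------------

SCHEME_SCHEMA_VERSION <- 1L

node_to_list <- function(n) {
  if (n$kind == "group")
    list(kind = "group", logic = n$logic, children = lapply(n$children, node_to_list))
  else
    list(kind = "atom", field = n$field, op = n$op, value = n$value,
         missing_policy = n$missing_policy)
}

node_from_list <- function(x) {
  if (x$kind == "group") {
    structure(list(kind = "group", logic = x$logic,
                   children = lapply(x$children, node_from_list)),
              class = "filter_node")
  } else {
    value <- x$value
    if (!is.null(value)) value <- unlist(value)
    structure(list(kind = "atom", field = x$field, op = x$op, value = value,
                   missing_policy = x$missing_policy), class = "filter_node")
  }
}

#' Serialize a filter scheme to JSON
#' @param scheme A `filter_scheme`.
#' @return JSON string (schema-versioned).
#' @export
scheme_to_json <- function(scheme) {
  jsonlite::toJSON(list(schema_version = SCHEME_SCHEMA_VERSION,
                        name = scheme$name, owner = scheme$owner,
                        created_at = scheme$created_at,
                        root = node_to_list(scheme$root)),
                   auto_unbox = TRUE, null = "null")
}

#' Rebuild a filter scheme from its JSON form
#' @param json JSON string from [scheme_to_json()].
#' @return A `filter_scheme` evaluating identically to the serialized one.
#' @export
scheme_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(x$schema_version) || x$schema_version > SCHEME_SCHEMA_VERSION)
    stop("unsupported scheme schema version", call. = FALSE)
  structure(list(name = x$name, owner = if (is.null(x$owner)) NA_character_ else x$owner,
                 root = node_from_list(x$root), created_at = x$created_at),
            class = "filter_scheme")
}

#' Save a filter scheme in the store
#' @param store A `vdb_store`.
#' @param scheme A `filter_scheme` (structure is validated; fields are
#'   late-bound and only checked at evaluation time).
#' @param overwrite Replace an existing scheme of the same name.
#' @export
save_scheme <- function(store, scheme, overwrite = FALSE) {
  exists <- nrow(dbGetQuery(store$con, "SELECT 1 FROM filter_schemes WHERE name = ?",
                            params = list(scheme$name))) > 0L
  if (exists && !overwrite)
    vdb_conflict("scheme '", scheme$name, "' already exists; pass overwrite = TRUE")
  walk <- function(n) {    # structural validation only (groups non-empty)
    if (n$kind == "group") {
      if (!length(n$children)) stop("empty filter group", call. = FALSE)
      lapply(n$children, walk)
    }
    invisible(NULL)
  }
  walk(scheme$root)
  if (exists)
    dbExecute(store$con, "DELETE FROM filter_schemes WHERE name = ?",
              params = list(scheme$name))
  dbExecute(store$con, "INSERT INTO filter_schemes VALUES (?,?,?,?)",
            params = list(scheme$name, scheme$owner,
                          as.character(scheme_to_json(scheme)), scheme$created_at))
  invisible(NULL)
}

#' Load a saved filter scheme by name
#' @param store A `vdb_store`.
#' @param name Scheme name.
#' @return The `filter_scheme`.
#' @export
load_scheme <- function(store, name) {
  row <- dbGetQuery(store$con, "SELECT tree_json FROM filter_schemes WHERE name = ?",
                    params = list(name))
  if (!nrow(row)) stop("no saved scheme named '", name, "'", call. = FALSE)
  scheme_from_json(row$tree_json[[1]])
}

## ---- gene panels --------------------------------------------------------

#' Create an in-silico gene panel
#'
#' A panel is a named set of RefSeq transcript identifiers owned by a user,
#' private by default, optionally shared as a public resource.
#'
#' @param store A `vdb_store`.
#' @param panel_name Panel name (unique per owner).
#' @param owner Owning user id.
#' @param transcript_ids Non-empty character vector of transcript ids.
#' @param comments Optional per-transcript comments (recycled).
#' @param public Share with all users.
#' @export
create_panel <- function(store, panel_name, owner, transcript_ids,
                         comments = NA_character_, public = FALSE) {
  if (!length(transcript_ids)) stop("empty gene panel", call. = FALSE)
  exists <- nrow(dbGetQuery(store$con,
    "SELECT 1 FROM gene_panels WHERE panel_name = ? AND owner = ? LIMIT 1",
    params = list(panel_name, owner))) > 0L
  if (exists) vdb_conflict("panel '", panel_name, "' already exists for ", owner)
  comments <- rep_len(comments, length(transcript_ids))
  for (i in seq_along(transcript_ids))
    dbExecute(store$con, "INSERT INTO gene_panels VALUES (?,?,?,?,?)",
              params = list(panel_name, owner, transcript_ids[[i]],
                            if (is.na(comments[[i]])) NA_character_ else comments[[i]],
                            as.integer(public)))
  invisible(NULL)
}

#' Panels visible to a user (their own plus public ones)
#' @param store A `vdb_store`.
#' @param user_id Requesting user; `NULL` lists everything.
#' @return data.frame of panel rows.
#' @export
list_panels <- function(store, user_id = NULL) {
  df <- dbGetQuery(store$con, "SELECT * FROM gene_panels ORDER BY panel_name, transcript_id")
  if (!is.null(user_id)) df <- df[df$owner == user_id | df$public == 1L, , drop = FALSE]
  df$public <- df$public == 1L
  df
}

#' Make a panel public
#' @param store A `vdb_store`.
#' @param panel_name,owner Panel key.
#' @export
share_panel <- function(store, panel_name, owner) {
  n <- dbExecute(store$con,
    "UPDATE gene_panels SET public = 1 WHERE panel_name = ? AND owner = ?",
    params = list(panel_name, owner))
  if (!n) stop("no panel '", panel_name, "' owned by ", owner, call. = FALSE)
  invisible(NULL)
}

#' Transcript ids of a visible panel
#' @param store A `vdb_store`.
#' @param panel_name Panel name.
#' @param user_id Requesting user (must own the panel or it must be public).
#' @return Character vector of transcript ids.
#' @export
get_panel <- function(store, panel_name, user_id) {
  df <- list_panels(store, user_id)
  df$transcript_id[df$panel_name == panel_name]
}
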