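#' @importFrom DBI dbExecute dbGetQuery dbBegin dbCommit dbRollback
NULL

SCHEMA_VERSION <- 1L

# conflict errors (exit code 2 at the CLI) vs plain validation errors (1)
vdb_conflict <- function(...) {
  stop(errorCondition(paste0(...), class = c("vdb_conflict", "error")))
}

ROLE_ORDER <- c(read_only = 1L, edit = 2L, admin = 3L)
GENOTYPES <- c("hom_ref", "het", "hom_alt", "missing")

#' Open (or create) a variant store
#'
#' The store is a single-file SQLite database holding samples, variants, the
#' sample-variant link table with the GATK quality vector, annotation sources
#' and records, change log, filter schemes, projects and role grants. Schema
#' upgrades are tracked in an explicit migration table.
#'
#' @param path Database file path, or `":memory:"` for a transient store.
#' @param build Genome build label used to initialise a fresh store
#'   (default `"hg19"`). Ignored when the store already exists.
#' @return A `vdb_store` connection object.
#' @export
vdb_connect <- function(path = ":memory:", build = "hg19") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  store <- structure(list(con = con, path = path), class = "vdb_store")
  applied <- tryCatch(
    dbGetQuery(con, "SELECT version FROM schema_migrations")$version,
    error = function(e) integer(0))
  if (!length(applied)) vdb_init_schema(store, build)
  store
}

#' @export
print.vdb_store <- function(x, ...) {
  n <- dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM variants")$n
  cat(sprintf("<vdb_store> %s | build %s | %d variants\n",
              x$path, vdb_current_build(x), n))
  invisible(x)
}

#' Close a variant store
#' @param store A `vdb_store`.
#' @export
vdb_disconnect <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

vdb_init_schema <- function(store, build) {
  con <- store$con
  stmts <- c(
    "CREATE TABLE schema_migrations (version INTEGER PRIMARY KEY, applied_at TEXT NOT NULL)",
    "CREATE TABLE builds (build TEXT PRIMARY KEY, is_current INTEGER NOT NULL DEFAULT 0,
       read_only INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE projects (project_id INTEGER PRIMARY KEY, name TEXT UNIQUE NOT NULL)",
    "CREATE TABLE role_grants (project_id INTEGER NOT NULL REFERENCES projects(project_id),
       user_id TEXT NOT NULL, role TEXT NOT NULL CHECK (role IN ('read_only','edit','admin')),
       PRIMARY KEY (project_id, user_id))",
    "CREATE TABLE samples (sample_id TEXT PRIMARY KEY, display_name TEXT,
       gender TEXT NOT NULL DEFAULT 'unknown' CHECK (gender IN ('male','female','unknown')),
       is_control INTEGER NOT NULL DEFAULT 0, affected INTEGER NOT NULL DEFAULT 0,
       father_id TEXT REFERENCES samples(sample_id),
       mother_id TEXT REFERENCES samples(sample_id),
       project_id INTEGER NOT NULL REFERENCES projects(project_id),
       bam_path TEXT)",
    "CREATE TABLE sample_hpo (sample_id TEXT NOT NULL REFERENCES samples(sample_id),
       hpo_term TEXT NOT NULL, PRIMARY KEY (sample_id, hpo_term))",
    "CREATE TABLE sample_siblings (sample_id TEXT NOT NULL REFERENCES samples(sample_id),
       sibling_id TEXT NOT NULL REFERENCES samples(sample_id),
       PRIMARY KEY (sample_id, sibling_id))",
    "CREATE TABLE variants (variant_id INTEGER PRIMARY KEY,
       build TEXT NOT NULL REFERENCES builds(build),
       chrom TEXT NOT NULL, pos INTEGER NOT NULL, ref TEXT NOT NULL, alt TEXT NOT NULL,
       UNIQUE (build, chrom, pos, ref, alt))",
    "CREATE TABLE genotype_calls (sample_id TEXT NOT NULL REFERENCES samples(sample_id),
       variant_id INTEGER NOT NULL REFERENCES variants(variant_id),
       genotype TEXT NOT NULL CHECK (genotype IN ('hom_ref','het','hom_alt','missing')),
       qual REAL, gq REAL, ad_ref INTEGER, ad_alt INTEGER, qd REAL, mq REAL, fs REAL,
       base_q_rank_sum REAL, mq_rank_sum REAL, read_pos_rank_sum REAL, filter_status TEXT,
       PRIMARY KEY (sample_id, variant_id))",
    "CREATE TABLE annotation_sources (source_name TEXT PRIMARY KEY,
       version_label TEXT NOT NULL, registered_at TEXT NOT NULL, field_schema TEXT NOT NULL)",
    "CREATE TABLE source_versions (source_name TEXT NOT NULL, version_label TEXT NOT NULL,
       registered_at TEXT NOT NULL, PRIMARY KEY (source_name, version_label))",
    "CREATE TABLE annotations (annotation_id INTEGER PRIMARY KEY,
       variant_id INTEGER NOT NULL REFERENCES variants(variant_id),
       source_name TEXT NOT NULL, field_name TEXT NOT NULL, value TEXT,
       source_version TEXT NOT NULL, active INTEGER NOT NULL DEFAULT 1,
       created_at TEXT NOT NULL, retired_at TEXT)",
    "CREATE INDEX idx_ann_lookup ON annotations (variant_id, source_name, field_name, active)",
    "CREATE UNIQUE INDEX idx_ann_one_active ON annotations (variant_id, source_name, field_name)
       WHERE active = 1",
    "CREATE TABLE change_log (change_id INTEGER PRIMARY KEY,
       variant_id INTEGER NOT NULL, source_name TEXT NOT NULL, field_name TEXT NOT NULL,
       old_value TEXT, new_value TEXT, old_version TEXT, new_version TEXT,
       timestamp TEXT NOT NULL, interesting INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE user_classifications (variant_id INTEGER NOT NULL,
       sample_id TEXT NOT NULL, inheritance_note TEXT, validation_status TEXT,
       diagnostic_class TEXT, free_text TEXT, PRIMARY KEY (variant_id, sample_id))",
    "CREATE TABLE filter_schemes (name TEXT PRIMARY KEY, owner TEXT,
       tree_json TEXT NOT NULL, created_at TEXT NOT NULL)",
    "CREATE TABLE gene_panels (panel_name TEXT NOT NULL, owner TEXT NOT NULL,
       transcript_id TEXT NOT NULL, comment TEXT, public INTEGER NOT NULL DEFAULT 0,
       PRIMARY KEY (panel_name, owner, transcript_id))",
    "CREATE TABLE liftover_failures (variant_id INTEGER NOT NULL, target_build TEXT NOT NULL,
       reason TEXT NOT NULL, resolved TEXT NOT NULL DEFAULT 'pending')",
    "CREATE TABLE audit_log (entry_id INTEGER PRIMARY KEY, timestamp TEXT NOT NULL,
       command TEXT NOT NULL, arguments TEXT)"
  )
  for (s in stmts) dbExecute(con, s)
  dbExecute(con, "INSERT INTO schema_migrations (version, applied_at) VALUES (?, ?)",
            params = list(SCHEMA_VERSION, vdb_now()))
  dbExecute(con, "INSERT INTO builds (build, is_current) VALUES (?, 1)", params = list(build))
  invisible(store)
}

vdb_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")

#' Current genome build of a store
#' @param store A `vdb_store`.
#' @return Build label, e.g. `"hg19"`.
#' @export
vdb_current_build <- function(store) {
  dbGetQuery(store$con, "SELECT build FROM builds WHERE is_current = 1")$build
}

vdb_build_read_only <- function(store, build) {
  row <- dbGetQuery(store$con, "SELECT read_only FROM builds WHERE build = ?",
                    params = list(build))
  if (!nrow(row)) stop("unknown build: ", build, call. = FALSE)
  row$read_only == 1L
}

assert_writable_build <- function(store, build) {
  if (vdb_build_read_only(store, build))
    vdb_conflict("build '", build, "' is retired and read-only")
  invisible(TRUE)
}

## ---- projects, roles, samples ------------------------------------------

#' Create a project
#' @param store A `vdb_store`.
#' @param name Project name (unique).
#' @return Integer project id.
#' @export
add_project <- function(store, name) {
  dbExecute(store$con, "INSERT INTO projects (name) VALUES (?)", params = list(name))
  dbGetQuery(store$con, "SELECT project_id FROM projects WHERE name = ?",
             params = list(name))$project_id
}

#' Grant a role on a project
#'
#' Roles are ordered `read_only < edit < admin`; a higher role implies all
#' lower ones.
#'
#' @param store A `vdb_store`.
#' @param project_id Project id.
#' @param user_id Plain string user identifier.
#' @param role One of `"read_only"`, `"edit"`, `"admin"`.
#' @export
grant_role <- function(store, project_id, user_id, role) {
  role <- match.arg(role, names(ROLE_ORDER))
  dbExecute(store$con,
    "INSERT INTO role_grants (project_id, user_id, role) VALUES (?, ?, ?)
     ON CONFLICT (project_id, user_id) DO UPDATE SET role = excluded.role",
    params = list(project_id, user_id, role))
  invisible(NULL)
}

#' Check whether a user holds at least a given role on a project
#' @inheritParams grant_role
#' @param required_role Minimum role required.
#' @return `TRUE` iff the user's granted role is >= `required_role`.
#' @export
check_permission <- function(store, user_id, project_id, required_role = "read_only") {
  required_role <- match.arg(required_role, names(ROLE_ORDER))
  if (!nrow(dbGetQuery(store$con, "SELECT 1 FROM projects WHERE project_id = ?",
                       params = list(project_id))))
    stop("unknown project: ", project_id, call. = FALSE)
  held <- dbGetQuery(store$con,
    "SELECT role FROM role_grants WHERE project_id = ? AND user_id = ?",
    params = list(project_id, user_id))$role
  length(held) == 1L && ROLE_ORDER[[held]] >= ROLE_ORDER[[required_role]]
}

#' Register a sample
#' @param store A `vdb_store`.
#' @param sample_id Sample identifier (unique across the store).
#' @param project_id Owning project (every sample belongs to exactly one).
#' @param display_name Optional human-readable name.
#' @param gender `"male"`, `"female"` or `"unknown"`.
#' @param is_control Control-cohort flag used by occurrence filtering.
#' @param affected Affected-status flag used by the dominant model.
#' @param hpo_terms Character vector of HPO identifiers.
#' @export
add_sample <- function(store, sample_id, project_id, display_name = sample_id,
                       gender = "unknown", is_control = FALSE, affected = FALSE,
                       hpo_terms = character(0)) {
  gender <- match.arg(gender, c("male", "female", "unknown"))
  dbExecute(store$con,
    "INSERT INTO samples (sample_id, display_name, gender, is_control, affected, project_id)
     VALUES (?, ?, ?, ?, ?, ?)",
    params = list(sample_id, display_name, gender, as.integer(is_control),
                  as.integer(affected), project_id))
  for (term in hpo_terms)
    dbExecute(store$con, "INSERT OR IGNORE INTO sample_hpo VALUES (?, ?)",
              params = list(sample_id, term))
  invisible(sample_id)
}

#' Set family relations for a sample
#'
#' Parent links must reference existing samples and may not create an
#' ancestry cycle. Sibling links are stored symmetrically.
#'
#' @param store A `vdb_store`.
#' @param sample_id The child/proband sample.
#' @param father_id,mother_id Optional parental sample ids.
#' @param sibling_ids Character vector of sibling sample ids.
#' @export
set_family <- function(store, sample_id, father_id = NULL, mother_id = NULL,
                       sibling_ids = character(0)) {
  for (p in c(father_id, mother_id)) {
    if (!sample_exists(store, p)) stop("unknown parent sample: ", p, call. = FALSE)
    if (is_ancestor(store, sample_id, p))
      stop("parent link would create an ancestry cycle: ", p, call. = FALSE)
  }
  if (!is.null(father_id))
    dbExecute(store$con, "UPDATE samples SET father_id = ? WHERE sample_id = ?",
              params = list(father_id, sample_id))
  if (!is.null(mother_id))
    dbExecute(store$con, "UPDATE samples SET mother_id = ? WHERE sample_id = ?",
              params = list(mother_id, sample_id))
  for (sib in sibling_ids) {
    if (!sample_exists(store, sib)) stop("unknown sibling sample: ", sib, call. = FALSE)
    dbExecute(store$con, "INSERT OR IGNORE INTO sample_siblings VALUES (?, ?)",
              params = list(sample_id, sib))
    dbExecute(store$con, "INSERT OR IGNORE INTO sample_siblings VALUES (?, ?)",
              params = list(sib, sample_id))
  }
  invisible(NULL)
}

sample_exists <- function(store, sample_id) {
  nrow(dbGetQuery(store$con, "SELECT 1 FROM samples WHERE sample_id = ?",
                  params = list(sample_id))) > 0L
}

# TRUE if `candidate` is sample_id itself or one of its descendants, i.e.
# linking candidate as a parent of sample_id would close a cycle.
is_ancestor <- function(store, sample_id, candidate) {
  if (identical(sample_id, candidate)) return(TRUE)
  frontier <- candidate
  seen <- character(0)
  while (length(frontier)) {
    cur <- frontier[[1]]; frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    parents <- dbGetQuery(store$con,
      "SELECT father_id, mother_id FROM samples WHERE sample_id = ?", params = list(cur))
    ps <- stats::na.omit(unlist(parents))
    if (sample_id %in% ps) return(TRUE)
    frontier <- c(frontier, ps)
  }
  FALSE
}

#' Retrieve sample metadata
#' @param store A `vdb_store`.
#' @param sample_id Sample identifier.
#' @return A one-row data.frame plus `hpo_terms` / `sibling_ids` attributes
#'   folded in as list columns.
#' @export
get_sample <- function(store, sample_id) {
  s <- dbGetQuery(store$con, "SELECT * FROM samples WHERE sample_id = ?",
                  params = list(sample_id))
  if (!nrow(s)) stop("unknown sample: ", sample_id, call. = FALSE)
  s$is_control <- s$is_control == 1L
  s$affected <- s$affected == 1L
  s$hpo_terms <- list(dbGetQuery(store$con,
    "SELECT hpo_term FROM sample_hpo WHERE sample_id = ? ORDER BY hpo_term",
    params = list(sample_id))$hpo_term)
  s$sibling_ids <- list(dbGetQuery(store$con,
    "SELECT sibling_id FROM sample_siblings WHERE sample_id = ? ORDER BY sibling_id",
    params = list(sample_id))$sibling_id)
  s
}

## ---- variants & calls ---------------------------------------------------

assert_valid_alleles <- function(ref, alt) {
  ok <- function(x) grepl("^[ACGT]+$", x)
  if (!ok(ref) || !ok(alt))
    stop("alleles must be non-empty uppercase A/C/G/T sequences: ",
         ref, ">", alt, call. = FALSE)
  if (identical(ref, alt)) stop("ref and alt must differ", call. = FALSE)
  invisible(TRUE)
}

#' Insert a variant if absent, returning its id
#'
#' The identity key of the whole store is the normalized
#' (build, chrom, pos, ref, alt) 5-tuple; re-inserting an existing tuple
#' returns the existing id (idempotent).
#'
#' @param store A `vdb_store`.
#' @param build Genome build label (must match a registered, writable build).
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first changed base.
#' @param ref,alt Normalized allele strings (uppercase A/C/G/T).
#' @return Integer variant id.
#' @export
upsert_variant <- function(store, build, chrom, pos, ref, alt) {
  assert_valid_alleles(ref, alt)
  assert_writable_build(store, build)
  dbExecute(store$con,
    "INSERT OR IGNORE INTO variants (build, chrom, pos, ref, alt) VALUES (?, ?, ?, ?, ?)",
    params = list(build, chrom, as.integer(pos), ref, alt))
  dbGetQuery(store$con,
    "SELECT variant_id FROM variants WHERE build=? AND chrom=? AND pos=? AND ref=? AND alt=?",
    params = list(build, chrom, as.integer(pos), ref, alt))$variant_id
}

#' Store a genotype call linking a sample to a variant
#'
#' One call per (sample, variant); storing a second call for the same pair
#' without `overwrite = TRUE` is a conflict error. Absent quality values are
#' stored as nulls, never as sentinel numbers.
#'
#' @param store A `vdb_store`.
#' @param sample_id,variant_id The linked pair.
#' @param genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param qual,gq,ad_ref,ad_alt,qd,mq,fs Quality fields (GATK vector); `NA`
#'   for absent.
#' @param base_q_rank_sum,mq_rank_sum,read_pos_rank_sum Rank-sum statistics.
#' @param filter_status VCF FILTER string stored verbatim (e.g. a VQSR
#'   tranche label).
#' @param overwrite Replace an existing call for the pair.
#' @export
store_call <- function(store, sample_id, variant_id, genotype,
                       qual = NA, gq = NA, ad_ref = NA, ad_alt = NA,
                       qd = NA, mq = NA, fs = NA,
                       base_q_rank_sum = NA, mq_rank_sum = NA, read_pos_rank_sum = NA,
                       filter_status = NA, overwrite = FALSE) {
  genotype <- match.arg(genotype, GENOTYPES)
  exists <- nrow(dbGetQuery(store$con,
    "SELECT 1 FROM genotype_calls WHERE sample_id = ? AND variant_id = ?",
    params = list(sample_id, variant_id))) > 0L
  if (exists && !overwrite)
    vdb_conflict("call already stored for (", sample_id, ", ", variant_id,
                 "); pass overwrite = TRUE to replace")
  if (exists)
    dbExecute(store$con, "DELETE FROM genotype_calls WHERE sample_id = ? AND variant_id = ?",
              params = list(sample_id, variant_id))
  num <- function(x) if (is.na(x)) NA_real_ else as.numeric(x)
  int <- function(x) if (is.na(x)) NA_integer_ else as.integer(x)
  dbExecute(store$con,
    "INSERT INTO genotype_calls VALUES (?,?,?,?,?,?,?,?,?,?,?,?,?,?)",
    params = list(sample_id, variant_id, genotype, num(qual), num(gq),
                  int(ad_ref), int(ad_alt), num(qd), num(mq), num(fs),
                  num(base_q_rank_sum), num(mq_rank_sum), num(read_pos_rank_sum),
                  if (is.na(filter_status)) NA_character_ else as.character(filter_status)))
  invisible(NULL)
}

#' Retrieve a genotype call
#'
#' `allelic_ratio` is derived as `ad_alt / (ad_ref + ad_alt)` and is `NA`
#' whenever the allelic depths are absent or sum to zero.
#'
#' @param store A `vdb_store`.
#' @param sample_id,variant_id The linked pair.
#' @return One-row data.frame, or zero rows when no call is stored.
#' @export
get_call <- function(store, sample_id, variant_id) {
  df <- dbGetQuery(store$con,
    "SELECT * FROM genotype_calls WHERE sample_id = ? AND variant_id = ?",
    params = list(sample_id, variant_id))
  if (nrow(df)) df$allelic_ratio <- allelic_ratio(df$ad_ref, df$ad_alt)
  df
}

allelic_ratio <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(is.na(tot) | tot == 0L, NA_real_, ad_alt / tot)
}

#' Variants stored for a build
#' @param store A `vdb_store`.
#' @param build Build label; default the store's current build.
#' @return data.frame ordered by (chrom, pos).
#' @export
get_variants <- function(store, build = vdb_current_build(store)) {
  dbGetQuery(store$con,
    "SELECT variant_id, build, chrom, pos, ref, alt FROM variants
     WHERE build = ? ORDER BY chrom, pos, ref, alt", params = list(build))
}

#' Calls of one sample joined to their variants
#' @param store A `vdb_store`.
#' @param sample_id Sample identifier.
#' @param build Build label; default current.
#' @return data.frame ordered by (chrom, pos), with `allelic_ratio` derived.
#' @export
get_sample_calls <- function(store, sample_id, build = vdb_current_build(store)) {
  df <- dbGetQuery(store$con,
    "SELECT v.variant_id, v.chrom, v.pos, v.ref, v.alt, c.*
     FROM genotype_calls c JOIN variants v ON v.variant_id = c.variant_id
     WHERE c.sample_id = ? AND v.build = ? ORDER BY v.chrom, v.pos, v.ref, v.alt",
    params = list(sample_id, build))
  df <- df[, !duplicated(names(df))]
  df$allelic_ratio <- allelic_ratio(df$ad_ref, df$ad_alt)
  df
}

## ---- user classification & project deletion -----------------------------

#' Record a user classification of a variant in a sample
#'
#' Requires the `edit` role on the sample's project.
#'
#' @param store A `vdb_store`.
#' @param user_id Acting user (checked against the project's role grants).
#' @param variant_id,sample_id Target pair.
#' @param inheritance_note,validation_status,diagnostic_class,free_text
#'   Free-form classification fields.
#' @export
classify_variant <- function(store, user_id, variant_id, sample_id,
                             inheritance_note = NA, validation_status = NA,
                             diagnostic_class = NA, free_text = NA) {
  proj <- dbGetQuery(store$con, "SELECT project_id FROM samples WHERE sample_id = ?",
                     params = list(sample_id))$project_id
  if (!length(proj)) stop("unknown sample: ", sample_id, call. = FALSE)
  if (!check_permission(store, user_id, proj, "edit"))
    stop("user '", user_id, "' lacks edit role on project ", proj, call. = FALSE)
  chr <- function(x) if (is.na(x)) NA_character_ else as.character(x)
  dbExecute(store$con,
    "INSERT INTO user_classifications VALUES (?,?,?,?,?,?)
     ON CONFLICT (variant_id, sample_id) DO UPDATE SET
       inheritance_note=excluded.inheritance_note,
       validation_status=excluded.validation_status,
       diagnostic_class=excluded.diagnostic_class, free_text=excluded.free_text",
    params = list(variant_id, sample_id, chr(inheritance_note), chr(validation_status),
                  chr(diagnostic_class), chr(free_text)))
  invisible(NULL)
}

#' Delete a project and its dependent rows
#'
#' Refuses to orphan: with `cascade = FALSE` (default) deletion fails while
#' samples remain; with `cascade = TRUE` samples, their calls, HPO terms,
#' sibling links and classifications are removed first. Requires `admin`.
#'
#' @param store A `vdb_store`.
#' @param user_id Acting user.
#' @param project_id Project to delete.
#' @param cascade Remove dependent samples and calls.
#' @export
delete_project <- function(store, user_id, project_id, cascade = FALSE) {
  if (!check_permission(store, user_id, project_id, "admin"))
    stop("user '", user_id, "' lacks admin role on project ", project_id, call. = FALSE)
  samples <- dbGetQuery(store$con, "SELECT sample_id FROM samples WHERE project_id = ?",
                        params = list(project_id))$sample_id
  if (length(samples) && !cascade)
    stop("project ", project_id, " still owns ", length(samples),
         " sample(s); use cascade = TRUE", call. = FALSE)
  con <- store$con
  dbBegin(con)
  on.exit(tryCatch(dbRollback(con), error = function(e) NULL))
  for (s in samples) {
    dbExecute(con, "DELETE FROM user_classifications WHERE sample_id = ?", params = list(s))
    dbExecute(con, "DELETE FROM genotype_calls WHERE sample_id = ?", params = list(s))
    dbExecute(con, "DELETE FROM sample_hpo WHERE sample_id = ?", params = list(s))
    dbExecute(con, "DELETE FROM sample_siblings WHERE sample_id = ? OR sibling_id = ?",
              params = list(s, s))
    dbExecute(con, "UPDATE samples SET father_id = NULL WHERE father_id = ?", params = list(s))
    dbExecute(con, "UPDATE samples SET mother_id = NULL WHERE mother_id = ?", params = list(s))
  }
  if (length(samples))
    dbExecute(con, sprintf("DELETE FROM samples WHERE project_id = %d", as.integer(project_id)))
  dbExecute(con, "DELETE FROM role_grants WHERE project_id = ?", params = list(project_id))
  dbExecute(con, "DELETE FROM projects WHERE project_id = ?", params = list(project_id))
  dbCommit(con)
  on.exit(NULL)
  invisible(NULL)
}

#' Load sample metadata from a PED-like file
#'
#' Tab-delimited columns: family_id, sample_id, father_id, mother_id, sex
#' (1 = male, 2 = female, other = unknown), phenotype (2 = affected).
#' `0` or `.` mean "not set" for parent columns. An optional sidecar
#' (sample_id, hpo_terms `;`-separated, is_control 0/1) adds phenotype terms
#' and control flags.
#'
#' @param store A `vdb_store`.
#' @param ped_path Path to the PED file.
#' @param project_id Project receiving the samples.
#' @param sidecar_path Optional path to the HPO/control sidecar.
#' @return Character vector of imported sample ids.
#' @export
load_pedigree <- function(store, ped_path, project_id, sidecar_path = NULL) {
  ped <- utils::read.table(ped_path, sep = "\t", header = FALSE,
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"),
                           colClasses = "character")
  unset <- function(x) x %in% c("0", ".", "")
  side <- NULL
  if (!is.null(sidecar_path)) {
    side <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                              colClasses = "character")
    rownames(side) <- side$sample_id
  }
  for (i in seq_len(nrow(ped))) {
    r <- ped[i, ]
    gender <- switch(r$sex, "1" = "male", "2" = "female", "unknown")
    hpo <- character(0); ctrl <- FALSE
    if (!is.null(side) && r$sample_id %in% rownames(side)) {
      sr <- side[r$sample_id, ]
      if (nzchar(sr$hpo_terms)) hpo <- strsplit(sr$hpo_terms, ";", fixed = TRUE)[[1]]
      ctrl <- sr$is_control == "1"
    }
    add_sample(store, r$sample_id, project_id, gender = gender,
               is_control = ctrl, affected = r$phenotype == "2", hpo_terms = hpo)
  }
  for (i in seq_len(nrow(ped))) {
    r <- ped[i, ]
    fa <- if (unset(r$father_id)) NULL else r$father_id
    mo <- if (unset(r$mother_id)) NULL else r$mother_id
    sibs <- ped$sample_id[ped$family_id == r$family_id &
                            ped$sample_id != r$sample_id &
                            !unset(ped$father_id) & !unset(ped$mother_id) &
                            ped$father_id == r$father_id & ped$mother_id == r$mother_id]
    if (unset(r$father_id)) sibs <- character(0)
    set_family(store, r$sample_id, fa, mo, sibs)
  }
  ped$sample_id
}
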