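# store with 10 variants and a 6-variant lookup table source
ann_fixture <- function(env = parent.frame()) {
  st <- local_store(env = env)
  pid <- add_project(st, "p")
  add_sample(st, "S1", pid)
  for (i in 1:10) {
    vid <- upsert_variant(st, "hg19", "chrT", 100 * i, "A", "G")
    store_call(st, "S1", vid, "het")
  }
  vars <- get_variants(st)
  tabs <- generate_annotation_tables(11, vars)
  list(store = st, vars = vars, tabs = tabs)
}

test_that("annotate_missing only queries unannotated variants and is idempotent", {
  fx <- ann_fixture()
  seen <- NULL
  src <- annotation_source("probe", "v1",
    data.frame(field_name = "score", value_kind = "number"),
    provider = function(v) {
      seen <<- c(seen, v$variant_id)
      data.frame(variant_id = v$variant_id[1:3], field_name = "score",
                 value = as.character(1:3))
    })
  register_source(fx$store, src)
  n1 <- annotate_missing(fx$store, src)
  expect_equal(n1, 10L)
  expect_length(seen, 10L)
  # variants 4..10 got explicit no-hit markers, so a re-run queries nothing
  expect_equal(annotate_missing(fx$store, src), 0L)
  ann <- get_annotations(fx$store, source_name = "probe")
  expect_equal(nrow(ann), 3L)   # no-hit markers hidden from normal reads
})

test_that("provider batches shrink by exactly the already-annotated set", {
  st <- local_store()
  pid <- add_project(st, "p"); add_sample(st, "S1", pid)
  ids <- vapply(1:5, function(i) upsert_variant(st, "hg19", "chrT", i * 10, "C", "T"), 1L)
  src_of <- function(version) annotation_source("s", version,
    data.frame(field_name = "x", value_kind = "text"),
    function(v) data.frame(variant_id = v$variant_id, field_name = "x", value = "y"))
  # annotate first two manually at v1
  DBI::dbExecute(st$con,
    "INSERT INTO annotations (variant_id, source_name, field_name, value,
     source_version, active, created_at) VALUES (?,?,?,?,?,1,?)",
    params = list(ids[[1]], "s", "x", "y", "v1", "t"))
  DBI::dbExecute(st$con,
    "INSERT INTO annotations (variant_id, source_name, field_name, value,
     source_version, active, created_at) VALUES (?,?,?,?,?,1,?)",
    params = list(ids[[2]], "s", "x", "y", "v1", "t"))
  got <- NULL
  src <- annotation_source("s", "v1",
    data.frame(field_name = "x", value_kind = "text"),
    function(v) { got <<- v$variant_id
      data.frame(variant_id = v$variant_id, field_name = "x", value = "y") })
  register_source(st, src)
  annotate_missing(st, src)
  expect_setequal(got, ids[3:5])   # exactly the 3 missing ones
})

test_that("update_source retires changed records, logs changes and archives history", {
  fx <- ann_fixture()
  s1 <- table_source("clin", "2024-01", fx$tabs$v1)
  register_source(fx$store, s1)
  annotate_missing(fx$store, s1)

  s2 <- table_source("clin", "2024-02", fx$tabs$v2)
  changes <- update_source(fx$store, s2)

  # planted value changes all logged (plus drop-records for the removed variant)
  expect_equal(sum(!is.na(changes$new_value)), nrow(fx$tabs$planted))
  expect_equal(sum(is.na(changes$new_value)), 3L)   # 3 fields of the dropped variant

  # at most one active record per (variant, source, field), even after update
  dup <- DBI::dbGetQuery(fx$store$con,
    "SELECT COUNT(*) n FROM annotations WHERE active = 1
     GROUP BY variant_id, source_name, field_name ORDER BY n DESC LIMIT 1")
  expect_lte(dup$n, 1L)

  # archived, not deleted: a changed fact keeps its superseded value
  p <- fx$tabs$planted[1, ]
  vid <- fx$vars$variant_id[fx$vars$pos == p$pos & fx$vars$alt == p$alt]
  h <- annotation_history(fx$store, vid, "clin", p$field_name)
  expect_equal(nrow(h), 2L)
  expect_identical(h$value[h$active == 0], p$old_value)
  expect_false(is.na(h$retired_at[h$active == 0]))
  expect_identical(h$value[h$active == 1], p$new_value)

  # an identical re-release is rejected as not newer; a no-op newer release logs nothing
  expect_error(update_source(fx$store, s2), "not newer")
  s3 <- table_source("clin", "2024-03", fx$tabs$v2)
  expect_equal(nrow(update_source(fx$store, s3)), 0L)
})

test_that("replaying the change log reconstructs the current active state", {
  fx <- ann_fixture()
  s1 <- table_source("clin", "2024-01", fx$tabs$v1)
  register_source(fx$store, s1)
  annotate_missing(fx$store, s1)
  update_source(fx$store, table_source("clin", "2024-02", fx$tabs$v2))
  # second update back to v1 content exercises repeated updates
  update_source(fx$store, table_source("clin", "2024-03", fx$tabs$v1))

  log <- get_change_log(fx$store)
  hist <- DBI::dbGetQuery(fx$store$con,
    "SELECT * FROM annotations WHERE source_name = 'clin'
       AND field_name != '.no_hit' ORDER BY annotation_id")
  keys <- unique(paste(hist$variant_id, hist$field_name, sep = "/"))
  for (k in keys) {
    vid <- as.integer(sub("/.*", "", k)); fld <- sub(".*/", "", k)
    first <- hist$value[hist$variant_id == vid & hist$field_name == fld][1]
    cur <- first
    lk <- log[log$variant_id == vid & log$field_name == fld, ]
    for (i in seq_len(nrow(lk))) {
      if (!is.na(lk$old_value[i])) expect_identical(cur, lk$old_value[i])
      cur <- lk$new_value[i]
    }
    active <- hist$value[hist$variant_id == vid & hist$field_name == fld &
                           hist$active == 1]
    if (length(active)) expect_identical(cur, active) else expect_true(is.na(cur))
  }
})

test_that("putatively interesting flagging hits planted high-impact and pathogenic changes only", {
  fx <- ann_fixture()
  s1 <- table_source("clin", "2024-01", fx$tabs$v1)
  register_source(fx$store, s1)
  annotate_missing(fx$store, s1)
  changes <- update_source(fx$store, table_source("clin", "2024-02", fx$tabs$v2))

  planted <- fx$tabs$planted
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    vid <- fx$vars$variant_id[fx$vars$pos == p$pos & fx$vars$alt == p$alt]
    row <- changes[changes$variant_id == vid & changes$field_name == p$field_name, ]
    expect_equal(nrow(row), 1L)
    expect_identical(row$interesting, p$expect_interesting,
                     label = paste(p$field_name, p$old_value, "->", p$new_value))
  }
  # drop-changes are never flagged
  expect_false(any(changes$interesting[is.na(changes$new_value)]))
  # and the flag survives in the persistent log
  expect_equal(sum(get_change_log(fx$store, interesting_only = TRUE)$interesting),
               sum(planted$expect_interesting))
})

test_that("flag_interesting covers the vocabulary edges", {
  mk <- function(field, old, new) data.frame(
    variant_id = 1L, source_name = "s", field_name = field,
    old_value = old, new_value = new, old_version = "1", new_version = "2",
    timestamp = "t", stringsAsFactors = FALSE)
  expect_true(flag_interesting(mk("effect", "synonymous", "stopgain")))
  expect_true(flag_interesting(mk("effect", "missense", "frameshift")))
  expect_true(flag_interesting(mk("location", "intronic", "splicing")))
  expect_false(flag_interesting(mk("effect", "stopgain", "stopgain|missense")))  # already high impact
  expect_false(flag_interesting(mk("maf", "0.010", "0.011")))
  expect_true(flag_interesting(mk("clinical_significance", "uncertain", "pathogenic")))
  expect_true(flag_interesting(mk("clinical_significance", "benign", "likely_pathogenic")))
  expect_false(flag_interesting(mk("clinical_significance", "pathogenic", "benign")))
  # any-transcript semantics on multi-values
  expect_true(flag_interesting(mk("effect", "synonymous|missense", "synonymous|stopgain")))
})

test_that("frequency lookup is allele-exact and reports known/novel", {
  tab <- data.frame(chrom = "chrT", pos = 500L, ref = "A", alt = "G",
                    GLOBAL = "0.05", EUR = "0.01", rsid = "rs123",
                    stringsAsFactors = FALSE)
  hit <- lookup_frequency(list(chrom = "chrT", pos = 500, ref = "A", alt = "G"), tab)
  expect_equal(hit$GLOBAL, 0.05)
  expect_true(hit$known)
  expect_identical(hit$rsid, "rs123")
  expect_null(lookup_frequency(list(chrom = "chrT", pos = 500, ref = "A", alt = "T"), tab))
})

test_that("multi-value join/split round-trips including literal pipes", {
  vals <- c("NM_1", "NM_2", "a|b")
  expect_identical(mv_split(mv_join(vals)), vals)
  expect_identical(mv_split("x"), "x")
})
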