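test_that("atoms, AND and OR behave as set intersection and union", {
  fx <- local_trio_store(seed = 3, n_per_class = 4)
  st <- fx$store
  a <- filter_atom("gq", "ge", 60)
  b <- filter_atom("genotype", "eq", "het")
  ra <- evaluate_scheme(st, a, "CHILD")$variant_id
  rb <- evaluate_scheme(st, b, "CHILD")$variant_id
  rand <- evaluate_scheme(st, filter_and(a, b), "CHILD")$variant_id
  ror <- evaluate_scheme(st, filter_or(a, b), "CHILD")$variant_id
  expect_setequal(rand, intersect(ra, rb))
  expect_setequal(ror, union(ra, rb))
  # evaluation independent of child order
  expect_setequal(evaluate_scheme(st, filter_and(b, a), "CHILD")$variant_id, rand)
  # results ordered by position
  res <- evaluate_scheme(st, a, "CHILD")
  expect_false(is.unsorted(res$pos))
})

test_that("schemes with unknown fields or empty groups fail validation before evaluation", {
  fx <- local_trio_store(seed = 3, n_per_class = 2)
  expect_error(evaluate_scheme(fx$store, filter_atom("no_such_field", "eq", 1), "CHILD"),
               "unknown filter field")
  empty <- structure(list(kind = "group", logic = "AND", children = list()),
                     class = "filter_node")
  expect_error(evaluate_scheme(fx$store, empty, "CHILD"), "empty filter group")
})

test_that("missing-value policy decides atom outcomes on unannotated variants", {
  st <- local_store()
  pid <- add_project(st, "p"); add_sample(st, "S1", pid)
  v1 <- upsert_variant(st, "hg19", "chrT", 100, "A", "G")
  v2 <- upsert_variant(st, "hg19", "chrT", 200, "C", "T")
  store_call(st, "S1", v1, "het"); store_call(st, "S1", v2, "het")
  tab <- data.frame(chrom = "chrT", pos = 100L, ref = "A", alt = "G", maf = "0.2")
  src <- table_source("freq", "v1", tab)
  register_source(st, src); annotate_missing(st, src)

  excl <- evaluate_scheme(st, filter_atom("maf", "le", 0.5), "S1")
  expect_identical(excl$variant_id, v1)            # v2 has no MAF -> fails
  incl <- evaluate_scheme(st,
    filter_atom("maf", "le", 0.5, missing_policy = "include"), "S1")
  expect_setequal(incl$variant_id, c(v1, v2))
  mis <- evaluate_scheme(st, filter_atom("maf", "is_missing"), "S1")
  expect_identical(mis$variant_id, v2)
})

test_that("random trees evaluate identically to the brute-force oracle", {
  fx <- local_filter_corpus(seed = 21)
  st <- fx$store
  set.seed(123)
  for (i in 1:40) {
    tree <- random_tree()
    got <- sort(evaluate_scheme(st, tree, "CHILD")$variant_id)
    want <- oracle_evaluate(st, tree, "CHILD")
    expect_identical(got, want, label = sprintf("tree %d", i))
  }
})

test_that("inheritance filters recover exactly their planted classes", {
  for (seed in c(2, 17)) {
    fx <- local_trio_store(seed = seed, n_per_class = 5)
    st <- fx$store
    key <- function(df) paste(df$pos, df$alt)
    truth <- split(fx$trio$truth, fx$trio$truth$class)
    expect_setequal(key(filter_de_novo(st, "CHILD")), key(truth$de_novo))
    expect_setequal(key(filter_recessive(st, "CHILD")), key(truth$recessive))
    expect_setequal(key(filter_dominant(st, "CHILD")), key(truth$dominant))
  }
})

test_that("de novo parent policies follow the genotype truth table", {
  st <- local_store()
  pid <- add_project(st, "p")
  add_sample(st, "F", pid); add_sample(st, "M", pid); add_sample(st, "C", pid)
  set_family(st, "C", father_id = "F", mother_id = "M")
  parent_gts <- c("hom_ref", "het", "hom_alt", "missing", "absent")
  pos <- 0L
  cases <- list()
  for (fg in parent_gts) for (mg in parent_gts) {
    pos <- pos + 10L
    vid <- upsert_variant(st, "hg19", "chrT", pos, "A", "G")
    store_call(st, "C", vid, "het", gq = 99)
    if (fg != "absent") store_call(st, "F", vid, fg)
    if (mg != "absent") store_call(st, "M", vid, mg)
    cases[[length(cases) + 1L]] <- list(vid = vid, fg = fg, mg = mg)
  }
  strict <- filter_de_novo(st, "C", require_called_parents = TRUE)$variant_id
  lenient <- filter_de_novo(st, "C", require_called_parents = FALSE)$variant_id
  for (cs in cases) {
    expect_identical(cs$vid %in% strict,
                     cs$fg == "hom_ref" && cs$mg == "hom_ref",
                     label = sprintf("strict F=%s M=%s", cs$fg, cs$mg))
    ok <- function(g) g %in% c("hom_ref", "missing", "absent")
    expect_identical(cs$vid %in% lenient, ok(cs$fg) && ok(cs$mg),
                     label = sprintf("lenient F=%s M=%s", cs$fg, cs$mg))
  }
})

test_that("recessive requires hom child and het parents; missing parent links error", {
  st <- local_store()
  pid <- add_project(st, "p")
  for (s in c("F", "M", "C", "LONER")) add_sample(st, s, pid)
  set_family(st, "C", father_id = "F", mother_id = "M")
  mk <- function(pos, cg, fg, mg) {
    vid <- upsert_variant(st, "hg19", "chrT", pos, "A", "G")
    store_call(st, "C", vid, cg); store_call(st, "F", vid, fg)
    store_call(st, "M", vid, mg)
    vid
  }
  yes <- mk(100, "hom_alt", "het", "het")
  no1 <- mk(200, "hom_alt", "het", "hom_alt")
  no2 <- mk(300, "het", "het", "het")
  expect_identical(filter_recessive(st, "C")$variant_id, yes)
  expect_error(filter_de_novo(st, "LONER"), "family configuration")
  expect_error(filter_recessive(st, "LONER"), "family configuration")
})

test_that("dominant co-segregation includes affected carriers and excludes unaffected ones", {
  st <- local_store()
  pid <- add_project(st, "p")
  add_sample(st, "F", pid, affected = TRUE)
  add_sample(st, "M", pid, affected = FALSE)
  add_sample(st, "C", pid, affected = TRUE)
  set_family(st, "C", father_id = "F", mother_id = "M")
  mk <- function(pos, cg, fg, mg) {
    vid <- upsert_variant(st, "hg19", "chrT", pos, "A", "G")
    if (cg != "absent") store_call(st, "C", vid, cg)
    if (fg != "absent") store_call(st, "F", vid, fg)
    if (mg != "absent") store_call(st, "M", vid, mg)
    vid
  }
  yes <- mk(100, "het", "het", "hom_ref")
  no_unaff <- mk(200, "het", "het", "het")       # unaffected mother carries
  no_missing <- mk(300, "het", "missing", "hom_ref")  # affected father not called
  no_absent <- mk(400, "het", "absent", "hom_ref")
  expect_identical(filter_dominant(st, "C")$variant_id, yes)

  # without any affected member the model is ill-posed
  st2 <- local_store()
  pid2 <- add_project(st2, "p")
  for (s in c("F", "M", "C")) add_sample(st2, s, pid2)
  set_family(st2, "C", father_id = "F", mother_id = "M")
  expect_error(filter_dominant(st2, "C"), "no affected members")
})

test_that("de novo and recessive are disjoint on any trio", {
  fx <- local_trio_store(seed = 11, n_per_class = 8)
  dn <- filter_de_novo(fx$store, "CHILD")$variant_id
  rc <- filter_recessive(fx$store, "CHILD")$variant_id
  expect_length(intersect(dn, rc), 0L)
})

test_that("occurrence filter counts carrier samples with optional bounds", {
  st <- local_store()
  pid <- add_project(st, "p")
  samples <- sprintf("S%d", 1:5)
  for (s in samples) add_sample(st, s, pid, is_control = TRUE)
  vid1 <- upsert_variant(st, "hg19", "chrT", 100, "A", "G")  # 3 carriers
  for (s in samples[1:3]) store_call(st, s, vid1, "het")
  store_call(st, samples[4], vid1, "hom_ref")
  vid2 <- upsert_variant(st, "hg19", "chrT", 200, "C", "T")  # 2 carriers (1 hom)
  store_call(st, samples[1], vid2, "hom_alt")
  store_call(st, samples[2], vid2, "het")

  r <- filter_occurrence(st, samples, max_count = 2)
  expect_identical(r$variant_id, vid2)          # vid1 has 3 > 2
  r2 <- filter_occurrence(st, samples, min_count = 2)
  expect_setequal(r2$variant_id, c(vid1, vid2))
  r3 <- filter_occurrence(st, samples)          # no-op bounds keep everything
  expect_equal(nrow(r3), 2L)
  expect_error(filter_occurrence(st, character(0), 1, 2), "non-empty")
  expect_error(filter_occurrence(st, samples, 3, 2), "must not exceed")
  # monotonicity: raising min_count never grows the result
  sizes <- vapply(0:4, function(m)
    nrow(filter_occurrence(st, samples, min_count = m)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("burden filter counts distinct carrier samples per gene", {
  st <- local_store()
  gmod <- generate_gene_model(31)
  co <- generate_cohort(31, n_samples = 6, gene_model = gmod$models[1, ], n_carriers = 3)
  pid <- add_project(st, "p")
  for (s in co$sample_ids) add_sample(st, s, pid)
  vcf <- tempfile(fileext = ".vcf"); writeLines(co$vcf, vcf)
  import_vcf(st, vcf, "hg19")
  src <- gene_model_source("genes", "v1", gmod$models, gmod$cds)
  register_source(st, src); annotate_missing(st, src)
  gene <- gmod$models$gene_symbol[1]

  b3 <- filter_burden(st, co$sample_ids, "genes", min_samples = 3)
  expect_true(gene %in% b3$genes$gene)
  expect_equal(b3$genes$n_samples[b3$genes$gene == gene], 3L)
  b4 <- filter_burden(st, co$sample_ids, "genes", min_samples = 4)
  expect_false(gene %in% b4$genes$gene)
  bmax <- filter_burden(st, co$sample_ids, "genes", max_samples = 1)
  expect_false(gene %in% bmax$genes$gene)

  # brute-force recount from the call table: distinct samples, not variants
  in_gene <- co$truth[co$truth$in_gene, ]
  expect_gt(nrow(in_gene), 3L)                 # one carrier holds two variants
  expect_equal(length(unique(in_gene$carrier)), 3L)
})

test_that("gene panels match transcripts version-insensitively and can be shared", {
  st <- local_store()
  gmod <- generate_gene_model(5)
  pid <- add_project(st, "p"); add_sample(st, "S1", pid)
  v_in <- upsert_variant(st, "hg19", "chrT", 1150, "A", "G")   # in NM_0001.2 only
  v_out <- upsert_variant(st, "hg19", "chrT", 4350, "A", "G")  # NM_0002.1 only
  v_far <- upsert_variant(st, "hg19", "chrT", 90000, "A", "G") # intergenic
  for (v in c(v_in, v_out, v_far)) store_call(st, "S1", v, "het")
  src <- gene_model_source("genes", "v1", gmod$models, gmod$cds)
  register_source(st, src); annotate_missing(st, src)

  ids <- c(v_in, v_out, v_far)
  hit <- filter_panel(st, ids, panel = "NM_0001", source_name = "genes")
  expect_identical(hit, v_in)
  # resolved through the gene model by symbol as well
  hit2 <- filter_panel(st, ids, panel = "NM_0002.9", source_name = "genes",
                       gene_models = gmod$models)
  expect_identical(hit2, v_out)
  expect_error(filter_panel(st, ids, character(0), "genes"), "empty gene panel")

  create_panel(st, "cardiac", "alice", c("NM_0001.2", "NM_0009.1"))
  expect_error(create_panel(st, "cardiac", "alice", "NM_0001"), "already exists",
               class = "vdb_conflict")
  expect_length(get_panel(st, "cardiac", "bob"), 0L)   # private
  share_panel(st, "cardiac", "alice")
  expect_length(get_panel(st, "cardiac", "bob"), 2L)   # public now
})

test_that("schemes persist and reload to evaluation-equivalent trees", {
  fx <- local_filter_corpus(seed = 33)
  st <- fx$store
  tree <- filter_and(
    filter_or(filter_atom("location", "eq", "exonic"),
              filter_atom("location", "eq", "splicing")),
    filter_atom("gq", "ge", 40),
    filter_or(filter_atom("maf", "le", 0.05),
              filter_atom("maf", "is_missing")))
  sch <- filter_scheme("rare_exonic", tree, owner = "alice")
  save_scheme(st, sch)
  back <- load_scheme(st, "rare_exonic")
  expect_identical(evaluate_scheme(st, back, "CHILD")$variant_id,
                   evaluate_scheme(st, sch, "CHILD")$variant_id)
  expect_error(save_scheme(st, sch), "already exists", class = "vdb_conflict")
  save_scheme(st, sch, overwrite = TRUE)
  expect_error(load_scheme(st, "nope"), "no saved scheme")

  # late binding: a scheme naming a missing field loads but fails evaluation
  ghost <- filter_scheme("ghost", filter_atom("cadd_phred", "ge", 20))
  save_scheme(st, ghost)
  loaded <- load_scheme(st, "ghost")
  expect_error(evaluate_scheme(st, loaded, "CHILD"), "cadd_phred")
})
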