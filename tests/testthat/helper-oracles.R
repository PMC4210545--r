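# Shared fixtures and independent brute-force oracles used across tests.

# in-memory store torn down with the calling test
local_store <- function(build = "hg19", env = parent.frame()) {
  st <- vdb_connect(":memory:", build = build)
  withr::defer(vdb_disconnect(st), envir = env)
  st
}

# trio store with imported fixture VCF
local_trio_store <- function(seed = 1, n_per_class = 5, env = parent.frame()) {
  st <- local_store(env = env)
  trio <- generate_trio(seed, n_per_class)
  load_trio(st, trio)
  list(store = st, trio = trio)
}

# --- brute-force filter-tree evaluator ------------------------------------
# Re-derives, per variant and with scalar logic only, whether the tree
# passes; deliberately shares no code with the set-based evaluator.
oracle_evaluate <- function(store, node, sample_id, calls = NULL, ann = NULL) {
  if (is.null(calls)) calls <- get_sample_calls(store, sample_id)
  if (is.null(ann)) ann <- get_annotations(store, calls$variant_id)
  srcs <- unique(ann$source_name)
  rows <- lapply(seq_len(nrow(calls)), function(i) as.list(calls[i, ]))
  atom_pass <- function(atom, row) {
    if (atom$field %in% c("chrom", "pos", "ref", "alt", "genotype", "qual", "gq",
                          "ad_ref", "ad_alt", "allelic_ratio", "qd", "mq", "fs",
                          "base_q_rank_sum", "mq_rank_sum", "read_pos_rank_sum",
                          "filter_status")) {
      v <- row[[atom$field]]
      elems <- if (is.na(v)) character(0) else as.character(v)
    } else {
      fld <- sub("^[^.]+\\.", "", atom$field)
      src <- if (grepl(".", atom$field, fixed = TRUE))
        sub("\\..*$", "", atom$field) else srcs[
          vapply(srcs, function(s) any(ann$source_name == s & ann$field_name == fld), TRUE)]
      hit <- ann$value[ann$variant_id == row$variant_id &
                         ann$source_name %in% src & ann$field_name == fld]
      elems <- if (!length(hit)) character(0) else {
        e <- strsplit(hit[[1]], "|", fixed = TRUE)[[1]]
        e[e != "."]
      }
    }
    if (atom$op == "is_missing") return(length(elems) == 0)
    if (atom$op == "not_missing") return(length(elems) > 0)
    if (!length(elems)) return(atom$missing_policy == "include")
    res <- FALSE
    for (e in elems) {
      en <- suppressWarnings(as.numeric(e))
      vn <- suppressWarnings(as.numeric(atom$value[[1]]))
      r <- switch(atom$op,
        eq = e == as.character(atom$value),
        ne = e != as.character(atom$value),
        lt = !is.na(en) && !is.na(vn) && en < vn,
        le = !is.na(en) && !is.na(vn) && en <= vn,
        gt = !is.na(en) && !is.na(vn) && en > vn,
        ge = !is.na(en) && !is.na(vn) && en >= vn,
        contains = grepl(as.character(atom$value), e, fixed = TRUE),
        in_set = e %in% as.character(atom$value))
      if (isTRUE(any(r))) res <- TRUE
    }
    res
  }
  node_pass <- function(n, row) {
    if (n$kind == "atom") return(atom_pass(n, row))
    results <- vapply(n$children, node_pass, TRUE, row = row)
    if (n$logic == "AND") all(results) else any(results)
  }
  keep <- vapply(rows, function(row) node_pass(node, row), TRUE)
  sort(calls$variant_id[keep])
}

# random AND/OR trees over a fixed field vocabulary
random_tree <- function(max_depth = 4, max_atoms = 10) {
  atoms_left <- max_atoms
  mk_atom <- function() {
    atoms_left <<- atoms_left - 1
    spec <- sample(list(
      list(f = "gq", ops = c("ge", "lt", "le", "gt")),
      list(f = "qual", ops = c("ge", "lt")),
      list(f = "allelic_ratio", ops = c("ge", "le")),
      list(f = "genotype", ops = c("eq", "ne", "in_set")),
      list(f = "location", ops = c("eq", "in_set", "not_missing", "is_missing")),
      list(f = "effect", ops = c("eq", "contains", "not_missing")),
      list(f = "maf", ops = c("le", "ge", "is_missing"))), 1)[[1]]
    op <- sample(spec$ops, 1)
    value <- if (op %in% c("is_missing", "not_missing")) NULL else switch(spec$f,
      gq = sample(30:99, 1), qual = round(runif(1, 100, 3000)),
      allelic_ratio = round(runif(1), 2),
      genotype = if (op == "in_set") sample(c("het", "hom_alt", "hom_ref"), 2)
                 else sample(c("het", "hom_alt"), 1),
      location = if (op == "in_set") sample(c("exonic", "intronic", "utr",
                                              "splicing", "downstream"), 2)
                 else sample(c("exonic", "intronic", "utr"), 1),
      effect = sample(c("synonymous", "missense", "stopgain", "noncoding"), 1),
      maf = round(runif(1, 0, 0.2), 3))
    filter_atom(spec$f, op, value,
                missing_policy = sample(c("exclude", "include"), 1))
  }
  mk_node <- function(depth) {
    if (depth >= max_depth || atoms_left <= 1 || runif(1) < 0.35) return(mk_atom())
    n_children <- min(sample(1:3, 1), atoms_left)
    children <- lapply(seq_len(n_children), function(i) mk_node(depth + 1))
    if (runif(1) < 0.5) filter_and(children) else filter_or(children)
  }
  mk_node(1)
}

# a 500-variant single-sample store with gene-model and table annotations,
# used by the filter-tree equivalence checks
local_filter_corpus <- function(seed = 7, env = parent.frame()) {
  st <- local_store(env = env)
  trio <- generate_trio(seed, n_per_class = 100)   # 500 variants
  load_trio(st, trio)
  gm <- generate_gene_model(seed)
  register_source(st, gene_model_source("genes", "v1", gm$models, gm$cds))
  annotate_missing(st, gene_model_source("genes", "v1", gm$models, gm$cds))
  vars <- get_variants(st)
  # frequency table covering ~60% of variants so missingness is exercised
  keep <- withr::with_seed(seed, sample(nrow(vars), round(0.6 * nrow(vars))))
  freq <- withr::with_seed(seed, data.frame(
    chrom = vars$chrom[keep], pos = vars$pos[keep], ref = vars$ref[keep],
    alt = vars$alt[keep], maf = sprintf("%.4f", runif(length(keep), 0, 0.2)),
    rsid = sprintf("rs%06d", seq_along(keep)), stringsAsFactors = FALSE))
  fsrc <- table_source("freq", "v1", freq)
  register_source(st, fsrc)
  annotate_missing(st, fsrc)
  list(store = st, trio = trio, freq = freq)
}

# --- coding-effect oracle --------------------------------------------------
# Rebuilds the full mutated CDS and classifies from complete protein
# translations, independent of the affected-codon logic in the package.
oracle_snv_effect <- function(cds, idx, alt_base) {
  mut <- cds
  substr(mut, idx, idx) <- alt_base
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
  if (p0 == p1) return("synonymous")
  stop0 <- regexpr("*", p0, fixed = TRUE)
  stop1 <- regexpr("*", p1, fixed = TRUE)
  if (stop1 > 0 && (stop0 < 0 || stop1 < stop0)) return("stopgain")
  if (stop1 < 0 && stop0 > 0) return("stoploss")
  "missense"
}

# --- normalization oracle --------------------------------------------------
# Applies a variant record as an edit to an embedding sequence; two records
# are the same edit iff the edited sequences are equal.
apply_edit <- function(context, pos, ref, alt) {
  stopifnot(substr(context, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(context, 1, pos - 1), alt,
         substr(context, pos + nchar(ref), nchar(context)))
}
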