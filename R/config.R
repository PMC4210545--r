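## YAML configuration: database location, current build, registered
## annotation sources and interface defaults. Validated at load time;
## unknown keys are rejected so typos fail fast.

CONFIG_KEYS <- c("database", "build", "sources", "missing_policy", "page_size")
SOURCE_KEYS <- c("name", "version", "path", "kind", "cds_fasta")

#' Load and validate a configuration file
#'
#' @param path YAML file with keys `database` (store path), `build`
#'   (current genome build), `sources` (list of `name`, `version`, `path`,
#'   `kind` = `table`/`gene_model`, optional `cds_fasta`), `missing_policy`
#'   (default atom policy, `exclude`/`include`) and `page_size`.
#' @return Validated config list with defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(cfg$database)) stop("config requires 'database'", call. = FALSE)
  if (is.null(cfg$build)) cfg$build <- "hg19"
  if (is.null(cfg$missing_policy)) cfg$missing_policy <- "exclude"
  cfg$missing_policy <- match.arg(cfg$missing_policy, c("exclude", "include"))
  if (is.null(cfg$page_size)) cfg$page_size <- PAGE_SIZE
  stopifnot(cfg$page_size >= 1)
  for (src in cfg$sources) {
    bad <- setdiff(names(src), SOURCE_KEYS)
    if (length(bad))
      stop("unknown source key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(src$name) || is.null(src$version) || is.null(src$path))
      stop("each source needs name, version and path", call. = FALSE)
  }
  cfg
}

# instantiate the annotation_source objects a config describes
config_sources <- function(cfg) {
  lapply(cfg$sources, function(src) {
    kind <- if (is.null(src$kind)) "table" else src$kind
    if (kind == "gene_model") {
      models <- read_gene_models(src$path)
      cds <- if (!is.null(src$cds_fasta)) read_cds_fasta(src$cds_fasta) else NULL
      gene_model_source(src$name, src$version, models, cds)
    } else {
      table_source(src$name, src$version, src$path)
    }
  })
}
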