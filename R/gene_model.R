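## Transcript gene models and variant classification at the cDNA/protein
## level: location (exonic/intronic/splicing/UTR/up-/downstream/intergenic)
## and, where a CDS sequence is available, the coding effect via codon
## translation (synonymous/missense/stopgain/stoploss; frameshift/inframe
## for CDS indels).

SPLICE_WINDOW <- 2L     # intronic bases from an exon boundary called "splicing"
FLANK_WINDOW <- 1000L   # up/downstream annotation window

#' Read transcript gene models from a BED12 file
#'
#' Standard 12-column BED: chrom, chromStart, chromEnd, name, score, strand,
#' thickStart, thickEnd, itemRgb, blockCount, blockSizes, blockStarts. The
#' `name` column is `transcript_id|gene_symbol|nomenclature` (falling back
#' to the transcript id alone). Thick bounds delimit the CDS; a transcript
#' with `thickStart == thickEnd` is non-coding.
#'
#' @param path BED12 file path.
#' @param nomenclature Default nomenclature when not encoded in `name`
#'   (`refseq`, `ensembl` or `ucsc`).
#' @return A `gene_models` data.frame, one row per transcript, exon
#'   intervals as list columns of 1-based inclusive starts/ends.
#' @export
read_gene_models <- function(path, nomenclature = "refseq") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
    col.names = c("chrom", "start0", "end0", "name", "score", "strand",
                  "thick_start0", "thick_end0", "rgb", "block_count",
                  "block_sizes", "block_starts"),
    colClasses = c("character", "integer", "integer", "character", "character",
                   "character", "integer", "integer", "character", "integer",
                   "character", "character"))
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    b <- bed[i, ]
    parts <- strsplit(b$name, "|", fixed = TRUE)[[1]]
    sizes <- as.integer(strsplit(sub(",$", "", b$block_sizes), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", b$block_starts), ",")[[1]])
    ex_start <- b$start0 + offs + 1L          # to 1-based inclusive
    ex_end <- b$start0 + offs + sizes
    data.frame(transcript_id = parts[[1]],
               gene_symbol = if (length(parts) > 1L) parts[[2]] else parts[[1]],
               nomenclature = if (length(parts) > 2L) parts[[3]] else nomenclature,
               chrom = b$chrom, strand = b$strand,
               tx_start = b$start0 + 1L, tx_end = b$end0,
               cds_start = if (b$thick_start0 == b$thick_end0) NA_integer_
                           else b$thick_start0 + 1L,
               cds_end = if (b$thick_start0 == b$thick_end0) NA_integer_
                         else b$thick_end0,
               exon_starts = I(list(ex_start)), exon_ends = I(list(ex_end)),
               stringsAsFactors = FALSE)
  })
  models <- do.call(rbind, rows)
  validate_gene_models(models)
  models
}

#' Validate gene-model invariants
#'
#' Exons must be sorted and non-overlapping and the CDS contained in the
#' transcript span.
#'
#' @param models A `gene_models` data.frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    if (any(e < s)) stop("exon end before start in ", models$transcript_id[[i]])
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] <= e[-length(e)]))
      stop("exons overlap or are unsorted in ", models$transcript_id[[i]])
    cs <- models$cds_start[[i]]; ce <- models$cds_end[[i]]
    if (!is.na(cs) && (cs < models$tx_start[[i]] || ce > models$tx_end[[i]]))
      stop("CDS outside transcript span in ", models$transcript_id[[i]])
  }
  invisible(TRUE)
}

# CDS exon intervals (1-based inclusive) in genomic order
cds_intervals <- function(model) {
  if (is.na(model$cds_start)) return(NULL)
  s <- pmax(model$exon_starts[[1]], model$cds_start)
  e <- pmin(model$exon_ends[[1]], model$cds_end)
  keep <- s <= e
  if (!any(keep)) return(NULL)
  list(start = s[keep], end = e[keep])
}

# genomic position -> 1-based index into the spliced CDS (strand-aware);
# NA when pos lies outside the CDS exons
cds_index <- function(model, pos) {
  iv <- cds_intervals(model)
  if (is.null(iv)) return(NA_integer_)
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (!length(hit)) return(NA_integer_)
  before <- sum(pmax(0L, iv$end[seq_len(hit - 1L)] - iv$start[seq_len(hit - 1L)] + 1L))
  idx_plus <- before + (pos - iv$start[[hit]] + 1L)
  if (model$strand == "+") return(as.integer(idx_plus))
  total <- sum(iv$end - iv$start + 1L)
  as.integer(total - idx_plus + 1L)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  paste(rev(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# coding effect of a SNV at CDS index idx, alleles given on the CDS strand
snv_effect <- function(cds_seq, idx, ref_base, alt_base) {
  codon_i <- (idx - 1L) %/% 3L + 1L
  off <- (idx - 1L) %% 3L + 1L
  codon <- substr(cds_seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  if (nchar(codon) < 3L) return("unavailable")
  new_codon <- codon
  substr(new_codon, off, off) <- alt_base
  old_aa <- translate_codon(codon)
  new_aa <- translate_codon(new_codon)
  if (is.na(old_aa) || is.na(new_aa)) return("unavailable")
  if (old_aa == new_aa) "synonymous"
  else if (new_aa == "*") "stopgain"
  else if (old_aa == "*") "stoploss"
  else "missense"
}

#' Classify a variant against transcript gene models
#'
#' Produces one annotation per overlapping transcript. Location is one of
#' `exonic`, `utr`, `intronic`, `splicing` (within `splice_window` intronic
#' bases of an exon boundary), `upstream`, `downstream` or — when no
#' transcript is in range — a single `intergenic` row. For exonic CDS SNVs
#' with a CDS sequence available the coding effect is derived by codon
#' translation; CDS indels are `frameshift` when the length change is not a
#' multiple of 3, else `inframe`. Transcripts without a CDS sequence get
#' effect `unavailable` (non-coding transcripts: `noncoding`).
#'
#' @param variant List/row with `chrom`, `pos`, `ref`, `alt` (normalized).
#' @param gene_models A `gene_models` data.frame ([read_gene_models()]).
#' @param cds_seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   spliced CDS sequences keyed by `transcript_id`; may be missing entries.
#' @param splice_window Intronic distance (bases) called `splicing`.
#' @return data.frame with `transcript_id`, `gene_symbol`, `nomenclature`,
#'   `location`, `effect`, `cds_pos`, `protein_pos`.
#' @export
classify_against_gene_model <- function(variant, gene_models, cds_seqs = NULL,
                                        splice_window = SPLICE_WINDOW) {
  if (!is.null(cds_seqs) && !is.character(cds_seqs))
    cds_seqs <- stats::setNames(as.character(cds_seqs), names(cds_seqs))
  pos <- as.integer(variant$pos)
  vend <- pos + nchar(variant$ref) - 1L
  is_snv <- nchar(variant$ref) == 1L && nchar(variant$alt) == 1L
  rows <- list()
  for (i in seq_len(nrow(gene_models))) {
    m <- gene_models[i, ]
    if (m$chrom != variant$chrom) next
    if (vend < m$tx_start - FLANK_WINDOW || pos > m$tx_end + FLANK_WINDOW) next
    loc <- NULL; effect <- NA_character_; cpos <- NA_integer_; ppos <- NA_integer_
    if (vend < m$tx_start) {
      loc <- if (m$strand == "+") "upstream" else "downstream"
    } else if (pos > m$tx_end) {
      loc <- if (m$strand == "+") "downstream" else "upstream"
    } else {
      ex_s <- m$exon_starts[[1]]; ex_e <- m$exon_ends[[1]]
      in_exon <- any(pos >= ex_s & pos <= ex_e) || any(vend >= ex_s & vend <= ex_e) ||
        any(pos <= ex_s & vend >= ex_e)
      if (in_exon) {
        has_cds <- !is.na(m$cds_start)
        in_cds <- has_cds && vend >= m$cds_start && pos <= m$cds_end
        if (!has_cds) {
          loc <- "exonic"; effect <- "noncoding"
        } else if (!in_cds) {
          loc <- "utr"
        } else {
          loc <- "exonic"
          cds_seq <- if (!is.null(cds_seqs) && m$transcript_id %in% names(cds_seqs))
            cds_seqs[[m$transcript_id]] else NULL
          if (is_snv) {
            cpos <- cds_index(m, pos)
            if (is.na(cpos)) {               # CDS span but intron-side (shouldn't occur)
              effect <- "unavailable"
            } else if (is.null(cds_seq)) {
              effect <- "unavailable"
              ppos <- (cpos - 1L) %/% 3L + 1L
            } else {
              ref_b <- variant$ref; alt_b <- variant$alt
              if (m$strand == "-") { ref_b <- revcomp(ref_b); alt_b <- revcomp(alt_b) }
              effect <- snv_effect(cds_seq, cpos, ref_b, alt_b)
              ppos <- (cpos - 1L) %/% 3L + 1L
            }
          } else {
            delta <- nchar(variant$alt) - nchar(variant$ref)
            effect <- if (delta %% 3L != 0L) "frameshift" else "inframe"
            cpos <- cds_index(m, max(pos, m$cds_start))
            if (!is.na(cpos)) ppos <- (cpos - 1L) %/% 3L + 1L
          }
        }
      } else {
        # intronic; splicing when within splice_window of a boundary
        d_donor <- pos - ex_e[ex_e < pos]
        d_accept <- ex_s[ex_s > vend] - vend
        dmin <- suppressWarnings(min(c(d_donor[d_donor > 0], d_accept[d_accept > 0])))
        loc <- if (is.finite(dmin) && dmin <= splice_window) "splicing" else "intronic"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = m$transcript_id, gene_symbol = m$gene_symbol,
      nomenclature = m$nomenclature, location = loc, effect = effect,
      cds_pos = cpos, protein_pos = ppos, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(transcript_id = NA_character_, gene_symbol = NA_character_,
                      nomenclature = NA_character_, location = "intergenic",
                      effect = NA_character_, cds_pos = NA_integer_,
                      protein_pos = NA_integer_, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Gene-model annotation source
#'
#' Wraps [classify_against_gene_model()] as a pluggable annotation source
#' emitting the fields `gene_symbol`, `transcript_id`, `location`, `effect`,
#' `cds_pos` and `protein_pos`; per-transcript values are pipe-joined in
#' transcript order.
#'
#' @param source_name,version_label As in [annotation_source()].
#' @param gene_models A `gene_models` data.frame.
#' @param cds_seqs Named CDS sequences (see [classify_against_gene_model()]).
#' @param splice_window Passed through.
#' @return An `annotation_source`.
#' @export
gene_model_source <- function(source_name, version_label, gene_models,
                              cds_seqs = NULL, splice_window = SPLICE_WINDOW) {
  fields <- data.frame(
    field_name = c("gene_symbol", "transcript_id", "location", "effect",
                   "cds_pos", "protein_pos"),
    value_kind = c("text", "text", "text", "text", "text", "text"),
    stringsAsFactors = FALSE)
  provider <- function(variants) {
    out <- lapply(seq_len(nrow(variants)), function(i) {
      cls <- classify_against_gene_model(variants[i, ], gene_models, cds_seqs,
                                         splice_window)
      if (nrow(cls) == 1L && cls$location[[1]] == "intergenic") return(NULL)
      data.frame(variant_id = variants$variant_id[[i]],
                 field_name = fields$field_name,
                 value = c(mv_join(cls$gene_symbol), mv_join(cls$transcript_id),
                           mv_join(cls$location), mv_join(ifelse(is.na(cls$effect),
                                                                 ".", cls$effect)),
                           mv_join(ifelse(is.na(cls$cds_pos), ".", cls$cds_pos)),
                           mv_join(ifelse(is.na(cls$protein_pos), ".", cls$protein_pos))),
                 stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(data.frame(variant_id = integer(0),
                                        field_name = character(0),
                                        value = character(0)))
    do.call(rbind, out)
  }
  annotation_source(source_name, version_label, fields, provider)
}

#' Read CDS sequences from a FASTA file keyed by transcript id
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
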