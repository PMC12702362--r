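#' Write a variant count table as TSV
#'
#' Columns are \code{position}, \code{wt_aa}, \code{alt_aa}, then one
#' integer column per sample named \code{condition_replicate}.
#'
#' @param counts Integer matrix, variants x samples, with column names.
#' @param variants data.frame keying the rows (position, wt_aa, alt_aa);
#'   parsed from row names when absent.
#' @param path Output file.
#' @export
write_count_table <- function(counts, path, variants = NULL) {
  counts <- as.matrix(counts)
  if (is.null(variants)) variants <- parse_variants(rownames(counts))
  check_variant_table(variants, require_unique = TRUE)
  out <- cbind(variants[c("position", "wt_aa", "alt_aa")],
               as.data.frame(counts, row.names = NULL))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant count table from TSV
#'
#' Validates the schema of a table written by
#' \code{\link{write_count_table}}; malformed rows (non-integer or
#' negative counts, bad residues, duplicate keys) are rejected with their
#' row numbers.
#'
#' @param path TSV file.
#' @return List with \code{counts} (integer matrix, row names in
#'   one-letter variant notation) and \code{variants} (data.frame).
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("position", "wt_aa", "alt_aa")
  if (!all(needed %in% names(tab)))
    stop("parse error: count table must start with columns position, wt_aa, alt_aa")
  sample_cols <- setdiff(names(tab), needed)
  if (length(sample_cols) == 0)
    stop("parse error: count table has no sample columns")
  counts <- as.matrix(tab[sample_cols])
  bad <- which(rowSums(!is.finite(counts) | counts < 0 |
                         counts != round(counts)) > 0)
  if (length(bad) > 0)
    stop("parse error: invalid (negative or non-integer) counts in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  variants <- tab[needed]
  check_variant_table(variants, require_unique = TRUE)
  storage.mode(counts) <- "integer"
  rownames(counts) <- variant_key(variants)
  list(counts = counts, variants = variants)
}

#' Write an enrichment score table as TSV
#'
#' Column names (\code{baseMean}, \code{log2FoldChange}, \code{lfcSE},
#' \code{pvalue}, \code{padj}) follow the DESeq2 results convention so
#' exported results from a real screen can be ingested interchangeably.
#'
#' @param scores data.frame from \code{\link{score_contrast}}.
#' @param path Output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an enrichment score table
#'
#' Accepts tables written by \code{\link{write_scores}} or DESeq2-style
#' exports carrying a \code{variant} column instead of the split key.
#'
#' @param path TSV file.
#' @return data.frame with variant keys (position, wt_aa, alt_aa) and a
#'   score column (\code{log2FoldChange}, or the refined-table pair
#'   \code{inhibition_score}/\code{functional_stability_score}); a missing
#'   \code{passed_filter} column is filled with TRUE.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(tab) && "variant" %in% names(tab))
    tab <- cbind(parse_variants(tab$variant),
                 tab[setdiff(names(tab), "variant")])
  has_score <- any(c("log2FoldChange", "functional_stability_score") %in%
                     names(tab))
  if (!all(c("position", "wt_aa", "alt_aa") %in% names(tab)) || !has_score)
    stop("parse error: score table needs variant keys and a score column")
  if (!"passed_filter" %in% names(tab)) tab$passed_filter <- TRUE
  tab
}

#' Read a variant-keyed predictor table
#'
#' Generic CSV/TSV ingestion for external predictor files (variant effect
#' predictors, ddG tables). Columns are remapped through \code{mapping};
#' a single \code{variant} column in "A123G"/"Ala123Gly" notation is
#' split into the standard key.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param mapping Named character vector mapping standard names
#'   (position, wt_aa, alt_aa, variant, vep_score, ddg_active, ddg_latent,
#'   ...) to the file's column names; identity for names not listed.
#' @return data.frame keyed by position, wt_aa, alt_aa.
#' @export
read_predictor_table <- function(path, mapping = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(tab))
        stop("parse error: mapped column '", mapping[[std]], "' not found")
      names(tab)[names(tab) == mapping[[std]]] <- std
    }
  }
  if (!"position" %in% names(tab) && "variant" %in% names(tab))
    tab <- cbind(parse_variants(tab$variant),
                 tab[setdiff(names(tab), "variant")])
  check_variant_table(tab)
  tab
}

#' Read a per-position conservation score table
#'
#' @param path CSV/TSV with columns mappable to (position, conservation).
#' @param mapping Optional named character vector as in
#'   \code{\link{read_predictor_table}}.
#' @return data.frame with columns position, conservation.
#' @export
read_conservation_table <- function(path, mapping = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!is.null(mapping))
    for (std in names(mapping))
      names(tab)[names(tab) == mapping[[std]]] <- std
  if (!all(c("position", "conservation") %in% names(tab)))
    stop("parse error: conservation table needs columns position, conservation")
  tab[c("position", "conservation")]
}

#' Write called regions as a BED file
#'
#' The per-position profile uses 1-based inclusive coordinates throughout;
#' the BED export is the single 0-based half-open surface.
#'
#' @param intervals data.frame with columns region_class, start, end
#'   (1-based inclusive).
#' @param path Output file.
#' @param chrom Sequence name placed in the first BED column.
#' @export
write_regions_bed <- function(intervals, path, chrom = "protein") {
  bed <- data.frame(chrom = chrom, start = intervals$start - 1L,
                    end = intervals$end, name = intervals$region_class)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a position x amino-acid heatmap matrix
#'
#' Long score tables are pivoted into the 20-row (amino acids) by L-column
#' (positions) grid used for mutational landscape heatmaps. Unscored cells
#' are NA (rendered white downstream); wild-type cells are flagged in the
#' \code{wt_mask} attribute.
#'
#' @param scores Variant-keyed data.frame with the value column.
#' @param L Protein length; defaults to the maximum scored position.
#' @param value_field Column to place in the grid.
#' @param wt_seq Optional wild-type sequence used to flag wild-type cells.
#' @return Numeric 20 x L matrix (rownames amino acids, colnames
#'   positions) with attribute \code{wt_mask} (logical matrix).
#' @export
export_heatmap_matrix <- function(scores, L = NULL,
                                  value_field = "log2FoldChange",
                                  wt_seq = NULL) {
  check_variant_table(scores)
  key <- paste(scores$position, scores$alt_aa)
  if (anyDuplicated(key))
    stop("export error: duplicate variant keys in score table")
  if (is.null(L)) L <- max(scores$position)
  mat <- matrix(NA_real_, nrow = 20, ncol = L,
                dimnames = list(AA20, seq_len(L)))
  mat[cbind(match(scores$alt_aa, AA20), scores$position)] <-
    scores[[value_field]]
  wt_mask <- matrix(FALSE, nrow = 20, ncol = L,
                    dimnames = dimnames(mat))
  if (is.null(wt_seq)) {
    wt_at <- tapply(scores$wt_aa, scores$position, function(x) x[1])
    wt_mask[cbind(match(as.character(wt_at), AA20),
                  as.integer(names(wt_at)))] <- TRUE
  } else {
    wt_mask[cbind(match(wt_seq, AA20), seq_len(L))] <- TRUE
  }
  attr(mat, "wt_mask") <- wt_mask
  mat
}

#' Pivot a heatmap matrix back to a long score table
#'
#' Inverse of \code{\link{export_heatmap_matrix}} for filled cells.
#'
#' @param mat Matrix from \code{\link{export_heatmap_matrix}}.
#' @param wt_seq Wild-type sequence (defaults to the flagged wild-type
#'   rows of the matrix's \code{wt_mask}).
#' @return data.frame with columns position, wt_aa, alt_aa, value.
#' @export
heatmap_to_long <- function(mat, wt_seq = NULL) {
  if (is.null(wt_seq)) {
    mask <- attr(mat, "wt_mask")
    if (is.null(mask)) stop("need wt_seq or a wt_mask attribute")
    wt_seq <- rownames(mat)[apply(mask, 2, function(col)
      if (any(col)) which(col)[1] else NA_integer_)]
  }
  idx <- which(!is.na(mat), arr.ind = TRUE)
  out <- data.frame(position = as.integer(colnames(mat)[idx[, 2]]),
                    wt_aa = wt_seq[idx[, 2]],
                    alt_aa = rownames(mat)[idx[, 1]],
                    value = mat[idx], stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
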