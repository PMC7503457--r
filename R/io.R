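# Tab-separated dialects shared by the generator and the pipeline readers.
# Expression: header row of sample IDs, first column `gene_id`.
# Interactions: (mirna_id, target_id, target_class); purity: (sample_id,
# purity); clinical: (sample_id, time, event); truth: (lnc_id, mir_id, mrna_id).
# All UTF-8, Unix newlines.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

write_tsv_plain <- function(df, path) {
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE,
                               fileEncoding = "UTF-8", eol = "\n"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' @param path tab-separated file; first column `gene_id`, remaining columns
#'   one per sample.
#' @param layer_class RNA class of the matrix.
#' @param is_log2 whether values are already log2(x + 1).
#' @return an [expression_layer()].
#' @export
read_expression_matrix <- function(path,
                                   layer_class = c("lncRNA", "miRNA", "mRNA"),
                                   is_log2 = TRUE) {
  layer_class <- match.arg(layer_class)
  df <- read_tsv_checked(path, "gene_id")
  genes <- as.character(df$gene_id)
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  expression_layer(mat, layer_class, is_log2 = is_log2)
}

#' Write an expression layer in the pipeline dialect
#' @param layer an `expr_layer`.
#' @param path output path.
#' @export
write_expression_matrix <- function(layer, path) {
  df <- data.frame(gene_id = layer_genes(layer), layer$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read the sample purity table
#' @param path tab-separated file with columns `sample_id`, `purity`.
#' @return data.frame with those columns; purity validated to lie in [0, 1].
#' @export
read_purity_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "purity"))
  df$purity <- as.numeric(df$purity)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in purity table ", path, call. = FALSE)
  if (any(!is.finite(df$purity)) || any(df$purity < 0 | df$purity > 1))
    stop("purity values must lie in [0, 1]: ", path, call. = FALSE)
  df[, c("sample_id", "purity")]
}

#' Read the clinical (survival) table
#' @param path tab-separated file with columns `sample_id`, `time`, `event`.
#' @return data.frame; `time` positive, `event` in {0, 1}.
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "time", "event"))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("clinical times must be positive: ", path, call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("clinical event indicator must be 0 or 1: ", path, call. = FALSE)
  df[, c("sample_id", "time", "event")]
}

#' Read the miRNA-target interaction table
#' @param path tab-separated file with columns `mirna_id`, `target_id`,
#'   `target_class` (values `lncRNA` or `mRNA`).
#' @return de-duplicated data.frame of pairs.
#' @export
read_interaction_table <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "target_id", "target_class"))
  if (!all(df$target_class %in% c("lncRNA", "mRNA")))
    stop("target_class must be 'lncRNA' or 'mRNA': ", path, call. = FALSE)
  unique(df[, c("mirna_id", "target_id", "target_class")])
}

#' Read a planted-triplet truth table
#' @param path tab-separated file with columns `lnc_id`, `mir_id`, `mrna_id`.
#' @return data.frame of planted triplets (possibly zero rows).
#' @export
read_truth_table <- function(path) {
  read_tsv_checked(path, c("lnc_id", "mir_id", "mrna_id"))
}
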