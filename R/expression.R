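#' Expression layer container
#'
#' A light S3 container for one RNA class's gene-by-sample expression matrix.
#' Values are expected on the log2(x + 1) scale once `is_log2` is `TRUE`;
#' linear-scale matrices (e.g. RPKM/RPM) carry `is_log2 = FALSE` until
#' [log2_transform()] is applied.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimnames must be set, unique, and non-empty.
#' @param layer_class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @param is_log2 logical flag; `TRUE` if `values` are already log2(x + 1).
#' @return an object of class `expr_layer`.
#' @export
expression_layer <- function(values, layer_class = c("lncRNA", "miRNA", "mRNA"),
                             is_log2 = TRUE) {
  layer_class <- match.arg(layer_class)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in ", layer_class, " layer", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in ", layer_class, " layer", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values in ", layer_class, " layer", call. = FALSE)
  if (any(values < 0))
    stop("negative values in ", layer_class, " layer", call. = FALSE)
  structure(list(values = values, layer_class = layer_class,
                 is_log2 = isTRUE(is_log2)),
            class = "expr_layer")
}

#' @export
print.expr_layer <- function(x, ...) {
  cat(sprintf("<expr_layer: %s> %d genes x %d samples (%s scale)\n",
              x$layer_class, nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "linear"))
  invisible(x)
}

#' @export
dim.expr_layer <- function(x) dim(x$values)

#' Gene and sample identifiers of a layer
#' @param layer an `expr_layer`.
#' @return character vector of identifiers.
#' @export
layer_genes <- function(layer) rownames(layer$values)

#' @rdname layer_genes
#' @export
layer_samples <- function(layer) colnames(layer$values)

# Subset helpers keep the class/flag and never touch surviving values.
subset_layer_samples <- function(layer, sample_ids) {
  missing <- setdiff(sample_ids, layer_samples(layer))
  if (length(missing))
    stop("samples absent from ", layer$layer_class, " layer: ",
         paste(missing, collapse = ", "), call. = FALSE)
  layer$values <- layer$values[, sample_ids, drop = FALSE]
  layer
}

subset_layer_genes <- function(layer, gene_ids) {
  missing <- setdiff(gene_ids, layer_genes(layer))
  if (length(missing))
    stop("genes absent from ", layer$layer_class, " layer: ",
         paste(missing, collapse = ", "), call. = FALSE)
  layer$values <- layer$values[gene_ids, , drop = FALSE]
  layer
}

#' Extract one gene's per-sample expression vector
#' @param layer an `expr_layer`.
#' @param gene_id single gene identifier.
#' @return named numeric vector (names = sample IDs).
#' @export
gene_values <- function(layer, gene_id) {
  if (!gene_id %in% layer_genes(layer))
    stop("gene ", gene_id, " absent from ", layer$layer_class, " layer",
         call. = FALSE)
  layer$values[gene_id, ]
}
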