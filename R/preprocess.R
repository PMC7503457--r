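# Sample/gene filtering: sample matching across layers, tumor-purity
# filtering, log2 transformation, low-expression removal, and the IQR
# variability filter. Filters only drop rows/columns; survivor values are
# never modified.

#' Restrict three layers to their common ordered sample set
#'
#' @param layers list of three [expression_layer()] objects (lncRNA, miRNA,
#'   mRNA in any order).
#' @return list of the three layers restricted to the common samples, in a
#'   single shared order (first layer's order restricted to the
#'   intersection); attribute `n_common` carries the common-sample count.
#' @export
match_samples <- function(layers) {
  if (length(layers) != 3L)
    stop("`layers` must contain exactly three expression layers", call. = FALSE)
  sample_sets <- lapply(layers, layer_samples)
  common <- Reduce(intersect, sample_sets)
  if (length(common) == 0)
    stop("no samples shared across layers: ",
         paste(vapply(layers, function(l) l$layer_class, ""), collapse = ", "),
         call. = FALSE)
  common <- sample_sets[[1]][sample_sets[[1]] %in% common]
  out <- lapply(layers, subset_layer_samples, sample_ids = common)
  names(out) <- names(layers)
  attr(out, "n_common") <- length(common)
  out
}

#' Keep samples with tumor purity strictly above a threshold
#'
#' @param layer an [expression_layer()].
#' @param purity data.frame (`sample_id`, `purity`), e.g. ESTIMATE-style
#'   values in [0, 1]; every sample in `layer` must be present.
#' @param threshold purity cutoff; samples with purity strictly greater are
#'   kept (default 0.8).
#' @return the filtered layer (sample order preserved).
#' @export
filter_by_purity <- function(layer, purity, threshold = 0.8) {
  ids <- layer_samples(layer)
  missing <- setdiff(ids, purity$sample_id)
  if (length(missing))
    stop("samples missing from purity table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pv <- purity$purity[match(ids, purity$sample_id)]
  keep <- ids[pv > threshold]
  if (length(keep) == 0)
    warning("purity filter removed every sample from the ",
            layer$layer_class, " layer")
  layer$values <- layer$values[, keep, drop = FALSE]
  layer
}

#' Log2-transform a linear-scale layer
#'
#' @param layer an [expression_layer()] with `is_log2 = FALSE`.
#' @param pseudocount added before the log (default 1, so 0 maps to 0).
#' @return the transformed layer with `is_log2 = TRUE`.
#' @export
log2_transform <- function(layer, pseudocount = 1) {
  if (isTRUE(layer$is_log2))
    stop("layer is already log2-transformed (is_log2 flag set)", call. = FALSE)
  neg <- which(layer$values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative expression values, e.g. gene ",
         rownames(layer$values)[neg[1, 1]], " sample ",
         colnames(layer$values)[neg[1, 2]], call. = FALSE)
  layer$values <- log2(layer$values + pseudocount)
  layer$is_log2 <- TRUE
  layer
}

#' Remove genes that are lowly expressed in most samples
#'
#' Drops genes whose fraction of samples with log2 value below `min_log2`
#' is strictly greater than `max_fraction_below`.
#'
#' @param layer a log2-scale [expression_layer()].
#' @param min_log2 low-expression cutoff on the log2 scale (default 1).
#' @param max_fraction_below tolerated fraction of low samples (default 0.7).
#' @return the filtered layer.
#' @export
filter_low_expression <- function(layer, min_log2 = 1,
                                  max_fraction_below = 0.7) {
  if (!isTRUE(layer$is_log2))
    stop("filter_low_expression expects a log2-scale layer", call. = FALSE)
  frac_below <- rowMeans(layer$values < min_log2)
  keep <- frac_below <= max_fraction_below
  if (!any(keep))
    warning("low-expression filter removed every gene from the ",
            layer$layer_class, " layer")
  layer$values <- layer$values[keep, , drop = FALSE]
  layer
}

#' Keep genes with sufficient expression variability
#'
#' Retains genes whose interquartile range of log2 values is strictly greater
#' than `min_iqr`. Quantiles use linear interpolation between order statistics
#' (type-7 convention).
#'
#' @param layer a log2-scale [expression_layer()].
#' @param min_iqr IQR cutoff (default 0.58).
#' @return the filtered layer.
#' @export
filter_by_iqr <- function(layer, min_iqr = 0.58) {
  if (!isTRUE(layer$is_log2))
    stop("filter_by_iqr expects a log2-scale layer", call. = FALSE)
  iqr <- apply(layer$values, 1, stats::IQR, type = 7)
  keep <- iqr > min_iqr
  if (!any(keep))
    warning("IQR filter removed every gene from the ",
            layer$layer_class, " layer")
  layer$values <- layer$values[keep, , drop = FALSE]
  layer
}

#' Run the full preprocessing chain over three layers
#'
#' Order: sample matching, purity filter, log2 transform (if needed),
#' low-expression filter, IQR filter.
#'
#' @param layers list of three [expression_layer()] objects named `lnc`,
#'   `mir`, `mrna`.
#' @param purity purity table (see [filter_by_purity()]).
#' @param purity_threshold,min_log2,max_fraction_below,min_iqr,pseudocount
#'   filter parameters, defaults as in the individual filters.
#' @return list with the three filtered layers plus a `counts` data.frame of
#'   per-stage sample/gene tallies.
#' @export
preprocess_layers <- function(layers, purity, purity_threshold = 0.8,
                              min_log2 = 1, max_fraction_below = 0.7,
                              min_iqr = 0.58, pseudocount = 1) {
  stopifnot(all(c("lnc", "mir", "mrna") %in% names(layers)))
  layers <- match_samples(layers[c("lnc", "mir", "mrna")])
  n_matched <- attr(layers, "n_common")
  layers <- lapply(layers, filter_by_purity, purity = purity,
                   threshold = purity_threshold)
  n_pure <- ncol(layers$lnc$values)
  layers <- lapply(layers, function(l)
    if (isTRUE(l$is_log2)) l else log2_transform(l, pseudocount))
  genes_in <- vapply(layers, function(l) nrow(l$values), 0L)
  layers <- lapply(layers, filter_low_expression, min_log2 = min_log2,
                   max_fraction_below = max_fraction_below)
  genes_expr <- vapply(layers, function(l) nrow(l$values), 0L)
  layers <- lapply(layers, filter_by_iqr, min_iqr = min_iqr)
  genes_iqr <- vapply(layers, function(l) nrow(l$values), 0L)
  counts <- data.frame(
    stage = c("matched_samples", "purity_samples",
              "genes_in", "genes_after_low_expression", "genes_after_iqr"),
    lnc = c(n_matched, n_pure, genes_in[["lnc"]], genes_expr[["lnc"]],
            genes_iqr[["lnc"]]),
    mir = c(n_matched, n_pure, genes_in[["mir"]], genes_expr[["mir"]],
            genes_iqr[["mir"]]),
    mrna = c(n_matched, n_pure, genes_in[["mrna"]], genes_expr[["mrna"]],
             genes_iqr[["mrna"]]),
    stringsAsFactors = FALSE)
  list(lnc = layers$lnc, mir = layers$mir, mrna = layers$mrna, counts = counts)
}
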