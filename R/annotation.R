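# Descriptive annotation layers: exon-averaged conservation scores,
# group comparison, tumor-vs-normal differential expression and
# copy-number/mutation frequency summaries.

#' Read gene models from BED12 or GTF
#'
#' @param path BED12 (blocks = exons) or GTF (exon features grouped by
#'   `gene_id`) file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return a [GenomicRanges::GRangesList] of exons, one element per gene.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ex <- rtracklayer::blocks(gr)
    names(ex) <- gr$name
    ex
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    GenomicRanges::split(gr, gr$gene_id)
  }
}

#' Read a per-base conservation score track
#'
#' @param path bedGraph or wiggle file with scores in [0, 1]
#'   (phastCons-style).
#' @return a [GenomicRanges::GRanges] with a `score` column.
#' @export
read_score_track <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("wig", "wiggle")) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (any(gr$score < 0 | gr$score > 1))
    stop("conservation scores must lie in [0, 1]: ", path, call. = FALSE)
  gr
}

#' Mean conservation score over a gene's exons
#'
#' Averages per-base scores over the union of exon intervals (overlapping
#' exons counted once); bases absent from the track are excluded from the
#' denominator.
#'
#' @param exons a [GenomicRanges::GRanges] of one gene's exons (any transcript
#'   mix; they are reduced to their union).
#' @param track score track from [read_score_track()].
#' @return the mean score, or `NA` if no exon base is covered.
#' @export
exon_conservation <- function(exons, track) {
  red <- GenomicRanges::reduce(exons)
  if (!any(as.character(GenomicRanges::seqnames(red)) %in%
             as.character(GenomicRanges::seqnames(track)))) {
    warning("chromosome(s) absent from score track: ",
            paste(unique(as.character(GenomicRanges::seqnames(red))),
                  collapse = ", "))
    return(NA_real_)
  }
  hits <- GenomicRanges::findOverlaps(red, track)
  if (length(hits) == 0) return(NA_real_)
  pieces <- GenomicRanges::pintersect(red[S4Vectors::queryHits(hits)],
                                      track[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(pieces)
  sc <- track$score[S4Vectors::subjectHits(hits)]
  sum(sc * w) / sum(w)
}

#' Exon-averaged conservation for every gene in a model set
#' @param models a `GRangesList` from [read_gene_models()].
#' @param track score track.
#' @return named numeric vector of per-gene means.
#' @export
conservation_by_gene <- function(models, track) {
  out <- vapply(seq_along(models),
                function(i) exon_conservation(models[[i]], track), numeric(1))
  stats::setNames(out, names(models))
}

#' Compare conservation between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test on per-gene mean conservation scores.
#'
#' @param group_a,group_b numeric vectors of per-gene means.
#' @return list with `p`, `median_a`, `median_b`.
#' @export
conservation_compare <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("conservation_compare: empty group", call. = FALSE)
  # ties fall back to the normal approximation; the exactness warning is
  # expected behaviour, not a data problem
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided")$p.value)
  list(p = p, median_a = stats::median(group_a),
       median_b = stats::median(group_b))
}

#' Tumor-vs-normal differential expression
#'
#' Per-gene two-sided Student's t-test on log2 values, with
#' `log2FC = mean(tumor) - mean(normal)` and BH FDR across genes. Status is
#' `"up"`/`"down"` only when `|log2FC|` strictly exceeds `min_abs_lfc` and
#' the q-value is strictly below `fdr`.
#'
#' @param tumor,normal gene-by-sample numeric matrices (log2 scale) sharing
#'   rownames; each needs at least 2 samples.
#' @param min_abs_lfc log2 fold-change cutoff (default 1).
#' @param fdr FDR cutoff (default 0.05).
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @return data.frame (`gene_id`, `log2fc`, `p`, `q`, `status`).
#' @export
tumor_normal_de <- function(tumor, normal, min_abs_lfc = 1, fdr = 0.05,
                            var_equal = TRUE) {
  if (ncol(tumor) < 2 || ncol(normal) < 2)
    stop("tumor_normal_de: each condition needs at least 2 samples",
         call. = FALSE)
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor_normal_de: matrices must share rownames", call. = FALSE)
  lfc <- rowMeans(tumor) - rowMeans(normal)
  p <- vapply(seq_len(nrow(tumor)), function(i) {
    if (stats::sd(tumor[i, ]) == 0 && stats::sd(normal[i, ]) == 0)
      return(NA_real_)
    stats::t.test(tumor[i, ], normal[i, ], var.equal = var_equal)$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  status <- rep("ns", length(p))
  sig <- ok & q < fdr & abs(lfc) > min_abs_lfc
  status[sig & lfc > 0] <- "up"
  status[sig & lfc < 0] <- "down"
  data.frame(gene_id = rownames(tumor), log2fc = unname(lfc), p = p, q = q,
             status = status, stringsAsFactors = FALSE)
}

#' Fraction of samples with a somatic copy-number alteration
#'
#' @param cn_calls gene-by-sample integer matrix of thresholded states in
#'   {-2, -1, 0, 1, 2} (GISTIC-style).
#' @param gene_id gene to summarize.
#' @return fraction of samples with a nonzero state (amplifications and
#'   deletions count jointly).
#' @export
scna_frequency <- function(cn_calls, gene_id) {
  if (!gene_id %in% rownames(cn_calls))
    stop("unknown gene: ", gene_id, call. = FALSE)
  states <- cn_calls[gene_id, ]
  if (!all(states %in% -2:2))
    stop("copy-number states must lie in {-2,...,2}", call. = FALSE)
  mean(states != 0)
}

#' Per-gene SCNA summary with per-direction frequencies
#' @param cn_calls gene-by-sample state matrix as in [scna_frequency()].
#' @return data.frame (`gene_id`, `freq_altered`, `freq_amplified`,
#'   `freq_deleted`).
#' @export
scna_summary <- function(cn_calls) {
  data.frame(gene_id = rownames(cn_calls),
             freq_altered = rowMeans(cn_calls != 0),
             freq_amplified = rowMeans(cn_calls > 0),
             freq_deleted = rowMeans(cn_calls < 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of samples carrying a non-silent mutation in a gene
#'
#' @param mutations data.frame (`gene_id`, `sample_id`, `class`) with class
#'   `"silent"` or `"non_silent"`; multiple records per sample count once.
#' @param gene_id gene to summarize.
#' @param n_samples cohort size (denominator).
#' @return fraction of samples with at least one non-silent record.
#' @export
mutation_frequency <- function(mutations, gene_id, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  hits <- mutations[mutations$gene_id == gene_id &
                      mutations$class == "non_silent", "sample_id"]
  length(unique(hits)) / n_samples
}
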