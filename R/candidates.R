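# Candidate triplet construction: hypergeometric shared-miRNA screen with
# FDR control, followed by the global negative-correlation gate on
# miRNA-mRNA pairs.

#' Hypergeometric test for shared miRNAs between an lncRNA and an mRNA
#'
#' Returns the upper-tail probability
#' \deqn{P = 1 - \sum_{i=0}^{x-1} \binom{L}{i}\binom{N-L}{M-i} / \binom{N}{M}}
#' of observing at least `x` shared miRNAs when the lncRNA interacts with `L`
#' of the `N` background miRNAs and the mRNA with `M`. Binomial coefficients
#' are evaluated in log space.
#'
#' @param L,M counts of miRNAs interacting with the lncRNA and the mRNA.
#' @param x observed shared-miRNA count.
#' @param N background miRNA universe size.
#' @return p-value in [0, 1]; vectorized over its arguments.
#' @export
shared_mirna_test <- function(L, M, x, N) {
  args <- cbind(L = L, M = M, x = x, N = N)
  L <- args[, "L"]; M <- args[, "M"]; x <- args[, "x"]; N <- args[, "N"]
  check <- function(ok, field)
    if (!all(ok)) stop("shared_mirna_test: invalid `", field, "`",
                       call. = FALSE)
  check(N >= 1, "N")
  check(L >= 0 & L <= N, "L")
  check(M >= 0 & M <= N, "M")
  check(x >= 0 & x <= pmin(L, M), "x")
  p <- vapply(seq_along(x), function(k) {
    if (x[k] == 0) return(1)
    i <- 0:(x[k] - 1)
    terms <- exp(lchoose(L[k], i) + lchoose(N[k] - L[k], M[k] - i) -
                   lchoose(N[k], M[k]))
    1 - sum(terms)
  }, numeric(1))
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Build candidate lncRNA-miRNA-mRNA triplets
#'
#' Restricts the interaction table to genes present in the (filtered)
#' expression layers, forms every lncRNA-mRNA pair sharing at least one
#' miRNA, applies the hypergeometric shared-miRNA test with BH FDR over all
#' such pairs, and fans each passing pair out into one candidate per shared
#' miRNA.
#'
#' @param interactions data.frame (`mirna_id`, `target_id`, `target_class`).
#' @param layers list with `lnc`, `mir`, `mrna` [expression_layer()] objects.
#' @param fdr_threshold keep pairs with q strictly below this (default 0.05).
#' @param universe `"expressed"` restricts the miRNA background to miRNAs in
#'   the filtered miRNA layer; `"all"` uses every miRNA in the interaction
#'   table.
#' @return data.frame of candidates: `lnc_id`, `mir_id`, `mrna_id`, `L`, `M`,
#'   `x`, `p_hyper`, `q_hyper` (plus `scc_global`/`scc_p` slots filled by
#'   [negative_pair_filter()]).
#' @export
build_candidates <- function(interactions, layers, fdr_threshold = 0.05,
                             universe = c("expressed", "all")) {
  universe <- match.arg(universe)
  if (is.null(interactions) || nrow(interactions) == 0)
    stop("empty interaction set", call. = FALSE)
  pairs <- unique(interactions[, c("mirna_id", "target_id", "target_class")])
  pairs <- pairs[(pairs$target_class == "lncRNA" &
                    pairs$target_id %in% layer_genes(layers$lnc)) |
                   (pairs$target_class == "mRNA" &
                      pairs$target_id %in% layer_genes(layers$mrna)), ,
                 drop = FALSE]
  if (universe == "expressed")
    pairs <- pairs[pairs$mirna_id %in% layer_genes(layers$mir), , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("no interactions remain after restricting to expressed genes",
         call. = FALSE)
  N <- length(unique(pairs$mirna_id))
  lnc_pairs <- pairs[pairs$target_class == "lncRNA", c("mirna_id", "target_id")]
  mrna_pairs <- pairs[pairs$target_class == "mRNA", c("mirna_id", "target_id")]
  names(lnc_pairs) <- c("mir_id", "lnc_id")
  names(mrna_pairs) <- c("mir_id", "mrna_id")
  L_map <- table(lnc_pairs$lnc_id)
  M_map <- table(mrna_pairs$mrna_id)
  shared <- merge(lnc_pairs, mrna_pairs, by = "mir_id")
  if (nrow(shared) == 0)
    return(data.frame(lnc_id = character(0), mir_id = character(0),
                      mrna_id = character(0), L = integer(0), M = integer(0),
                      x = integer(0), p_hyper = numeric(0),
                      q_hyper = numeric(0), stringsAsFactors = FALSE))
  key <- paste(shared$lnc_id, shared$mrna_id, sep = "\r")
  x_map <- table(key)
  tested <- data.frame(key = names(x_map), x = as.integer(x_map),
                       stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(tested$key, "\r", fixed = TRUE))
  tested$lnc_id <- parts[, 1]
  tested$mrna_id <- parts[, 2]
  tested$L <- as.integer(L_map[tested$lnc_id])
  tested$M <- as.integer(M_map[tested$mrna_id])
  tested$p_hyper <- shared_mirna_test(tested$L, tested$M, tested$x, N)
  tested$q_hyper <- bh_fdr(tested$p_hyper)
  keep <- tested[tested$q_hyper < fdr_threshold, , drop = FALSE]
  out <- merge(shared, keep[, c("lnc_id", "mrna_id", "L", "M", "x",
                                "p_hyper", "q_hyper")],
               by = c("lnc_id", "mrna_id"))
  out <- out[order(out$lnc_id, out$mrna_id, out$mir_id),
             c("lnc_id", "mir_id", "mrna_id", "L", "M", "x",
               "p_hyper", "q_hyper")]
  rownames(out) <- NULL
  out
}

#' Keep candidates whose miRNA-mRNA pair is globally negatively correlated
#'
#' Computes the all-sample Spearman correlation for each candidate's
#' miRNA-mRNA pair and keeps candidates with R < 0 and correlation p < alpha.
#' Candidates whose correlation is undefined (constant vector) are dropped
#' with a warning.
#'
#' @param candidates data.frame from [build_candidates()].
#' @param layers list with `mir` and `mrna` [expression_layer()] objects
#'   sharing one sample order.
#' @param alpha significance cutoff for the correlation p-value (default 0.05).
#' @return the filtered candidates with `scc_global` and `scc_p` filled in.
#' @export
negative_pair_filter <- function(candidates, layers, alpha = 0.05) {
  if (nrow(candidates) == 0) {
    candidates$scc_global <- numeric(0)
    candidates$scc_p <- numeric(0)
    return(candidates)
  }
  missing_mir <- setdiff(unique(candidates$mir_id), layer_genes(layers$mir))
  missing_mrna <- setdiff(unique(candidates$mrna_id), layer_genes(layers$mrna))
  if (length(missing_mir) || length(missing_mrna))
    stop("candidate genes absent from layers: ",
         paste(c(missing_mir, missing_mrna), collapse = ", "), call. = FALSE)
  pair_key <- paste(candidates$mir_id, candidates$mrna_id, sep = "\r")
  uniq <- !duplicated(pair_key)
  stats_map <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    st <- spearman_test(gene_values(layers$mir, candidates$mir_id[i]),
                        gene_values(layers$mrna, candidates$mrna_id[i]))
    assign(pair_key[i], st, envir = stats_map)
  }
  rs <- vapply(pair_key, function(k) get(k, envir = stats_map)$r, numeric(1))
  ps <- vapply(pair_key, function(k) get(k, envir = stats_map)$p, numeric(1))
  candidates$scc_global <- unname(rs)
  candidates$scc_p <- unname(ps)
  undef <- is.na(candidates$scc_global)
  if (any(undef))
    warning(sum(undef), " candidate(s) dropped: undefined Spearman ",
            "correlation (constant expression)")
  keep <- !undef & candidates$scc_global < 0 & candidates$scc_p < alpha
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
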