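# The core rewiring statistic: quartile stratification by lncRNA expression,
# directional differential-expression gates, within-stratum Spearman
# correlations, the Fisher-z rewiring score, and permutation p-values.

#' Split samples into high/low groups by lncRNA expression
#'
#' Samples are sorted by decreasing expression (ties broken by sample-ID
#' lexicographic order for reproducibility); the top `floor(fraction * n)`
#' form the H-group and the bottom `floor(fraction * n)` the L-group.
#'
#' @param lnc_values named per-sample numeric vector.
#' @param fraction group fraction (default 0.25, i.e. quartiles).
#' @param lnc_id optional identifier stored in the result.
#' @return a `group_split` list: `h_samples`, `l_samples`, `n_high`, `n_low`.
#' @export
split_groups <- function(lnc_values, fraction = 0.25, lnc_id = NULL) {
  n <- length(lnc_values)
  if (is.null(names(lnc_values)))
    stop("`lnc_values` must carry sample names", call. = FALSE)
  k <- floor(fraction * n)
  if (n < 16 || k < 4)
    stop("too few samples to form quartile groups (n = ", n, ")",
         call. = FALSE)
  if (length(unique(lnc_values)) == 1L)
    warning("all lncRNA values equal; groups determined entirely by ",
            "sample-ID tie-break")
  ord <- order(-lnc_values, names(lnc_values))
  ids <- names(lnc_values)[ord]
  structure(list(lnc_id = lnc_id,
                 h_samples = ids[seq_len(k)],
                 l_samples = ids[(n - k + 1):n],
                 n_high = k, n_low = k),
            class = "group_split")
}

#' Directional differential-expression gate between the H- and L-groups
#'
#' Two-sided Student's t-test on log2 values between the groups; the
#' fold-change is the ratio of linear-scale group means (back-transformed as
#' `2^x - pseudocount`), oriented so that values above 1 agree with the
#' stated direction. Passing requires p < alpha, fold-change strictly above
#' `min_fc`, and the correct direction.
#'
#' @param values named per-sample numeric vector on the log2 scale.
#' @param split a [split_groups()] result.
#' @param direction `"down_in_H"` (expected for miRNAs) or `"up_in_H"`
#'   (expected for mRNAs).
#' @param alpha significance cutoff (default 0.05).
#' @param min_fc fold-change cutoff on the linear scale (default 1.5).
#' @param pseudocount back-transform offset (default 1).
#' @param var_equal use the pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives the Welch variant.
#' @return list with `pass`, `p`, `fc`.
#' @export
group_de_gate <- function(values, split, direction = c("down_in_H", "up_in_H"),
                          alpha = 0.05, min_fc = 1.5, pseudocount = 1,
                          var_equal = TRUE) {
  direction <- match.arg(direction)
  vh <- values[split$h_samples]
  vl <- values[split$l_samples]
  if (any(is.na(vh)) || any(is.na(vl)))
    stop("values missing for some split samples", call. = FALSE)
  if (stats::sd(vh) == 0 && stats::sd(vl) == 0) {
    warning("zero within-group variance in both groups; DE test undefined")
    return(list(pass = FALSE, p = NA_real_, fc = NA_real_))
  }
  p <- stats::t.test(vh, vl, var.equal = var_equal)$p.value
  lin_h <- mean(pmax(2^vh - pseudocount, 0))
  lin_l <- mean(pmax(2^vl - pseudocount, 0))
  fc <- if (direction == "up_in_H") lin_h / lin_l else lin_l / lin_h
  pass <- is.finite(p) && p < alpha && !is.na(fc) && fc > min_fc
  list(pass = pass, p = p, fc = fc)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `F(R) = 0.5 * ln((1 + R) / (1 - R))`.
#'
#' @param R correlation in (-1, 1).
#' @param clip if `TRUE`, values with |R| >= 1 are clipped to 1 - 1e-12 in
#'   magnitude instead of raising an error (off by default).
#' @return the transformed value; vectorized.
#' @export
fisher_z <- function(R, clip = FALSE) {
  if (any(!is.finite(R)))
    stop("fisher_z: R must be finite", call. = FALSE)
  if (any(abs(R) >= 1)) {
    if (!clip)
      stop("fisher_z: |R| >= 1 is outside the domain (set clip = TRUE to ",
           "clip at 1 - 1e-12)", call. = FALSE)
    R <- sign(R) * pmin(abs(R), 1 - 1e-12)
  }
  0.5 * log((1 + R) / (1 - R))
}

#' Rewiring score from low/high-group correlations
#'
#' Standardizes the difference of Fisher-transformed correlations by its
#' approximate null standard error `sqrt(1/(n_low - 3) + 1/(n_high - 3))` and
#' maps it through the standard normal CDF, giving a score in (0, 1). With
#' `convention = "corrected"` (default) the score is the CDF at
#' `(F(R_high) - F(R_low)) / SE`, so stronger rewiring (negative coupling
#' relaxing at high lncRNA) gives larger scores; `"literal"` returns the CDF
#' at the negated statistic (the two conventions sum to 1).
#'
#' @param R_low,R_high within-group Spearman correlations, each in (-1, 1).
#' @param n_low,n_high group sizes, both > 3.
#' @param convention `"corrected"` or `"literal"`.
#' @param clip clip |R| at 1 - 1e-12 instead of erroring (default `FALSE`).
#' @return the score in (0, 1).
#' @export
rewiring_score <- function(R_low, R_high, n_low, n_high,
                           convention = c("corrected", "literal"),
                           clip = FALSE) {
  convention <- match.arg(convention)
  if (n_low <= 3 || n_high <= 3)
    stop("rewiring_score: group sizes must exceed 3", call. = FALSE)
  z <- (fisher_z(R_high, clip = clip) - fisher_z(R_low, clip = clip)) /
    sqrt(1 / (n_low - 3) + 1 / (n_high - 3))
  if (convention == "corrected") stats::pnorm(z) else stats::pnorm(-z)
}

# Internal scoring with clipping always on: inside the permutation loop a
# random small group can be perfectly monotone, which must not abort a run.
score_from_groups <- function(mir, mrna, h_idx, l_idx, convention) {
  r_low <- spearman_r(mir[l_idx], mrna[l_idx])
  r_high <- spearman_r(mir[h_idx], mrna[h_idx])
  if (is.na(r_low) || is.na(r_high)) return(NA_real_)
  rewiring_score(r_low, r_high, length(l_idx), length(h_idx),
                 convention = convention, clip = TRUE)
}

#' Permutation p-value for an observed rewiring score
#'
#' Each replicate draws a uniformly random disjoint (H, L) pair of size
#' `floor(fraction * n_total)` (equivalent to re-sorting samples by a random
#' lncRNA), recomputes the within-group correlations and the rewiring score,
#' and counts replicates whose score strictly exceeds the observed score.
#'
#' @param mir_values,mrna_values per-sample numeric vectors.
#' @param observed observed rewiring score in [0, 1].
#' @param n_total total sample count (defaults to `length(mir_values)`).
#' @param fraction group fraction (default 0.25).
#' @param m number of replicates (default 100).
#' @param seed integer seed for the replicate stream.
#' @param convention score convention, as in [rewiring_score()].
#' @param add_one if `TRUE`, use the add-one estimator
#'   `(n_exceed + 1) / (m + 1)` instead of the plain `n_exceed / m`.
#' @return list with `p_perm` and `n_exceed`.
#' @export
permutation_pvalue <- function(mir_values, mrna_values, observed,
                               n_total = length(mir_values), fraction = 0.25,
                               m = 100L, seed = 1L,
                               convention = c("corrected", "literal"),
                               add_one = FALSE) {
  convention <- match.arg(convention)
  if (m < 1) stop("permutation_pvalue: m must be >= 1", call. = FALSE)
  if (!is.finite(observed) || observed < 0 || observed > 1)
    stop("permutation_pvalue: observed score must lie in [0, 1]",
         call. = FALSE)
  k <- floor(fraction * n_total)
  if (k < 4) stop("permutation_pvalue: groups too small (k = ", k, ")",
                  call. = FALSE)
  set.seed(seed)
  scores <- vapply(seq_len(m), function(j) {
    idx <- sample.int(n_total)
    score_from_groups(mir_values, mrna_values,
                      idx[seq_len(k)], idx[(n_total - k + 1):n_total],
                      convention)
  }, numeric(1))
  n_exceed <- sum(scores > observed, na.rm = TRUE)
  p <- if (add_one) (n_exceed + 1) / (m + 1) else n_exceed / m
  list(p_perm = p, n_exceed = n_exceed)
}

#' Detect lncRNA-perturbated triplets among candidates
#'
#' For every candidate triplet: split samples into quartile H/L groups by the
#' lncRNA, apply the directional DE gates (miRNA down in H, mRNA up in H),
#' compute within-group Spearman correlations, require
#' `R_low < rlow_max`, `R_high >= R_low` and `|R_low - R_high| > min_delta_r`,
#' compute the rewiring score and its permutation p-value, and flag triplets
#' passing every gate with `p_perm < perm_alpha`. All candidates are reported
#' with their per-gate flags. Each triplet draws its permutation stream from
#' a seed derived from the master seed and the triplet identifiers, so
#' results do not depend on evaluation order.
#'
#' @param candidates data.frame with `lnc_id`, `mir_id`, `mrna_id` columns
#'   (typically from [negative_pair_filter()]).
#' @param layers list with `lnc`, `mir`, `mrna` [expression_layer()] objects
#'   sharing one ordered sample set.
#' @param fraction quartile fraction (default 0.25).
#' @param de_alpha,min_fc DE-gate parameters (defaults 0.05 and 1.5).
#' @param rlow_max upper bound on `R_low` (default -0.4).
#' @param min_delta_r minimum `|R_low - R_high|` (default 0.3).
#' @param n_perm permutation replicates per triplet (default 100).
#' @param perm_alpha permutation significance cutoff (default 0.01).
#' @param convention rewiring-score convention (default `"corrected"`).
#' @param seed master seed.
#' @param var_equal,pseudocount,add_one passed to the component operations.
#' @return data.frame with one row per candidate carrying group sizes, DE
#'   gate results, `r_low`, `r_high`, `f_low`, `f_high`, `rewiring_score`,
#'   `n_exceed`, `p_perm`, per-gate flags and the overall `passed` flag.
#' @export
detect_triplets <- function(candidates, layers, fraction = 0.25,
                            de_alpha = 0.05, min_fc = 1.5, rlow_max = -0.4,
                            min_delta_r = 0.3, n_perm = 100L,
                            perm_alpha = 0.01,
                            convention = c("corrected", "literal"),
                            seed = 1L, var_equal = TRUE, pseudocount = 1,
                            add_one = FALSE) {
  convention <- match.arg(convention)
  n_cand <- nrow(candidates)
  samples <- layer_samples(layers$lnc)
  if (!identical(samples, layer_samples(layers$mir)) ||
      !identical(samples, layer_samples(layers$mrna)))
    stop("layers must share one ordered sample set (run match_samples first)",
         call. = FALSE)
  splits <- new.env(parent = emptyenv())
  res <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    lnc_id <- candidates$lnc_id[i]
    mir_id <- candidates$mir_id[i]
    mrna_id <- candidates$mrna_id[i]
    if (is.null(splits[[lnc_id]]))
      splits[[lnc_id]] <- split_groups(gene_values(layers$lnc, lnc_id),
                                       fraction, lnc_id = lnc_id)
    sp <- splits[[lnc_id]]
    mirv <- gene_values(layers$mir, mir_id)
    mrnav <- gene_values(layers$mrna, mrna_id)
    de_mir <- group_de_gate(mirv, sp, "down_in_H", alpha = de_alpha,
                            min_fc = min_fc, pseudocount = pseudocount,
                            var_equal = var_equal)
    de_mrna <- group_de_gate(mrnav, sp, "up_in_H", alpha = de_alpha,
                             min_fc = min_fc, pseudocount = pseudocount,
                             var_equal = var_equal)
    r_low <- spearman_r(mirv[sp$l_samples], mrnav[sp$l_samples])
    r_high <- spearman_r(mirv[sp$h_samples], mrnav[sp$h_samples])
    corr_defined <- !is.na(r_low) && !is.na(r_high)
    corr_pass <- corr_defined && r_low < rlow_max && r_high >= r_low &&
      abs(r_low - r_high) > min_delta_r
    if (corr_defined) {
      score <- rewiring_score(r_low, r_high, sp$n_low, sp$n_high,
                              convention = convention, clip = TRUE)
      f_low <- fisher_z(r_low, clip = TRUE)
      f_high <- fisher_z(r_high, clip = TRUE)
      perm <- permutation_pvalue(
        mirv, mrnav, score, n_total = length(samples), fraction = fraction,
        m = n_perm, seed = derive_seed(seed, paste(lnc_id, mir_id, mrna_id)),
        convention = convention, add_one = add_one)
      p_perm <- perm$p_perm
      n_exceed <- perm$n_exceed
    } else {
      score <- f_low <- f_high <- p_perm <- NA_real_
      n_exceed <- NA_integer_
    }
    passed <- isTRUE(de_mir$pass) && isTRUE(de_mrna$pass) && corr_pass &&
      !is.na(p_perm) && p_perm < perm_alpha
    res[[i]] <- data.frame(
      lnc_id = lnc_id, mir_id = mir_id, mrna_id = mrna_id,
      n_high = sp$n_high, n_low = sp$n_low,
      de_pass_mir = de_mir$pass, de_p_mir = de_mir$p, de_fc_mir = de_mir$fc,
      de_pass_mrna = de_mrna$pass, de_p_mrna = de_mrna$p,
      de_fc_mrna = de_mrna$fc,
      r_low = r_low, r_high = r_high, f_low = f_low, f_high = f_high,
      rewiring_score = score, n_perm = as.integer(n_perm),
      n_exceed = n_exceed, p_perm = p_perm,
      corr_pass = corr_pass, passed = passed,
      stringsAsFactors = FALSE)
  }
  out <- if (n_cand) do.call(rbind, res) else data.frame(
    lnc_id = character(0), mir_id = character(0), mrna_id = character(0),
    n_high = integer(0), n_low = integer(0), de_pass_mir = logical(0),
    de_p_mir = numeric(0), de_fc_mir = numeric(0), de_pass_mrna = logical(0),
    de_p_mrna = numeric(0), de_fc_mrna = numeric(0), r_low = numeric(0),
    r_high = numeric(0), f_low = numeric(0), f_high = numeric(0),
    rewiring_score = numeric(0), n_perm = integer(0), n_exceed = integer(0),
    p_perm = numeric(0), corr_pass = logical(0), passed = logical(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
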