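# Triplet prognosis: per-element Cox association, the linear triplet risk
# score, mean-split risk grouping, log-rank testing, Kaplan-Meier export and
# the "functions together" classification.

surv_object <- function(clinical, sample_ids) {
  missing <- setdiff(sample_ids, clinical$sample_id)
  if (length(missing))
    stop("samples missing from clinical table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cl <- clinical[match(sample_ids, clinical$sample_id), ]
  survival::Surv(cl$time, cl$event)
}

#' Univariate Cox association of one gene's expression with survival
#'
#' @param expr named per-sample numeric vector (log2 expression).
#' @param clinical data.frame (`sample_id`, `time`, `event`).
#' @return list with `coefficient`, `se`, `p` (Wald) and `classification`
#'   (`"risk"` if the coefficient is positive, else `"protective"`).
#' @export
element_cox <- function(expr, clinical) {
  if (stats::sd(expr) == 0)
    stop("element_cox: constant expression vector", call. = FALSE)
  y <- surv_object(clinical, names(expr))
  if (sum(y[, "status"]) < 2)
    stop("element_cox: fewer than 2 events", call. = FALSE)
  fit <- survival::coxph(y ~ expr, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  s <- summary(fit)
  co <- unname(s$coefficients[1, "coef"])
  list(coefficient = co,
       se = unname(s$coefficients[1, "se(coef)"]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       classification = if (co > 0) "risk" else "protective")
}

#' Per-sample triplet risk score
#'
#' `risk_i = alpha * lnc_i + beta * mir_i + gamma * mrna_i`, the exact linear
#' combination of the three members' (log2) expression values.
#'
#' @param coeffs length-3 numeric (alpha, beta, gamma).
#' @param exprs list with named per-sample vectors `lnc`, `mir`, `mrna`.
#' @return named numeric vector of risk scores.
#' @export
triplet_risk_score <- function(coeffs, exprs) {
  if (length(coeffs) != 3L || any(!is.finite(coeffs)))
    stop("coefficients must be three finite reals", call. = FALSE)
  ids <- names(exprs$lnc)
  if (is.null(ids) || !identical(ids, names(exprs$mir)) ||
      !identical(ids, names(exprs$mrna)))
    stop("expression vectors must share one named sample set", call. = FALSE)
  scores <- coeffs[1] * exprs$lnc + coeffs[2] * exprs$mir +
    coeffs[3] * exprs$mrna
  names(scores) <- ids
  scores
}

#' Split samples at the mean risk score
#'
#' Scores strictly above the mean are labelled `"high"`, scores at or below
#' the mean `"low"`.
#'
#' @param scores named numeric vector.
#' @return named character vector of `"high"`/`"low"` labels.
#' @export
split_by_mean <- function(scores) {
  if (length(unique(scores)) < 2)
    stop("degenerate split: all scores identical", call. = FALSE)
  labels <- ifelse(scores > mean(scores), "high", "low")
  names(labels) <- names(scores)
  labels
}

#' Two-group log-rank test
#'
#' @param groups named character vector of group labels (two levels).
#' @param clinical data.frame (`sample_id`, `time`, `event`).
#' @return the chi-square log-rank p-value.
#' @export
logrank_test <- function(groups, clinical) {
  if (length(unique(groups)) < 2)
    stop("log-rank test needs two non-empty groups", call. = FALSE)
  y <- surv_object(clinical, names(groups))
  if (sum(y[, "status"]) < 1)
    stop("log-rank test needs at least one event", call. = FALSE)
  g <- factor(groups)
  sd <- survival::survdiff(y ~ g)
  stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
}

#' Kaplan-Meier step-function table per group
#'
#' @param groups named character vector of group labels.
#' @param clinical data.frame (`sample_id`, `time`, `event`).
#' @return data.frame (`group`, `time`, `n_risk`, `n_event`, `surv`).
#' @export
km_table <- function(groups, clinical) {
  y <- surv_object(clinical, names(groups))
  g <- factor(groups)
  fit <- survival::survfit(y ~ g)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), levels(g)[1])
            else fit$strata
  data.frame(group = sub("^g=", "", rep(names(strata), strata)),
             time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Classify a triplet survival signature
#'
#' @param logrank_p log-rank p-value of the mean-split risk groups.
#' @param element_p length-3 numeric of univariate Cox p-values
#'   (lncRNA, miRNA, mRNA).
#' @param alpha significance level (default 0.05).
#' @return `"functions_together"` if the triplet separates survival while no
#'   single member does, `"triplet_significant"` if the triplet separates
#'   survival but at least one member also does, else `"not_significant"`.
#' @export
classify_signature <- function(logrank_p, element_p, alpha = 0.05) {
  if (logrank_p >= alpha) return("not_significant")
  if (all(element_p >= alpha)) "functions_together" else "triplet_significant"
}

#' Fit the full risk model for one triplet
#'
#' Fits the three univariate Cox models (for element p-values and, under
#' `cox_mode = "univariate"`, the risk-score coefficients), obtains
#' (alpha, beta, gamma) from a joint three-covariate Cox fit by default,
#' computes per-sample risk scores, the mean-split grouping, the log-rank
#' p-value and the signature category.
#'
#' @param exprs list with named per-sample vectors `lnc`, `mir`, `mrna`.
#' @param clinical data.frame (`sample_id`, `time`, `event`).
#' @param cox_mode `"joint"` (default) or `"univariate"` coefficient source.
#' @param alpha significance level for classification (default 0.05).
#' @return a `risk_model` list: `coeffs`, `element_p`, `element_class`,
#'   `scores`, `groups`, `logrank_p`, `category`.
#' @export
fit_risk_model <- function(exprs, clinical,
                           cox_mode = c("joint", "univariate"),
                           alpha = 0.05) {
  cox_mode <- match.arg(cox_mode)
  uni <- lapply(exprs[c("lnc", "mir", "mrna")], element_cox,
                clinical = clinical)
  element_p <- vapply(uni, `[[`, numeric(1), "p")
  if (cox_mode == "joint") {
    y <- surv_object(clinical, names(exprs$lnc))
    df <- data.frame(l = exprs$lnc, m = exprs$mir, r = exprs$mrna)
    fit <- survival::coxph(y ~ l + m + r, data = df, ties = "breslow",
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 100))
    coeffs <- unname(stats::coef(fit))
    if (any(!is.finite(coeffs)))
      stop("joint Cox fit did not converge to finite coefficients",
           call. = FALSE)
  } else {
    coeffs <- vapply(uni, `[[`, numeric(1), "coefficient")
  }
  scores <- triplet_risk_score(coeffs, exprs)
  groups <- split_by_mean(scores)
  lr_p <- logrank_test(groups, clinical)
  structure(list(coeffs = setNames(coeffs, c("alpha", "beta", "gamma")),
                 element_p = setNames(element_p, c("lnc", "mir", "mrna")),
                 element_class = vapply(uni, `[[`, character(1),
                                        "classification"),
                 scores = scores, groups = groups, logrank_p = lr_p,
                 category = classify_signature(lr_p, element_p, alpha)),
            class = "risk_model")
}

#' Prognosis screen over a table of triplets
#'
#' @param triplets data.frame with `lnc_id`, `mir_id`, `mrna_id`.
#' @param layers list with `lnc`, `mir`, `mrna` [expression_layer()] objects.
#' @param clinical data.frame (`sample_id`, `time`, `event`); restricted to
#'   the layers' samples.
#' @param cox_mode,alpha passed to [fit_risk_model()].
#' @return data.frame with coefficients, element p-values, log-rank p and
#'   category per triplet.
#' @export
triplet_prognosis <- function(triplets, layers, clinical,
                              cox_mode = c("joint", "univariate"),
                              alpha = 0.05) {
  cox_mode <- match.arg(cox_mode)
  out <- vector("list", nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    exprs <- list(lnc = gene_values(layers$lnc, triplets$lnc_id[i]),
                  mir = gene_values(layers$mir, triplets$mir_id[i]),
                  mrna = gene_values(layers$mrna, triplets$mrna_id[i]))
    rm_ <- fit_risk_model(exprs, clinical, cox_mode = cox_mode, alpha = alpha)
    out[[i]] <- data.frame(
      lnc_id = triplets$lnc_id[i], mir_id = triplets$mir_id[i],
      mrna_id = triplets$mrna_id[i],
      alpha = rm_$coeffs[["alpha"]], beta = rm_$coeffs[["beta"]],
      gamma = rm_$coeffs[["gamma"]],
      p_lnc = rm_$element_p[["lnc"]], p_mir = rm_$element_p[["mir"]],
      p_mrna = rm_$element_p[["mrna"]],
      logrank_p = rm_$logrank_p, category = rm_$category,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    lnc_id = character(0), mir_id = character(0), mrna_id = character(0),
    alpha = numeric(0), beta = numeric(0), gamma = numeric(0),
    p_lnc = numeric(0), p_mir = numeric(0), p_mrna = numeric(0),
    logrank_p = numeric(0), category = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Single-gene survival signature via mean split
#'
#' @param expr named per-sample numeric vector.
#' @param clinical data.frame (`sample_id`, `time`, `event`).
#' @return list with `p` (log-rank), `groups` and `km` (the Kaplan-Meier
#'   step table).
#' @export
single_gene_signature <- function(expr, clinical) {
  groups <- split_by_mean(expr)
  list(p = logrank_test(groups, clinical), groups = groups,
       km = km_table(groups, clinical))
}
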