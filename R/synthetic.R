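#' Configuration for the synthetic cohort generator
#'
#' The generator plants lncRNA-perturbated triplets among independent decoys.
#' For a planted triplet the miRNA is drawn with negative dependence on the
#' lncRNA (Gaussian copula, rank correlation `mir_lnc_rho`), and the mRNA
#' follows `intercept + c(l) * miRNA + noise` where the slope `c(l)`
#' interpolates linearly in the lncRNA's within-cohort quantile from
#' `coupling_low` (lowest quartile) to `coupling_high` (highest quartile),
#' with plateaus inside the two extreme quartiles. All abundances are
#' generated directly on the log2(x + 1) scale.
#'
#' @param n_samples number of samples (>= 32 so quartile groups keep n - 3 > 0).
#' @param n_planted number of planted triplets.
#' @param n_decoy_lnc,n_decoy_mir,n_decoy_mrna decoy gene counts per class;
#'   the first `min` of the three counts are wired into decoy triplets in the
#'   interaction table.
#' @param coupling_low negative miRNA-to-mRNA slope in the low-lncRNA regime.
#' @param coupling_high slope in the high-lncRNA regime; must be smaller in
#'   magnitude than `coupling_low`.
#' @param noise_sd residual standard deviation of the planted mRNA (log2 units).
#' @param base_expression_mean,base_expression_sd marginal mean/sd of log2
#'   abundances.
#' @param mir_lnc_rho magnitude of the negative lncRNA-miRNA rank correlation
#'   for planted triplets.
#' @param purity_mean,purity_sd parameters of the truncated-normal (on (0,1))
#'   tumor purity distribution.
#' @param survival_coeffs length-3 numeric (alpha, beta, gamma): Cox linear
#'   predictor weights for the first planted triplet's lncRNA/miRNA/mRNA.
#' @param censor_rate expected fraction of censored samples, in [0, 1].
#' @param emit_linear if `TRUE`, layers are emitted on the linear scale
#'   (2^x - 1) with `is_log2 = FALSE`, to exercise the log transform.
#' @param seed integer master seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_samples = 400L,
                             n_planted = 20L,
                             n_decoy_lnc = 500L,
                             n_decoy_mir = 500L,
                             n_decoy_mrna = 500L,
                             coupling_low = -0.9,
                             coupling_high = 0,
                             noise_sd = 0.5,
                             base_expression_mean = 7,
                             base_expression_sd = 1.5,
                             mir_lnc_rho = 0.7,
                             purity_mean = 0.9,
                             purity_sd = 0.04,
                             survival_coeffs = c(1, -1, 0.5),
                             censor_rate = 0.3,
                             emit_linear = FALSE,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_planted = as.integer(n_planted),
              n_decoy_lnc = as.integer(n_decoy_lnc),
              n_decoy_mir = as.integer(n_decoy_mir),
              n_decoy_mrna = as.integer(n_decoy_mrna),
              coupling_low = coupling_low, coupling_high = coupling_high,
              noise_sd = noise_sd,
              base_expression_mean = base_expression_mean,
              base_expression_sd = base_expression_sd,
              mir_lnc_rho = mir_lnc_rho,
              purity_mean = purity_mean, purity_sd = purity_sd,
              survival_coeffs = as.numeric(survival_coeffs),
              censor_rate = censor_rate,
              emit_linear = isTRUE(emit_linear),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) stop("invalid generator configuration: `", field,
                                   "` ", why, call. = FALSE)
  if (cfg$n_samples < 32L) bad("n_samples", "must be >= 32")
  if (cfg$n_planted < 0L) bad("n_planted", "must be >= 0")
  for (f in c("n_decoy_lnc", "n_decoy_mir", "n_decoy_mrna"))
    if (cfg[[f]] < 0L) bad(f, "must be >= 0")
  if (!is.finite(cfg$coupling_low) || cfg$coupling_low >= 0)
    bad("coupling_low", "must be a negative real")
  if (cfg$n_planted > 0L && cfg$coupling_low != cfg$coupling_high &&
      abs(cfg$coupling_high) >= abs(cfg$coupling_low))
    bad("coupling_high", "must be attenuated relative to coupling_low")
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be positive")
  if (cfg$base_expression_sd <= 0) bad("base_expression_sd", "must be positive")
  if (cfg$mir_lnc_rho <= 0 || cfg$mir_lnc_rho >= 1)
    bad("mir_lnc_rho", "must lie in (0, 1)")
  if (cfg$purity_mean <= 0 || cfg$purity_mean >= 1)
    bad("purity_mean", "must lie in (0, 1)")
  if (cfg$purity_sd <= 0) bad("purity_sd", "must be positive")
  if (length(cfg$survival_coeffs) != 3L || any(!is.finite(cfg$survival_coeffs)))
    bad("survival_coeffs", "must be three finite reals")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    bad("censor_rate", "must lie in [0, 1]")
  invisible(cfg)
}

# Truncated normal on (0, 1) by inverse-CDF sampling.
rtrunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Planted coupling slope as a function of the lncRNA's within-cohort quantile:
# coupling_low inside the lowest quartile, coupling_high inside the highest,
# linear in between.
coupling_slope <- function(lnc_values, coupling_low, coupling_high) {
  n <- length(lnc_values)
  q <- (rank(lnc_values, ties.method = "first") - 1) / (n - 1)
  u <- pmin(pmax((q - 0.25) / 0.5, 0), 1)
  coupling_low + u * (coupling_high - coupling_low)
}

#' Generate a synthetic tri-layer cohort with planted perturbated triplets
#'
#' @param config a [generator_config()].
#' @return a `synthetic_cohort`: list with `lnc_layer`, `mir_layer`,
#'   `mrna_layer` ([expression_layer()] objects sharing one ordered sample
#'   set), `interactions`, `purity`, `clinical`, and `truth` (the planted
#'   triplet registry). Deterministic for a fixed seed.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  m0 <- config$base_expression_mean
  s0 <- config$base_expression_sd
  rho <- config$mir_lnc_rho

  np <- config$n_planted
  lnc_p <- mir_p <- mrna_p <- NULL
  if (np > 0) {
    lnc_p <- matrix(0, np, n)
    mir_p <- matrix(0, np, n)
    mrna_p <- matrix(0, np, n)
    for (t in seq_len(np)) {
      zl <- stats::rnorm(n)
      zm <- -rho * zl + sqrt(1 - rho^2) * stats::rnorm(n)
      lnc <- pmax(m0 + s0 * zl, 0)
      mir <- pmax(m0 + s0 * zm, 0)
      cc <- coupling_slope(lnc, config$coupling_low, config$coupling_high)
      mrna <- pmax(m0 + cc * (mir - m0) + stats::rnorm(n, 0, config$noise_sd), 0)
      lnc_p[t, ] <- lnc
      mir_p[t, ] <- mir
      mrna_p[t, ] <- mrna
    }
    rownames(lnc_p) <- sprintf("LNC_P%03d", seq_len(np))
    rownames(mir_p) <- sprintf("MIR_P%03d", seq_len(np))
    rownames(mrna_p) <- sprintf("MRNA_P%03d", seq_len(np))
  }

  decoy_block <- function(k, prefix) {
    if (k == 0) return(NULL)
    m <- matrix(pmax(stats::rnorm(k * n, m0, s0), 0), nrow = k)
    rownames(m) <- sprintf("%s%04d", prefix, seq_len(k))
    m
  }
  lnc_d <- decoy_block(config$n_decoy_lnc, "LNC_D")
  mir_d <- decoy_block(config$n_decoy_mir, "MIR_D")
  mrna_d <- decoy_block(config$n_decoy_mrna, "MRNA_D")

  bind_layer <- function(p, d, cls) {
    m <- rbind(p, d)
    if (is.null(m)) stop("layer ", cls, " would be empty", call. = FALSE)
    colnames(m) <- samples
    if (config$emit_linear)
      expression_layer(pmax(2^m - 1, 0), cls, is_log2 = FALSE)
    else
      expression_layer(m, cls, is_log2 = TRUE)
  }
  lnc_layer <- bind_layer(lnc_p, lnc_d, "lncRNA")
  mir_layer <- bind_layer(mir_p, mir_d, "miRNA")
  mrna_layer <- bind_layer(mrna_p, mrna_d, "mRNA")

  truth <- data.frame(lnc_id = character(0), mir_id = character(0),
                      mrna_id = character(0), stringsAsFactors = FALSE)
  inter <- list()
  if (np > 0) {
    truth <- data.frame(lnc_id = rownames(lnc_p), mir_id = rownames(mir_p),
                        mrna_id = rownames(mrna_p), stringsAsFactors = FALSE)
    inter[[1]] <- data.frame(mirna_id = truth$mir_id, target_id = truth$lnc_id,
                             target_class = "lncRNA", stringsAsFactors = FALSE)
    inter[[2]] <- data.frame(mirna_id = truth$mir_id, target_id = truth$mrna_id,
                             target_class = "mRNA", stringsAsFactors = FALSE)
  }
  nd <- min(config$n_decoy_lnc, config$n_decoy_mir, config$n_decoy_mrna)
  if (nd > 0) {
    dl <- rownames(lnc_d)[seq_len(nd)]
    dm <- rownames(mir_d)[seq_len(nd)]
    dr <- rownames(mrna_d)[seq_len(nd)]
    inter[[length(inter) + 1]] <-
      data.frame(mirna_id = dm, target_id = dl, target_class = "lncRNA",
                 stringsAsFactors = FALSE)
    inter[[length(inter) + 1]] <-
      data.frame(mirna_id = dm, target_id = dr, target_class = "mRNA",
                 stringsAsFactors = FALSE)
  }
  interactions <- if (length(inter)) do.call(rbind, inter) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), stringsAsFactors = FALSE)

  purity <- data.frame(sample_id = samples,
                       purity = rtrunc01(n, config$purity_mean, config$purity_sd),
                       stringsAsFactors = FALSE)

  # Survival driven by the first planted triplet (null linear predictor when
  # nothing is planted), on the log2 scale the pipeline works on.
  if (np > 0) {
    expr3 <- rbind(lnc = lnc_p[1, ], mir = mir_p[1, ], mrna = mrna_p[1, ])
  } else {
    expr3 <- rbind(lnc = rep(0, n), mir = rep(0, n), mrna = rep(0, n))
    colnames(expr3) <- samples
  }
  colnames(expr3) <- samples
  clinical <- generate_survival(expr3, coeffs = config$survival_coeffs,
                                censor_rate = config$censor_rate,
                                seed = derive_seed(config$seed, "survival"))

  structure(list(lnc_layer = lnc_layer, mir_layer = mir_layer,
                 mrna_layer = mrna_layer, interactions = interactions,
                 purity = purity, clinical = clinical, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d samples; %d planted triplets; ",
                     "layers %d/%d/%d genes (lnc/mir/mrna)\n"),
              ncol(x$lnc_layer$values), nrow(x$truth),
              nrow(x$lnc_layer$values), nrow(x$mir_layer$values),
              nrow(x$mrna_layer$values)))
  invisible(x)
}

#' Simulate survival times from a proportional-hazards model
#'
#' Event times are exponential with hazard `h0 * exp(lp)` where the linear
#' predictor is `alpha * lnc + beta * mir + gamma * mrna` (centered). The
#' censoring time is an independent exponential whose rate is calibrated in
#' closed form (`mean(c / (c + h_i)) = censor_rate`) so the expected censored
#' fraction equals `censor_rate`; censoring is therefore non-informative given
#' the covariates.
#'
#' @param expr either a 3-row numeric matrix (rows lncRNA, miRNA, mRNA;
#'   columns samples, with sample colnames) combined via `coeffs`, or a named
#'   numeric vector already holding the per-sample linear predictor.
#' @param coeffs length-3 numeric (alpha, beta, gamma); ignored when `expr`
#'   is a vector.
#' @param censor_rate expected fraction of censored samples, in [0, 1].
#' @param seed integer seed.
#' @param baseline_hazard baseline hazard per day at the average linear
#'   predictor (default: median event time of two years).
#' @return data.frame (`sample_id`, `time`, `event`) with `time` in days.
#' @export
generate_survival <- function(expr, coeffs = c(0, 0, 0), censor_rate = 0,
                              seed = 1L, baseline_hazard = log(2) / 730) {
  if (censor_rate < 0 || censor_rate > 1)
    stop("invalid configuration: `censor_rate` must lie in [0, 1]",
         call. = FALSE)
  if (is.matrix(expr) || is.data.frame(expr)) {
    expr <- as.matrix(expr)
    if (nrow(expr) != 3L)
      stop("`expr` matrix must have 3 rows (lncRNA, miRNA, mRNA)",
           call. = FALSE)
    if (length(coeffs) != 3L || any(!is.finite(coeffs)))
      stop("`coeffs` must be three finite reals", call. = FALSE)
    lp <- as.numeric(coeffs %*% expr)
    ids <- colnames(expr)
  } else {
    lp <- as.numeric(expr)
    ids <- names(expr)
  }
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor", call. = FALSE)
  n <- length(lp)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  set.seed(seed)
  h <- baseline_hazard * exp(lp - mean(lp))
  t_event <- stats::rexp(n) / h
  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else if (censor_rate == 1) {
    time <- t_event
    event <- rep(0L, n)
  } else {
    target <- function(logc) mean(exp(logc) / (exp(logc) + h)) - censor_rate
    logc <- stats::uniroot(target, lower = log(min(h)) - 40,
                           upper = log(max(h)) + 40, tol = 1e-12)$root
    c_time <- stats::rexp(n, rate = exp(logc))
    event <- as.integer(t_event <= c_time)
    time <- pmin(t_event, c_time)
  }
  data.frame(sample_id = ids, time = pmax(time, 1e-8), event = event,
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort as plain tab-separated fixture files
#'
#' Emits the seven files the pipeline readers accept: one matrix per layer,
#' the interaction, purity and clinical tables, and the planted-triplet truth
#' registry.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if needed).
#' @return data.frame manifest (`kind`, `file`, `n_rows`), invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- file.path(directory,
                     c("lnc_expression.tsv", "mir_expression.tsv",
                       "mrna_expression.tsv", "interactions.tsv",
                       "purity.tsv", "clinical.tsv", "truth.tsv"))
  write_expression_matrix(cohort$lnc_layer, paths[1])
  write_expression_matrix(cohort$mir_layer, paths[2])
  write_expression_matrix(cohort$mrna_layer, paths[3])
  write_tsv_plain(cohort$interactions, paths[4])
  write_tsv_plain(cohort$purity, paths[5])
  write_tsv_plain(cohort$clinical, paths[6])
  write_tsv_plain(cohort$truth, paths[7])
  manifest <- data.frame(
    kind = c("lnc_layer", "mir_layer", "mrna_layer", "interactions",
             "purity", "clinical", "truth"),
    file = basename(paths),
    n_rows = c(nrow(cohort$lnc_layer$values), nrow(cohort$mir_layer$values),
               nrow(cohort$mrna_layer$values), nrow(cohort$interactions),
               nrow(cohort$purity), nrow(cohort$clinical), nrow(cohort$truth)),
    stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Read a fixture directory back into a cohort object
#' @param directory directory written by [write_fixture()] (or hand-built in
#'   the same dialect).
#' @param is_log2 whether the stored matrices are log2(x + 1).
#' @return a `synthetic_cohort` (without generator config).
#' @export
read_cohort <- function(directory, is_log2 = TRUE) {
  structure(list(
    lnc_layer = read_expression_matrix(file.path(directory, "lnc_expression.tsv"),
                                       "lncRNA", is_log2),
    mir_layer = read_expression_matrix(file.path(directory, "mir_expression.tsv"),
                                       "miRNA", is_log2),
    mrna_layer = read_expression_matrix(file.path(directory, "mrna_expression.tsv"),
                                        "mRNA", is_log2),
    interactions = read_interaction_table(file.path(directory, "interactions.tsv")),
    purity = read_purity_table(file.path(directory, "purity.tsv")),
    clinical = read_clinical_table(file.path(directory, "clinical.tsv")),
    truth = read_truth_table(file.path(directory, "truth.tsv")),
    config = NULL), class = "synthetic_cohort")
}
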