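# End-to-end orchestration: preprocessing, candidate construction, rewiring
# detection and prognosis, with per-stage record counts and deterministic
# seeding.

#' Build a pipeline run configuration
#'
#' Default thresholds follow the framework's published settings: purity
#' > 0.8, low-expression rule (< 1 log2 in more than 70% of samples),
#' log2 IQR > 0.58, candidate FDR < 0.05, quartile (25%) groups, DE gates at
#' p < 0.05 with fold-change > 1.5, R_low < -0.4, |R_low - R_high| > 0.3,
#' 100 permutations at p < 0.01.
#'
#' @param input_dir directory holding the seven fixture-dialect files (see
#'   [write_fixture()]); alternatively supply a `synthetic_cohort` directly
#'   to [run_pipeline()].
#' @param purity_threshold,min_log2,max_fraction_below,min_iqr,pseudocount
#'   preprocessing parameters.
#' @param fdr_threshold,scc_alpha candidate-screen parameters.
#' @param universe miRNA background (`"expressed"` or `"all"`).
#' @param fraction,de_alpha,min_fc,rlow_max,min_delta_r,n_perm,perm_alpha,convention
#'   detection parameters.
#' @param cox_mode,signature_alpha prognosis parameters.
#' @param already_log2 whether input matrices are already log2(x + 1).
#' @param seed master seed.
#' @param output_dir optional directory; when set, result tables are written
#'   there as tab-separated text.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, purity_threshold = 0.8,
                       min_log2 = 1, max_fraction_below = 0.7,
                       min_iqr = 0.58, pseudocount = 1,
                       fdr_threshold = 0.05, scc_alpha = 0.05,
                       universe = "expressed",
                       fraction = 0.25, de_alpha = 0.05, min_fc = 1.5,
                       rlow_max = -0.4, min_delta_r = 0.3, n_perm = 100L,
                       perm_alpha = 0.01, convention = "corrected",
                       cox_mode = "joint", signature_alpha = 0.05,
                       already_log2 = TRUE, seed = 1L, output_dir = NULL) {
  structure(list(input_dir = input_dir, purity_threshold = purity_threshold,
                 min_log2 = min_log2, max_fraction_below = max_fraction_below,
                 min_iqr = min_iqr, pseudocount = pseudocount,
                 fdr_threshold = fdr_threshold, scc_alpha = scc_alpha,
                 universe = universe, fraction = fraction,
                 de_alpha = de_alpha, min_fc = min_fc, rlow_max = rlow_max,
                 min_delta_r = min_delta_r, n_perm = as.integer(n_perm),
                 perm_alpha = perm_alpha, convention = convention,
                 cox_mode = cox_mode, signature_alpha = signature_alpha,
                 already_log2 = isTRUE(already_log2), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a [run_config()].
#' @return character vector of problems; empty when the configuration is
#'   valid. Content problems never raise.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  bad <- function(msg) problems <<- c(problems, msg)
  in01 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v) &&
    v >= 0 && v <= 1
  if (!in01(config$purity_threshold))
    bad("purity_threshold must lie in [0, 1]")
  if (!in01(config$max_fraction_below))
    bad("max_fraction_below must lie in [0, 1]")
  if (!is.finite(config$min_iqr) || config$min_iqr < 0)
    bad("min_iqr must be non-negative")
  if (!in01(config$fdr_threshold)) bad("fdr_threshold must lie in [0, 1]")
  if (!in01(config$scc_alpha)) bad("scc_alpha must lie in [0, 1]")
  if (!config$universe %in% c("expressed", "all"))
    bad("universe must be 'expressed' or 'all'")
  if (!is.finite(config$fraction) || config$fraction <= 0 ||
      config$fraction > 0.5)
    bad("fraction must lie in (0, 0.5] so groups cannot overlap")
  if (!in01(config$de_alpha)) bad("de_alpha must lie in [0, 1]")
  if (!is.finite(config$min_fc) || config$min_fc < 1)
    bad("min_fc must be >= 1")
  if (!is.finite(config$rlow_max) || abs(config$rlow_max) > 1)
    bad("rlow_max must lie in [-1, 1]")
  if (!is.finite(config$min_delta_r) || config$min_delta_r < 0 ||
      config$min_delta_r > 2)
    bad("min_delta_r must lie in [0, 2]")
  if (config$n_perm < 1) bad("n_perm must be >= 1")
  if (!in01(config$perm_alpha)) bad("perm_alpha must lie in [0, 1]")
  if (!config$convention %in% c("corrected", "literal"))
    bad("convention must be 'corrected' or 'literal'")
  if (!config$cox_mode %in% c("joint", "univariate"))
    bad("cox_mode must be 'joint' or 'univariate'")
  if (!in01(config$signature_alpha)) bad("signature_alpha must lie in [0, 1]")
  problems
}

#' Run the full triplet-detection pipeline
#'
#' Stages: read inputs (or take a cohort object), match samples, purity
#' filter, log2 transform (when needed), low-expression and IQR filters,
#' hypergeometric candidate screen, global negative-correlation gate,
#' rewiring detection with permutation p-values, and prognosis over the
#' passing triplets. Fully deterministic per master seed.
#'
#' @param config a validated [run_config()].
#' @param cohort optional `synthetic_cohort` (bypasses `input_dir`).
#' @return list with `triplets` (all detection results), `passed` (passing
#'   triplets), `prognosis`, `report` (per-stage counts) and the echoed
#'   `config`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(cohort)) {
    if (is.null(config$input_dir))
      stop("either `cohort` or `config$input_dir` must be provided",
           call. = FALSE)
    cohort <- read_cohort(config$input_dir, is_log2 = config$already_log2)
  }
  t0 <- proc.time()[["elapsed"]]
  stage_rows <- list()
  note <- function(stage, metric, value)
    stage_rows[[length(stage_rows) + 1]] <<-
      data.frame(stage = stage, metric = metric, value = value,
                 stringsAsFactors = FALSE)

  pp <- preprocess_layers(
    list(lnc = cohort$lnc_layer, mir = cohort$mir_layer,
         mrna = cohort$mrna_layer),
    purity = cohort$purity, purity_threshold = config$purity_threshold,
    min_log2 = config$min_log2,
    max_fraction_below = config$max_fraction_below,
    min_iqr = config$min_iqr, pseudocount = config$pseudocount)
  layers <- pp[c("lnc", "mir", "mrna")]
  note("preprocess", "samples_matched", pp$counts$lnc[1])
  note("preprocess", "samples_after_purity", pp$counts$lnc[2])
  for (cls in c("lnc", "mir", "mrna"))
    note("preprocess", paste0("genes_", cls, "_after_filters"),
         nrow(layers[[cls]]$values))

  candidates <- build_candidates(cohort$interactions, layers,
                                 fdr_threshold = config$fdr_threshold,
                                 universe = config$universe)
  note("candidates", "triplets_after_fdr", nrow(candidates))
  candidates <- negative_pair_filter(candidates, layers,
                                     alpha = config$scc_alpha)
  note("candidates", "triplets_after_negative_scc", nrow(candidates))

  triplets <- detect_triplets(candidates, layers,
                              fraction = config$fraction,
                              de_alpha = config$de_alpha,
                              min_fc = config$min_fc,
                              rlow_max = config$rlow_max,
                              min_delta_r = config$min_delta_r,
                              n_perm = config$n_perm,
                              perm_alpha = config$perm_alpha,
                              convention = config$convention,
                              seed = config$seed,
                              pseudocount = config$pseudocount)
  passed <- triplets[triplets$passed, , drop = FALSE]
  note("detection", "triplets_evaluated", nrow(triplets))
  note("detection", "triplets_passed", nrow(passed))

  prognosis <- if (nrow(passed) && !is.null(cohort$clinical)) {
    clin <- cohort$clinical[cohort$clinical$sample_id %in%
                              layer_samples(layers$lnc), , drop = FALSE]
    triplet_prognosis(passed, layers, clin, cox_mode = config$cox_mode,
                      alpha = config$signature_alpha)
  } else {
    triplet_prognosis(passed[0, , drop = FALSE], layers,
                      cohort$clinical)
  }
  note("prognosis", "triplets_scored", nrow(prognosis))
  note("prognosis", "functions_together",
       sum(prognosis$category == "functions_together"))
  note("run", "elapsed_seconds",
       round(proc.time()[["elapsed"]] - t0, 3))

  report <- do.call(rbind, stage_rows)
  out <- list(triplets = triplets, passed = passed, prognosis = prognosis,
              report = report, config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(triplets, file.path(config$output_dir, "triplets.tsv"))
    write_tsv_plain(passed, file.path(config$output_dir,
                                      "passed_triplets.tsv"))
    write_tsv_plain(prognosis, file.path(config$output_dir, "prognosis.tsv"))
    write_tsv_plain(report, file.path(config$output_dir, "report.tsv"))
  }
  out
}
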