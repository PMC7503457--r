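# Synthetic cohort generator: determinism, planted structure, survival model,
# fixture round-trips.

test_that("identical seeds give identical cohorts", {
  a <- small_cohort(seed = 42, n_samples = 60, n_planted = 3, n_decoy = 10)
  b <- small_cohort(seed = 42, n_samples = 60, n_planted = 3, n_decoy = 10)
  expect_identical(a$lnc_layer$values, b$lnc_layer$values)
  expect_identical(a$mir_layer$values, b$mir_layer$values)
  expect_identical(a$mrna_layer$values, b$mrna_layer$values)
  expect_identical(a$purity, b$purity)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(seed = 43, n_samples = 60, n_planted = 3, n_decoy = 10)
  expect_false(identical(a$lnc_layer$values, c$lnc_layer$values))
})

test_that("all tables share one ordered sample set and truth is wired", {
  coh <- small_cohort(seed = 7, n_samples = 60, n_planted = 4, n_decoy = 10)
  s <- layer_samples(coh$lnc_layer)
  expect_identical(layer_samples(coh$mir_layer), s)
  expect_identical(layer_samples(coh$mrna_layer), s)
  expect_identical(coh$purity$sample_id, s)
  expect_identical(coh$clinical$sample_id, s)
  for (i in seq_len(nrow(coh$truth))) {
    expect_true(any(coh$interactions$mirna_id == coh$truth$mir_id[i] &
                      coh$interactions$target_id == coh$truth$lnc_id[i] &
                      coh$interactions$target_class == "lncRNA"))
    expect_true(any(coh$interactions$mirna_id == coh$truth$mir_id[i] &
                      coh$interactions$target_id == coh$truth$mrna_id[i] &
                      coh$interactions$target_class == "mRNA"))
  }
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(n_samples = 16), "n_samples")
  expect_error(generator_config(coupling_low = 0.5), "coupling_low")
  expect_error(generator_config(coupling_low = -0.5, coupling_high = -0.9),
               "coupling_high")
  expect_error(generator_config(censor_rate = 1.2), "censor_rate")
  expect_error(generator_config(noise_sd = 0), "noise_sd")
})

test_that("planted triplets satisfy the within-quartile correlation regime", {
  # Strong-coupling regime: Rlow < -0.4 and Rhigh - Rlow > 0.3 for >= 90%
  # of 200 planted triplets at n = 400.
  coh <- generate_cohort(generator_config(
    n_samples = 400, n_planted = 200, n_decoy_lnc = 0, n_decoy_mir = 0,
    n_decoy_mrna = 0, seed = 11))
  ok <- vapply(seq_len(200), function(i) {
    sp <- split_groups(gene_values(coh$lnc_layer, coh$truth$lnc_id[i]))
    mir <- gene_values(coh$mir_layer, coh$truth$mir_id[i])
    mrna <- gene_values(coh$mrna_layer, coh$truth$mrna_id[i])
    rl <- spearman_r(mir[sp$l_samples], mrna[sp$l_samples])
    rh <- spearman_r(mir[sp$h_samples], mrna[sp$h_samples])
    rl < -0.4 && (rh - rl) > 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("equal couplings plant no rewiring", {
  coh <- generate_cohort(generator_config(
    n_samples = 200, n_planted = 40, n_decoy_lnc = 0, n_decoy_mir = 0,
    n_decoy_mrna = 0, coupling_low = -0.9, coupling_high = -0.9, seed = 12))
  delta <- vapply(seq_len(40), function(i) {
    sp <- split_groups(gene_values(coh$lnc_layer, coh$truth$lnc_id[i]))
    mir <- gene_values(coh$mir_layer, coh$truth$mir_id[i])
    mrna <- gene_values(coh$mrna_layer, coh$truth$mrna_id[i])
    spearman_r(mir[sp$h_samples], mrna[sp$h_samples]) -
      spearman_r(mir[sp$l_samples], mrna[sp$l_samples])
  }, numeric(1))
  expect_lt(abs(mean(delta)), 0.06)
  expect_lt(mean(abs(delta) > 0.3), 0.1)
})

test_that("survival generator honors censoring and recovers coefficient signs", {
  ex <- rbind(lnc = rnorm(300, 7, 1.5), mir = rnorm(300, 7, 1.5),
              mrna = rnorm(300, 7, 1.5))
  colnames(ex) <- sprintf("S%03d", 1:300)
  cl0 <- generate_survival(ex, coeffs = c(1, -1, 0.5), censor_rate = 0,
                           seed = 5)
  expect_true(all(cl0$event == 1L))
  expect_true(all(cl0$time > 0))
  cl <- generate_survival(ex, coeffs = c(1, -1, 0.5), censor_rate = 0.3,
                          seed = 5)
  expect_lt(abs(mean(cl$event == 0) - 0.3), 0.1)
  y <- survival::Surv(cl$time, cl$event)
  df <- data.frame(l = ex[1, ], m = ex[2, ], g = ex[3, ])
  fit <- survival::coxph(y ~ l + m + g, data = df)
  expect_true(all(sign(coef(fit)) == c(1, -1, 1)))
  expect_error(generate_survival(ex, coeffs = c(1, -1, 0.5),
                                 censor_rate = 1.5, seed = 5), "censor_rate")
})

test_that("null survival coefficients leave expression uninformative", {
  set.seed(9)
  pvals <- replicate(30, {
    ex <- rbind(lnc = rnorm(100), mir = rnorm(100), mrna = rnorm(100))
    colnames(ex) <- sprintf("S%03d", 1:100)
    cl <- generate_survival(ex, coeffs = c(0, 0, 0), censor_rate = 0,
                            seed = sample.int(1e6, 1))
    logrank_test(split_by_mean(ex[1, ]), cl)
  })
  expect_gt(mean(pvals > 0.05), 0.8)
})

test_that("fixtures round-trip losslessly and the manifest lists 7 files", {
  coh <- small_cohort(seed = 3, n_samples = 40, n_planted = 2, n_decoy = 5)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(coh, dir)
  expect_equal(nrow(manifest), 7L)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  back <- read_cohort(dir)
  expect_equal(back$lnc_layer$values, coh$lnc_layer$values)
  expect_equal(back$mir_layer$values, coh$mir_layer$values)
  expect_equal(back$mrna_layer$values, coh$mrna_layer$values)
  expect_equal(back$purity$purity, coh$purity$purity)
  expect_equal(back$clinical$time, coh$clinical$time)
  expect_identical(back$truth, coh$truth)
})

test_that("an unplanted cohort is valid with an empty truth registry", {
  coh <- small_cohort(seed = 4, n_samples = 40, n_planted = 0, n_decoy = 5)
  expect_equal(nrow(coh$truth), 0L)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(coh, dir)
  expect_equal(nrow(manifest), 7L)
  expect_equal(nrow(read_cohort(dir)$truth), 0L)
})

test_that("linear-scale emission inverts the log transform", {
  lin <- small_cohort(seed = 6, n_samples = 40, n_planted = 2, n_decoy = 5,
                      emit_linear = TRUE)
  log <- small_cohort(seed = 6, n_samples = 40, n_planted = 2, n_decoy = 5)
  expect_false(lin$lnc_layer$is_log2)
  relog <- log2_transform(lin$lnc_layer)
  expect_equal(relog$values, log$lnc_layer$values, tolerance = 1e-12)
})
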