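# Quartile splitting, DE gates, Fisher transform, rewiring score,
# permutation p-values and the composed detector.

test_that("quartile split honors the floor rule and ID tie-break", {
  v40 <- setNames(seq_len(40), sprintf("s%02d", 1:40))
  sp <- split_groups(v40)
  expect_equal(sp$n_high, 10L)
  expect_equal(sp$n_low, 10L)
  expect_identical(sp$h_samples, sprintf("s%02d", 40:31))
  expect_identical(sp$l_samples, sprintf("s%02d", 10:1))
  expect_length(intersect(sp$h_samples, sp$l_samples), 0)

  v401 <- setNames(rnorm(401), sprintf("s%03d", 1:401))
  sp2 <- split_groups(v401)
  expect_equal(sp2$n_high, 100L)

  flat <- setNames(rep(1, 20), sprintf("s%02d", 1:20))
  expect_warning(sp3 <- split_groups(flat), "tie-break")
  expect_identical(sp3$h_samples, sprintf("s%02d", 1:5))
  expect_identical(sp3$l_samples, sprintf("s%02d", 16:20))
  expect_error(split_groups(setNames(1:10, letters[1:10])), "too few")
})

test_that("DE gate orients fold-change and applies strict thresholds", {
  ids <- sprintf("s%02d", 1:16)
  sp <- split_groups(setNames(16:1, ids))
  # H samples s01..s04 at linear 30, L samples s13..s16 at linear 10 (exact
  # group means), with within-group spread for a defined t-test
  lin <- c(25, 35, 28, 32, rep(20, 8), 8, 12, 9, 11)
  vals <- setNames(log2(lin + 1), ids)
  up <- group_de_gate(vals, sp, "up_in_H")
  expect_true(up$pass)
  expect_equal(up$fc, 3)
  down <- group_de_gate(vals, sp, "down_in_H")
  expect_false(down$pass)
  expect_equal(down$fc, 1 / 3)

  same <- setNames(log2(rep(c(9, 11), 8) + 1), ids)
  expect_false(group_de_gate(same, sp, "up_in_H")$pass)

  # fold-change exactly 1.5 fails the strict cut even with alpha ~ 1
  fc15 <- setNames(log2(c(2.5, 3.5, 2.5, 3.5, rep(2, 8), 1.5, 2.5, 1.5, 2.5) + 1),
                   ids)
  gate <- group_de_gate(fc15, sp, "up_in_H", alpha = 0.999)
  expect_equal(gate$fc, 1.5)
  expect_false(gate$pass)

  flat <- setNames(rep(3, 16), ids)
  expect_warning(res <- group_de_gate(flat, sp, "up_in_H"), "variance")
  expect_false(res$pass)
})

test_that("Fisher transform matches the closed form and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  grid <- seq(-0.99, 0.99, length.out = 199)
  expect_equal(fisher_z(-grid), -fisher_z(grid), tolerance = 1e-12)
  expect_error(fisher_z(1), "clip")
  expect_equal(fisher_z(1, clip = TRUE), fisher_z(1 - 1e-12))
})

test_that("rewiring score equals the normal-CDF oracle and conventions sum to 1", {
  expect_equal(rewiring_score(-0.3, -0.3, 30, 30), 0.5)
  expect_equal(rewiring_score(-0.3, -0.3, 30, 30, convention = "literal"), 0.5)
  # hand-assembled Z: (F(0) - F(-0.8)) / sqrt(1/25 + 1/25) = 1.098612 / 0.282843
  z <- 1.0986123 / 0.2828427
  expect_equal(rewiring_score(-0.8, 0, 28, 28), pnorm(z), tolerance = 1e-6)
  expect_equal(rewiring_score(-0.8, 0, 28, 28), 0.99995, tolerance = 1e-4)
  expect_equal(rewiring_score(-0.8, 0, 28, 28, convention = "literal"),
               1 - pnorm(z), tolerance = 1e-6)
  set.seed(41)
  for (i in 1:50) {
    rl <- runif(1, -0.95, 0.95); rh <- runif(1, -0.95, 0.95)
    nl <- sample(5:60, 1); nh <- sample(5:60, 1)
    zo <- (0.5 * log((1 + rh) / (1 - rh)) - 0.5 * log((1 + rl) / (1 - rl))) /
      sqrt(1 / (nl - 3) + 1 / (nh - 3))
    expect_equal(rewiring_score(rl, rh, nl, nh), pnorm(zo), tolerance = 1e-12)
    expect_equal(rewiring_score(rl, rh, nl, nh) +
                   rewiring_score(rl, rh, nl, nh, convention = "literal"),
                 1, tolerance = 1e-12)
  }
  expect_error(rewiring_score(-0.5, 0.5, 3, 30), "exceed 3")
})

test_that("rewiring score is monotone in the correlation gap and group size", {
  gaps <- seq(-0.5, 0.5, by = 0.1)
  scores <- vapply(gaps, function(g) rewiring_score(-0.4, -0.4 + g, 28, 28),
                   numeric(1))
  expect_true(all(diff(scores) > 0))
  sizes <- c(8, 16, 32, 64, 128)
  s2 <- vapply(sizes, function(n) rewiring_score(-0.6, -0.1, n, n),
               numeric(1))
  expect_true(all(diff(s2) > 0))
})

test_that("permutation p-value edge cases behave as defined", {
  set.seed(42)
  mir <- rnorm(80)
  mrna <- rnorm(80)
  top <- permutation_pvalue(mir, mrna, observed = 1, m = 50, seed = 1)
  expect_equal(top$p_perm, 0)
  expect_equal(top$n_exceed, 0L)
  bottom <- permutation_pvalue(mir, mrna, observed = 0, m = 50, seed = 1)
  expect_equal(bottom$p_perm, 1)
  plus <- permutation_pvalue(mir, mrna, observed = 1, m = 50, seed = 1,
                             add_one = TRUE)
  expect_equal(plus$p_perm, 1 / 51)
  expect_error(permutation_pvalue(mir, mrna, observed = 2, m = 50, seed = 1),
               "observed")
})

test_that("detector composes gates and reports every candidate", {
  # one genuinely rewired triplet, one coupled-but-static, one null
  coh <- generate_cohort(generator_config(
    n_samples = 120, n_planted = 1, n_decoy_lnc = 2, n_decoy_mir = 2,
    n_decoy_mrna = 2, seed = 51))
  static <- generate_cohort(generator_config(
    n_samples = 120, n_planted = 1, n_decoy_lnc = 0, n_decoy_mir = 0,
    n_decoy_mrna = 0, coupling_low = -0.9, coupling_high = -0.9, seed = 52))
  layers <- list(
    lnc = layer_from_vectors(list(
      P = gene_values(coh$lnc_layer, "LNC_P001"),
      S = gene_values(static$lnc_layer, "LNC_P001"),
      D = gene_values(coh$lnc_layer, "LNC_D0001")), "lncRNA"),
    mir = layer_from_vectors(list(
      P = gene_values(coh$mir_layer, "MIR_P001"),
      S = gene_values(static$mir_layer, "MIR_P001"),
      D = gene_values(coh$mir_layer, "MIR_D0001")), "miRNA"),
    mrna = layer_from_vectors(list(
      P = gene_values(coh$mrna_layer, "MRNA_P001"),
      S = gene_values(static$mrna_layer, "MRNA_P001"),
      D = gene_values(coh$mrna_layer, "MRNA_D0001")), "mRNA"))
  cands <- data.frame(lnc_id = c("P", "S", "D"), mir_id = c("P", "S", "D"),
                      mrna_id = c("P", "S", "D"), stringsAsFactors = FALSE)
  res <- detect_triplets(cands, layers, seed = 7)
  expect_equal(nrow(res), 3L)
  p_row <- res[res$lnc_id == "P", ]
  s_row <- res[res$lnc_id == "S", ]
  d_row <- res[res$lnc_id == "D", ]
  expect_true(p_row$passed)
  # static coupling: both strata strongly negative, |delta R| gate fails
  expect_lt(s_row$r_low, -0.4)
  expect_false(s_row$corr_pass)
  expect_false(s_row$passed)
  # null triplet: DE gates fail regardless of correlations
  expect_false(d_row$de_pass_mir && d_row$de_pass_mrna)
  expect_false(d_row$passed)
})

test_that("detection is deterministic and independent of candidate order", {
  coh <- small_cohort(seed = 53, n_samples = 80, n_planted = 3, n_decoy = 3)
  layers <- preprocessed_layers(coh)
  cands <- build_candidates(coh$interactions, layers)
  a <- detect_triplets(cands, layers, seed = 99)
  b <- detect_triplets(cands, layers, seed = 99)
  expect_identical(a, b)
  shuffled <- cands[rev(seq_len(nrow(cands))), ]
  c <- detect_triplets(shuffled, layers, seed = 99)
  c_sorted <- c[match(triplet_key(a), triplet_key(c)), ]
  rownames(c_sorted) <- NULL
  expect_equal(a, c_sorted)
})
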