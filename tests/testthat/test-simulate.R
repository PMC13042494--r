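test_that("the generator is deterministic and honours its class proportions", {
  a <- simulate_dual_contrast(n_genes = 300, seed = 7)
  b <- simulate_dual_contrast(n_genes = 300, seed = 7)
  expect_identical(a, b)
  d <- simulate_dual_contrast(n_genes = 300, seed = 8)
  expect_false(identical(a$contrasts$e1, d$contrasts$e1))

  all_null <- simulate_dual_contrast(
    n_genes = 100, seed = 2,
    proportions = c(shared_up = 0, shared_down = 0, different = 0, null = 1))
  expect_true(all(all_null$truth$true_class == "null"))
  expect_true(all(all_null$truth$theta1 == 0 & all_null$truth$theta2 == 0))
})

test_that("planted truth classes have sign-consistent true effects", {
  sim <- simulate_dual_contrast(n_genes = 1000, seed = 3)
  tr <- sim$truth
  su <- tr[tr$true_class == "shared_up", ]
  expect_true(all(su$theta1 > 0 & su$theta2 > 0))
  sd_ <- tr[tr$true_class == "shared_down", ]
  expect_true(all(sd_$theta1 < 0 & sd_$theta2 < 0))
  df <- tr[tr$true_class == "different", ]
  expect_true(all(df$theta1 * df$theta2 < 0))
  expect_true(all(tr$theta1[tr$true_class == "null"] == 0))
  # contrasts and truth align feature-wise
  expect_identical(sim$contrasts$feature, tr$feature)
  # FDRs are valid BH outputs
  expect_true(all(sim$contrasts$fdr1 >= 0 & sim$contrasts$fdr1 <= 1))
})

test_that("generator configuration is validated", {
  expect_error(simulate_dual_contrast(n_genes = 5),
               class = "cscore_config_error")
  expect_error(
    simulate_dual_contrast(proportions = c(shared_up = 0.5, shared_down = 0.5,
                                           different = 0.5, null = 0.5)),
    class = "cscore_config_error")
  expect_error(simulate_dual_contrast(noise_se = 0),
               class = "cscore_config_error")
})

test_that("direction fidelity: confident shared-up genes score positive", {
  sim <- simulate_dual_contrast(n_genes = 500, seed = 11)
  sc <- score_contrasts(sim$contrasts)
  m <- dplyr::inner_join(as_tibble(sc), sim$truth, by = "feature")
  confident <- m$true_class == "shared_up" & m$e1 > 0 & m$e2 > 0 &
    m$fdr1 < 0.05 & m$fdr2 < 0.05
  expect_gt(sum(confident), 0)
  expect_true(all(m$c_score[confident] > 0))
})

test_that("null data keep the pooled permutation test calibrated", {
  # the one-sided rule tests in whichever tail matches the observed sign, so
  # the all-null rejection rate is ~0.05 per tail and ~0.10 overall; bounds
  # frozen from a 20-seed pilot (per-tail max 0.064, overall max 0.106)
  sim <- simulate_dual_contrast(
    n_genes = 500, seed = 7,
    proportions = c(shared_up = 0, shared_down = 0, different = 0, null = 1))
  r <- cscore_test(sim$contrasts, n_perm = 4000, seed = 77)
  expect_lte(mean(r$perm_p < 0.05 & r$c_score > 0), 0.08)
  expect_lte(mean(r$perm_p < 0.05 & r$c_score < 0), 0.08)
  expect_lte(mean(r$perm_p < 0.05), 0.12)
})

test_that("the toy resource generator respects size and complex fraction", {
  pool <- sprintf("g%03d", 1:60)
  res <- simulate_lr_resource(pool, n_pairs = 6, complex_fraction = 0,
                              seed = 1)
  expect_equal(nrow(res), 6)
  expect_true(all(lengths(res$receptor_subunits) == 1))
  res2 <- simulate_lr_resource(pool, n_pairs = 6, complex_fraction = 1,
                               seed = 1)
  expect_true(all(lengths(res2$receptor_subunits) == 2))
  expect_identical(res2, simulate_lr_resource(pool, n_pairs = 6,
                                              complex_fraction = 1, seed = 1))
  # without-replacement sampling keeps genes distinct while the pool lasts
  used <- c(res2$ligand, unlist(res2$receptor_subunits))
  expect_equal(anyDuplicated(used), 0)
  expect_error(simulate_lr_resource(pool[1:3]), class = "cscore_config_error")
})

test_that("multi-cell-type simulation composes per-cell-type calls", {
  sims <- simulate_celltype_scores(n_cell_types = 2, n_genes = 40, seed = 21)
  expect_named(sims, c("CT1", "CT2"))
  expect_false(identical(sims$CT1$scores$e1, sims$CT2$scores$e1))
  # composition equals a manual call with the same offset seeds
  manual <- simulate_dual_contrast(n_genes = 40, seed = 22,
                                   cell_type = "CT1")
  manual_scores <- cscore_test(manual$contrasts, seed = 21 + 500 + 1)
  expect_equal(as.data.frame(sims$CT1$scores),
               as.data.frame(manual_scores))
  expect_equal(sims$CT1$truth, manual$truth)
})

test_that("parameter recovery holds at a reduced problem size", {
  # scaled-down version of the headline recovery check (full size runs in
  # the acceptance suite): 400 genes, 15% planted signal
  sim <- simulate_dual_contrast(n_genes = 400, seed = 1)
  r <- cscore_test(sim$contrasts, n_perm = 4000, seed = 501)
  m <- dplyr::inner_join(as_tibble(r), sim$truth, by = "feature")
  called_shared <- m$pattern %in% c("shared_up", "shared_down")
  called_diff <- m$pattern == "different"
  expect_gte(mean(m$true_class[called_shared] %in%
                    c("shared_up", "shared_down")), 0.8)
  expect_gte(mean(m$true_class[called_diff] == "different"), 0.8)
  for (cl in c("shared_up", "shared_down", "different")) {
    expect_gte(mean(m$pattern[m$true_class == cl] == cl), 0.5)
  }
})
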