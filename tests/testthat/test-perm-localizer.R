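test_that("residualization reduces to centering when covariates are constant", {
  st <- make_stack(3, 3, seed = 5)
  st$manifest$age_years <- rep(10, 6)
  st$manifest$sex <- rep("F", 6)
  adj <- suppressWarnings(residualize_covariates(st))
  centered <- sweep(st$data, 2, colMeans(st$data))
  expect_equal(unname(adj$data), unname(centered), tolerance = 1e-12)
})

test_that("intensities exactly linear in age leave zero residuals", {
  st <- make_stack(4, 4, seed = 6)
  ages <- st$manifest$age_years
  st$data <- outer(ages, seq_len(ncol(st$data)), function(a, v) 3 * a + v)
  adj <- residualize_covariates(st)
  expect_lt(max(abs(adj$data)), 1e-10)
})

test_that("residuals match an independent normal-equations solve", {
  st <- make_stack(4, 4, seed = 7)
  adj <- residualize_covariates(st)
  X <- cbind(1, st$manifest$age_years, as.numeric(st$manifest$sex == "M"))
  want <- ls_oracle(X, st$data)$resid
  expect_equal(unname(adj$data), unname(want), tolerance = 1e-8)
})

test_that("rank-deficient nuisance designs fall back with a warning", {
  st <- make_stack(3, 3, seed = 8)
  st$manifest$age_years <- rep(9, 6)
  st$manifest$sex <- rep("M", 6)
  expect_warning(residualize_covariates(st), "rank-deficient")
})

test_that("voxel statistic is the absolute patient-minus-control mean difference", {
  man <- make_manifest(2, 2)
  data <- matrix(c(1, 1, 2, 4), ncol = 1)      # controls {1,1}, patients {2,4}
  vs <- voxel_statistic(data, man$group)
  expect_equal(vs$signed_difference, 2.0)
  expect_equal(vs$raw_stat, 2.0)

  st <- make_stack(3, 3, seed = 9)
  st$data[st$manifest$group == "patient", ] <- st$data[st$manifest$group == "control", ]
  expect_true(all(voxel_statistic(st)$raw_stat == 0))

  vs2 <- voxel_statistic(make_stack(4, 3, seed = 10))
  st2 <- make_stack(4, 3, seed = 10)
  brute <- apply(st2$data, 2, function(col) {
    mean(col[st2$manifest$group == "patient"]) -
      mean(col[st2$manifest$group == "control"])
  })
  expect_equal(vs2$signed_difference, brute, tolerance = 1e-14)
  expect_error(voxel_statistic(st2$data, rep("control", 7)), "non-empty")
})

test_that("3v3 exhaustive enumeration matches the brute-force oracle exactly", {
  st <- make_stack(3, 3, grid = c(3L, 3L, 3L), seed = 12)
  adj <- residualize_covariates(st)
  expect_message(
    nul <- permutation_null(adj, tfce = tfce_params(n_steps = 20),
                            cfg = perm_config(n_permutations = 1000,
                                              rng_seed = 4)),
    "enumerating exhaustively")
  expect_equal(nul$n_performed, choose(6, 3))
  pm <- correct_and_extract(nul)

  oracle <- perm_oracle_exhaustive(adj$data, adj$manifest$group,
                                   adj$voxel_index, adj$grid_shape,
                                   n_steps = 20)
  expect_identical(oracle$n_labelings, 20L)
  expect_equal(pm$p_voxel, oracle$p, tolerance = 1e-12)
  expect_equal(nul$tfce_stat, oracle$t_obs, tolerance = 1e-10)
})

test_that("Monte-Carlo p-values respect the counting bounds and determinism", {
  st <- make_stack(8, 8, grid = c(3L, 3L, 2L), seed = 13)
  adj <- residualize_covariates(st)
  cfg <- perm_config(n_permutations = 300, rng_seed = 99)
  nul <- permutation_null(adj, cfg = cfg)
  pm <- correct_and_extract(nul)
  expect_true(all(pm$p_voxel >= 1 / 301))
  expect_true(all(pm$p_voxel <= 1))
  expect_true(all(pm$p_adjusted >= pm$p_voxel))
  expect_true(all(which(pm$region) %in% which(pm$p_adjusted < cfg$alpha)))
  expect_true(all(pm$signed_difference[pm$region] > 0))

  pm2 <- correct_and_extract(permutation_null(adj, cfg = cfg))
  expect_identical(pm, pm2)
})

test_that("non-exact mode approaches the exhaustive answer for a 4v4 cohort", {
  st <- make_stack(4, 4, grid = c(3L, 3L, 2L), seed = 14)
  adj <- residualize_covariates(st)
  suppressMessages(
    ex <- correct_and_extract(
      permutation_null(adj, cfg = perm_config(n_permutations = 100,
                                              rng_seed = 1)))
  )
  expect_true(ex$exhaustive)
  expect_warning(cfg_coarse <- perm_config(n_permutations = 60, rng_seed = 2),
                 "too coarse")
  mc <- correct_and_extract(permutation_null(adj, cfg = cfg_coarse))
  expect_false(mc$exhaustive)
  # Monte-Carlo tolerance: p_mc has sd <= 0.5/sqrt(60) ~ 0.065; allow 4 sd
  expect_lt(max(abs(mc$p_voxel - ex$p_voxel)), 0.26)
})

test_that("Bonferroni adjustment equals the per-voxel p on a one-voxel mask", {
  mask <- array(FALSE, c(3L, 3L, 3L)); mask[2, 2, 2] <- TRUE
  st <- make_stack(8, 8, grid = c(3L, 3L, 3L), seed = 15, mask = mask)
  adj <- residualize_covariates(st)
  pm <- correct_and_extract(
    permutation_null(adj, cfg = perm_config(200, rng_seed = 3,
                                            fwe_method = "bonferroni")))
  expect_equal(pm$p_adjusted, pm$p_voxel)
})

test_that("the Bonferroni granularity floor triggers a warning", {
  st <- make_stack(8, 8, grid = c(4L, 4L, 4L), seed = 16)
  adj <- residualize_covariates(st)
  nul <- permutation_null(adj, cfg = perm_config(200, rng_seed = 5,
                                                 fwe_method = "bonferroni"))
  # floor = 1/201; 64 voxels -> min adjusted p = 0.318 >= alpha
  expect_warning(correct_and_extract(nul), "Bonferroni floor")
})

test_that("null per-voxel p-values are super-uniform", {
  # exchangeable null: pooled P(p <= alpha) <= alpha + Monte-Carlo slack
  p_all <- c()
  for (r in 1:20) {
    cfg <- simulation_config(n_per_group = 8, grid_shape = c(3L, 3L, 3L),
                             mask = array(TRUE, c(3, 3, 3)), n_clusters = 0L,
                             baseline_sd = 30, rng_seed = 400 + r)
    st <- cohort_to_stack(generate_cohort(cfg))
    pm <- correct_and_extract(
      permutation_null(residualize_covariates(st),
                       cfg = perm_config(400, rng_seed = 800 + r)))
    p_all <- c(p_all, pm$p_voxel)
  }
  for (alpha in c(0.01, 0.05, 0.1)) {
    # voxels within a cohort are dependent; allow 3 binomial SE on 20
    # effectively independent cohort draws
    slack <- 3 * sqrt(alpha * (1 - alpha) / 20)
    expect_lte(mean(p_all <= alpha), alpha + slack,
               label = paste("alpha", alpha))
  }
})

st_mask_from <- function(st) {
  m <- array(FALSE, st$grid_shape)
  lin <- 1L + st$voxel_index %*% c(1L, st$grid_shape[1],
                                   st$grid_shape[1] * st$grid_shape[2])
  m[as.vector(lin)] <- TRUE
  m
}

test_that("localize_regions output geometry is consistent with its stack", {
  cfg <- simulation_config(n_per_group = 6, grid_shape = c(8L, 8L, 8L),
                           mask = make_ball_mask(c(8L, 8L, 8L), 3),
                           n_clusters = 1L, cluster_radius_voxels = 1.5,
                           rng_seed = 19)
  st <- cohort_to_stack(generate_cohort(cfg))
  pm <- localize_regions(st, tfce = tfce_params(n_steps = 30),
                         cfg = perm_config(300, rng_seed = 6))
  expect_length(pm$p_voxel, ncol(st$data))
  # extracted region lives inside the mask by construction
  vol <- region_to_volume(pm$region, st)
  expect_true(all(vol[!st_mask_from(st)] == 0))
})
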