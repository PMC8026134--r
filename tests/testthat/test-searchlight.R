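# Sphere geometry, searchlight maps, smoothing, cluster permutation test.

test_that("sphere offsets match enumeration of integer lattice points", {
  expect_equal(nrow(sphere_offsets(0, 3)), 1)
  expect_equal(nrow(sphere_offsets(9, 3)), 123)
  expect_equal(nrow(sphere_offsets(3, 3)), 7)
  for (cs in list(c(9, 3), c(6, 3), c(10, 2.5))) {
    expect_equal(nrow(sphere_offsets(cs[1], cs[2])),
                 oracle_sphere_count(cs[1], cs[2]))
  }
  expect_true(any(apply(sphere_offsets(9, 3) == 0, 1, all)))  # centre kept
})

test_that("searchlight localises a planted value code", {
  cfg <- sim_config(n_subjects = 1, n_items = 30, seed = 51,
                    n_sessions = 2, imagination_per_session = 30,
                    choice_per_session = 6, n_volumes = 130,
                    grid_dim = c(12L, 12L, 12L),
                    region_specs = list(region_spec(
                      "cube", center = c(4, 4, 4), n_voxels = 64,
                      codes = "usefulness_goal_general",
                      code_weights = 2.5)))
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg, mask = "grid")[[1]]
  lk <- goalrsa:::ratings_lookup(r, 1, cfg$goals)
  gi <- match(ps$conditions$goal, cfg$goals)
  model <- model_value(lk$U[cbind(ps$conditions$item, gi)], ps$conditions)
  sl <- searchlight_map(ps, model)
  inreg <- array(FALSE, dim(ps$mask))
  inreg[which(ps$mask)[ps$regions$cube]] <- TRUE
  m_in <- mean(sl$values[inreg], na.rm = TRUE)
  m_out <- mean(sl$values[!inreg & sl$mask], na.rm = TRUE)
  expect_gt(m_in - m_out, 0.2)
  expect_lt(abs(m_out), 0.05)
  # label mismatch is refused
  bad <- model_value(lk$U[cbind(ps$conditions$item, gi)],
                     ps$conditions[c(2:nrow(ps$conditions), 1), ])
  expect_error(searchlight_map(ps, bad), "mismatch")
})

test_that("pure-noise searchlight maps centre on zero", {
  cfg <- sim_config(n_subjects = 1, n_items = 20, seed = 53,
                    n_sessions = 2, imagination_per_session = 20,
                    choice_per_session = 5, n_volumes = 90,
                    grid_dim = c(9L, 9L, 9L),
                    region_specs = list(region_spec("roi", n_voxels = 20,
                                                    code_weights = 0)))
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg, mask = "grid")[[1]]
  lk <- goalrsa:::ratings_lookup(r, 1, cfg$goals)
  gi <- match(ps$conditions$goal, cfg$goals)
  model <- model_value(lk$U[cbind(ps$conditions$item, gi)], ps$conditions)
  sl <- searchlight_map(ps, model)
  # a small positive bias is inherent to correlating two metric structures
  expect_lt(abs(mean(sl$values[sl$mask])), 0.05)
})

test_that("centres without enough in-mask voxels are invalid", {
  mask <- array(FALSE, c(7, 7, 7)); mask[4, 4, 4] <- TRUE
  ps <- pattern_set(matrix(rnorm(8), 8, 1), cond_df(4), mask)
  # single-voxel mask: every sphere retains 1 voxel < min_voxels
  model <- model_identity(cond_df(4))
  sl <- searchlight_map(ps, model)
  expect_equal(sum(sl$mask), 0)
})

test_that("smoothing is mask-normalised and hits the requested width", {
  dims <- c(21, 21, 21)
  mask <- array(TRUE, dims)
  cons <- stat_map(array(3.7, dims), mask, 3)
  sm0 <- smooth_map(cons, 0)
  expect_identical(sm0$values, cons$values)            # fwhm 0 = identity
  sm <- smooth_map(cons, 8)
  expect_equal(sm$values[mask], rep(3.7, sum(mask)), tolerance = 1e-10)
  # delta input: fitted FWHM of the output within 5% of requested
  v <- array(0, dims); v[11, 11, 11] <- 1
  smd <- smooth_map(stat_map(v, mask, 3), 12)
  prof <- smd$values[, 11, 11]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_mm <- (f_hi - f_lo) * 3
  expect_lt(abs(fwhm_mm - 12) / 12, 0.05)
})

test_that("cluster permutation test controls and orders cluster p-values", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  set.seed(60)
  cube <- array(FALSE, dims); cube[3:6, 3:6, 3:6] <- TRUE
  maps <- lapply(1:12, function(i) {
    v <- array(rnorm(1000), dims); v[cube] <- v[cube] + 1.2
    stat_map(v, mask, 3)
  })
  rep <- cluster_permutation_test(maps, n_perm = 300, seed = 61)
  expect_gt(nrow(rep$clusters), 0)
  expect_lt(rep$clusters$p_fwe[1], 0.05)
  # p never below the estimator bound, monotone in cluster size
  expect_true(all(rep$clusters$p_fwe >= 1 / (rep$n_perm + 1)))
  expect_true(all(diff(rep$clusters$p_fwe) >= 0))
})

test_that("exactly antisymmetric subject maps yield no clusters", {
  dims <- c(8, 8, 8)
  mask <- array(TRUE, dims)
  set.seed(62)
  base <- array(rnorm(512), dims)
  maps <- c(lapply(1:4, function(i) stat_map(base, mask, 3)),
            lapply(1:4, function(i) stat_map(-base, mask, 3)))
  rep <- suppressWarnings(cluster_permutation_test(maps, n_perm = 400,
                                                   seed = 63))
  expect_equal(nrow(rep$clusters), 0)
  expect_true(rep$exact)          # 2^8 = 256 <= 400 flips: enumeration
  expect_lt(max(abs(rep$t_map$values[mask])), 1e-6)
})

test_that("searchlight output is equivariant to consistent axis permutation", {
  cfg <- sim_config(n_subjects = 1, n_items = 12, seed = 55,
                    n_sessions = 2, imagination_per_session = 12,
                    choice_per_session = 3, n_volumes = 60,
                    grid_dim = c(8L, 8L, 8L),
                    region_specs = list(region_spec("roi", n_voxels = 27,
                                                    center = c(3, 3, 3))))
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg, mask = "grid")[[1]]
  model <- model_identity(ps$conditions)
  sl1 <- searchlight_map(ps, model, min_voxels = 5)
  # permute the x and y axes consistently in patterns and mask
  dims <- dim(ps$mask)
  lin <- array(seq_len(prod(dims)), dims)
  lin_p <- aperm(lin, c(2, 1, 3))
  perm_cols <- match(which(ps$mask)[order(match(which(ps$mask),
                                                lin_p[ps$mask]))], which(ps$mask))
  ps2 <- pattern_set(ps$patterns[, order(lin_p[aperm(ps$mask, c(2, 1, 3))])],
                     ps$conditions, aperm(ps$mask, c(2, 1, 3)),
                     voxel_mm = ps$voxel_mm)
  sl2 <- searchlight_map(ps2, model, min_voxels = 5)
  expect_equal(sl2$values, aperm(sl1$values, c(2, 1, 3)), tolerance = 1e-10)
})
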