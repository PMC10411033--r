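test_that("SAR difference maps match hand arithmetic", {
  p <- make_sar_pair(matrix(c(1, 3, 2, 4), 2, 2),
                     matrix(c(1, 3, 2, 5), 2, 2))
  d <- diff_map_sar(p$meas, p$sim)
  expect_equal(d$diff, matrix(c(0, 0, 0, 0.25), 2, 2))
  # identity
  expect_equal(diff_map_sar(p$sim, p$sim)$diff, matrix(0, 2, 2))
  # meas = 2*sim -> diff = sim/max(sim), peaking at 1
  dbl <- make_sar_pair(matrix(1:4, 2, 2), 2 * matrix(1:4, 2, 2))
  d2 <- diff_map_sar(dbl$meas, dbl$sim)
  expect_equal(d2$diff, matrix(1:4, 2, 2) / 4)
  expect_equal(max(d2$diff), 1)
})

test_that("B1 difference maps support both conventions", {
  sim <- field_map(matrix(c(3, 4), 1, 2), modality = "B1")
  meas <- field_map(matrix(c(3, 5), 1, 2), modality = "B1")
  expect_equal(diff_map_b1(meas, sim, "squared")$diff,
               matrix(c(0, 9 / 16), 1, 2))
  expect_equal(diff_map_b1(meas, sim, "linear")$diff,
               matrix(c(0, 0.25), 1, 2))
  expect_equal(diff_map_b1(sim, sim)$diff, matrix(0, 1, 2))
})

test_that("difference maps enforce grid and normalization preconditions", {
  a <- field_map(matrix(1, 4, 4), modality = "SAR")
  b <- field_map(matrix(1, 2, 2), modality = "SAR")
  expect_error(diff_map_sar(a, b), "resample")
  z <- field_map(matrix(0, 4, 4), modality = "SAR")
  expect_error(diff_map_sar(a, z), "maximum")
  p1 <- field_map(matrix(1, 4, 4), modality = "SAR", norm_power = 8)
  p2 <- field_map(matrix(1, 4, 4), modality = "SAR", norm_power = 4)
  expect_error(diff_map_sar(p1, p2), "power")
  expect_error(diff_map_sar(a, field_map(matrix(1, 4, 4), modality = "B1")),
               "expected two SAR maps")
})

test_that("difference numerators are antisymmetric under meas/sim swap", {
  set.seed(17)
  for (rep in 1:5) {
    v1 <- matrix(runif(36, 1, 5), 6, 6)
    v2 <- matrix(runif(36, 1, 5), 6, 6)
    p <- make_sar_pair(v1, v2)
    q <- make_sar_pair(v2, v1)
    d1 <- diff_map_sar(p$meas, p$sim)$diff * max(v1)
    d2 <- diff_map_sar(q$meas, q$sim)$diff * max(v2)
    expect_equal(d1, -d2, tolerance = 1e-12)
  }
})

test_that("modeling_uncertainty equals the nearest-rank sort oracle", {
  # exact rank semantics on a constructed grid
  expect_equal(as.numeric(modeling_uncertainty(seq(0.001, 1, by = 0.001))),
               0.999)
  expect_equal(as.numeric(modeling_uncertainty(matrix(0, 5, 5))), 0)
  # random grids up to 1e4 voxels, several quantiles
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(c(100, 1000, 10000), 1)
    x <- stats::rnorm(n, 0, 0.2)
    for (q in c(0.5, 0.9, 0.999)) {
      mu <- modeling_uncertainty(x, quantile = q)
      expect_identical(attr(mu, "raw"), sort_rank_quantile(x, q))
      expect_identical(as.numeric(mu), max(attr(mu, "raw"), 0))
    }
  }
  expect_error(modeling_uncertainty(numeric(0)), "empty")
  expect_error(modeling_uncertainty(1:3, quantile = 1), "quantile")
})

test_that("modeling_uncertainty is monotone under constant shifts", {
  set.seed(29)
  x <- stats::rnorm(5000, 0, 0.1)
  base <- attr(modeling_uncertainty(x), "raw")
  for (c0 in c(0.05, 0.2, 1)) {
    shifted <- attr(modeling_uncertainty(x + c0), "raw")
    expect_equal(shifted, base + c0, tolerance = 1e-12)
  }
})

test_that("negative quantiles clamp to zero but keep the raw value", {
  mu <- modeling_uncertainty(seq(-1, -0.001, by = 0.001))
  expect_equal(as.numeric(mu), 0)
  expect_lt(attr(mu, "raw"), 0)
})

test_that("pooling lists of diff maps matches pooling their values", {
  p <- make_sar_pair(matrix(1:9 / 9, 3, 3), matrix(9:1 / 9, 3, 3))
  d <- diff_map_sar(p$meas, p$sim)
  mu_list <- modeling_uncertainty(list(d, d))
  mu_vec <- modeling_uncertainty(c(d$diff[d$mask], d$diff[d$mask]))
  expect_equal(as.numeric(mu_list), as.numeric(mu_vec))
  expect_equal(attr(mu_list, "n_voxels"), 18L)
})

test_that("worst_case_uncertainty takes the maximum and enforces tiers", {
  # published per-comparison values: worst case 76.6% (SAR, 0/180 mode)
  res <- data.frame(
    shim = c("alt180", "alt180", "zero", "left"),
    modality = c("B1", "SAR", "B1", "SAR"),
    uncertainty = c(0.639, 0.766, 0.30, 0.52))
  wc <- worst_case_uncertainty(res, tier = 3)
  expect_equal(wc$final, 0.766)
  expect_equal(wc$which$modality, "SAR")
  # head-array style: 9% to 21%, B1 only
  vals <- c(zero = 0.09, random = 0.21, cp = 0.15, linear = 0.12)
  wc2 <- worst_case_uncertainty(vals)
  expect_equal(wc2$final, 0.21)
  expect_equal(wc2$which$shim, "random")
  expect_equal(worst_case_uncertainty(c(a = 0.21))$final, 0.21)
  # tier guards
  b1only <- data.frame(shim = "zero", modality = "B1", uncertainty = 0.2)
  expect_silent(worst_case_uncertainty(b1only, tier = 2))
  expect_error(worst_case_uncertainty(b1only, tier = 3), "tier 3")
  saronly <- data.frame(shim = "zero", modality = "SAR", uncertainty = 0.2)
  expect_error(worst_case_uncertainty(saronly, tier = 2), "B1")
})

test_that("phase alignment recovers known offsets modulo 360", {
  fields <- synth_channel_fields(shape = c(30, 40), n_channels = 4, seed = 3)
  true_off <- c(10, 123.5, 250, 370)   # 370 wraps to 10
  meas <- lapply(seq_len(4), function(c)
    Arg(fields$b1[[c]]) * 180 / pi + true_off[c])
  rec <- align_channel_phases(meas, fields$b1, mask = fields$mask, step = 0.5)
  delta <- abs(((rec - true_off + 180) %% 360) - 180)
  expect_true(all(delta <= 0.5))
  expect_equal(rec[[4]], 10, tolerance = 0.5)
  # identical phases -> zero offsets
  same <- lapply(fields$b1, function(b) Arg(b) * 180 / pi)
  rec0 <- align_channel_phases(same, fields$b1, mask = fields$mask)
  expect_equal(as.numeric(rec0), rep(0, 4))
  expect_error(align_channel_phases(meas[1:2], fields$b1), "mismatch")
  # ssim objective locks onto the true offset for maps free of the
  # +-180 branch cut (wrapped maps are why cosine is the default)
  ps <- outer(seq(-60, 60, length.out = 20), seq(-30, 30, length.out = 20),
              `+`) / 2
  rec_ssim <- align_channel_phases(list(ps + 10), list(ps), step = 1,
                                   objective = "ssim")
  expect_equal(as.numeric(rec_ssim), 10, tolerance = 1)
})

test_that("pipeline closure: injected perturbations are recovered", {
  fields <- synth_channel_fields(seed = 2)
  maps <- combine_shim(fields, shim_phases(fields, "zero"))
  # pure scale error: quantile equals s * q-quantile of sim/max
  s <- 0.12
  meas <- perturb_measurement(maps$sar, scale_error = s, seed = 1)
  q <- as.numeric(modeling_uncertainty(diff_map_sar(meas, maps$sar)))
  direct <- s * sort_rank_quantile(mask_values(maps$sar) /
                                     mask_max(maps$sar), 0.999)
  expect_equal(q, direct, tolerance = 1e-10)
})
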