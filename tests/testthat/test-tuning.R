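test_that("polar basis is a partition of unity on the tiled interior", {
  b <- polar_basis()
  g <- expand.grid(a = seq(b$radial_interior, 1, length.out = 200),
                   th = seq(0, pi, length.out = 200))
  W <- eval_polar_basis(g$a, g$a * cos(g$th), b)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
  expect_true(all(W >= 0))
})

test_that("basis flat tops, crossovers, and rest state behave as designed", {
  b <- polar_basis()
  # flat-top center of radial bin 2, angular bin 1: single unit weight
  r_c <- 3.5 / 6
  w <- eval_polar_basis(r_c, r_c * cos(b$angular_centers[1]), b)
  expect_equal(max(w), 1)
  expect_equal(sum(w > 1e-12), 1)
  # midway between two adjacent angular bins at a radial flat top: 0.5 / 0.5
  th_mid <- 1.5 * pi / 7 # center of the first angular transition segment
  w2 <- eval_polar_basis(r_c, r_c * cos(th_mid), b)
  expect_equal(sort(w2[w2 > 1e-12]), c(0.5, 0.5))
  # rest carries no regressor weight
  expect_true(all(eval_polar_basis(0, 0, b) == 0))
  # clipping warns
  expect_warning(eval_polar_basis(1.2, 0.1, b), "clip")
  expect_error(eval_polar_basis(0.5, 0.7, b), "exceed")
})

test_that("impulse kernel has unit peak and the stated support", {
  k <- impulse_kernel(1, 5, 2)
  expect_equal(max(k), 1)
  expect_equal(length(k), 13) # 6 s support at 2 Hz plus the zero lag
  expect_true(all(diff(k[1:3]) > 0) && all(diff(k[3:13]) < 0))
})

test_that("behavior signals normalize the strongest bout to one", {
  bouts <- data.frame(t_peak = c(1, 3, 5), vigor = c(2, 8, 4),
                      turn_amplitude = c(1, -8, 0))
  s <- behavior_signals(bouts, T_len = 20, frame_rate = 2)
  expect_equal(max(s$amp), 1)
  expect_equal(s$amp[round(3 * 2) + 1], 1)
  expect_equal(s$dir[round(3 * 2) + 1], -1)
  # pure forward bout: dir = 0, amp > 0
  expect_equal(s$dir[round(5 * 2) + 1], 0)
  expect_gt(s$amp[round(5 * 2) + 1], 0)
  expect_true(all(abs(s$dir) <= s$amp + 1e-12))
  expect_error(behavior_signals(bouts, T_len = 5, frame_rate = 2), "shorter")
})

test_that("regressor construction is a causal convolution and linear", {
  fr <- 2
  k <- impulse_kernel(1, 5, fr)
  # single bout wholly inside one basis bin: row is a shifted copy of the kernel
  b <- polar_basis()
  r_c <- 3.5 / 6
  bouts <- data.frame(t_peak = 10, vigor = r_c,
                      turn_amplitude = r_c * cos(b$angular_centers[2]))
  bouts$vigor <- 1 # normalized amp becomes 1 -> use radial flat top at r=1
  bouts$turn_amplitude <- cos(b$angular_centers[2])
  s <- behavior_signals(bouts, T_len = 60, frame_rate = fr)
  X <- build_regressors(s, b, k)
  frame <- round(10 * fr) + 1
  active <- which(rowSums(X$X[1:12, ]) > 0)
  expect_length(active, 1)
  expect_equal(X$X[active, frame:(frame + length(k) - 1)], k)
  expect_true(all(X$X[active, 1:(frame - 1)] == 0))
  expect_equal(X$X[13, ], rep(1, 60))
  # superposition of two bouts one frame apart
  bouts2 <- rbind(bouts, transform(bouts, t_peak = 10.5))
  s2 <- behavior_signals(bouts2, T_len = 60, frame_rate = fr)
  X2 <- build_regressors(s2, b, k)
  manual <- X$X[active, ]
  manual <- manual + c(0, manual[-60])
  expect_equal(X2$X[active, ], manual, tolerance = 1e-12)
  short <- behavior_signals(transform(bouts, t_peak = 1), 10, fr)
  expect_error(build_regressors(short, b, k), "kernel")
})

test_that("null voxels yield the expected OLS R-squared floor", {
  set.seed(30)
  bouts <- data.frame(t_peak = seq(2, 500, by = 2.2), vigor = 1)
  bouts$vigor <- runif(nrow(bouts), 0.2, 1)
  bouts$turn_amplitude <- bouts$vigor * runif(nrow(bouts), -1, 1)
  s <- behavior_signals(bouts, T_len = 950, frame_rate = 1.87)
  X <- build_regressors(s)
  T_len <- 950
  noise <- matrix(rnorm(T_len * 1000), T_len, 1000)
  fit <- fit_voxels(X, noise)
  expect_lt(mean(fit$r2), 13 / T_len + 3 * sd(fit$r2))
  # zero-variance voxel contract
  fitz <- fit_voxels(X, matrix(5, T_len, 1))
  expect_equal(fitz$r2, 0)
  expect_true(all(fitz$b == 0))
})

test_that("untuned-but-active voxels fit well with near-zero laterality", {
  set.seed(31)
  bouts <- data.frame(t_peak = seq(2, 500, by = 2.2), vigor = 1)
  bouts$vigor <- runif(nrow(bouts), 0.2, 1)
  bouts$turn_amplitude <- bouts$vigor * runif(nrow(bouts), -1, 1)
  s <- behavior_signals(bouts, T_len = 950, frame_rate = 1.87)
  X <- build_regressors(s)
  b_true <- rep(0.25, 12)
  y <- as.numeric(t(X$X[1:12, ]) %*% b_true) + rnorm(950, 0, 0.01)
  fit <- fit_voxels(X, matrix(y))
  expect_gt(fit$r2, 0.9)
  expect_lt(abs(fit$laterality), 0.05)
})

test_that("laterality index maps angular mass as specified", {
  b <- polar_basis()
  # all mass in the leftmost angular bin: the extreme attainable value
  v <- numeric(12); v[1:3] <- 1
  expect_equal(laterality_index(v, b), 1 - 2 * b$angular_centers[1] / pi)
  expect_equal(laterality_index(v, b), 6 / 7, tolerance = 1e-12)
  # left/right symmetric coefficients cancel
  v2 <- rep(1, 12)
  expect_equal(laterality_index(v2, b), 0, tolerance = 1e-12)
  # all-zero (or all-negative, rectified away) coefficients: undefined -> 0
  expect_equal(laterality_index(rep(-1, 12), b), 0)
  # flipping the direction convention mirrors the index exactly
  set.seed(32)
  B <- matrix(rexp(120), 10, 12)
  B_flip <- B
  for (m in 1:4) {
    B_flip[, (m - 1) * 3 + 1:3] <- B[, (4 - m) * 3 + 1:3]
  }
  expect_equal(laterality_index(B_flip, b), -laterality_index(B, b),
               tolerance = 1e-12)
})

test_that("dF/F conversion inverts a known forward model", {
  # constant trace: identically zero
  expect_true(all(compute_dff(matrix(7, 200, 1), 2) == 0))
  # step to 2 F0: plateau at 1 until the baseline window catches up
  x <- c(rep(10, 100), rep(20, 40))
  d <- compute_dff(matrix(x), 2, window_s = 60)
  expect_equal(d[105:115, 1], rep(1, 11))
  # forward/inverse round trip with known baseline
  f0 <- 10
  sig <- f0 * (1 + c(rep(0, 50), impulse_kernel(1, 5, 2), rep(0, 100)))
  d2 <- compute_dff(matrix(sig), 2, window_s = 60)
  expect_equal(max(d2), 1, tolerance = 1e-6)
  # non-positive baseline masks the voxel
  expect_true(all(is.na(compute_dff(matrix(rep(-5, 100)), 2))))
})

test_that("map rendering is monotone in R-squared and color-codes laterality", {
  tun <- structure(list(r2 = c(0, 0.2, 0.05), laterality = c(0, 1, -1),
                        b = matrix(0, 3, 12), intercept = numeric(3)),
                   class = "voxel_tuning")
  rm0 <- render_map(structure(list(r2 = rep(0, 8), laterality = rep(0, 8)),
                              class = "voxel_tuning"), c(2, 2, 2))
  expect_true(all(rm0$rgb == 0))
  rm1 <- render_map(tun, c(3, 1, 1), saturation = 0.06)
  # left-tuned voxel is green-dominant, right-tuned magenta-dominant
  expect_gt(rm1$rgb[2, 1, 1, 2], rm1$rgb[2, 1, 1, 1])
  expect_gt(rm1$rgb[3, 1, 1, 1], rm1$rgb[3, 1, 1, 2])
  # brightness rank order preserved across saturation settings
  rm2 <- render_map(tun, c(3, 1, 1), saturation = 0.12)
  b1 <- apply(rm1$rgb, 1, max)
  b2 <- apply(rm2$rgb, 1, max)
  expect_equal(order(b1), order(b2))
})

test_that("kernel shape variants give closely matching laterality maps", {
  set.seed(33)
  bouts <- data.frame(t_peak = seq(2, 400, by = 2.1), vigor = 1)
  bouts$vigor <- runif(nrow(bouts), 0.2, 1)
  bouts$turn_amplitude <- bouts$vigor * runif(nrow(bouts), -1, 1)
  s <- behavior_signals(bouts, T_len = 760, frame_rate = 1.87)
  img <- generate_imaging(s, imaging_gen_params(noise_sd = 0.05, seed = 34))
  fit_default <- fit_voxels(img$regressors, img$volume)
  X_alt <- build_regressors(s, kernel = impulse_kernel(0.5, 2, 1.87))
  fit_alt <- fit_voxels(X_alt, img$volume)
  tuned <- img$ground_truth$kind == "tuned"
  expect_gt(cor(fit_default$laterality[tuned], fit_alt$laterality[tuned]), 0.95)
})
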