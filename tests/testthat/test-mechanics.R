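test_that("origin is the first sample whose preload stress exceeds 0.02", {
  rec <- manual_recording(load = c(0, 0.1, 0.25, 1.0),
                          disp = c(0, 0.01, 0.02, 0.03))
  org <- find_origin(rec, a0_mm2 = 10)
  expect_equal(org$index, 3) # 0.25/10 = 0.025 > 0.02
  expect_equal(org$recording$displacement_mm[1], 0)
  expect_error(find_origin(manual_recording(load = c(0, 0.1, 0.15),
                                            disp = c(0, 0.01, 0.02)), 10),
               "no contact")
})

test_that("stress formula matches both loading-area expressions", {
  # samples at eps = 0, 0.25, 0.5 of a 4 mm-tall nodule, constant 1 N load
  h0 <- 4
  rec <- manual_recording(load = c(1, 1, 1), disp = c(0, 0.25, 0.5) * h0)
  nod <- nodule_record("f", 10, h0)
  cv <- to_stress_strain(rec, nod)
  expect_equal(cv$strain, c(0, 0.25, 0.5))
  expect_equal(cv$contact_ratio, c(0.5, 0.75, 1.0))
  # A via Rc * A0 / (1 - eps)
  expect_equal(cv$area_mm2, c(5, 10, 20))
  # independently via Rc * V0 / H
  v0 <- 10 * h0
  h <- h0 * (1 - cv$strain)
  expect_equal(cv$area_mm2, cv$contact_ratio * v0 / h)
  expect_equal(cv$stress_mpa, c(0.2, 0.1, 0.05))
})

test_that("strain at or beyond 1 is rejected, 0.95 truncated", {
  rec <- manual_recording(load = c(1, 1, 1), disp = c(0, 2, 4.2))
  expect_error(to_stress_strain(rec, nodule_record("x", 10, 4)), "geometry")
  rec2 <- manual_recording(load = c(1, 1, 1), disp = c(0, 2, 3.9))
  cv2 <- to_stress_strain(rec2, nodule_record("x", 10, 4))
  expect_equal(nrow(cv2), 2) # eps 0.975 dropped
})

test_that("constant load implies stress falling as (1-eps)/(0.5+eps)", {
  eps <- seq(0, 0.5, 0.01)
  rec <- manual_recording(load = rep(1, length(eps)), disp = eps * 4)
  cv <- to_stress_strain(rec, nodule_record("c", 10, 4))
  expect_true(all(diff(cv$stress_mpa) < 0))
  expect_equal(cv$stress_mpa, 0.1 * (1 - eps) / (0.5 + eps))
})

test_that("grid resampling interpolates linearly and truncates the grid", {
  cv <- analytic_curve(c(0, 0.04, 0.06), c(0, 0.4, 0.6))
  g <- resample_to_grid(cv, 0.05)
  expect_equal(g$stress_mpa[g$strain == 0.05], 0.5)
  cv2 <- analytic_curve(seq(0, 0.43, 0.01), seq(0, 0.43, 0.01)^2)
  g2 <- resample_to_grid(cv2, 0.05)
  expect_equal(max(g2$strain), 0.40)
  expect_error(resample_to_grid(analytic_curve(0.1, 1)), "2 samples")
})

test_that("gridded values match an independent interpolation oracle", {
  set.seed(31)
  eps <- sort(runif(400, 0, 0.8))
  sig <- cumsum(abs(rnorm(400, 0.01)))
  g <- resample_to_grid(analytic_curve(eps, sig), 0.05)
  # bracketing-search linear interpolation, written out by hand
  oracle <- vapply(g$strain, function(x) {
    if (x <= eps[1]) return(NA_real_)
    i <- max(which(eps <= x))
    if (eps[i] == x) return(sig[i])
    sig[i] + (sig[i + 1] - sig[i]) * (x - eps[i]) / (eps[i + 1] - eps[i])
  }, numeric(1))
  ok <- !is.na(oracle)
  expect_lt(max(abs(g$stress_mpa[ok] - oracle[ok])), 1e-12)
})

test_that("compression strength is the peak stress up to the level", {
  lin <- analytic_curve(seq(0, 0.6, 0.001), 2 * seq(0, 0.6, 0.001))
  expect_equal(compression_strength(lin, 0.5), 1.0)
  # interior peak: 0.9 MPa at eps 0.12 then drop to 0.5
  eps <- c(0, 0.05, 0.12, 0.18, 0.25)
  peak <- analytic_curve(eps, c(0, 0.4, 0.9, 0.5, 0.55))
  expect_equal(compression_strength(peak, 0.2), 0.9)
  # beyond achieved strain: missing, never extrapolated
  expect_true(is.na(compression_strength(peak, 0.5)))
  expect_true(is.na(compression_energy(peak, 0.5)))
})

test_that("serrated curves: CS equals an exhaustive scan oracle", {
  set.seed(55)
  p <- crush_params(drop_rate = 60, drop_depth_fraction = 0.25,
                    noise_load_sd = 0, noise_disp_sd = 0)
  nod <- nodule_record("s", 18, 3)
  cv <- to_stress_strain(simulate_crush_curve(p, nod, seed = 9), nod)
  for (lev in c(0.1, 0.3, 0.5)) {
    idx <- which(cv$strain <= lev)
    i_hi <- max(idx)
    interp <- if (cv$strain[i_hi] < lev) {
      cv$stress_mpa[i_hi] + (cv$stress_mpa[i_hi + 1] - cv$stress_mpa[i_hi]) *
        (lev - cv$strain[i_hi]) / (cv$strain[i_hi + 1] - cv$strain[i_hi])
    } else -Inf
    oracle <- max(c(cv$stress_mpa[idx], interp))
    expect_equal(compression_strength(cv, lev), oracle)
  }
})

test_that("compression energy matches closed forms", {
  eps <- seq(0, 0.6, 0.0005)
  expect_equal(compression_energy(analytic_curve(eps, 2 * eps), 0.5), 0.25)
  expect_equal(compression_energy(analytic_curve(eps, rep(1, length(eps))), 0.3),
               0.3)
})

test_that("compression energy matches a fine-grid refinement oracle", {
  set.seed(77)
  p <- crush_params(drop_rate = 40, noise_load_sd = 0, noise_disp_sd = 0)
  nod <- nodule_record("e", 20, 3)
  cv <- to_stress_strain(simulate_crush_curve(p, nod, seed = 13), nod)
  for (lev in c(0.2, 0.5)) {
    xs <- seq(0, lev, length.out = 1e5)
    ys <- approx(c(0, cv$strain), c(cv$stress_mpa[1], cv$stress_mpa),
                 xout = xs, ties = mean)$y
    oracle <- trapz_oracle(xs, ys)
    expect_equal(compression_energy(cv, lev), oracle,
                 tolerance = 1e-6)
  }
})

test_that("CE is invariant to resampling density", {
  eps <- sort(c(0, runif(500, 0, 0.7), 0.7))
  sig <- 3 * eps^1.5
  coarse <- analytic_curve(eps, sig)
  dense_eps <- sort(c(eps, runif(5000, 0, 0.7)))
  dense <- analytic_curve(dense_eps, 3 * dense_eps^1.5)
  expect_equal(compression_energy(coarse, 0.5),
               compression_energy(dense, 0.5), tolerance = 1e-4)
})

test_that("stiffness profiles are monotone with CE bounded by s*CS", {
  set.seed(101)
  levels <- seq(0.1, 0.5, 0.1)
  for (k in 1:25) {
    p <- random_params()
    nod <- nodule_record("m", runif(1, 8, 45), runif(1, 2, 5))
    cv <- to_stress_strain(simulate_crush_curve(p, nod, seed = k), nod)
    prof <- stiffness_profile(cv, levels)
    cs <- as.numeric(prof[paste0("CS", levels * 100)])
    ce <- as.numeric(prof[paste0("CE", levels * 100)])
    ok <- !is.na(cs)
    expect_true(all(diff(cs[ok]) >= -1e-12))
    expect_true(all(diff(ce[ok]) >= 0))
    expect_true(all(ce[ok] <= levels[ok] * cs[ok] + 1e-12))
  }
})
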