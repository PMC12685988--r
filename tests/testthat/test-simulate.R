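noise_free <- function(...) {
  crush_params(noise_load_sd = 0, noise_disp_sd = 0, ...)
}

test_that("noise-free three-phase round trip recovers the plateau exactly", {
  p <- noise_free(plateau_stress = 1, elastic_modulus = 20, drop_rate = 0)
  nod <- nodule_record("n1", 10, 4)
  rec <- simulate_crush_curve(p, nod, seed = 1)
  cv <- to_stress_strain(rec, nod)
  plateau <- cv$stress_mpa[cv$strain > 0.1 & cv$strain < 0.5]
  expect_true(length(plateau) > 100)
  expect_equal(plateau, rep(1, length(plateau)), tolerance = 1e-12)
})

test_that("noise-free round trip recovers the full target law pointwise", {
  for (pat in c("three_phase", "gradual")) {
    p <- noise_free(pattern = pat, gradual_scale = 4, gradual_power = 2,
                    drop_rate = 0)
    nod <- nodule_record("n1", 15, 3)
    rec <- simulate_crush_curve(p, nod, seed = 2)
    cv <- to_stress_strain(rec, nod)
    # first corrected sample is the preload contact pedestal; ground truth
    # applies strictly after it
    truth <- target_stress(p, cv$strain[-1])
    expect_lt(max(abs(cv$stress_mpa[-1] - truth)), 1e-6)
  }
})

test_that("gradual pattern recovers sigma = 4 eps^2 against the closed form", {
  p <- noise_free(pattern = "gradual", gradual_scale = 4, gradual_power = 2)
  nod <- nodule_record("g1", 12, 3.5)
  cv <- to_stress_strain(simulate_crush_curve(p, nod, seed = 3), nod)
  eps <- cv$strain[-1]
  expect_lt(max(abs(cv$stress_mpa[-1] - 4 * eps^2)), 1e-6)
})

test_that("recordings stop at the machine load limit", {
  p <- crush_params(plateau_stress = 40, elastic_modulus = 800,
                    drop_rate = 0, noise_load_sd = 0, noise_disp_sd = 0)
  rec <- simulate_crush_curve(p, nodule_record("big", 30, 3), seed = 4)
  expect_true(all(rec$load_N <= 2000))
  expect_lt(max(rec$displacement_mm) / 3, 0.95) # stopped early, not at 0.95
  # noisy runs never exceed limit + accuracy
  for (s in 1:5) {
    p2 <- crush_params(plateau_stress = 40, elastic_modulus = 800)
    r2 <- simulate_crush_curve(p2, nodule_record("big", 30, 3), seed = s)
    expect_true(all(r2$load_N <= 2000 + 0.1))
  }
})

test_that("origin detection lands on the generator's contact sample", {
  set.seed(123)
  for (s in 1:5) {
    # deterministic preload ramp: detection is exact
    p <- random_params(noise = FALSE)
    nod <- nodule_record("o", runif(1, 10, 40), runif(1, 2, 5))
    rec <- simulate_crush_curve(p, nod, seed = s)
    org <- find_origin(rec, nod$A0_mm2)
    expect_lte(abs(org$index - attr(rec, "truth")$contact_index), 1)
    # with load noise at the 0.1 N accuracy the crossing may jitter a few
    # samples up the ramp, i.e. microns of displacement
    pn <- random_params(noise = TRUE)
    recn <- simulate_crush_curve(pn, nod, seed = s)
    orgn <- find_origin(recn, nod$A0_mm2)
    expect_lte(abs(orgn$index - attr(recn, "truth")$contact_index), 25)
  }
})

test_that("fixed seed reproduces recordings; different seeds differ", {
  p <- crush_params()
  nod <- nodule_record("s", 20, 3)
  r1 <- simulate_crush_curve(p, nod, seed = 11)
  r2 <- simulate_crush_curve(p, nod, seed = 11)
  r3 <- simulate_crush_curve(p, nod, seed = 12)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(isTRUE(all.equal(r1$load_N[1:100], r3$load_N[1:100])))
})

test_that("degenerate geometry is rejected with a message", {
  expect_error(simulate_crush_curve(crush_params(), list(A0_mm2 = 0, H0_mm = 3)),
               "degenerate")
  expect_error(simulate_crush_curve(crush_params(), list(A0_mm2 = 10, H0_mm = -1)),
               "degenerate")
})

test_that("cohort marginals match the spec exactly at the assignment level", {
  coh <- simulate_cohort(cohort_spec(seed = 7), recordings = FALSE)
  tab <- table(coh$nodules$pattern_truth)
  expect_equal(unname(tab[["three_phase"]]), 118)
  expect_equal(unname(tab[["gradual"]]), 11)
  dial <- table(coh$nodules$pattern_truth, coh$nodules$dialysis)
  expect_equal(unname(dial["three_phase", "TRUE"]), 20)
  expect_equal(unname(dial["gradual", "TRUE"]), 7)
})

test_that("cohorts are byte-identical for a fixed seed", {
  c1 <- simulate_cohort(cohort_spec(n_nodules = 10, seed = 99))
  c2 <- simulate_cohort(cohort_spec(n_nodules = 10, seed = 99))
  expect_identical(c1$nodules, c2$nodules)
  expect_identical(lapply(c1$recordings, as.data.frame),
                   lapply(c2$recordings, as.data.frame))
})

test_that("CT-stiffness copula hits the target correlation at large n", {
  coh <- simulate_cohort(cohort_spec(n_nodules = 2000, seed = 21),
                         recordings = FALSE)
  r <- cor(coh$nodules$ct_hu, log(coh$nodules$cs10_true))
  expect_lt(abs(r - 0.45), 0.05)
})

test_that("uniform-blob phantom projects to its plateau HU", {
  spec <- ct_phantom_spec(shape = c(32, 32, 40), spacing_mm = c(1, 1, 0.5),
                          background_hu = 0,
                          blobs = list(list(center = c(16, 16, 20),
                                            radii_mm = c(6, 6, 4),
                                            peak_hu = 900)),
                          slab_mm = c(2.5, 17.5))
  ph <- simulate_ct_volume(spec)
  mip <- suppressWarnings(make_mip(ph$volume, ph$spacing_mm, axis = 3,
                                   slab_mm = spec$slab_mm))
  m <- mean_ct_number(mip, ph$roi)
  expect_equal(m$mean_hu, 900)
  expect_gt(m$n_pixels, 0)
})

test_that("a blob-free phantom yields a flagged-missing ROI measurement", {
  ph <- simulate_ct_volume(ct_phantom_spec(shape = c(20, 20, 40),
                                           background_hu = 30))
  mip <- suppressWarnings(make_mip(ph$volume, ph$spec$spacing_mm, axis = 3))
  expect_warning(m <- mean_ct_number(mip, ph$roi), "missing")
  expect_identical(m$n_pixels, 0L)
  expect_true(is.na(m$mean_hu))
})

test_that("MIP of overlapping blobs equals the brute-force projection", {
  spec <- ct_phantom_spec(shape = c(12, 14, 16), spacing_mm = c(1, 1, 1),
                          background_hu = 50,
                          blobs = list(list(center = c(6, 7, 8),
                                            radii_mm = c(4, 3, 5),
                                            peak_hu = 700),
                                       list(center = c(8, 7, 9),
                                            radii_mm = c(3, 4, 4),
                                            peak_hu = 400)),
                          noise_sd_hu = 20, slab_mm = c(0, 16))
  ph <- simulate_ct_volume(spec, seed = 5)
  mip <- suppressWarnings(make_mip(ph$volume, spec$spacing_mm, axis = 3,
                                   slab_mm = c(0, 16)))
  oracle <- matrix(NA_real_, 12, 14)
  for (i in 1:12) for (j in 1:14) oracle[i, j] <- max(ph$volume[i, j, ])
  expect_equal(mip$pixels, oracle)
})
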