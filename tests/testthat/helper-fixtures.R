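# Shared fixtures and independent oracles (never the code paths they check).

# an analytic stress-strain curve as the mechanics functions expect it
analytic_curve <- function(strain, stress, id = "fx") {
  structure(tibble::tibble(strain = strain, stress_mpa = stress),
            nodule_id = id,
            class = c("crush_curve", class(tibble::tibble())))
}

# gridded curve built directly (bypasses resample_to_grid on purpose)
analytic_grid <- function(strain, stress, id = "fx") {
  structure(tibble::tibble(strain = strain, stress_mpa = stress),
            nodule_id = id, increment = diff(strain[1:2]),
            class = c("crush_curve_grid", class(tibble::tibble())))
}

# brute-force trapezoid on an explicit point set
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# order-statistic interpolation quantile (R default convention), written
# from the textbook definition: h = (n-1)p + 1, linear between x_(h)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# two-sided Fisher exact p by full hypergeometric enumeration with choose()
fisher_oracle <- function(a, b, c, d) {
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # col 1 total
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# per-pixel even-odd point-in-polygon, coded as a scalar loop
pip_oracle <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly_y[i] > py) != (poly_y[j] > py)) {
      x_cross <- poly_x[i] + (py - poly_y[i]) *
        (poly_x[j] - poly_x[i]) / (poly_y[j] - poly_y[i])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# hand-rolled recording for a prescribed load/displacement path
manual_recording <- function(load, disp, dt_ms = 20,
                             machine = machine_spec()) {
  tibble::tibble(time_ms = (seq_along(load) - 1) * dt_ms,
                 load_N = load, displacement_mm = disp)
}

# random crush parameters spanning both families
random_params <- function(pattern = sample(c("three_phase", "gradual"), 1),
                          noise = TRUE) {
  cs <- exp(rnorm(1, log(0.4), 0.8))
  if (pattern == "three_phase") {
    crush_params(
      pattern = "three_phase",
      elastic_modulus = cs / 0.05,
      yield_strain = 0.05,
      plateau_stress = cs,
      drop_rate = runif(1, 0, 40),
      drop_depth_fraction = runif(1, 0, 0.3),
      densification_onset = runif(1, 0.4, 0.7),
      densification_exponent = runif(1, 1.1, 2),
      noise_load_sd = if (noise) 0.1 else 0,
      noise_disp_sd = if (noise) 0.001 else 0
    )
  } else {
    crush_params(
      pattern = "gradual",
      gradual_scale = cs / 0.1^2,
      gradual_power = runif(1, 1.5, 2.5),
      noise_load_sd = if (noise) 0.1 else 0,
      noise_disp_sd = if (noise) 0.001 else 0
    )
  }
}
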