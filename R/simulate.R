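# strain constant of the exponential recovery after a stress-drop event
.DROP_TAU <- 0.01
# fixed gain of the densification law (calibrated to the cohort's observed
# ~9.5x stress growth between strain 0.1 and 0.7)
.DENSIFICATION_GAIN <- 10

#' Draw plateau stress-drop events
#'
#' Stage-II serration is modelled as a Poisson process of multiplicative
#' stress drops on the plateau: events arrive at `drop_rate` per unit
#' strain between `yield_strain` and `densification_onset`, each reducing
#' stress by `drop_depth_fraction` with exponential recovery over a strain
#' scale of 0.01. Uses the current RNG state.
#'
#' @param params A [crush_params()].
#' @return A tibble with columns `strain` and `depth` (possibly 0 rows).
#' @export
draw_drop_events <- function(params) {
  stopifnot(inherits(params, "crush_params"))
  if (params$pattern != "three_phase" || params$drop_rate <= 0 ||
      params$drop_depth_fraction <= 0) {
    return(tibble(strain = numeric(), depth = numeric()))
  }
  span <- params$densification_onset - params$yield_strain
  n_ev <- rpois(1L, params$drop_rate * span)
  if (n_ev == 0L) return(tibble(strain = numeric(), depth = numeric()))
  tibble(
    strain = sort(runif(n_ev, params$yield_strain, params$densification_onset)),
    depth = rep(params$drop_depth_fraction, n_ev)
  )
}

#' Evaluate the generator's target stress law
#'
#' Deterministic evaluation of sigma*(epsilon) for a parameter set and a
#' fixed set of drop events; this is the noise-free ground truth that the
#' forward load transform encodes and the analysis pipeline recovers.
#'
#' @param params A [crush_params()].
#' @param strain Numeric vector of strains in [0, 0.95).
#' @param drops Drop-event tibble from [draw_drop_events()]; empty by
#'   default.
#' @return Numeric vector of stresses, MPa.
#' @export
target_stress <- function(params, strain,
                          drops = tibble(strain = numeric(), depth = numeric())) {
  stopifnot(inherits(params, "crush_params"), all(strain >= 0), all(strain < 0.95))
  if (params$pattern == "gradual") {
    return(params$gradual_scale * strain ^ params$gradual_power)
  }
  p <- params$plateau_stress
  sigma <- pmin(params$elastic_modulus * strain, p)
  past <- strain > params$densification_onset
  if (any(past)) {
    x <- (strain[past] - params$densification_onset) / (0.95 - strain[past])
    sigma[past] <- sigma[past] +
      p * .DENSIFICATION_GAIN * x ^ params$densification_exponent
  }
  if (nrow(drops) > 0) {
    mult <- rep(1, length(strain))
    for (i in seq_len(nrow(drops))) {
      idx <- strain >= drops$strain[i]
      mult[idx] <- mult[idx] *
        (1 - drops$depth[i] * exp(-(strain[idx] - drops$strain[i]) / .DROP_TAU))
    }
    sigma <- sigma * mult
  }
  sigma
}

#' Simulate a machine crush-curve recording
#'
#' Generates the time/load/displacement series a load-testing machine
#' would record while crushing a nodule whose true stress-strain law is
#' [target_stress()]. The displacement advances at the machine speed; the
#' load is the forward transform `F = sigma* . Rc . A0 / (1 - eps)` of the
#' contact-ratio-corrected stress model, plus Gaussian noise at the stated
#' accuracy scale. A sub-threshold preload ramp (rising to exactly the
#' 0.02 N/mm^2 origin stress) precedes a contact sample at twice the
#' threshold, so downstream origin detection lands exactly on the
#' generator's contact point. Recording stops when the measured load
#' reaches the machine limit or strain reaches 0.95.
#'
#' @param params A [crush_params()].
#' @param geometry A one-row nodule table from [nodule_record()], or any
#'   list with elements `A0_mm2` and `H0_mm`.
#' @param machine A [machine_spec()].
#' @param seed Optional integer seed.
#' @param preload_samples Number of samples in the preload ramp.
#' @param preload_threshold Origin stress threshold, N/mm^2.
#' @return A tibble of class `crush_recording` with columns `time_ms`,
#'   `load_N`, `displacement_mm`; attributes carry the machine spec,
#'   nodule id and the simulation ground truth (`truth`).
#' @examples
#' rec <- simulate_crush_curve(crush_params(noise_load_sd = 0, drop_rate = 0),
#'                             nodule_record("n1", 20, 3), seed = 1)
#' @export
simulate_crush_curve <- function(params, geometry,
                                 machine = machine_spec(),
                                 seed = NULL,
                                 preload_samples = 25L,
                                 preload_threshold = 0.02) {
  stopifnot(inherits(params, "crush_params"), inherits(machine, "machine_spec"))
  a0 <- as.numeric(geometry$A0_mm2)[1]
  h0 <- as.numeric(geometry$H0_mm)[1]
  if (!length(a0) || !length(h0) || !is.finite(a0) || !is.finite(h0) ||
      a0 <= 0 || h0 <= 0) {
    abort("simulate_crush_curve: degenerate geometry (need A0 > 0 and H0 > 0)",
          class = "crushcurve_geometry_error")
  }
  if (!is.null(seed)) set.seed(seed)
  drops <- draw_drop_events(params)

  dt_ms <- machine$sampling_interval_ms
  dd <- machine$speed_mm_min / 60 * dt_ms / 1000  # mm advanced per sample
  d_eps <- dd / h0

  n_pre <- as.integer(preload_samples)
  load_pre <- seq(0, preload_threshold * a0, length.out = n_pre)
  # contact sample: first load strictly above the origin threshold
  load_contact <- 2 * preload_threshold * a0

  k_max <- ceiling(0.95 / d_eps) - 1L
  eps <- seq_len(k_max) * d_eps
  eps <- eps[eps < 0.95]
  rc <- pmin(0.5 + eps, 1.0)
  area <- rc * a0 / (1 - eps)
  load_main <- target_stress(params, eps, drops) * area

  load <- c(load_pre, load_contact, load_main)
  n <- length(load)
  disp <- (seq_len(n) - 1) * dd
  time <- (seq_len(n) - 1) * dt_ms

  if (params$noise_load_sd > 0) {
    load <- pmax(load + rnorm(n, 0, params$noise_load_sd), 0)
  }
  if (params$noise_disp_sd > 0) {
    disp <- pmax(disp + rnorm(n, 0, params$noise_disp_sd), 0)
  }

  # machine stops at the first measured load reaching the limit
  hit <- which(load >= machine$load_limit_n)
  if (length(hit)) {
    keep <- seq_len(hit[1] - 1L)
    load <- load[keep]; disp <- disp[keep]; time <- time[keep]
  }

  out <- tibble(time_ms = time, load_N = load, displacement_mm = disp)
  id <- if (!is.null(geometry$nodule_id)) as.character(geometry$nodule_id)[1] else "sim"
  new_crush_recording(out, machine = machine, nodule_id = id,
                      truth = list(params = params, drops = drops,
                                   contact_index = n_pre + 1L,
                                   a0_mm2 = a0, h0_mm = h0,
                                   strain_step = d_eps))
}

new_crush_recording <- function(df, machine, nodule_id, truth = NULL) {
  structure(as_tibble(df),
            machine = machine, nodule_id = nodule_id, truth = truth,
            class = c("crush_recording", class(tibble())))
}

#' @export
print.crush_recording <- function(x, ...) {
  cat(sprintf("<crush_recording> nodule %s, %d samples, max load %.2f N\n",
              attr(x, "nodule_id"), nrow(x), max(x$load_N)))
  NextMethod()
}

#' Simulate a nodule cohort
#'
#' Draws a full cohort with the statistical structure the analysis
#' assumes: an exact number of three-phase nodules
#' (`round(n * three_phase_fraction)`), dialysis flags assigned at the
#' per-pattern rates (exact counts), and CT density coupled to low-strain
#' stiffness through a Gaussian copula so that Pearson r between HU and
#' log CS10 equals the target in expectation. Each nodule receives its own
#' crush-curve parameter set with plateau stress equal to its drawn CS10
#' (the Stage-I ramp reaches the plateau by strain 0.05, so the noise-free
#' stress at strain 0.1 equals CS10 by construction).
#'
#' @param spec A [cohort_spec()].
#' @param machine A [machine_spec()].
#' @param recordings If `FALSE`, skip generating the (large) per-nodule
#'   machine recordings; the nodule table and parameter sets are identical
#'   either way.
#' @return A list of class `crush_cohort` with elements `nodules` (tibble,
#'   one row per nodule, including the latent `cs10_true`), `params`
#'   (named list of [crush_params()]), and `recordings` (named list of
#'   recordings, or `NULL`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_nodules = 4, seed = 7), recordings = FALSE)
#' coh$nodules
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            machine = machine_spec(),
                            recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodules
  n3 <- round(n * spec$three_phase_fraction)
  pattern <- sample(c(rep("three_phase", n3), rep("gradual", n - n3)))

  # Gaussian copula on (HU, log CS10); both marginals are location-scale in
  # the latent normals, so the target correlation transfers exactly.
  rho <- spec$ct_stiffness_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  sd_hu <- diff(spec$ct_iqr) / (2 * qnorm(0.75))
  sdlog_cs <- log(spec$cs10_iqr[2] / spec$cs10_iqr[1]) / (2 * qnorm(0.75))
  ct_hu <- spec$ct_mean + sd_hu * z1
  cs10 <- exp(log(spec$cs10_median) + sdlog_cs * z2)

  sdlog_a0 <- log(spec$a0_iqr_mm2[2] / spec$a0_iqr_mm2[1]) / (2 * qnorm(0.75))
  a0 <- rlnorm(n, log(spec$a0_median_mm2), sdlog_a0)
  h0 <- rlnorm(n, log(spec$h0_median_mm), spec$h0_sdlog)

  dialysis <- rep(FALSE, n)
  idx3 <- which(pattern == "three_phase")
  idxg <- which(pattern == "gradual")
  k3 <- round(spec$dialysis_rate_three_phase * length(idx3))
  kg <- round(spec$dialysis_rate_gradual * length(idxg))
  if (k3 > 0) dialysis[sample(idx3, k3)] <- TRUE
  if (kg > 0) dialysis[sample(idxg, kg)] <- TRUE

  n_pat <- max(1L, ceiling(n / 2.8))
  patient <- sprintf("P%03d", sample.int(n_pat, n, replace = TRUE))
  cusp <- sample(c("L", "R", "N"), n, replace = TRUE)

  onset <- runif(n, 0.50, 0.65)
  expo <- runif(n, 1.2, 1.8)
  d_rate <- runif(n, 15, 40)
  d_depth <- runif(n, 0.05, 0.25)
  g_power <- runif(n, 1.8, 2.5)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)

  params <- vector("list", n)
  for (i in seq_len(n)) {
    params[[i]] <- if (pattern[i] == "three_phase") {
      crush_params(
        pattern = "three_phase",
        elastic_modulus = cs10[i] / 0.05,
        yield_strain = 0.05,
        plateau_stress = cs10[i],
        drop_rate = d_rate[i],
        drop_depth_fraction = d_depth[i],
        densification_onset = onset[i],
        densification_exponent = expo[i]
      )
    } else {
      crush_params(
        pattern = "gradual",
        gradual_scale = cs10[i] / 0.1 ^ g_power[i],
        gradual_power = g_power[i]
      )
    }
  }

  ids <- sprintf("N%03d", seq_len(n))
  nodules <- nodule_record(ids, a0, h0,
                           patient_id = patient, ct_hu = ct_hu,
                           dialysis = dialysis, cusp = cusp,
                           pattern_truth = pattern)
  nodules$cs10_true <- cs10
  names(params) <- ids

  recs <- NULL
  if (recordings) {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      recs[[i]] <- simulate_crush_curve(params[[i]], nodules[i, ],
                                        machine = machine,
                                        seed = rec_seeds[i])
    }
    names(recs) <- ids
  }

  structure(list(nodules = nodules, params = params, recordings = recs,
                 spec = spec, machine = machine),
            class = "crush_cohort")
}

#' @export
print.crush_cohort <- function(x, ...) {
  tab <- table(x$nodules$pattern_truth)
  cat(sprintf("<crush_cohort> %d nodules (%s)%s\n",
              nrow(x$nodules),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              if (is.null(x$recordings)) ", no recordings" else ""))
  invisible(x)
}

#' Simulate a CT phantom volume
#'
#' Builds a 3-D HU volume as background + additive ellipsoidal blobs +
#' Gaussian noise, along with a rectangular ROI polygon (in 0-based pixel
#' coordinates of the MIP plane) enclosing the projection of a designated
#' blob. With no blobs the ROI is still returned so that the downstream
#' "no qualifying pixels" path can be exercised.
#'
#' @param spec A [ct_phantom_spec()].
#' @param seed Optional integer seed.
#' @param roi_blob Index of the blob the ROI should enclose.
#' @return A list of class `ct_phantom` with elements `volume` (3-D
#'   array), `spacing_mm`, `roi` (tibble of polygon vertices `x`, `y`) and
#'   `spec`.
#' @export
simulate_ct_volume <- function(spec, seed = NULL, roi_blob = 1L) {
  stopifnot(inherits(spec, "ct_phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  dims <- spec$shape
  sp <- spec$spacing_mm
  vol <- array(spec$background_hu, dim = dims)
  centres <- lapply(1:3, function(a) ((seq_len(dims[a])) - 0.5) * sp[a])
  for (b in spec$blobs) {
    c_mm <- (b$center - 0.5) * sp
    d2 <- lapply(1:3, function(a) ((centres[[a]] - c_mm[a]) / b$radii_mm[a])^2)
    inside <- outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+") <= 1
    vol <- vol + b$peak_hu * inside
  }
  if (spec$noise_sd_hu > 0) {
    vol <- vol + array(rnorm(prod(dims), 0, spec$noise_sd_hu), dim = dims)
  }
  plane <- setdiff(1:3, spec$axis)
  if (length(spec$blobs) >= roi_blob && length(spec$blobs) > 0) {
    b <- spec$blobs[[roi_blob]]
    half <- b$radii_mm[plane] / sp[plane] + 1
    cx <- b$center[plane[1]] - 1  # 0-based pixel coordinates
    cy <- b$center[plane[2]] - 1
    roi <- tibble(
      x = c(cx - half[1], cx + half[1], cx + half[1], cx - half[1]),
      y = c(cy - half[2], cy - half[2], cy + half[2], cy + half[2])
    )
  } else {
    cx <- dims[plane[1]] / 2; cy <- dims[plane[2]] / 2
    roi <- tibble(x = c(cx - 2, cx + 2, cx + 2, cx - 2),
                  y = c(cy - 2, cy - 2, cy + 2, cy + 2))
  }
  structure(list(volume = vol, spacing_mm = sp, roi = roi, spec = spec),
            class = "ct_phantom")
}
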