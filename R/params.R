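#' Testing-machine specification
#'
#' Describes the load-testing machine: sampling cadence, crosshead speed,
#' load cut-off and measurement accuracies. Defaults reproduce the
#' instrument settings used for nodule testing: samples every 20 ms at
#' 2.00 mm/min up to a 2000 N limit, with accuracies of +/- 0.1 N and
#' +/- 0.01 mm.
#'
#' @param sampling_interval_ms Sampling interval in milliseconds.
#' @param speed_mm_min Compression (crosshead) speed in mm/min.
#' @param load_limit_n Load cut-off in newtons; recording stops when the
#'   measured load reaches this limit.
#' @param load_accuracy_n Load measurement accuracy in newtons.
#' @param disp_accuracy_mm Displacement measurement accuracy in mm. Also
#'   the tolerance used when validating displacement monotonicity on read.
#' @return An object of class `machine_spec`.
#' @examples
#' machine_spec()
#' @export
machine_spec <- function(sampling_interval_ms = 20,
                         speed_mm_min = 2.00,
                         load_limit_n = 2000,
                         load_accuracy_n = 0.1,
                         disp_accuracy_mm = 0.01) {
  spec <- list(
    sampling_interval_ms = sampling_interval_ms,
    speed_mm_min = speed_mm_min,
    load_limit_n = load_limit_n,
    load_accuracy_n = load_accuracy_n,
    disp_accuracy_mm = disp_accuracy_mm
  )
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("machine_spec: `", nm, "` must be a single positive number"),
            class = "crushcurve_spec_error")
    }
  }
  structure(spec, class = "machine_spec")
}

#' @export
print.machine_spec <- function(x, ...) {
  cat("<machine_spec>\n")
  cat(sprintf("  sampling %g ms | speed %g mm/min | limit %g N | accuracy +/-%g N, +/-%g mm\n",
              x$sampling_interval_ms, x$speed_mm_min, x$load_limit_n,
              x$load_accuracy_n, x$disp_accuracy_mm))
  invisible(x)
}

#' Crush-curve shape parameters
#'
#' Parameterises the target stress-strain law sigma*(epsilon) of a single
#' simulated nodule. Two families are supported:
#'
#' * `three_phase`: an elastic ramp of slope `elastic_modulus` up to
#'   `yield_strain`, a serrated plateau at `plateau_stress` (stress drops
#'   arrive as a Poisson process of rate `drop_rate` per unit strain, each
#'   knocking stress down by `drop_depth_fraction` with exponential
#'   recovery), and a densification upturn beyond `densification_onset`
#'   following `plateau * (1 + k * ((eps - onset)/(0.95 - eps))^exponent)`
#'   with fixed gain `k = 10`.
#' * `gradual`: a smooth convex power law
#'   `sigma = gradual_scale * epsilon^gradual_power` with no plateau,
#'   matching the minority of nodules that stiffen monotonically.
#'
#' @param pattern `"three_phase"` or `"gradual"`.
#' @param elastic_modulus Stage-I slope, MPa per unit strain.
#' @param yield_strain Strain ending the elastic ramp, in (0, 0.2].
#' @param plateau_stress Plateau stress level, MPa.
#' @param drop_rate Expected number of stress-drop events per unit strain
#'   on the plateau (>= 0).
#' @param drop_depth_fraction Fractional stress drop per event, in [0, 1).
#' @param densification_onset Strain at which densification begins; must
#'   exceed `yield_strain` and lie below 0.9.
#' @param densification_exponent Exponent of the densification law (> 1).
#' @param gradual_scale,gradual_power Power-law parameters for the
#'   `gradual` family (`gradual_power` > 1).
#' @param noise_load_sd Gaussian load noise sd, N.
#' @param noise_disp_sd Gaussian displacement jitter sd, mm. Default is
#'   well below the machine accuracy so reading back simulated files never
#'   trips the monotonicity check.
#' @return An object of class `crush_params`.
#' @examples
#' crush_params(plateau_stress = 1, drop_rate = 0, noise_load_sd = 0)
#' @export
crush_params <- function(pattern = c("three_phase", "gradual"),
                         elastic_modulus = 12,
                         yield_strain = 0.05,
                         plateau_stress = 0.6,
                         drop_rate = 25,
                         drop_depth_fraction = 0.15,
                         densification_onset = 0.55,
                         densification_exponent = 1.5,
                         gradual_scale = 4,
                         gradual_power = 2,
                         noise_load_sd = 0.1,
                         noise_disp_sd = 0.001) {
  pattern <- match.arg(pattern)
  chk <- function(ok, msg) if (!ok) abort(paste0("crush_params: ", msg),
                                          class = "crushcurve_spec_error")
  chk(elastic_modulus > 0, "elastic_modulus must be > 0")
  chk(yield_strain > 0 && yield_strain <= 0.2, "yield_strain must be in (0, 0.2]")
  chk(plateau_stress > 0, "plateau_stress must be > 0")
  chk(drop_rate >= 0, "drop_rate must be >= 0")
  chk(drop_depth_fraction >= 0 && drop_depth_fraction < 1,
      "drop_depth_fraction must be in [0, 1)")
  chk(densification_onset > yield_strain && densification_onset < 0.9,
      "densification_onset must lie in (yield_strain, 0.9)")
  chk(densification_exponent > 1, "densification_exponent must be > 1")
  chk(gradual_scale > 0, "gradual_scale must be > 0")
  chk(gradual_power > 1, "gradual_power must be > 1")
  chk(noise_load_sd >= 0 && noise_disp_sd >= 0, "noise sds must be >= 0")
  structure(list(
    pattern = pattern,
    elastic_modulus = elastic_modulus,
    yield_strain = yield_strain,
    plateau_stress = plateau_stress,
    drop_rate = drop_rate,
    drop_depth_fraction = drop_depth_fraction,
    densification_onset = densification_onset,
    densification_exponent = densification_exponent,
    gradual_scale = gradual_scale,
    gradual_power = gradual_power,
    noise_load_sd = noise_load_sd,
    noise_disp_sd = noise_disp_sd
  ), class = "crush_params")
}

#' Per-nodule record
#'
#' One row of nodule metadata: geometry measured before testing (initial
#' projected area `A0` from a frontal photograph, height `H0` by calipers;
#' the nodule volume `V0 = A0 * H0` is assumed conserved during crushing),
#' CT density if available, and clinical covariates.
#'
#' @param nodule_id,patient_id Identifiers.
#' @param a0_mm2 Initial projected area, mm^2 (> 0).
#' @param h0_mm Initial height, mm (> 0).
#' @param ct_hu Mean CT number of the nodule, HU, or `NA`.
#' @param dialysis Logical covariate: specimen from a dialysis patient.
#' @param cusp Valve cusp of origin: `"L"`, `"R"` or `"N"`.
#' @param pattern_truth For simulated nodules, the generating pattern.
#' @return A one-row tibble with columns `nodule_id`, `patient_id`,
#'   `A0_mm2`, `H0_mm`, `V0_mm3`, `ct_hu`, `dialysis`, `cusp`,
#'   `pattern_truth`.
#' @export
nodule_record <- function(nodule_id, a0_mm2, h0_mm,
                          patient_id = NA_character_,
                          ct_hu = NA_real_, dialysis = NA,
                          cusp = NA_character_,
                          pattern_truth = NA_character_) {
  if (!is.numeric(a0_mm2) || !is.numeric(h0_mm) ||
      any(!is.finite(a0_mm2)) || any(!is.finite(h0_mm)) ||
      any(a0_mm2 <= 0) || any(h0_mm <= 0)) {
    abort("nodule_record: geometry requires A0 > 0 mm^2 and H0 > 0 mm",
          class = "crushcurve_geometry_error")
  }
  if (!all(is.na(cusp) | cusp %in% c("L", "R", "N"))) {
    abort("nodule_record: cusp must be one of 'L', 'R', 'N'",
          class = "crushcurve_spec_error")
  }
  tibble(
    nodule_id = as.character(nodule_id),
    patient_id = as.character(patient_id),
    A0_mm2 = a0_mm2,
    H0_mm = h0_mm,
    V0_mm3 = a0_mm2 * h0_mm,
    ct_hu = as.numeric(ct_hu),
    dialysis = as.logical(dialysis),
    cusp = as.character(cusp),
    pattern_truth = as.character(pattern_truth)
  )
}

#' Cohort simulation specification
#'
#' Defaults emulate the reference cohort: 129 nodules of which 118 crush in
#' three phases, mean CT number 937 [842, 1018] HU, a Pearson correlation of
#' 0.45 between HU and log low-strain stiffness (CS10), and dialysis
#' enrichment among non-three-phase nodules (20/118 vs 7/11). Geometry is
#' lognormal: projected area calibrated to the printed calcium-area
#' quartiles 23.67 [15.9, 35.22] mm^2; height median 3 mm (nodules larger
#' than 2 mm were tested).
#'
#' @param n_nodules Number of nodules.
#' @param three_phase_fraction Fraction crushing in three phases.
#' @param ct_mean Median CT number, HU.
#' @param ct_iqr Length-2 IQR of CT number, HU.
#' @param ct_stiffness_correlation Target Pearson correlation between HU
#'   and log CS10.
#' @param dialysis_rate_three_phase,dialysis_rate_gradual Dialysis rates
#'   within each pattern group.
#' @param cs10_median,cs10_iqr Median and IQR of the CS10 marginal (MPa),
#'   defining the lognormal stiffness distribution.
#' @param a0_median_mm2,a0_iqr_mm2 Median and IQR of projected area.
#' @param h0_median_mm,h0_sdlog Median and log-sd of nodule height.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nodules = 129,
                        three_phase_fraction = 118 / 129,
                        ct_mean = 937,
                        ct_iqr = c(842, 1018),
                        ct_stiffness_correlation = 0.45,
                        dialysis_rate_three_phase = 20 / 118,
                        dialysis_rate_gradual = 7 / 11,
                        cs10_median = 0.38,
                        cs10_iqr = c(0.23, 0.86),
                        a0_median_mm2 = 23.67,
                        a0_iqr_mm2 = c(15.9, 35.22),
                        h0_median_mm = 3,
                        h0_sdlog = 0.2,
                        seed = 1L) {
  chk <- function(ok, msg) if (!ok) abort(paste0("cohort_spec: ", msg),
                                          class = "crushcurve_spec_error")
  chk(n_nodules >= 1, "n_nodules must be >= 1")
  rates <- c(three_phase_fraction, dialysis_rate_three_phase, dialysis_rate_gradual)
  chk(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  chk(length(ct_iqr) == 2 && diff(ct_iqr) > 0, "ct_iqr must be increasing pair")
  chk(length(cs10_iqr) == 2 && all(cs10_iqr > 0) && diff(cs10_iqr) > 0,
      "cs10_iqr must be a positive increasing pair")
  chk(abs(ct_stiffness_correlation) < 1, "correlation must be in (-1, 1)")
  chk(a0_median_mm2 > 0 && h0_median_mm > 0, "geometry medians must be > 0")
  structure(list(
    n_nodules = as.integer(n_nodules),
    three_phase_fraction = three_phase_fraction,
    ct_mean = ct_mean,
    ct_iqr = ct_iqr,
    ct_stiffness_correlation = ct_stiffness_correlation,
    dialysis_rate_three_phase = dialysis_rate_three_phase,
    dialysis_rate_gradual = dialysis_rate_gradual,
    cs10_median = cs10_median,
    cs10_iqr = cs10_iqr,
    a0_median_mm2 = a0_median_mm2,
    a0_iqr_mm2 = a0_iqr_mm2,
    h0_median_mm = h0_median_mm,
    h0_sdlog = h0_sdlog,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' CT phantom specification
#'
#' Describes a synthetic CT volume: a constant background with additive
#' ellipsoidal high-density blobs plus Gaussian noise, and the slab used
#' for maximum-intensity projection.
#'
#' @param shape Integer length-3 volume shape in voxels (x, y, z).
#' @param spacing_mm Numeric length-3 voxel spacing, mm.
#' @param background_hu Background intensity, HU.
#' @param blobs List of blobs, each a list with `center` (voxel units,
#'   length 3), `radii_mm` (length 3) and `peak_hu` (added to background).
#' @param noise_sd_hu Gaussian noise sd, HU.
#' @param slab_mm Length-2 slab bounds along the projection axis, mm.
#' @param axis Projection axis (1, 2 or 3).
#' @return An object of class `ct_phantom_spec`.
#' @export
ct_phantom_spec <- function(shape = c(64L, 64L, 40L),
                            spacing_mm = c(0.5, 0.5, 0.5),
                            background_hu = 40,
                            blobs = list(),
                            noise_sd_hu = 0,
                            slab_mm = c(1, 19),
                            axis = 3L) {
  chk <- function(ok, msg) if (!ok) abort(paste0("ct_phantom_spec: ", msg),
                                          class = "crushcurve_spec_error")
  chk(length(shape) == 3 && all(shape >= 1), "shape must be 3 positive counts")
  chk(length(spacing_mm) == 3 && all(spacing_mm > 0), "spacing must be positive")
  chk(axis %in% 1:3, "axis must be 1, 2 or 3")
  chk(length(slab_mm) == 2 && slab_mm[2] > slab_mm[1], "slab_mm must be increasing")
  extent <- shape[axis] * spacing_mm[axis]
  chk(slab_mm[2] - slab_mm[1] <= extent,
      "slab thickness exceeds the volume extent along the projection axis")
  for (b in blobs) {
    chk(all(c("center", "radii_mm", "peak_hu") %in% names(b)),
        "each blob needs center, radii_mm, peak_hu")
    centre_mm <- (b$center - 0.5) * spacing_mm
    chk(all(centre_mm > 0) && all(centre_mm < shape * spacing_mm),
        "blob center lies outside the volume")
  }
  structure(list(
    shape = as.integer(shape), spacing_mm = spacing_mm,
    background_hu = background_hu, blobs = blobs,
    noise_sd_hu = noise_sd_hu, slab_mm = slab_mm, axis = as.integer(axis)
  ), class = "ct_phantom_spec")
}

#' Pipeline run configuration
#'
#' Collects every analysis constant in one auditable place: the preload
#' origin threshold (0.02 N/mm^2), the strain grid increment (0.05), the
#' CS/CE strain levels (10-50%), the crush-pattern criteria (area ratio
#' >= 0.7 over the window [0.05, 0.5], or a negative grid slope inside
#' it), the CT segmentation threshold (600 HU) and the quantile
#' convention (type 7, linear interpolation of order statistics).
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read recordings and a nodule table from `input_dir`).
#' @param out_dir Output directory for result tables and figures.
#' @param input_dir Directory with `nodules.csv` and per-nodule
#'   `<nodule_id>.csv` recordings (ingest mode).
#' @param cohort A [cohort_spec()] (simulate mode).
#' @param machine A [machine_spec()].
#' @param grid_increment Strain grid increment.
#' @param levels Strain levels for CS/CE.
#' @param preload_threshold_n_mm2 Preload stress defining the origin.
#' @param area_ratio_threshold Classifier area-ratio cut-off.
#' @param slope_window Strain window scanned for a negative slope.
#' @param classifier_baseline Baseline stress subtracted in the area
#'   ratio, N/mm^2.
#' @param ct_threshold_hu CT segmentation threshold.
#' @param quantile_type Quantile algorithm type passed to
#'   [stats::quantile()].
#' @param seed Integer seed.
#' @param figures Write figures under `out_dir/figures`?
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       out_dir = tempfile("crushcurve-run-"),
                       input_dir = NULL,
                       cohort = cohort_spec(),
                       machine = machine_spec(),
                       grid_increment = 0.05,
                       levels = seq(0.1, 0.5, by = 0.1),
                       preload_threshold_n_mm2 = 0.02,
                       area_ratio_threshold = 0.7,
                       slope_window = c(0.05, 0.5),
                       classifier_baseline = 0.02,
                       ct_threshold_hu = 600,
                       quantile_type = 7,
                       seed = 1L,
                       figures = TRUE) {
  mode <- match.arg(mode)
  chk <- function(ok, msg) if (!ok) abort(paste0("run_config: ", msg),
                                          class = "crushcurve_spec_error")
  chk(grid_increment > 0, "grid_increment must be > 0")
  chk(all(levels > 0), "levels must be positive")
  mult <- levels / grid_increment
  chk(all(abs(mult - round(mult)) < 1e-9),
      "levels must be multiples of grid_increment")
  chk(preload_threshold_n_mm2 > 0 && area_ratio_threshold > 0 &&
        ct_threshold_hu > 0, "thresholds must be positive")
  chk(length(slope_window) == 2 && slope_window[2] > slope_window[1],
      "slope_window must be an increasing pair")
  if (mode == "ingest") chk(!is.null(input_dir), "ingest mode needs input_dir")
  structure(list(
    mode = mode, out_dir = out_dir, input_dir = input_dir,
    cohort = cohort, machine = machine,
    grid_increment = grid_increment, levels = levels,
    preload_threshold_n_mm2 = preload_threshold_n_mm2,
    area_ratio_threshold = area_ratio_threshold,
    slope_window = slope_window,
    classifier_baseline = classifier_baseline,
    ct_threshold_hu = ct_threshold_hu,
    quantile_type = quantile_type,
    seed = as.integer(seed), figures = figures
  ), class = "run_config")
}
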