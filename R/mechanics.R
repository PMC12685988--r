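#' Locate the compression origin in a recording
#'
#' The displacement origin is the first sample whose preload stress
#' exceeds 0.02 N/mm^2, i.e. the first sample with `load / A0 >
#' threshold`; the initial projected area A0 is used because the true
#' contact area at touch-down is unknown. Displacements are re-zeroed to
#' that sample.
#'
#' @param rec A recording tibble with columns `time_ms`, `load_N`,
#'   `displacement_mm`.
#' @param a0_mm2 Initial projected area, mm^2.
#' @param threshold Preload stress threshold, N/mm^2.
#' @return A list with `index` (origin sample in the source recording)
#'   and `recording` (the samples from the origin on, displacement
#'   re-zeroed).
#' @export
find_origin <- function(rec, a0_mm2, threshold = 0.02) {
  stopifnot(is.data.frame(rec), nrow(rec) > 0)
  if (!is.numeric(a0_mm2) || a0_mm2 <= 0) {
    abort("find_origin: A0 must be > 0", class = "crushcurve_geometry_error")
  }
  idx <- which(rec$load_N / a0_mm2 > threshold)
  if (!length(idx)) {
    abort(sprintf(
      "find_origin: no contact - preload never exceeded %.3g N/mm^2 (max %.3g)",
      threshold, max(rec$load_N) / a0_mm2), class = "crushcurve_no_contact")
  }
  i <- idx[1]
  out <- rec[i:nrow(rec), , drop = FALSE]
  out$displacement_mm <- out$displacement_mm - rec$displacement_mm[i]
  list(index = i, recording = as_tibble(out))
}

#' Convert a recording to a corrected stress-strain curve
#'
#' Applies the evolving-contact-area stress model: with conserved volume
#' `V0 = A0 * H0` and current height `H = H0 * (1 - eps)`, the loading
#' area is `A = Rc * V0 / H = Rc * A0 / (1 - eps)` where the contact
#' ratio `Rc = min(0.5 + eps, 1)` ramps linearly from 0.5 at first touch
#' to 1.0 at half height (and is clamped at 1 beyond). Strain is
#' displacement after the origin divided by the initial height. Strain is
#' made non-decreasing with a running maximum (the platen position cannot
#' retreat; jitter is within the machine accuracy), and samples at or
#' beyond strain 0.95 are dropped.
#'
#' @param rec A recording tibble (see [read_load_test()]).
#' @param nodule A one-row nodule table from [nodule_record()], or a list
#'   with `A0_mm2` and `H0_mm`.
#' @param preload_threshold Origin stress threshold, N/mm^2.
#' @return A tibble of class `crush_curve` with columns `strain`,
#'   `stress_mpa`, `contact_ratio`, `area_mm2`, `height_mm`, `load_n`,
#'   `time_ms`; attributes `nodule_id`, `a0_mm2`, `h0_mm`,
#'   `origin_index`.
#' @examples
#' rec <- simulate_crush_curve(crush_params(noise_load_sd = 0, drop_rate = 0),
#'                             nodule_record("n1", 20, 3), seed = 1)
#' curve <- to_stress_strain(rec, nodule_record("n1", 20, 3))
#' @export
to_stress_strain <- function(rec, nodule, preload_threshold = 0.02) {
  a0 <- as.numeric(nodule$A0_mm2)[1]
  h0 <- as.numeric(nodule$H0_mm)[1]
  if (!is.finite(a0) || !is.finite(h0) || a0 <= 0 || h0 <= 0) {
    abort("to_stress_strain: nodule geometry requires A0 > 0 and H0 > 0",
          class = "crushcurve_geometry_error")
  }
  org <- find_origin(rec, a0, threshold = preload_threshold)
  r <- org$recording
  disp <- cummax(pmax(r$displacement_mm, 0))
  eps <- disp / h0
  if (any(eps >= 1)) {
    abort(paste0("to_stress_strain: strain reached 1.0 before truncation; ",
                 "displacement exceeds nodule height - geometry suspect"),
          class = "crushcurve_geometry_error")
  }
  keep <- eps < 0.95
  eps <- eps[keep]
  rc <- pmin(0.5 + eps, 1.0)
  area <- rc * a0 / (1 - eps)
  load <- r$load_N[keep]
  out <- tibble(
    strain = eps,
    stress_mpa = load / area,
    contact_ratio = rc,
    area_mm2 = area,
    height_mm = h0 * (1 - eps),
    load_n = load,
    time_ms = r$time_ms[keep]
  )
  id <- if (!is.null(nodule$nodule_id)) as.character(nodule$nodule_id)[1] else
    attr(rec, "nodule_id") %||% NA_character_
  structure(out, nodule_id = id, a0_mm2 = a0, h0_mm = h0,
            origin_index = org$index,
            class = c("crush_curve", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a stress-strain curve onto a regular strain grid
#'
#' Linear interpolation of stress at multiples of `increment`, from 0 up
#' to the largest multiple not exceeding the maximum achieved strain.
#' The per-nodule cohort tables use the 0.05 grid; CS/CE are computed on
#' the raw curve, not this grid.
#'
#' @param curve A `crush_curve` (or any tibble with `strain` and
#'   `stress_mpa`).
#' @param increment Grid spacing in strain units.
#' @return A tibble of class `crush_curve_grid` with columns `strain`,
#'   `stress_mpa`.
#' @export
resample_to_grid <- function(curve, increment = 0.05) {
  stopifnot(is.data.frame(curve), increment > 0)
  if (nrow(curve) < 2) {
    abort("resample_to_grid: need at least 2 samples",
          class = "crushcurve_input_error")
  }
  max_eps <- max(curve$strain)
  top <- floor(max_eps / increment + 1e-12) * increment
  grid <- seq(0, top, by = increment)
  s <- approx(curve$strain, curve$stress_mpa, xout = grid,
              ties = mean, rule = 1)$y
  structure(tibble(strain = grid, stress_mpa = s),
            nodule_id = attr(curve, "nodule_id"), increment = increment,
            class = c("crush_curve_grid", class(tibble())))
}

# stress interpolated at one strain (linear, averaged ties)
.stress_at <- function(curve, level) {
  approx(curve$strain, curve$stress_mpa, xout = level, ties = mean, rule = 1)$y
}

#' Compression Strength: peak stress up to a strain level
#'
#' CS at level `s` is the maximum stress observed over strains in
#' `[0, s]` on the raw origin-corrected curve (e.g. CS20 is the peak over
#' 0-20% strain). If the curve never reached the level the value is
#' missing (`NA`), never extrapolated.
#'
#' @param curve A `crush_curve` (or tibble with `strain`, `stress_mpa`).
#' @param level Strain level (e.g. 0.2 for CS20).
#' @return CS in MPa, or `NA_real_` if compression was insufficient.
#' @export
compression_strength <- function(curve, level) {
  stopifnot(is.data.frame(curve), level > 0)
  if (nrow(curve) == 0 || max(curve$strain) < level) return(NA_real_)
  in_range <- curve$strain <= level + 1e-12
  max(c(curve$stress_mpa[in_range], .stress_at(curve, level)))
}

#' Compression Energy: area under the stress-strain curve
#'
#' CE at level `s` is the trapezoidal integral of stress (MPa) over
#' strain in `[0, s]` (e.g. CE30 is the area over 0-30% strain). The
#' unit identity MPa x strain = MJ/m^3 = J/cm^3 holds with no conversion
#' factor: CE is the work per unit initial volume needed to crush the
#' nodule to that strain. If the first corrected sample sits above strain
#' 0, a sample at (0, first stress) is prepended so the integral starts
#' at the origin. Missing (`NA`) if the level was not reached.
#'
#' @inheritParams compression_strength
#' @return CE in J/cm^3, or `NA_real_` if compression was insufficient.
#' @export
compression_energy <- function(curve, level) {
  stopifnot(is.data.frame(curve), level > 0)
  if (nrow(curve) == 0 || max(curve$strain) < level) return(NA_real_)
  x <- curve$strain
  y <- curve$stress_mpa
  if (x[1] > 0) { x <- c(0, x); y <- c(y[1], y) }
  keep <- x < level
  x_clip <- c(x[keep], level)
  y_clip <- c(y[keep], .stress_at(curve, level))
  sum(diff(x_clip) * (head(y_clip, -1) + tail(y_clip, -1)) / 2)
}

#' Per-nodule stiffness profile
#'
#' Evaluates CS and CE at each requested strain level on the raw curve.
#'
#' @param curve A `crush_curve`.
#' @param levels Strain levels; default 10-50% in steps of 10%.
#' @return A one-row tibble with `nodule_id`, `CS10`..., `CE10`... and
#'   `max_strain`. Levels beyond the achieved strain are `NA`.
#' @export
stiffness_profile <- function(curve, levels = seq(0.1, 0.5, by = 0.1)) {
  stopifnot(is.data.frame(curve), all(levels > 0))
  cs <- vapply(levels, function(l) compression_strength(curve, l), numeric(1))
  ce <- vapply(levels, function(l) compression_energy(curve, l), numeric(1))
  out <- tibble(nodule_id = attr(curve, "nodule_id") %||% NA_character_)
  for (i in seq_along(levels)) {
    out[[sprintf("CS%d", round(levels[i] * 100))]] <- cs[i]
  }
  for (i in seq_along(levels)) {
    out[[sprintf("CE%d", round(levels[i] * 100))]] <- ce[i]
  }
  out$max_strain <- max(curve$strain)
  out
}
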