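#' Area ratio of a gridded stress-strain curve
#'
#' Ratio of the baseline-subtracted area under the curve over strains
#' 0-0.5 to the area of the reference rectangle whose height runs from
#' the preload stress (0.02 N/mm^2) to the stress at strain 0.5 and whose
#' width is 0.5. A foam-like plateau gives a ratio near 1; a smooth
#' convex rise gives roughly 1/3 for a quadratic law. The numerator
#' clips the integrand at zero where stress sits below the baseline.
#'
#' @param grid A gridded curve from [resample_to_grid()] reaching strain
#'   0.5.
#' @param baseline Baseline stress subtracted from both numerator and
#'   rectangle height, N/mm^2.
#' @return The dimensionless ratio, or `NA_real_` (with a warning) when
#'   the stress at strain 0.5 does not exceed the baseline so the
#'   rectangle degenerates.
#' @export
area_ratio <- function(grid, baseline = 0.02) {
  stopifnot(is.data.frame(grid))
  if (max(grid$strain) < 0.5) {
    abort("area_ratio: curve must reach strain 0.5",
          class = "crushcurve_input_error")
  }
  g <- grid[grid$strain <= 0.5 + 1e-12, ]
  s_half <- g$stress_mpa[which.min(abs(g$strain - 0.5))]
  if (s_half <= baseline) {
    warn("area_ratio: stress at strain 0.5 does not exceed the baseline; ratio undefined")
    return(NA_real_)
  }
  y <- pmax(g$stress_mpa - baseline, 0)
  num <- sum(diff(g$strain) * (head(y, -1) + tail(y, -1)) / 2)
  num / ((s_half - baseline) * 0.5)
}

#' Detect a negative slope on the strain grid
#'
#' `TRUE` if stress decreases between any two consecutive grid points
#' whose strains lie inside the window (default 0.05-0.5). Evaluated on
#' the 0.05 grid rather than raw samples so machine noise at the 0.1 N
#' accuracy scale does not trigger it; decreases within floating-point
#' rounding of the interpolation (relative 1e-9 of the window maximum)
#' are ignored.
#'
#' @param grid A gridded curve from [resample_to_grid()].
#' @param window Length-2 strain window.
#' @return Logical.
#' @export
has_negative_slope <- function(grid, window = c(0.05, 0.5)) {
  stopifnot(is.data.frame(grid), length(window) == 2)
  g <- grid[grid$strain >= window[1] - 1e-12 &
              grid$strain <= window[2] + 1e-12, ]
  if (nrow(g) < 2) return(FALSE)
  tol <- 1e-9 * max(abs(g$stress_mpa))
  any(diff(g$stress_mpa) < -tol)
}

#' Classify the crush pattern of a curve
#'
#' A nodule crushes in three phases (elastic rise, serrated plateau,
#' densification) if its area ratio is at least `area_threshold` (default
#' 0.7) or a negative slope appears between strains 0.05 and 0.5;
#' otherwise its stress rises gradually. Curves not reaching strain 0.5
#' are unclassifiable and get a missing label.
#'
#' @param grid A gridded curve from [resample_to_grid()].
#' @param area_threshold Area-ratio cut-off.
#' @param slope_window Window scanned for a negative slope.
#' @param baseline Baseline stress for the area ratio, N/mm^2.
#' @return A one-row tibble: `nodule_id`, `area_ratio`,
#'   `negative_slope_found`, `label` (`"three_phase"`, `"gradual"` or
#'   `NA`), `classifiable`.
#' @examples
#' g <- resample_to_grid(tibble::tibble(strain = seq(0, 0.6, 0.01),
#'                                      stress_mpa = rep(1, 61)))
#' classify_phase(g)
#' @export
classify_phase <- function(grid, area_threshold = 0.7,
                           slope_window = c(0.05, 0.5), baseline = 0.02) {
  stopifnot(is.data.frame(grid))
  id <- attr(grid, "nodule_id") %||% NA_character_
  if (max(grid$strain) < 0.5) {
    return(tibble(nodule_id = id, area_ratio = NA_real_,
                  negative_slope_found = NA, label = NA_character_,
                  classifiable = FALSE))
  }
  ratio <- suppressWarnings(area_ratio(grid, baseline = baseline))
  neg <- has_negative_slope(grid, window = slope_window)
  label <- if (isTRUE(neg) || (!is.na(ratio) && ratio >= area_threshold)) {
    "three_phase"
  } else if (!is.na(ratio)) {
    "gradual"
  } else {
    NA_character_
  }
  tibble(nodule_id = id, area_ratio = ratio, negative_slope_found = neg,
         label = label, classifiable = !is.na(label))
}
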