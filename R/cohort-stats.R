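#' Quartile stress table across a cohort
#'
#' For every strain grid point reached by at least one curve, the
#' minimum, 25th percentile, median, 75th percentile and maximum stress
#' across nodules, plus two dispersion ratio rows: p75/p25 and max/min.
#' Ratios are quotients of the unrounded statistics; rounding is left to
#' display (see [format_quartile_table()]), since ratios of rounded cells
#' do not reproduce ratios of the underlying values.
#'
#' @param curves Either a long tibble with columns `nodule_id`, `strain`,
#'   `stress_mpa`, or a list of gridded curves from [resample_to_grid()].
#' @param quantile_type Quantile algorithm (see [stats::quantile()];
#'   type 7 = linear interpolation of order statistics, the convention of
#'   the R default).
#' @param drop_zero Drop the strain-0 grid point (the reference cohort
#'   tables start at 0.05).
#' @return A tibble with one row per strain: `strain`, `n`, `min`, `p25`,
#'   `median`, `p75`, `max`, `ratio_p75_p25`, `ratio_max_min`.
#' @export
stress_quartile_table <- function(curves, quantile_type = 7,
                                  drop_zero = TRUE) {
  long <- .as_long_curves(curves)
  if (nrow(long) == 0) {
    abort("stress_quartile_table: empty cohort", class = "crushcurve_input_error")
  }
  if (drop_zero) long <- long[long$strain > 1e-12, ]
  q <- function(x, p) unname(quantile(x, p, type = quantile_type))
  out <- long %>%
    group_by(.data$strain) %>%
    summarise(
      n = dplyr::n(),
      min = min(.data$stress_mpa),
      p25 = q(.data$stress_mpa, 0.25),
      median = q(.data$stress_mpa, 0.5),
      p75 = q(.data$stress_mpa, 0.75),
      max = max(.data$stress_mpa),
      .groups = "drop"
    ) %>%
    add_ratio_rows() %>%
    arrange(.data$strain)
  out
}

#' Add dispersion ratio rows to a quartile table
#'
#' Computes `ratio_p75_p25 = p75/p25` and `ratio_max_min = max/min` from
#' the (unrounded) quartile statistics. Kept separate from display
#' rounding: a ratio of rounded cells does not reproduce the ratio of
#' the underlying values.
#'
#' @param qtable A tibble with columns `p25`, `p75`, `min`, `max`.
#' @return The table with the two ratio columns appended.
#' @export
add_ratio_rows <- function(qtable) {
  stopifnot(all(c("p25", "p75", "min", "max") %in% names(qtable)))
  mutate(qtable, ratio_p75_p25 = .data$p75 / .data$p25,
         ratio_max_min = .data$max / .data$min)
}

.as_long_curves <- function(curves) {
  if (is.data.frame(curves)) {
    stopifnot(all(c("strain", "stress_mpa") %in% names(curves)))
    return(as_tibble(curves))
  }
  bind_rows(lapply(seq_along(curves), function(i) {
    g <- curves[[i]]
    id <- attr(g, "nodule_id") %||% names(curves)[i] %||% as.character(i)
    tibble(nodule_id = id, strain = g$strain, stress_mpa = g$stress_mpa)
  }))
}

#' Round a quartile table for display
#'
#' Stress statistics to 3 decimals, ratio rows to 1 or 2 decimals -
#' applied after, never before, the ratio computation.
#'
#' @param qtable Output of [stress_quartile_table()].
#' @param digits_stress,digits_ratio Decimal places.
#' @return The rounded tibble.
#' @export
format_quartile_table <- function(qtable, digits_stress = 3, digits_ratio = 2) {
  qtable %>%
    mutate(across(all_of(c("min", "p25", "median", "p75", "max")),
                  ~ round(.x, digits_stress)),
           across(all_of(c("ratio_p75_p25", "ratio_max_min")),
                  ~ round(.x, digits_ratio)))
}

#' Median and IQR of CS/CE across a cohort
#'
#' @param profiles Stiffness profiles (rows from [stiffness_profile()] or
#'   any table with `CS`/`CE` columns).
#' @param quantile_type Quantile algorithm type.
#' @return A tibble with one row per parameter: `parameter`, `n`
#'   (non-missing values), `median`, `p25`, `p75`. Parameters with no
#'   non-missing values are omitted with a warning.
#' @export
stiffness_summary <- function(profiles, quantile_type = 7) {
  stopifnot(is.data.frame(profiles))
  pars <- grep("^C[SE][0-9]+$", names(profiles), value = TRUE)
  if (!length(pars)) {
    abort("stiffness_summary: no CS/CE columns found",
          class = "crushcurve_input_error")
  }
  q <- function(x, p) unname(quantile(x, p, type = quantile_type))
  rows <- lapply(pars, function(pn) {
    v <- profiles[[pn]][!is.na(profiles[[pn]])]
    if (!length(v)) {
      warn(paste0("stiffness_summary: all values missing for ", pn, "; omitted"))
      return(NULL)
    }
    tibble(parameter = pn, n = length(v), median = q(v, 0.5),
           p25 = q(v, 0.25), p75 = q(v, 0.75))
  })
  bind_rows(rows)
}

#' Correlate stiffness parameters with CT density
#'
#' Pearson correlation between each CS/CE parameter and the nodule mean
#' CT number, with the two-sided p value from the t transform. Pairs with
#' a missing value in either variable are excluded listwise per
#' parameter.
#'
#' @param profiles Stiffness profiles keyed by `nodule_id`.
#' @param records Nodule table with `nodule_id` and `ct_hu`.
#' @param min_pairs Minimum complete pairs; parameters with fewer are
#'   omitted with a warning.
#' @return A tibble: `parameter`, `r`, `p_value`, `n`.
#' @export
correlate_with_ct <- function(profiles, records, min_pairs = 3) {
  stopifnot(is.data.frame(profiles), is.data.frame(records))
  joined <- left_join(profiles, records[c("nodule_id", "ct_hu")],
                      by = "nodule_id")
  pars <- grep("^C[SE][0-9]+$", names(profiles), value = TRUE)
  rows <- lapply(pars, function(pn) {
    ok <- !is.na(joined[[pn]]) & !is.na(joined$ct_hu)
    if (sum(ok) < min_pairs) {
      warn(paste0("correlate_with_ct: fewer than ", min_pairs,
                  " complete pairs for ", pn, "; omitted"))
      return(NULL)
    }
    ct <- cor.test(joined$ct_hu[ok], joined[[pn]][ok], method = "pearson")
    tibble(parameter = pn, r = unname(ct$estimate),
           p_value = ct$p.value, n = sum(ok))
  })
  bind_rows(rows)
}

#' Two-group contrast
#'
#' Compares an outcome between two groups. A logical (or two-level)
#' outcome is tested with the two-sided Fisher exact test on the 2x2
#' table; a continuous outcome with the two-sided Mann-Whitney U test
#' (normal approximation with tie correction), reporting group medians.
#'
#' @param data A data frame.
#' @param group Name of the two-level grouping column.
#' @param outcome Name of the outcome column (logical/two-level or
#'   numeric).
#' @return An object of class `crush_contrast`; see
#'   [tidy.crush_contrast()] and [glance.crush_contrast()].
#' @examples
#' d <- tibble::tibble(pattern = rep(c("three_phase", "gradual"), c(118, 11)),
#'                     dialysis = rep(c(TRUE, FALSE, TRUE, FALSE),
#'                                    c(20, 98, 7, 4)))
#' cmp <- compare_groups(d, "pattern", "dialysis")
#' glance(cmp)$p_value # ~0.002
#' @export
compare_groups <- function(data, group, outcome) {
  stopifnot(is.data.frame(data), group %in% names(data),
            outcome %in% names(data))
  g <- data[[group]]
  y <- data[[outcome]]
  lv <- if (is.factor(g)) levels(droplevels(factor(g))) else sort(unique(as.character(g)))
  if (length(lv) != 2) {
    abort("compare_groups: grouping column must have exactly 2 non-empty levels",
          class = "crushcurve_input_error")
  }
  g <- factor(as.character(g), levels = lv)
  if (any(table(g) == 0)) {
    abort("compare_groups: one group is empty", class = "crushcurve_input_error")
  }
  if (is.logical(y) || length(unique(y[!is.na(y)])) == 2) {
    yl <- if (is.logical(y)) y else y == sort(unique(y))[2]
    tab <- table(g, factor(yl, levels = c(TRUE, FALSE)))
    ft <- fisher.test(tab, alternative = "two.sided")
    summary_tbl <- tibble(
      group = lv,
      n = as.integer(table(g)),
      events = as.integer(tab[, "TRUE"]),
      proportion = as.numeric(tab[, "TRUE"] / table(g))
    )
    res <- list(method = "fisher_exact", p_value = ft$p.value,
                statistic = unname(ft$estimate), statistic_name = "odds_ratio",
                table = unclass(tab), summary = summary_tbl,
                group = group, outcome = outcome)
  } else {
    wt <- wilcox.test(y ~ g, exact = FALSE, correct = TRUE)
    summary_tbl <- data.frame(g = g, y = y) %>%
      group_by(.data$g) %>%
      summarise(n = sum(!is.na(.data$y)),
                median = median(.data$y, na.rm = TRUE), .groups = "drop") %>%
      dplyr::rename(group = "g")
    res <- list(method = "mann_whitney_u", p_value = wt$p.value,
                statistic = unname(wt$statistic), statistic_name = "U",
                table = NULL, summary = summary_tbl,
                group = group, outcome = outcome)
  }
  structure(res, class = "crush_contrast")
}

#' @export
print.crush_contrast <- function(x, ...) {
  cat(sprintf("<crush_contrast> %s of '%s' by '%s': p = %.4g\n",
              x$method, x$outcome, x$group, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `crush_contrast`.
#' @param ... Unused.
#' @method tidy crush_contrast
#' @export
tidy.crush_contrast <- function(x, ...) x$summary

#' @rdname compare_groups
#' @method glance crush_contrast
#' @export
glance.crush_contrast <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         statistic_name = x$statistic_name, p_value = x$p_value)
}
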