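#' Normalize a 9-point SAM rating to the unit interval
#'
#' Self-Assessment Manikin ratings run 1 ("very unpleasant" / "calm") to 9
#' ("extremely pleasant" / "excited"). The default `corrected` mode maps
#' the scale onto \[0, 1\] as `(rated - 1) / 8`, so the scale ends land
#' exactly on 0 and 1. The `as_printed` mode divides by the scale range
#' without subtracting the minimum (`rated / 8`, yielding 0.125--1.125);
#' it is kept for auditability of the min-subtracted correction and is not
#' used by the analysis functions.
#'
#' @param rated Integer rating(s) in 1..9.
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return Numeric normalized rating(s).
#' @export
normalize_rating <- function(rated, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (any(rated < 1 | rated > 9 | rated != round(rated)))
    stop("ratings must be integers in 1..9", call. = FALSE)
  if (mode == "corrected") (rated - 1) / 8 else rated / 8
}

rating_col <- function(dimension) {
  switch(match.arg(dimension, c("valence", "arousal")),
         valence = "rated_valence", arousal = "rated_arousal")
}

setting_col <- function(dimension) {
  switch(match.arg(dimension, c("valence", "arousal")),
         valence = "valence_setting", arousal = "arousal_setting")
}

check_records <- function(records) {
  need <- c("participant_id", "valence_setting", "arousal_setting",
            "instance", "rated_valence", "rated_arousal", "musician")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("ratings table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("empty ratings table", call. = FALSE)
  invisible(records)
}

#' Read a ratings table from CSV
#'
#' Expected columns: `participant_id`, `valence_setting`, `arousal_setting`,
#' `instance`, `rated_valence`, `rated_arousal`, `musician`.
#'
#' @param path CSV file path.
#' @return Validated ratings data frame.
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path)
  if (is.character(d$musician)) d$musician <- as.logical(d$musician)
  check_records(d)
}

#' Average normalized ratings by parameter setting
#'
#' Pools every record sharing the chosen dimension's parameter setting --
#' marginalising over the other dimension, e.g. all stimuli generated at
#' valence 0 regardless of arousal -- and reports the mean and standard
#' error of the record-level normalized ratings.
#'
#' @param records Ratings table (see [read_ratings()]).
#' @param dimension `"valence"` or `"arousal"`.
#' @return Data frame with columns `setting`, `mean_rating`, `se`, `n`,
#'   one row per distinct setting value, ordered by setting.
#' @export
average_by_setting <- function(records, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  check_records(records)
  s <- records[[setting_col(dimension)]]
  r <- normalize_rating(records[[rating_col(dimension)]])
  agg <- lapply(split(r, s), function(x)
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x)))
  out <- data.frame(setting = as.numeric(names(agg)),
                    mean_rating = vapply(agg, `[[`, 0, "mean"),
                    se = vapply(agg, `[[`, 0, "se"),
                    n = as.integer(vapply(agg, `[[`, 0, "n")))
  out <- out[order(out$setting), ]
  rownames(out) <- NULL
  out
}

#' Average normalized ratings by affect point
#'
#' One row per distinct (valence setting, arousal setting) pair -- the
#' point-level analogue of [average_by_setting()], used by the multiple
#' regression.
#'
#' @inheritParams average_by_setting
#' @return Data frame with columns `valence_setting`, `arousal_setting`,
#'   `mean_rating`, `se`, `n`.
#' @export
average_by_point <- function(records, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  check_records(records)
  key <- interaction(records$valence_setting, records$arousal_setting,
                     drop = TRUE)
  r <- normalize_rating(records[[rating_col(dimension)]])
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(valence_setting = records$valence_setting[[i[[1]]]],
               arousal_setting = records$arousal_setting[[i[[1]]]],
               mean_rating = mean(r[i]),
               se = stats::sd(r[i]) / sqrt(length(i)),
               n = length(i))
  }))
  out <- out[order(out$valence_setting, out$arousal_setting), ]
  rownames(out) <- NULL
  out
}

am_regression <- function(fit, predictors = NULL) {
  # perfect fits are expected from the noiseless simulator; summary.lm's
  # "essentially perfect fit" warning is noise here
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  r2 <- unname(sm$r.squared)
  constant_response <- stats::sd(stats::model.frame(fit)[[1L]]) < 1e-12
  if (constant_response || !is.finite(r2)) r2 <- 0  # nothing to explain
  f <- if (constant_response || is.null(fstat) || !is.finite(fstat[["value"]]))
    0 else unname(fstat[["value"]])
  p <- if (f == 0) 1 else
    unname(stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                     lower.tail = FALSE))
  structure(list(
    r_squared = r2,
    f_statistic = f,
    p_value = p,
    coefficients = stats::coef(fit),
    aic = stats::AIC(fit),
    n = length(stats::fitted(fit)),
    predictors = predictors,
    fit = fit
  ), class = "am_regression")
}

#' @export
print.am_regression <- function(x, ...) {
  cat(sprintf("<regression> R^2 = %.3f, F = %.2f, p = %.4g, AIC = %.2f (n = %d)\n",
              x$r_squared, x$f_statistic, x$p_value, x$aic, x$n))
  if (!is.null(x$predictors)) {
    for (i in seq_len(nrow(x$predictors)))
      cat(sprintf("  %s: beta = %.3f, F = %.2f, p = %.4g\n",
                  x$predictors$term[[i]], x$predictors$estimate[[i]],
                  x$predictors$f[[i]], x$predictors$p[[i]]))
  }
  invisible(x)
}

#' Simple linear regression of mean ratings on parameter settings
#'
#' Ordinary least squares of the mean normalized rating on the setting
#' value, the headline test of whether the system conveys the intended
#' emotion dimension.
#'
#' @param table Data frame with columns `setting` and `mean_rating`, as
#'   returned by [average_by_setting()].
#' @return An `am_regression`: `r_squared`, `f_statistic`, `p_value`,
#'   `coefficients` (intercept and slope), `aic`, `n`.
#' @export
simple_regression <- function(table) {
  stopifnot(all(c("setting", "mean_rating") %in% names(table)))
  if (length(unique(table$setting)) < 3L)
    stop("need at least 3 distinct setting values", call. = FALSE)
  am_regression(stats::lm(mean_rating ~ setting, data = table))
}

#' Multiple regression of perceived emotion on both parameter settings
#'
#' Regresses the per-point mean normalized rating of the chosen dimension
#' on both the valence and arousal parameter settings, quantifying
#' crossover effects (e.g. intended arousal shifting perceived valence).
#' Per-predictor F statistics are the squared coefficient t statistics
#' (partial F with 1 numerator df). AIC uses the Gaussian-likelihood
#' convention of [stats::AIC()] (parameters counted: intercept, slopes,
#' residual variance).
#'
#' @param records Ratings table.
#' @param dimension Rated dimension to model, `"valence"` or `"arousal"`.
#' @param unit `"point"` (default; one observation per affect point, as in
#'   the figure-level analysis) or `"record"` (one observation per rating).
#' @return An `am_regression` whose `predictors` field holds per-predictor
#'   estimates, F and p values.
#' @export
crossover_regression <- function(records, dimension = c("valence", "arousal"),
                                 unit = c("point", "record")) {
  dimension <- match.arg(dimension)
  unit <- match.arg(unit)
  check_records(records)
  d <- if (unit == "point") {
    average_by_point(records, dimension)
  } else {
    data.frame(valence_setting = records$valence_setting,
               arousal_setting = records$arousal_setting,
               mean_rating = normalize_rating(records[[rating_col(dimension)]]))
  }
  if (length(unique(d$valence_setting)) < 2L ||
      length(unique(d$arousal_setting)) < 2L)
    stop("both settings must vary in the data", call. = FALSE)
  fit <- stats::lm(mean_rating ~ valence_setting + arousal_setting, data = d)
  ct <- suppressWarnings(summary(fit))$coefficients
  terms <- c("valence_setting", "arousal_setting")
  predictors <- data.frame(term = terms,
                           estimate = ct[terms, "Estimate"],
                           f = ct[terms, "t value"]^2,
                           p = ct[terms, "Pr(>|t|)"],
                           stringsAsFactors = FALSE)
  rownames(predictors) <- NULL
  am_regression(fit, predictors)
}

#' Compare musician and non-musician subgroups
#'
#' Splits records by the musician flag (MT = musically trained, NMT = not)
#' and runs the setting-level simple regression for each group and each
#' emotion dimension, collecting R-squared, F, p and AIC into a table for
#' model comparison across groups.
#'
#' @param records Ratings table with a logical `musician` column; both
#'   groups must be non-empty, each with at least 3 represented settings.
#' @return List with `results` (nested list `MT`/`NMT` of per-dimension
#'   `am_regression` objects) and `aic_table` (data frame: `group`,
#'   `dimension`, `r_squared`, `f_statistic`, `p_value`, `aic`).
#' @export
subgroup_compare <- function(records) {
  check_records(records)
  groups <- list(MT = records[records$musician, , drop = FALSE],
                 NMT = records[!records$musician, , drop = FALSE])
  if (any(vapply(groups, nrow, 0L) == 0L))
    stop("both musician groups must be non-empty", call. = FALSE)
  results <- list()
  rows <- list()
  for (g in names(groups)) {
    for (dim in c("valence", "arousal")) {
      tab <- average_by_setting(groups[[g]], dim)
      if (nrow(tab) < 3L)
        stop("group ", g, " has fewer than 3 represented settings", call. = FALSE)
      reg <- simple_regression(tab)
      results[[g]][[dim]] <- reg
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, dimension = dim, r_squared = reg$r_squared,
        f_statistic = reg$f_statistic, p_value = reg$p_value, aic = reg$aic,
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, aic_table = do.call(rbind, rows))
}

#' Simulate a synthetic listener study
#'
#' Stands in for human raters so the validation pipeline is fully testable.
#' Each simulated rater's latent perceived valence is
#' `slope_v * V + crossover_a_on_v * A + e` and latent perceived arousal is
#' `slope_a * A + e`, with `e ~ Normal(0, noise_sd)` drawn independently
#' per rating -- mirroring the asymmetric crossover structure in which
#' intended arousal colours perceived valence but intended valence does not
#' colour perceived arousal. Latents are affine-mapped to the 9-point SAM
#' scale (`1 + 8 * latent`), rounded, and clipped to 1..9.
#'
#' @param design Data frame of affect points (`valence`, `arousal`);
#'   defaults to the 13 standard stimulus points.
#' @param instances Stimulus instances per point (default 3).
#' @param n_participants Number of simulated raters (default 26).
#' @param params List overriding any of `slope_v` (default 1), `slope_a`
#'   (1), `crossover_a_on_v` (0.15), `noise_sd` (0.1, on the normalized
#'   scale) and `musician_fraction` (12/26).
#' @param seed Integer seed, or `NULL`.
#' @return Ratings data frame: `participant_id`, `valence_setting`,
#'   `arousal_setting`, `instance`, `rated_valence`, `rated_arousal`,
#'   `musician`.
#' @export
simulate_ratings <- function(design = default_stimulus_points(),
                             instances = 3L, n_participants = 26L,
                             params = list(), seed = NULL) {
  defaults <- list(slope_v = 1, slope_a = 1, crossover_a_on_v = 0.15,
                   noise_sd = 0.1, musician_fraction = 12 / 26)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown simulator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(defaults, params)
  stopifnot(p$noise_sd >= 0, p$musician_fraction >= 0, p$musician_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  grid <- expand.grid(instance = seq_len(instances),
                      point = seq_len(nrow(design)),
                      participant_id = seq_len(n_participants))
  V <- design$valence[grid$point]
  A <- design$arousal[grid$point]
  n <- nrow(grid)
  latent_v <- p$slope_v * V + p$crossover_a_on_v * A +
    stats::rnorm(n, 0, p$noise_sd)
  latent_a <- p$slope_a * A + stats::rnorm(n, 0, p$noise_sd)
  to_sam <- function(x) pmin(pmax(round(1 + 8 * x), 1), 9)
  n_mus <- round(p$musician_fraction * n_participants)
  data.frame(
    participant_id = grid$participant_id,
    valence_setting = V,
    arousal_setting = A,
    instance = grid$instance,
    rated_valence = as.integer(to_sam(latent_v)),
    rated_arousal = as.integer(to_sam(latent_a)),
    musician = grid$participant_id <= n_mus
  )
}
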