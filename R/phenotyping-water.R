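#' Interpolate pot weights onto imaging days
#'
#' Pots were weighed on different days than they were photographed; weights
#' are carried onto the imaging days by piecewise-linear interpolation, with
#' linear extrapolation from the two nearest measurements beyond the ends of
#' the series. Water content is the interpolated weight minus the pot's dry
#' weight; cumulative water loss is the saturated (first) weight minus the
#' interpolated weight.
#'
#' @param weights A tibble with columns `pot`, `day`, `weight_g` and either a
#'   `dry_weight_g` column or the `dry_weight` argument.
#' @param target_days Days (numeric) at which to evaluate the series.
#' @param dry_weight Optional named vector of dry weights per pot (overrides
#'   the column).
#' @return A tibble with one row per pot x target day: `pot`, `day`,
#'   `weight_g`, `water_content_g`, `cumulative_water_loss_g`.
#' @examples
#' w <- tibble::tibble(pot = "p1", day = c(1, 3), weight_g = c(300, 280),
#'                     dry_weight_g = 100)
#' compute_water_series(w, target_days = 2)
#' @export
compute_water_series <- function(weights, target_days, dry_weight = NULL) {
  stopifnot(all(c("pot", "day", "weight_g") %in% names(weights)))
  weights %>%
    dplyr::group_by(.data$pot) %>%
    dplyr::group_modify(function(d, key) {
      dw <- if (!is.null(dry_weight)) {
        unname(dry_weight[[as.character(key$pot)]])
      } else {
        if (!"dry_weight_g" %in% names(d)) {
          abort("No dry weight available (column `dry_weight_g` or argument `dry_weight`).")
        }
        d$dry_weight_g[[1]]
      }
      d <- dplyr::arrange(d, .data$day)
      if (nrow(d) < 2) abort(sprintf("Pot '%s' has fewer than 2 weighings.", key$pot))
      if (dw > min(d$weight_g)) {
        abort(sprintf("Pot '%s': dry weight (%g g) exceeds a measured weight.",
                      key$pot, dw))
      }
      w <- interp_extrap(d$day, d$weight_g, target_days)
      gap <- max(diff(d$day))
      outside <- target_days < min(d$day) - gap | target_days > max(d$day) + gap
      if (any(outside)) {
        warn(sprintf(
          "Pot '%s': target day(s) %s lie more than one measurement interval outside the weighing range; extrapolation is unreliable.",
          key$pot, paste(target_days[outside], collapse = ", ")))
      }
      tibble::tibble(day = target_days, weight_g = w,
                     water_content_g = w - dw,
                     cumulative_water_loss_g = d$weight_g[1] - w)
    }) %>%
    dplyr::ungroup()
}

# Piecewise-linear interpolation with straight-line extrapolation from the
# two nearest points at either end.
interp_extrap <- function(x, y, xout) {
  out <- approx(x, y, xout = xout, method = "linear", rule = 1, ties = "ordered")$y
  lo <- xout < min(x)
  hi <- xout > max(x)
  if (any(lo)) {
    sl <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + sl * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + sl * (xout[hi] - x[n])
  }
  out
}

#' Linear model of water loss against plant size
#'
#' Fits ordinary least squares with water loss as the response and the plant
#' line (treatment-coded factor), vital pixel count (the size proxy) and
#' their interaction as explanatory variables; per-term significance uses
#' Type-II (marginal) F tests. A reduced model with line and interaction
#' dropped (`water_loss ~ vital_pixels`) quantifies how much the size proxy
#' alone explains.
#'
#' @param data A tibble with columns `line`, `vital_pixels`, `water_loss`.
#' @return An object of class `water_model_fit` with components `full`
#'   (`lm`), `reduced` (`lm`), `anova` (Type-II table as tibble),
#'   `r_squared`, `overall_p`, `reduced_r_squared`, `reduced_slope`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(line = rep(c("wt", "hc31"), each = 5),
#'                     vital_pixels = c(1:5, 1:5),
#'                     water_loss = 2 + 3 * c(1:5, 1:5))
#' glance(fit_water_model(d))
#' @export
fit_water_model <- function(data) {
  stopifnot(all(c("line", "vital_pixels", "water_loss") %in% names(data)))
  data <- dplyr::mutate(data, line = factor(.data$line))
  if (nlevels(data$line) < 2) abort("Need >= 2 lines for the full model.")
  if (any(table(data$line) < 2)) {
    abort("Need >= 2 observations per line for the line x size interaction.")
  }
  full <- lm(water_loss ~ line * vital_pixels, data = data)
  if (full$rank < length(coef(full))) {
    aliased <- names(which(is.na(coef(full))))
    abort(sprintf("Rank-deficient design; aliased term(s): %s.",
                  paste(aliased, collapse = ", ")))
  }
  reduced <- lm(water_loss ~ vital_pixels, data = data)
  sf <- suppressWarnings(summary(full))
  fstat <- sf$fstatistic
  rss <- sum(full$residuals^2)
  if (rss > 1e-10 * max(1, sum(data$water_loss^2))) {
    a2 <- car::Anova(full, type = 2)
    atab <- tibble::tibble(term = rownames(a2),
                           sumsq = a2[["Sum Sq"]], df = a2[["Df"]],
                           statistic = a2[["F value"]], p.value = a2[["Pr(>F)"]])
  } else {
    # perfect fit: F statistics are undefined against a zero residual
    g <- nlevels(data$line)
    atab <- tibble::tibble(
      term = c("line", "vital_pixels", "line:vital_pixels", "Residuals"),
      sumsq = c(NA_real_, NA_real_, NA_real_, rss),
      df = c(g - 1, 1, g - 1, nrow(data) - 2 * g),
      statistic = NA_real_, p.value = NA_real_)
  }
  structure(list(
    full = full, reduced = reduced, anova = atab,
    r_squared = sf$r.squared,
    overall_p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    reduced_r_squared = suppressWarnings(summary(reduced)$r.squared),
    reduced_slope = unname(coef(reduced)[["vital_pixels"]]),
    data = data), class = "water_model_fit")
}

#' @export
print.water_model_fit <- function(x, ...) {
  cat(sprintf("<water_model_fit> full R^2 = %.3f (overall P = %.3g); reduced R^2 = %.3f, slope = %.4g\n",
              x$r_squared, x$overall_p, x$reduced_r_squared, x$reduced_slope))
  cat("Type-II terms:\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_water_model
#' @param x A `water_model_fit` object.
#' @param ... Unused.
#' @export
tidy.water_model_fit <- function(x, ...) {
  x$anova
}

#' @rdname fit_water_model
#' @export
glance.water_model_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 adj.r.squared = suppressWarnings(summary(x$full)$adj.r.squared),
                 p.value = x$overall_p,
                 reduced.r.squared = x$reduced_r_squared,
                 reduced.slope = x$reduced_slope,
                 nobs = nrow(x$data))
}

#' @rdname fit_water_model
#' @param object A `water_model_fit` object.
#' @export
autoplot.water_model_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$vital_pixels, y = .data$water_loss, colour = .data$line)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = coef(object$reduced)[1],
                         slope = coef(object$reduced)[2]) +
    ggplot2::labs(x = "Vital pixel count (size proxy)",
                  y = "Cumulative water loss",
                  title = sprintf("Reduced model R² = %.2f",
                                  object$reduced_r_squared)) +
    ggplot2::theme_minimal()
}
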