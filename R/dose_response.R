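# Four-parameter logistic dose-response fitting with explicit IC50
# censoring semantics: an IC50 is "definite" only when the fitted midpoint
# lies inside the tested range and the response actually crossed
# half-maximum; flat or right-shifted curves are reported as ">max dose";
# QC-invalidated or unfittable series are "not determinable".

fourpl_curve <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `response = bottom + (top - bottom) / (1 + (conc / ic50)^hill)`,
#' least-squares via Levenberg-Marquardt on the mean response per
#' concentration (zero-dose wells act only as the normalisation anchor and
#' are excluded from the fit). Initialisation: top/bottom from the
#' extreme-dose means, IC50 from the dose nearest half-maximal response,
#' hill = 1, plus a deterministic grid of shifted restarts; the best
#' converged restart by residual sum of squares wins. The midpoint is
#' parameterised as log10(IC50) and kept within two decades of the tested
#' range; a fit ending on that bound is flagged unconverged.
#'
#' @param data Tibble with `concentration` (nM) and a response column.
#' @param response Name of the response column (default `"sigma"`).
#' @param weights Optional per-concentration weights (`"none"` or
#'   `"1/sd^2"`; default unweighted).
#' @return Object of class `fourpl_fit`: `top`, `bottom`, `hill`, `ic50`,
#'   `converged`, `rmse`, `vcov`, `data` (per-concentration means/SD),
#'   `reason` when unfittable.
#' @export
fit_4pl <- function(data, response = "sigma", weights = c("none", "1/sd^2")) {
  weights <- match.arg(weights)
  if (!all(c("concentration", response) %in% names(data))) {
    abort(paste0("need `concentration` and `", response, "` columns"))
  }
  if (!all(is.finite(data[[response]]))) abort("non-finite responses")

  per <- data |>
    filter(.data$concentration > 0) |>
    group_by(.data$concentration) |>
    summarise(mean = mean(.data[[response]]),
              sd = sd(.data[[response]]), n = n(), .groups = "drop") |>
    arrange(.data$concentration)

  base <- list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
               ic50 = NA_real_, converged = FALSE, rmse = NA_real_,
               vcov = NULL, data = per, response = response, reason = NULL)
  if (nrow(per) < 4) {
    base$reason <- "fewer than 4 distinct positive concentrations"
    return(structure(base, class = "fourpl_fit"))
  }

  y <- per$mean
  lx <- log10(per$concentration)
  top0 <- y[1]; bottom0 <- y[length(y)]
  mid0 <- (top0 + bottom0) / 2
  l50 <- lx[which.min(abs(y - mid0))]
  lo <- min(lx) - 2; hi <- max(lx) + 2

  wts <- if (weights == "1/sd^2" && all(is.finite(per$sd)) && all(per$sd > 0)) {
    1 / per$sd^2
  } else rep(1, nrow(per))

  starts <- rbind(
    c(l50, 1), c(l50 - 1, 1), c(l50 + 1, 1),
    c(l50 - 0.5, 2), c(l50 + 0.5, 0.5), c(l50, -1))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        # (conc/ic50)^hill written as 10^(hill * (lx - lic50))
        mean ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - lic50))),
        data = data.frame(mean = y, lx = lx),
        start = list(top = top0, bottom = bottom0,
                     hill = starts[s, 2], lic50 = starts[s, 1]),
        weights = wts,
        lower = c(-Inf, -Inf, -20, lo), upper = c(Inf, Inf, 20, hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(wts * resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    base$reason <- "optimizer failed for every start"
    return(structure(base, class = "fourpl_fit"))
  }

  cf <- coef(best$fit)
  hill <- cf[["hill"]]
  ic50 <- 10^cf[["lic50"]]
  on_bound <- cf[["lic50"]] <= lo + 1e-6 || cf[["lic50"]] >= hi - 1e-6 ||
    abs(cf[["hill"]]) >= 20 - 1e-6
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)

  structure(
    list(top = cf[["top"]], bottom = cf[["bottom"]], hill = hill,
         ic50 = ic50, converged = !on_bound,
         rmse = sqrt(mean(resid(best$fit)^2)), vcov = vc, data = per,
         response = response,
         reason = if (on_bound) "parameter at bound" else NULL),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (is.na(x$ic50)) {
    cat("4PL fit: not fitted (", x$reason %||% "unknown", ")\n", sep = "")
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g nM, hill = %.3g, top = %.3g, bottom = %.3g (%s)\n",
                x$ic50, x$hill, x$top, x$bottom,
                if (x$converged) "converged" else "not converged"))
  }
  invisible(x)
}

#' @export
tidy.fourpl_fit <- function(x, ...) {
  est <- c(top = x$top, bottom = x$bottom, hill = x$hill, ic50 = x$ic50)
  se <- rep(NA_real_, 4)
  if (!is.null(x$vcov)) {
    s <- sqrt(diag(x$vcov))
    # delta method for the transformed parameters
    se <- c(s[["top"]], s[["bottom"]], s[["hill"]],
            x$ic50 * log(10) * s[["lic50"]])
  }
  tibble(term = names(est), estimate = unname(est), std.error = se)
}

#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(converged = x$converged, rmse = x$rmse,
         n_concentrations = nrow(x$data), ic50 = x$ic50)
}

#' Classify a fitted IC50 with explicit censoring
#'
#' * `definite` — the fit converged, the IC50 lies within the tested
#'   range, and the observed response reached at least 50% of the fitted
#'   span (the curve genuinely crossed half-maximum);
#' * `greater_than` — the curve is flat or right-shifted: less than
#'   half-maximal effect at the top tested dose (bound = highest tested
#'   concentration);
#' * `not_determinable` — QC invalidated the series, or the fit failed on
#'   a series that is not simply flat.
#'
#' @param fit A `fourpl_fit`.
#' @param qc_valid FALSE when plate/curve QC invalidated the series.
#' @param flat_rel_span A series whose observed response span is below
#'   this fraction of its mean level is treated as flat (default 0.3).
#' @return Object of class `censored_ic50`: `kind`, `value` (nM; the bound
#'   for `greater_than`), `reason`.
#' @export
classify_ic50 <- function(fit, qc_valid = TRUE, flat_rel_span = 0.3) {
  stopifnot(inherits(fit, "fourpl_fit"))
  mk <- function(kind, value = NA_real_, reason = NA_character_) {
    structure(list(kind = kind, value = value, reason = reason),
              class = "censored_ic50")
  }
  if (!isTRUE(qc_valid)) return(mk("not_determinable", reason = "QC invalidated the series"))
  per <- fit$data
  if (nrow(per) == 0) return(mk("not_determinable", reason = fit$reason %||% "no data"))
  max_dose <- max(per$concentration)
  span_obs <- max(per$mean) - min(per$mean)
  flat <- span_obs < flat_rel_span * abs(mean(per$mean))
  if (flat) {
    return(mk("greater_than", max_dose, "flat response in tested range"))
  }
  if (!fit$converged || is.na(fit$ic50)) {
    return(mk("not_determinable", reason = fit$reason %||% "fit failed"))
  }
  span_fit <- abs(fit$top - fit$bottom)
  # observed effect in the fitted orientation
  eff <- if (fit$top >= fit$bottom) fit$top - min(per$mean) else max(per$mean) - fit$top
  half_crossed <- span_fit > 0 && eff >= 0.5 * span_fit
  in_range <- fit$ic50 >= min(per$concentration) && fit$ic50 <= max_dose

  if (half_crossed && in_range) return(mk("definite", fit$ic50))
  if (fit$ic50 > max_dose || !half_crossed) {
    return(mk("greater_than", max_dose,
              "midpoint beyond tested range or < 50% effect at top dose"))
  }
  mk("not_determinable", reason = "midpoint below tested range")
}

#' @export
format.censored_ic50 <- function(x, digits = 4, ...) {
  switch(x$kind,
         definite = format(signif(x$value, digits)),
         greater_than = paste0(">", format(x$value)),
         not_determinable = "n/a")
}

#' @export
print.censored_ic50 <- function(x, ...) {
  cat("IC50:", format(x), "nM\n"); invisible(x)
}

as_censored <- function(x) {
  if (inherits(x, "censored_ic50")) return(x)
  if (is.numeric(x) && length(x) == 1 && is.finite(x)) {
    return(structure(list(kind = "definite", value = x, reason = NA_character_),
                     class = "censored_ic50"))
  }
  abort("expected a censored_ic50 or a single finite number")
}

#' Ratio of two (possibly censored) IC50s
#'
#' Definite over definite gives a definite ratio rounded to two decimals.
#' When exactly one side is a `greater_than` bound, bound arithmetic gives
#' a one-sided ratio (`>b/a` or `<a/b`); any other combination is not
#' determinable.
#'
#' @param a,b `censored_ic50` objects (or bare numbers, taken as
#'   definite). The ratio is `a / b`.
#' @return List of class `ic50_ratio`: `kind` (`"definite"`,
#'   `"greater_than"`, `"less_than"`, `"na"`) and `value`.
#' @export
ic50_ratio <- function(a, b) {
  a <- as_censored(a); b <- as_censored(b)
  r <- function(kind, value = NA_real_) {
    structure(list(kind = kind, value = value), class = "ic50_ratio")
  }
  if (a$kind == "definite" && b$kind == "definite") {
    return(r("definite", round(a$value / b$value, 2)))
  }
  if (a$kind == "greater_than" && b$kind == "definite") {
    return(r("greater_than", round(a$value / b$value, 2)))
  }
  if (a$kind == "definite" && b$kind == "greater_than") {
    return(r("less_than", round(a$value / b$value, 2)))
  }
  r("na")
}

#' @export
format.ic50_ratio <- function(x, ...) {
  switch(x$kind,
         definite = format(x$value),
         greater_than = paste0(">", format(x$value)),
         less_than = paste0("<", format(x$value)),
         na = "n/a")
}

#' @export
print.ic50_ratio <- function(x, ...) {
  cat("IC50 ratio:", format(x), "\n"); invisible(x)
}

#' Fit and classify IC50s for every (cell line, compound) series
#'
#' @param tbl Tibble with `cell_line`, `compound`, `concentration` and a
#'   response column (e.g. the `sigma` output of
#'   [compute_composite_metric()]).
#' @param response Response column name.
#' @param readout Label recorded in the output (e.g. `"metric"`,
#'   `"area"`, `"proliferative"`).
#' @return Tidy IC50 table: `cell_line`, `compound`, `readout`, `kind`,
#'   `value` (nM), `rmse`, `converged`; attribute `fits` holds the
#'   underlying `fourpl_fit` objects.
#' @export
screen_ic50 <- function(tbl, response = "sigma", readout = "metric") {
  check_well_keys(tbl, c("cell_line", "compound", "concentration"))
  groups <- distinct(tbl, .data$cell_line, .data$compound)
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- tbl[tbl$cell_line == groups$cell_line[i] &
                 tbl$compound == groups$compound[i], ]
    fit <- fit_4pl(sub, response = response)
    cls <- classify_ic50(fit)
    key <- paste(groups$cell_line[i], groups$compound[i], sep = "/")
    fits[[key]] <- fit
    rows[[i]] <- tibble(
      cell_line = groups$cell_line[i], compound = groups$compound[i],
      readout = readout, kind = cls$kind, value = cls$value,
      rmse = fit$rmse, converged = fit$converged)
  }
  out <- list_rbind(rows)
  attr(out, "fits") <- fits
  out
}

#' Normalise a fluorescence table to its zero-dose control
#'
#' Adds a `response` column (`rfu` over the control mean), the anchor the
#' 4PL fit expects.
#'
#' @param fluor Tibble with `concentration` and `rfu` columns (optionally
#'   `cell_line`/`compound` groups).
#' @return The table with a `response` column.
#' @export
normalize_fluorescence <- function(fluor) {
  grp <- intersect(c("cell_line", "compound"), names(fluor))
  fluor |>
    group_by(across(dplyr::all_of(grp))) |>
    mutate(response = .data$rfu / mean(.data$rfu[.data$concentration == 0])) |>
    ungroup()
}
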