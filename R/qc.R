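# Assay-specific triplicate quality control.
#
# Fluorescence (proliferation) data use coefficient-of-variation rules with
# plate-validity logic; morphometric features use Dixon's Q-test with
# single-replacement and a dose-monotonicity guard. The two procedures are
# deliberately never combined on the same data.

# Dixon r10 critical value, n = 3, alpha = 0.05 (two-sided)
DIXON_Q_CRIT_N3 <- 0.970

#' Coefficient of variation of a triplicate, in percent
#'
#' Sample (n - 1 denominator) standard deviation over the mean, times 100.
#'
#' @param values Numeric vector of positive measurements (length >= 2).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2 || !all(is.finite(values))) {
    abort("need at least two finite values")
  }
  m <- mean(values)
  if (m <= 0) abort("mean must be > 0 for a coefficient of variation")
  100 * sd(values) / m
}

#' Dixon's Q statistic for a triplicate
#'
#' The suspect value is the one most distant from the other two;
#' `Q = |suspect - nearest| / |highest - lowest|`. With all three values
#' equal, Q is 0 and no action is possible.
#'
#' @param values Numeric vector of exactly 3 finite values.
#' @param q_crit Critical value (default 0.970: n = 3, 95% confidence).
#' @return List of class `q_decision`: `q_stat`, `q_crit`,
#'   `suspect_index` (position in `values`), `suspect_value`,
#'   `replacement` (mean of the remaining two), `exceeds` (logical).
#' @export
dixon_q <- function(values, q_crit = DIXON_Q_CRIT_N3) {
  if (length(values) != 3 || !all(is.finite(values))) {
    abort("Dixon's Q test here applies to triplicates of finite values")
  }
  rng <- max(values) - min(values)
  if (rng == 0) {
    return(structure(list(q_stat = 0, q_crit = q_crit, suspect_index = NA_integer_,
                          suspect_value = NA_real_, replacement = NA_real_,
                          exceeds = FALSE), class = "q_decision"))
  }
  ord <- order(values)
  s <- values[ord]
  gap_low <- s[2] - s[1]
  gap_high <- s[3] - s[2]
  if (gap_low >= gap_high) {
    suspect <- ord[1]; gap <- gap_low
  } else {
    suspect <- ord[3]; gap <- gap_high
  }
  q <- gap / rng
  structure(list(q_stat = q, q_crit = q_crit, suspect_index = suspect,
                 suspect_value = values[suspect],
                 replacement = mean(values[-suspect]),
                 exceeds = q > q_crit),
            class = "q_decision")
}

# Count of steps that violate monotonicity of the dose-ordered means, within
# a relative tolerance band, in the direction set by the first and last
# entries.
monotonicity_violations <- function(means, tol = 0.05) {
  if (length(means) < 2) return(0L)
  dir <- sign(means[length(means)] - means[1])
  if (dir == 0) return(0L)
  if (dir < 0) sum(means[-1] > means[-length(means)] * (1 + tol))
  else sum(means[-1] < means[-length(means)] * (1 - tol))
}

#' Dixon Q-test single replacement over a dose series of triplicates
#'
#' For every (cell line, compound, feature, concentration) triplicate whose
#' Q statistic exceeds the critical value, the suspect value is replaced by
#' the mean of the remaining two — but only if the replacement maintains
#' the expected monotonic dose-response relationship: it must not increase
#' the number of monotonicity violations of the concentration-ordered
#' triplicate means (within a 5% relative tolerance band, direction set by
#' the first and last doses), judged with all other candidate replacements
#' of the same series in place so that one outlier cannot mask another. At
#' most one value per triplicate is ever replaced; refused replacements are
#' logged, not applied. The procedure is idempotent.
#'
#' @param tbl Feature table (metadata plus feature columns), replicates as
#'   rows.
#' @param features Feature columns to screen (default: all).
#' @param q_crit Critical Q value (default 0.970).
#' @param tol Monotonicity tolerance band (relative, default 0.05).
#' @return The table with replacements applied; attribute `qc_log` (also
#'   via [qc_log()]) holds one row per tested triplicate with
#'   `q_stat`, `action` (`"none"`, `"replaced"`, `"refused_guard"`),
#'   `suspect_replicate` and the replacement value.
#' @export
dixon_replace <- function(tbl, features = NULL, q_crit = DIXON_Q_CRIT_N3,
                          tol = 0.05) {
  check_well_keys(tbl)
  features <- features %||% feature_columns(tbl)
  log <- list()

  groups <- distinct(tbl, .data$cell_line, .data$compound)
  for (g in seq_len(nrow(groups))) {
    gi <- tbl$cell_line == groups$cell_line[g] & tbl$compound == groups$compound[g]
    concs <- sort(unique(tbl$concentration[gi]))
    idx_by_conc <- lapply(concs, function(cc) which(gi & tbl$concentration == cc))
    for (f in features) {
      # phase 1: Q decisions for every triplicate of this dose series
      qds <- lapply(idx_by_conc, function(ti) {
        if (length(ti) != 3) return(NULL)
        dixon_q(tbl[[f]][ti], q_crit)
      })
      flagged <- which(vapply(qds, function(q) !is.null(q) && q$exceeds, logical(1)))

      # phase 2: the guard judges each candidate with all other candidates
      # applied, so one outlier cannot mask another's monotonicity
      col_all <- tbl[[f]]
      for (j in flagged) {
        col_all[idx_by_conc[[j]][qds[[j]]$suspect_index]] <- qds[[j]]$replacement
      }
      series_means <- function(col) {
        vapply(idx_by_conc, function(ti) mean(col[ti]), numeric(1))
      }
      accepted <- logical(length(qds))
      for (j in flagged) {
        col_wo <- col_all
        ti <- idx_by_conc[[j]]
        col_wo[ti[qds[[j]]$suspect_index]] <- tbl[[f]][ti[qds[[j]]$suspect_index]]
        v_with <- monotonicity_violations(series_means(col_all), tol)
        v_without <- monotonicity_violations(series_means(col_wo), tol)
        accepted[j] <- v_with <= v_without
      }

      for (i in seq_along(concs)) {
        qd <- qds[[i]]
        if (is.null(qd)) next
        ti <- idx_by_conc[[i]]
        action <- "none"
        if (qd$exceeds) {
          if (accepted[i]) {
            tbl[[f]][ti[qd$suspect_index]] <- qd$replacement
            action <- "replaced"
          } else {
            action <- "refused_guard"
          }
        }
        log[[length(log) + 1]] <- tibble(
          cell_line = groups$cell_line[g], compound = groups$compound[g],
          feature = f, concentration = concs[i],
          q_stat = qd$q_stat, q_crit = q_crit,
          suspect_replicate = if (is.na(qd$suspect_index)) NA_integer_ else
            as.integer(tbl$replicate[ti[qd$suspect_index]]),
          replacement = qd$replacement, action = action)
      }
    }
  }
  attr(tbl, "qc_log") <- if (length(log)) list_rbind(log) else
    tibble(cell_line = character(), compound = character(), feature = character(),
           concentration = numeric(), q_stat = numeric(), q_crit = numeric(),
           suspect_replicate = integer(), replacement = numeric(),
           action = character())
  tbl
}

#' Retrieve the QC decision log attached by [dixon_replace()]
#' @param tbl A table returned by [dixon_replace()].
#' @return Tibble of per-triplicate decisions.
#' @export
qc_log <- function(tbl) {
  attr(tbl, "qc_log") %||% abort("no qc_log attribute; run dixon_replace() first")
}

#' Fluorescence-assay outlier rules with plate validity
#'
#' Applies, in order, the proliferation-assay quality rules:
#' 1. a triplicate with CV > `cv_limit` is rescued by removing the single
#'    value whose removal minimises the CV of the remaining pair, if that
#'    brings it within the limit;
#' 2. a triplicate that cannot be rescued is excluded as a point;
#' 3. the curve is invalid if an excluded or rescued (outlier-bearing)
#'    point lies in the IC50/inflection region, operationalised as the two
#'    concentrations bracketing the half-maximal mean response;
#' 4. at most one exclusion is permitted, and only in the plateau region
#'    (outside the bracketing pair);
#' 5. the plate is invalid if the negative-control triplicate CV exceeds
#'    the limit and cannot be rescued by removing one value.
#'
#' @param tbl Tibble with columns `concentration` (0 = negative control),
#'   `replicate` and a value column.
#' @param value Name of the value column (default `"rfu"`).
#' @param cv_limit CV threshold in percent (default 20).
#' @return List: `data` (per-concentration tibble: `concentration`,
#'   `response` mean of retained values, `cv`, `n_used`, `removed_value`,
#'   `excluded`), `validity` (list: `status` `"valid"`/`"invalid"`,
#'   `reasons`, `excluded_points`).
#' @export
apply_fluorescence_rules <- function(tbl, value = "rfu", cv_limit = 20) {
  if (!all(c("concentration", value) %in% names(tbl))) {
    abort("need `concentration` and the value column")
  }
  if (!any(tbl$concentration == 0)) abort("missing negative control (concentration 0)")

  concs <- sort(unique(tbl$concentration))
  per <- map(concs, function(cc) {
    v <- tbl[[value]][tbl$concentration == cc]
    cv <- cv_percent(v)
    removed <- NA_real_; excluded <- FALSE; used <- v
    if (cv > cv_limit && length(v) >= 3) {
      pair_cvs <- vapply(seq_along(v), function(i) cv_percent(v[-i]), numeric(1))
      best <- which.min(pair_cvs)
      if (pair_cvs[best] <= cv_limit) {
        removed <- v[best]; used <- v[-best]
      } else {
        excluded <- TRUE
      }
    } else if (cv > cv_limit) {
      excluded <- TRUE
    }
    tibble(concentration = cc, response = mean(used),
           cv = cv_percent(used) , cv_raw = cv, n_used = length(used),
           removed_value = removed, excluded = excluded)
  }) |> list_rbind()

  reasons <- character()

  # rule 5: control triplicate
  ctrl <- per[per$concentration == 0, ]
  if (ctrl$excluded) {
    reasons <- c(reasons, "control CV > limit and not rescuable by removing one value")
  }

  # IC50/inflection region from provisional mean responses (positive doses)
  dose <- per[per$concentration > 0, ]
  region <- numeric(0)
  if (nrow(dose) >= 2) {
    mid <- (max(dose$response) + min(dose$response)) / 2
    below <- which(dose$response <= mid)
    if (length(below) > 0 && min(below) > 1) {
      i <- min(below)
      region <- dose$concentration[c(i - 1, i)]
    } else if (length(below) > 0 && min(below) == 1) {
      region <- dose$concentration[seq_len(min(2, nrow(dose)))]
    }
  }

  flagged <- per$concentration[per$excluded | !is.na(per$removed_value)]
  flagged <- flagged[flagged > 0]
  if (any(flagged %in% region)) {
    reasons <- c(reasons, "outlier or exclusion inside the IC50/inflection region")
  }
  n_excl <- sum(per$excluded & per$concentration > 0)
  if (n_excl > 1) {
    reasons <- c(reasons, "more than one point excluded")
  }

  list(data = per,
       validity = list(
         status = if (length(reasons) == 0) "valid" else "invalid",
         reasons = reasons,
         excluded_points = per$concentration[per$excluded]))
}
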