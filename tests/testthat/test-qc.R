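test_that("coefficient of variation follows the sample-SD formula", {
  expect_equal(cv_percent(c(100, 100, 100)), 0)
  expect_equal(cv_percent(c(100, 110, 120)), 100 * 10 / 110)
  expect_equal(cv_percent(c(1, 1, 2)), 100 * sd(c(1, 1, 2)) / mean(c(1, 1, 2)),
               tolerance = 1e-12)
  expect_equal(round(cv_percent(c(1, 1, 2)), 2), 43.30)
  expect_error(cv_percent(c(-1, 0, 1)), "mean")
})

test_that("cv is invariant to positive rescaling", {
  set.seed(42)
  for (i in 1:20) {
    v <- runif(3, 1, 100)
    k <- runif(1, 0.01, 50)
    expect_equal(cv_percent(k * v), cv_percent(v), tolerance = 1e-9)
  }
})

test_that("Dixon Q statistic matches the gap-over-range formula", {
  q <- dixon_q(c(10, 10.2, 25))
  expect_equal(q$q_stat, (25 - 10.2) / (25 - 10))
  expect_equal(round(q$q_stat, 4), 0.9867)
  expect_true(q$exceeds)
  expect_equal(q$suspect_index, 3L)
  expect_equal(q$replacement, 10.1)

  expect_equal(dixon_q(c(1, 2, 3))$q_stat, 0.5)
  expect_false(dixon_q(c(1, 2, 3))$exceeds)

  allsame <- dixon_q(c(5, 5, 5))
  expect_equal(allsame$q_stat, 0)
  expect_false(allsame$exceeds)

  expect_error(dixon_q(c(1, 2)), "triplicates")
})

qc_series <- function(values_by_conc, feature = "f") {
  concs <- as.numeric(names(values_by_conc))
  rows <- lapply(seq_along(concs), function(i) {
    tibble::tibble(cell_line = "CL", compound = "CP",
                   concentration = concs[i], replicate = 1:3,
                   !!feature := values_by_conc[[i]])
  })
  dplyr::bind_rows(rows)
}

test_that("Q replacement substitutes the mean of the remaining pair", {
  tbl <- qc_series(list(`1` = c(100, 101, 99), `10` = c(80, 81, 79),
                        `100` = c(10, 10.2, 25), `1000` = c(9, 9.5, 9.2)))
  out <- dixon_replace(tbl)
  log <- qc_log(out)
  hit <- log[log$action == "replaced", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$concentration, 100)
  expect_equal(sort(out$f[out$concentration == 100]), sort(c(10, 10.2, 10.1)))

  # below the critical value nothing is touched
  tbl2 <- qc_series(list(`1` = c(1, 2, 3), `10` = c(1, 2, 3)))
  out2 <- dixon_replace(tbl2)
  expect_equal(out2$f, tbl2$f)
  expect_true(all(qc_log(out2)$action == "none"))
})

test_that("the monotonicity guard refuses disruptive replacements", {
  # the middle triplicate mean (70) fits the decreasing order; replacing its
  # low suspect by the remaining pair's mean would bump it to 90 and break
  # monotonicity, so the replacement is refused
  tbl <- qc_series(list(`1` = c(80, 80, 80), `10` = c(90, 90, 30),
                        `100` = c(72, 72, 72)))
  out <- dixon_replace(tbl)
  log <- qc_log(out)
  mid <- log[log$concentration == 10, ]
  expect_equal(mid$action, "refused_guard")
  expect_equal(out$f, tbl$f) # untouched
})

test_that("Q replacement is idempotent", {
  set.seed(7)
  scn <- dose_scenario(noise_cv = 5, outlier_rate = 0.4, seed = 7)
  tbl <- make_dose_tables(scn)$features
  once <- dixon_replace(tbl)
  twice <- dixon_replace(once)
  for (f in feature_columns(tbl)) expect_equal(twice[[f]], once[[f]])
  expect_true(all(qc_log(twice)$action != "replaced"))
})

fluor_series <- function(ctrl, doses) {
  concs <- c(0, as.numeric(names(doses)))
  vals <- c(list(ctrl), unname(doses))
  dplyr::bind_rows(lapply(seq_along(concs), function(i) {
    tibble::tibble(concentration = concs[i], replicate = 1:3, rfu = vals[[i]])
  }))
}

test_that("fluorescence rules rescue a control outlier by single removal", {
  tbl <- fluor_series(c(100, 101, 250),
                      list(`10` = c(90, 91, 92), `100` = c(60, 61, 62),
                           `1000` = c(30, 31, 32), `10000` = c(20, 21, 22)))
  res <- apply_fluorescence_rules(tbl)
  expect_equal(res$validity$status, "valid")
  ctrl <- res$data[res$data$concentration == 0, ]
  expect_equal(ctrl$response, mean(c(100, 101)))
  expect_equal(ctrl$removed_value, 250)
})

test_that("an unrescuable control invalidates the plate", {
  tbl <- fluor_series(c(50, 150, 250),
                      list(`10` = c(90, 91, 92), `100` = c(60, 61, 62)))
  res <- apply_fluorescence_rules(tbl)
  expect_equal(res$validity$status, "invalid")
  expect_match(res$validity$reasons, "control", all = FALSE)
})

test_that("clean plates pass with no exclusions", {
  tbl <- fluor_series(c(100, 102, 98),
                      list(`10` = c(90, 91, 92), `100` = c(60, 61, 62),
                           `1000` = c(30, 31, 32)))
  res <- apply_fluorescence_rules(tbl)
  expect_equal(res$validity$status, "valid")
  expect_false(any(res$data$excluded))
  expect_true(all(is.na(res$data$removed_value)))
})

test_that("an outlier in the inflection region invalidates the curve", {
  # the 100 nM triplicate brackets the half-maximal response and cannot be
  # rescued
  tbl <- fluor_series(c(100, 101, 99),
                      list(`10` = c(95, 96, 94), `100` = c(30, 70, 110),
                           `1000` = c(25, 26, 24), `10000` = c(20, 21, 19)))
  res <- apply_fluorescence_rules(tbl)
  expect_equal(res$validity$status, "invalid")
  expect_match(res$validity$reasons, "IC50", all = FALSE)
})

test_that("injected gross outliers are caught, clean triplicates are kept", {
  n_seeds <- 40
  caught <- 0; injected <- 0; false_mod <- 0; clean <- 0
  for (s in seq_len(n_seeds)) {
    scn <- dose_scenario(noise_cv = 2, outlier_rate = 0.3, seed = 1000 + s)
    dt <- make_dose_tables(scn)
    out <- dixon_replace(dt$features)
    log <- qc_log(out)
    truth <- dt$truth$outliers
    key <- paste(log$feature, log$concentration)
    tkey <- paste(truth$feature, truth$concentration)
    injected <- injected + nrow(truth)
    caught <- caught + sum(log$action == "replaced" & key %in% tkey)
    clean <- clean + sum(!key %in% tkey)
    false_mod <- false_mod + sum(log$action == "replaced" & !key %in% tkey)
  }
  expect_gte(caught / injected, 0.95)
  # false modifications track the nominal 5% size of the Q test at its
  # 0.970 critical value; allow binomial noise at this smaller seed count
  expect_lte(false_mod / clean, 0.075)
})
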