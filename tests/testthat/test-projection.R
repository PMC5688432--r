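test_that("constant inputs give identical outcome counts every year", {
  cal <- calibrate_baseline(load_preset("Mali"))
  proj <- project(cal, scenario("constant", c(2015, 2025)))
  expect_equal(nrow(proj), 11L)
  for (col in c("tfr", "births", "abortions", "pregnancies", "stillbirths")) {
    expect_equal(proj[[col]], rep(proj[[col]][1], 11), tolerance = 1e-12)
  }
  # the fixed point reproduces the observed baseline TFR
  expect_equal(proj$tfr[1], 6.1, tolerance = 1e-9)
})

test_that("linear prevalence ramps hit their endpoints exactly", {
  ten_year_end <- function(name) {
    p <- load_preset(name)
    cal <- suppressWarnings(calibrate_baseline(p))
    proj <- project(cal, scenario(
      "scale-up", c(2015, 2025),
      cpr = traj_ramp(p$scenario$ramp_points_per_year,
                      start = p$scenario$start_cpr)
    ))
    c(proj$cpr[1], proj$cpr[11])
  }
  expect_identical(ten_year_end("Mali"), c(0.10, 0.30))
  expect_identical(ten_year_end("Kenya"), c(0.42, 0.62))
  expect_identical(ten_year_end("Indonesia"), c(0.62, 0.72))
  expect_identical(ten_year_end("Ukraine"), c(0.67, 0.77))
})

test_that("ramps saturate at their cap", {
  cal <- calibrate_baseline(load_preset("Mali"))
  proj <- project(cal, scenario("fast", c(2015, 2025),
                                cpr = traj_ramp(10, start = 0.10, cap = 0.5)))
  expect_equal(max(proj$cpr), 0.5)
  expect_equal(proj$cpr[11], 0.5)
})

test_that("the abortion index lags prevalence and fertility by one year", {
  cal <- calibrate_baseline(load_preset("Mali"))
  years <- 2015:2020
  base_cpr <- rep(0.11, 6)
  bumped <- base_cpr
  bumped[4] <- 0.25 # perturb 2018 only
  p0 <- project(cal, scenario("base", c(2015, 2020),
                              cpr = traj_series(years, base_cpr)))
  p1 <- project(cal, scenario("bump", c(2015, 2020),
                              cpr = traj_series(years, bumped)))
  i <- 4
  expect_identical(p1$ca[i], p0$ca[i])       # year-t Ca untouched
  expect_false(p1$ca[i + 1] == p0$ca[i + 1]) # year-(t+1) Ca responds
  expect_false(p1$tfr[i] == p0$tfr[i])       # Cc responds immediately
})

test_that("projection is deterministic", {
  cal <- calibrate_baseline(load_preset("Kenya")) |> suppressWarnings()
  scn <- scenario("s", c(2015, 2025), cpr = traj_ramp(2, start = 0.42))
  expect_identical(project(cal, scn), project(cal, scn))
})

test_that("under constant inputs the lagged-TFR recursion is at its fixed point", {
  cal <- calibrate_baseline(load_preset("Indonesia"))
  proj <- project(cal, scenario("constant", c(2015, 2040)))
  # composed equation holds with the lagged TFR equal to the current one
  last <- proj[nrow(proj), ]
  recomposed <- last$cm * last$ci *
    index_abortion(last$tfr, last$cpr, last$tar) * last$cs * last$cc * last$tf
  expect_equal(last$tfr, recomposed, tolerance = 1e-9)
})

test_that("a year that breaks the contraception-index domain is named", {
  p <- synth_population(3, ranges = list(
    cpr = c(0.5, 0.5), effectiveness = c(0.99, 0.99)
  ))
  cal <- suppressWarnings(calibrate_baseline(p))
  err <- expect_error(
    project(cal, scenario("runaway", c(2015, 2025),
                          cpr = traj_ramp(10, start = 0.5, cap = 0.99))),
    class = "fp_error_domain"
  )
  expect_match(conditionMessage(err), "year 20\\d\\d")
})

test_that("comparing a scenario with itself gives zero differences", {
  cal <- calibrate_baseline(load_preset("Mali"))
  proj <- project(cal, scenario("constant", c(2015, 2025)))
  cmp <- compare_scenarios(proj, proj)
  expect_true(all(cmp$d_births == 0))
  expect_true(all(cmp$cum_d_abortions == 0))
})

test_that("scale-up reduces abortions and births relative to constant use", {
  for (name in c("Mali", "Kenya", "Indonesia", "Ukraine")) {
    p <- load_preset(name)
    cal <- suppressWarnings(calibrate_baseline(p))
    start <- p$scenario$start_cpr
    cst <- project(cal, scenario("constant", c(2015, 2025),
                                 cpr = traj_constant(start)))
    up <- project(cal, scenario("scale-up", c(2015, 2025),
                                cpr = traj_ramp(p$scenario$ramp_points_per_year,
                                                start = start)))
    cmp <- compare_scenarios(cst, up)
    expect_true(all(cmp$d_abortions <= 0), label = name)
    expect_true(all(cmp$d_unintended_total <= 0), label = name)
    # the births gap widens as the prevalence gap grows
    expect_true(all(diff(cmp$d_births) < 0), label = name)
  }
})

test_that("mismatched year ranges cannot be compared", {
  cal <- calibrate_baseline(load_preset("Mali"))
  a <- project(cal, scenario("a", c(2015, 2020)))
  b <- project(cal, scenario("b", c(2015, 2025)))
  expect_error(compare_scenarios(a, b), class = "fp_error_invalid_input")
})

test_that("explicit unmet-need trajectories override the CPR coupling", {
  cal <- calibrate_baseline(load_preset("Mali"))
  coupled <- project(cal, scenario("up", c(2015, 2025),
                                   cpr = traj_ramp(2, start = 0.10)))
  fixed <- project(cal, scenario("up-fixed-unmet", c(2015, 2025),
                                 cpr = traj_ramp(2, start = 0.10),
                                 unmet_need = traj_constant()))
  expect_equal(fixed$unmet_need, rep(0.26, 11))
  expect_equal(coupled$unmet_need, pmax(0, 0.26 - (coupled$cpr - 0.10)))
  expect_true(all(coupled$abortions <= fixed$abortions))
})
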