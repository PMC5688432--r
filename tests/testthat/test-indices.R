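test_that("each index is exactly 1 at its neutral input", {
  expect_identical(index_postpartum(1.5), 1)
  expect_identical(index_sterility(3), 1)
  expect_identical(index_contraception(0, 0.97), 1)
  expect_identical(index_contraception(0, 0), 1)
  expect_equal(index_abortion(4.2, 0.3, 0), 1)
  expect_identical(index_marriage(1), 1)
})

test_that("indices match hand evaluation of the closed forms", {
  # postpartum insusceptibility: 20 / (18.5 + PPI)
  expect_equal(index_postpartum(11.7), 20 / 30.2, tolerance = 1e-12)
  expect_equal(index_postpartum(3.9), 20 / 22.4, tolerance = 1e-12)
  # sterility: (7.63 - 0.11 s) / 7.3
  expect_equal(index_sterility(2.2), (7.63 - 0.11 * 2.2) / 7.3,
               tolerance = 1e-12)
  expect_equal(index_sterility(0.9), (7.63 - 0.11 * 0.9) / 7.3,
               tolerance = 1e-12)
  # contraception: 1 - 1.08 CPR e
  expect_equal(index_contraception(0.58, 0.96), 1 - 1.08 * 0.58 * 0.96,
               tolerance = 1e-12)
  expect_equal(index_contraception(0.10, 0.95), 0.8974, tolerance = 1e-12)
  # abortion: TFR / (TFR + 0.4 (1 + CPR) TAR), lagged TFR
  expect_equal(index_abortion(6.1, 0.11, 1.085),
               6.1 / (6.1 + 0.4 * 1.11 * 1.085), tolerance = 1e-12)
  expect_equal(index_abortion(1.2, 0.67, 1.47),
               1.2 / (1.2 + 0.4 * 1.67 * 1.47), tolerance = 1e-12)
})

test_that("index domain violations raise typed errors naming the problem", {
  expect_error(index_postpartum(-1), class = "fp_error_invalid_input")
  expect_error(index_sterility(-0.1), class = "fp_error_invalid_input")
  expect_error(index_sterility(70), class = "fp_error_invalid_input")
  expect_error(index_abortion(0, 0.5, 1), class = "fp_error_invalid_input")
  expect_error(index_marriage(0), class = "fp_error_invalid_input")
  # Cc <= 0 is a model-domain error and names the offending inputs
  err <- expect_error(index_contraception(0.95, 0.99),
                      class = "fp_error_domain")
  expect_match(conditionMessage(err), "0.95")
  expect_match(conditionMessage(err), "0.99")
})

test_that("index values stay inside their analytic bounds over random draws", {
  withr::with_seed(42, {
    for (i in 1:200) {
      ppi <- runif(1, 0, 36)
      s <- runif(1, 0, 60)
      cpr <- runif(1, 0, 0.85)
      e <- runif(1, 0, 0.99)
      tar <- runif(1, 0, 4)
      tfr <- runif(1, 0.5, 8)
      expect_true(index_postpartum(ppi) > 0 &&
                    index_postpartum(ppi) <= 20 / 18.5)
      expect_true(index_sterility(s) > 0 &&
                    index_sterility(s) <= 7.63 / 7.3)
      expect_true(index_abortion(tfr, cpr, tar) > 0 &&
                    index_abortion(tfr, cpr, tar) <= 1)
      if (1.08 * cpr * e < 1) {
        cc <- index_contraception(cpr, e)
        expect_true(cc > 0 && cc <= 1)
      }
    }
  })
})

test_that("average effectiveness weights failure rates by the method mix", {
  # single-method mixes are the complement of that method's failure rate
  expect_equal(average_effectiveness(c("Implants" = 1)), 1 - 0.0005)
  expect_equal(average_effectiveness(c("Traditional methods" = 1)), 1 - 0.78)
  # 50/50 pill (6.9%) / condom (9.8%)
  expect_equal(average_effectiveness(c("Oral pill" = 0.5, "Male condom" = 0.5)),
               1 - (0.5 * 0.069 + 0.5 * 0.098))
  # permutation invariance
  mix <- c("IUD" = 0.2, "Injections" = 0.3, "Oral pill" = 0.5)
  expect_identical(average_effectiveness(mix),
                   average_effectiveness(rev(mix)))
  # a method that always fails gives zero effectiveness
  rates <- tibble::tibble(method = "Hope", failure_rate = 1)
  expect_equal(average_effectiveness(c("Hope" = 1), rates), 0)
})

test_that("unknown methods raise a lookup error listing valid methods", {
  err <- expect_error(average_effectiveness(c("Moonstone" = 1)),
                      class = "fp_error_lookup")
  expect_match(conditionMessage(err), "Moonstone")
  expect_match(conditionMessage(err), "Oral pill")
})

test_that("method mixes must be proper distributions", {
  expect_error(average_effectiveness(c("IUD" = 0.4, "Oral pill" = 0.4)),
               class = "fp_error_invalid_input")
  expect_error(average_effectiveness(c("IUD" = 1.2, "Oral pill" = -0.2)),
               class = "fp_error_invalid_input")
})

test_that("the bundled failure-rate table carries the nine standard methods", {
  rates <- fp_failure_rates()
  expect_equal(nrow(rates), 9L)
  expect_setequal(
    rates$method,
    c("Female sterilization", "Male sterilization", "Oral pill", "IUD",
      "Injections", "Implants", "Male condom", "Lactational amenorrhea",
      "Traditional methods")
  )
  expect_true(all(rates$failure_rate >= 0 & rates$failure_rate <= 1))
  expect_equal(rates$failure_rate[rates$method == "Oral pill"], 0.069)
})

test_that("abortion-rate conversion multiplies by the reproductive span", {
  expect_identical(tar_from_abortion_rate(0), 0)
  expect_equal(tar_from_abortion_rate(31), 31 * 35 / 1000)
  expect_equal(tar_from_abortion_rate(42), 42 * 35 / 1000)
  expect_equal(tar_from_abortion_rate(31, span_years = 30), 0.93)
  expect_error(tar_from_abortion_rate(-1), class = "fp_error_invalid_input")
})

test_that("composed TFR equals total fecundity under identity inputs", {
  res <- compose_tfr(identity_inputs(), tf = 15)
  expect_equal(res$tfr, 15, tolerance = 1e-12)
  expect_equal(res$cm * res$ci * res$ca * res$cs * res$cc, 1,
               tolerance = 1e-12)
})

test_that("composed TFR matches the independent formula transcription", {
  withr::with_seed(11, {
    for (i in 1:50) {
      pm <- runif(1, 0.3, 1)
      ppi <- runif(1, 0, 24)
      s <- runif(1, 0, 10)
      cpr <- runif(1, 0, 0.8)
      e <- runif(1, 0.5, 0.99)
      tar <- runif(1, 0, 3)
      tfr_prev <- runif(1, 1, 7)
      tf <- runif(1, 10, 18)
      inp <- proximate_inputs(pm, ppi, s, cpr, e, tar = tar,
                              tfr_for_ca = tfr_prev)
      expect_equal(compose_tfr(inp, tf)$tfr,
                   oracle_tfr(pm, ppi, s, cpr, e, tar, tfr_prev, tf),
                   tolerance = 1e-12)
    }
  })
})

test_that("TFR falls as contraceptive prevalence rises, all else equal", {
  cprs <- seq(0, 0.7, by = 0.05)
  tfrs <- vapply(cprs, function(p) {
    inp <- proximate_inputs(0.8, 10, 2, cpr = p, effectiveness = 0.95,
                            tar = 1, tfr_for_ca = 5)
    compose_tfr(inp, tf = 15)$tfr
  }, numeric(1))
  expect_true(all(diff(tfrs) < 0))
})

test_that("TFR does not rise as the abortion rate rises, all else equal", {
  tars <- seq(0, 3, by = 0.25)
  tfrs <- vapply(tars, function(a) {
    inp <- proximate_inputs(0.8, 10, 2, cpr = 0.3, effectiveness = 0.95,
                            tar = a, tfr_for_ca = 5)
    compose_tfr(inp, tf = 15)$tfr
  }, numeric(1))
  expect_true(all(diff(tfrs) <= 0))
})

test_that("effectiveness can be derived from a method mix at input assembly", {
  inp <- proximate_inputs(0.8, 6, 2, cpr = 0.5,
                          method_mix = c("Oral pill" = 0.5, "Male condom" = 0.5),
                          tar = 0, tfr_for_ca = 4)
  expect_equal(inp$effectiveness, 0.9165)
  expect_error(
    proximate_inputs(0.8, 6, 2, cpr = 0.5, tar = 0, tfr_for_ca = 4),
    class = "fp_error_invalid_input"
  )
})
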