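test_that("median-effect fit recovers generating parameters from exact data", {
  # fa = D/(D + 10) is the median-effect curve with Dm = 10, m = 1
  dr <- tibble::tibble(dose = c(1, 10, 100), fa = c(1 / 11, 0.5, 100 / 110))
  fit <- median_effect_fit(dr)
  expect_equal(fit$Dm, 10, tolerance = 1e-10)
  expect_equal(fit$m, 1, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)

  # generate-then-fit round trip at Dm = 5, m = 2
  dr2 <- simulate_dose_response(5, 2, c(0.5, 2, 5, 20, 80))
  fit2 <- median_effect_fit(dr2)
  expect_equal(fit2$Dm, 5, tolerance = 1e-9)
  expect_equal(fit2$m, 2, tolerance = 1e-9)

  expect_error(median_effect_fit(tibble::tibble(dose = c(1, 2),
                                                fa = c(0, 0))),
               "need >= 2 points")
  expect_error(median_effect_fit(tibble::tibble(dose = c(2, 2),
                                                fa = c(0.3, 0.6))),
               "zero variance")
  expect_message(median_effect_fit(tibble::tibble(dose = c(1, 5, 25),
                                                  fa = c(0, 0.4, 0.6))),
                 "excluded 1 point")
})

test_that("fit and inversion are exact inverses on noise-free curves", {
  withr::with_seed(61, {
    for (i in 1:20) {
      Dm <- runif(1, 0.1, 200)
      m <- runif(1, 0.4, 4)
      doses <- Dm * 10^seq(-1.5, 1.5, length.out = 6)
      fit <- median_effect_fit(simulate_dose_response(Dm, m, doses))
      expect_equal(fit$Dm, Dm, tolerance = 1e-9)
      expect_equal(fit$m, m, tolerance = 1e-9)
      for (fa in c(0.1, 0.5, 0.9)) {
        dx <- dose_for_effect(fit, fa)
        expect_equal(dx^fit$m / (dx^fit$m + fit$Dm^fit$m), fa,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("dose_for_effect evaluates the inverted median-effect equation", {
  fit <- median_effect_fit(simulate_dose_response(10, 1, c(1, 10, 100)))
  expect_equal(dose_for_effect(fit, 0.5), 10, tolerance = 1e-9)
  expect_equal(dose_for_effect(fit, 0.9), 90, tolerance = 1e-8)
  fit2 <- median_effect_fit(simulate_dose_response(10, 2, c(1, 10, 100)))
  expect_equal(dose_for_effect(fit2, 0.9), 30, tolerance = 1e-8)
  # fa = 0.5 returns Dm identically: with the measured gefitinib IC50 as Dm
  ic50 <- load_ic50_table()
  gef <- ic50$ic50_uM[ic50$drug == "Gefitinib" & ic50$cell_line == "MCF-7"]
  expect_equal(gef, 35.19)
  fit3 <- median_effect_fit(simulate_dose_response(gef, 1.3,
                                                   gef * c(0.1, 1, 10)))
  expect_equal(dose_for_effect(fit3, 0.5), 35.19, tolerance = 1e-8)
  expect_error(dose_for_effect(fit, 1), "strictly in")
})

test_that("combination index reproduces the worked example and self-additivity", {
  f1 <- median_effect_fit(simulate_dose_response(10, 1, c(1, 10, 100)))
  f2 <- median_effect_fit(simulate_dose_response(20, 2, c(2, 20, 200)))
  pt <- combination_index(f1, f2, total_dose = 15, fa = 0.5, ratio = c(1, 1))
  expect_equal(pt$d1, 7.5)
  expect_equal(pt$ci, 1.125, tolerance = 1e-9)
  expect_equal(pt$dri1, 4 / 3, tolerance = 1e-9)
  expect_equal(pt$dri2, 8 / 3, tolerance = 1e-9)
  expect_equal(pt$classification, "antagonism")

  # a drug combined with itself at total dose Dx(fa): CI = 1 exactly
  for (fa in c(0.2, 0.5, 0.8)) {
    self <- combination_index(f1, f1, total_dose = dose_for_effect(f1, fa),
                              fa = fa, ratio = c(1, 1))
    expect_equal(self$ci, 1, tolerance = 1e-9)
  }

  # deep-synergy regime classifies as synergism
  syn <- combination_index(f1, f2, total_dose = 1, fa = 0.9)
  expect_lt(syn$ci, 1)
  expect_equal(syn$classification, "synergism")
  expect_error(combination_index(f1, f2, total_dose = -1, fa = 0.5),
               "total_dose")
})

test_that("combination index invariants: symmetry, monotonicity, DRI identity", {
  f1 <- median_effect_fit(simulate_dose_response(10, 1.2, c(1, 10, 100)))
  f2 <- median_effect_fit(simulate_dose_response(40, 0.8, c(4, 40, 400)))
  a <- combination_index(f1, f2, 30, 0.6, ratio = c(2, 3))
  b <- combination_index(f2, f1, 30, 0.6, ratio = c(3, 2))
  expect_equal(a$ci, b$ci, tolerance = 1e-12)
  expect_equal(a$dri1, b$dri2, tolerance = 1e-12)

  # CI strictly increasing in total dose at fixed fa
  cis <- vapply(c(5, 10, 20, 40),
                function(td) combination_index(f1, f2, td, 0.6)$ci,
                numeric(1))
  expect_true(all(diff(cis) > 0))
  # DRI_i * D_i = Dx_i identically
  expect_equal(a$dri1 * a$d1, dose_for_effect(f1, 0.6), tolerance = 1e-12)
  expect_equal(a$dri2 * a$d2, dose_for_effect(f2, 0.6), tolerance = 1e-12)
  # 1/CI <= max(DRI)
  expect_lte(1 / a$ci, max(a$dri1, a$dri2) + 1e-12)
})

test_that("ci_fa_table scores measured mixtures and flags undefined rows", {
  f1 <- median_effect_fit(simulate_dose_response(10, 1, c(1, 10, 100)))
  f2 <- median_effect_fit(simulate_dose_response(20, 1, c(2, 20, 200)))
  # exactly additive 1:1 mixture of same-slope drugs: pooled Dm is
  # harmonic-style: D/2/10 + D/2/20 = 1 at fa 0.5 -> D = 40/3
  mix_dm <- 40 / 3
  mix <- simulate_dose_response(mix_dm, 1, mix_dm * c(0.25, 1, 4))
  tab <- ci_fa_table(f1, f2, tibble::tibble(total_dose = mix$dose,
                                            fa = mix$fa))
  expect_true(all(abs(tab$ci - 1) < 1e-9))
  expect_true(!is.unsorted(rev(tab$total_dose)))

  # potentiation: doses halved for the same effect -> CI ~ 0.5
  mix2 <- simulate_dose_response(mix_dm / 2, 1, mix_dm / 2 * c(0.25, 1, 4))
  tab2 <- ci_fa_table(f1, f2, tibble::tibble(total_dose = mix2$dose,
                                             fa = mix2$fa))
  expect_true(all(abs(tab2$ci - 0.5) < 1e-9))

  # fa at 0/1 kept but flagged
  expect_warning(
    tab3 <- ci_fa_table(f1, f2, tibble::tibble(total_dose = c(5, 10),
                                               fa = c(0, 0.5))),
    "CI undefined"
  )
  expect_equal(tab3$defined, c(TRUE, FALSE)) # sorted by dose descending
  expect_true(is.na(tab3$ci[2]))

  empty <- ci_fa_table(f1, f2, tibble::tibble(total_dose = numeric(0),
                                              fa = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("simulated dose-response is deterministic and recovers under noise", {
  exact <- simulate_dose_response(10, 1, 10)
  expect_equal(exact$fa, 0.5)
  a <- simulate_dose_response(5, 2, c(1, 5, 25), noise_sd = 0.02, seed = 4)
  b <- simulate_dose_response(5, 2, c(1, 5, 25), noise_sd = 0.02, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$fa >= 0 & a$fa <= 1))

  # Monte-Carlo recovery: fitted Dm within 10% of truth in >= 90% of runs.
  # Doses follow a standard assay design bracketing the IC50 so fa stays in
  # the quantifiable range (the logit noise blows up at fa near 0 or 1).
  doses <- 5 * 10^seq(-0.5, 0.5, length.out = 8)
  hits <- vapply(1:100, function(i) {
    fit <- median_effect_fit(simulate_dose_response(5, 2, doses,
                                                    noise_sd = 0.02,
                                                    seed = 1000 + i))
    abs(fit$Dm - 5) / 5 < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
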