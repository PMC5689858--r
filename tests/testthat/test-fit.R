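test_that("the r conversion follows ((R - 0.31) - 0.81 M) / (0.81 M)", {
  expect_equal(r_index(15.0, 10.0), (14.69 - 8.1) / 8.1)
  expect_equal(r_index(25.0, 10.0), (24.69 - 8.1) / 8.1)
  expect_equal(r_index(0.31 + 0.81 * 6, 6), 0)  # full-modulation limit
  expect_error(r_index(15, 0), "positive")
  expect_error(r_index(0.1, 5), "non-negative")
  conv <- r_conversion(delta_R = 0.5, rho_M = 0.9)
  expect_equal(r_index(10, 5, conv), (9.5 - 4.5) / 4.5)
})

test_that("r is monotone: decreasing in M at fixed R, increasing in R at fixed M", {
  M <- seq(2, 15, by = 0.5)
  expect_true(all(diff(r_index(20, M)) < 0))
  R <- seq(6, 30, by = 0.5)
  expect_true(all(diff(r_index(R, 5)) > 0))
})

test_that("the analytical basic term is strictly decreasing in r", {
  r <- seq(0.01, 10, length.out = 500)
  for (a0 in c(0.02, 0.1, 0.5)) for (a1 in c(0.3, 0.6, 1.2)) {
    expect_true(all(diff(100 / (1 + a0 * r^a1)) < 0))
  }
})

# direct formula-generated measurements for one synthetic option
formula_data <- function(amp = 140, a0 = 0.07, a1 = 0.62, s0 = 0.97,
                         s1 = 0.0125, R_L = 12.6, Rs = c(12.6, 13.8, 15.0),
                         M_sweep = c(2, 3, 4, 6, 8, 10, 12, 15)) {
  sweep <- tibble::tibble(option = 20, R = 15.0, M = M_sweep)
  shift <- tibble::tibble(option = 20, R = Rs, M = 8)
  d <- rbind(sweep, shift)
  r <- r_index(d$R, d$M)
  d$psi <- amp / (1 + a0 * r^a1) * (s0 + s1 * (d$R - R_L))
  d
}

test_that("model B recovers known constants exactly from noise-free data", {
  d <- formula_data()
  fit <- fit_sobp_model(d, model = "B")
  p <- fit$params
  expect_equal(p$a0, 0.07, tolerance = 1e-6)
  expect_equal(p$a1, 0.62, tolerance = 1e-6)
  # s is identified up to the amplitude convention s(R_max) = 1
  sRmax <- 0.97 + 0.0125 * (15.0 - 12.6)
  expect_equal(p$amp, 140 * sRmax, tolerance = 1e-6)
  expect_equal(p$s0, 0.97 / sRmax, tolerance = 1e-6)
  expect_equal(p$s1, 0.0125 / sRmax, tolerance = 1e-6)
})

test_that("model C recovers a known quartic to 1e-9 and interpolates 5 points", {
  q <- c(102, -11, 1.4, -0.09, 0.002)
  rs <- c(0.3, 0.8, 1.5, 2.4, 3.5, 5, 6.5, 8)
  d <- tibble::tibble(option = 20, R = 15.0, M = (15 - 0.31) / (0.81 * (1 + rs)))
  r <- r_index(d$R, d$M)
  d$psi <- q[1] + q[2] * r + q[3] * r^2 + q[4] * r^3 + q[5] * r^4
  d <- rbind(d, tibble::tibble(option = 20, R = c(12.6, 13.8), M = 8,
                               psi = NA))
  r2 <- r_index(d$R[9:10], d$M[9:10])
  d$psi[9:10] <- q[1] + q[2] * r2 + q[3] * r2^2 + q[4] * r2^3 + q[5] * r2^4
  fit <- fit_sobp_model(d, model = "C")
  p <- fit$params
  expect_equal(c(p$p0, p$p1, p$p2, p$p3, p$p4), q, tolerance = 1e-9)
  expect_equal(p$rel_rss, 0, tolerance = 1e-9)
  # exactly 5 sweep points: the quartic interpolates, residual 0
  d5 <- d[c(1:5, 9:10), ]
  d5 <- rbind(d5, d[8, ])  # keep 3 distinct ranges
  fit5 <- fit_sobp_model(d5, model = "C")
  expect_equal(fit5$params$rel_rss, 0, tolerance = 1e-10)
})

test_that("degenerate and rank-deficient designs are rejected or flagged", {
  d <- formula_data()
  d$psi[d$R == 15.0] <- 5  # constant sweep
  d$psi[d$R < 15.0] <- 5
  fit <- fit_sobp_model(d, model = "B")
  expect_true(fit$params$degenerate)
  expect_equal(fit$params$a0, 0)
  expect_equal(fit$params$amp, 5)
  same_r <- tibble::tibble(option = 20, R = 15, M = rep(8, 6),
                           psi = rnorm(6, 100))
  expect_error(fit_sobp_model(same_r, model = "C"), "rank-deficient|distinct")
  few <- formula_data(M_sweep = c(2, 4))  # plus the shift row at R_max: 3 points
  expect_error(fit_sobp_model(few, model = "B"), "need >= 4")
  two_R <- formula_data(Rs = c(13.8, 15.0))
  expect_error(fit_sobp_model(two_R, model = "B"), "need >= 3")
})

test_that("analytical predictions match direct formula evaluation", {
  truth <- shared_truth()
  camp <- shared_campaign0()
  fitdat <- dplyr::filter(camp, campaign %in% c("SOBPF", "RSF"))
  fb <- fit_sobp_model(fitdat, model = "B")
  fc <- fit_sobp_model(fitdat, model = "C")
  tb <- tables_from_campaign(camp)
  cat_df <- option_catalog()
  b <- beam_spec(7, R = 12.0, M = 6.0, dz_p = 1, dz = -2)
  for (fit in list(fb, fc)) {
    p <- predict_output(b, tb, model = fit$model, params = fit,
                        catalog = cat_df)
    pp <- fit$params[fit$params$option == 7, ]
    r <- r_index(12, 6)
    basic <- if (fit$model == "B") {
      pp$amp / (1 + pp$a0 * r^pp$a1)
    } else {
      pp$p0 + pp$p1 * r + pp$p2 * r^2 + pp$p3 * r^3 + pp$p4 * r^4
    }
    shift_cf <- if (fit$model == "B") c(pp$s0, pp$s1) else c(pp$s2, pp$s3)
    R_L <- cat_df$R_L[cat_df$option == 7]
    expected <- basic * (shift_cf[1] + shift_cf[2] * (12 - R_L)) *
      isf_ocf(cat_df$ESAD[cat_df$option == 7], 1, -2) *
      ocr_factor(tb, 7, 0, 0) * fsf_factor(tb, 7, "20x20", cat_df) *
      gacf_factor(tb, "large", 0)
    expect_equal(p$psi, expected, tolerance = 1e-12)
  }
})

test_that("fits on noisy data predict held-out points within 2.5 percent", {
  set.seed(314)
  d <- formula_data(M_sweep = c(2, 3, 4, 6, 8, 10, 12, 14, 15))
  d$psi <- d$psi * (1 + 0.005 * rnorm(nrow(d)))
  fit <- fit_sobp_model(d, model = "B")
  held <- tibble::tibble(option = 20, R = c(14.0, 13.2, 14.6),
                         M = c(5, 9, 11))
  r <- r_index(held$R, held$M)
  p <- fit$params
  pred <- p$amp / (1 + p$a0 * r^p$a1) * (p$s0 + p$s1 * (held$R - 12.6))
  sRmax <- 0.97 + 0.0125 * (15.0 - 12.6)
  true_psi <- 140 / (1 + 0.07 * r^0.62) * (0.97 + 0.0125 * (held$R - 12.6))
  expect_true(all(abs(pred / true_psi - 1) < 0.025))
})

test_that("fitting is deterministic for fixed data order and tidiers work", {
  d <- formula_data()
  f1 <- fit_sobp_model(d, model = "B")
  f2 <- fit_sobp_model(d, model = "B")
  expect_identical(f1$params, f2$params)
  td <- tidy(f1)
  expect_true(all(c("option", "term", "estimate") %in% names(td)))
  g <- glance(f1)
  expect_equal(g$n_options, 1)
  expect_s3_class(autoplot(f1), "ggplot")
  # mismatched model/params pairing is refused
  tb <- toy_tables()
  expect_error(predict_output(beam_spec(20, R = 14, M = 8), tb,
                              model = "C", params = f1),
               "not model C")
})
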