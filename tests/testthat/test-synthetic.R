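test_that("the default campaign reproduces the commissioning design sizes", {
  camp <- shared_campaign0()
  counts <- table(camp$campaign)
  expect_equal(as.integer(counts[c("ROF", "SOBPF", "RSF", "FSF", "GACF",
                                   "validation")]),
               c(24L, 182L, 324L, 54L, 75L, 272L))
  # SOBPF sweeps always reach each option's maximum modulation
  cat_df <- option_catalog()
  sw <- dplyr::filter(camp, campaign == "SOBPF") |>
    dplyr::group_by(option) |>
    dplyr::summarise(top = max(M))
  expect_equal(sw$top, cat_df$M_max[match(sw$option, cat_df$option)])
  # validation modulations are clinical: at least 3 g/cm2, never above range
  val <- dplyr::filter(camp, campaign == "validation")
  expect_true(all(val$M >= 3 & val$M <= val$R))
  expect_equal(sum(val$dz_p != 0 | val$dz != 0), 60)
})

test_that("zero-noise measurements equal the truth and seeds reproduce", {
  truth <- shared_truth()
  camp <- shared_campaign0()
  expect_equal(camp$psi, truth_output(truth, camp), tolerance = 1e-15)
  camp2 <- generate_campaign(truth, sigma = 0, seed = 1)
  expect_identical(camp, camp2)
  noisy1 <- generate_campaign(truth, sigma = 0.005, seed = 9)
  noisy2 <- generate_campaign(truth, sigma = 0.005, seed = 9)
  expect_identical(noisy1, noisy2)
  expect_false(identical(noisy1$psi,
                         generate_campaign(truth, sigma = 0.005, seed = 10)$psi))
  expect_error(generate_campaign(truth, sigma = -0.1), "non-negative")
})

test_that("tables built from a campaign satisfy every normalization invariant", {
  camp <- shared_campaign0()
  tb <- tables_from_campaign(camp)
  expect_length(validate_tables(tb), 0)
  expect_equal(rof_factor(tb, 20), 1)  # self-ratio of the calibration option
  expect_equal(tb$psi_o, 1.06, tolerance = 1e-12)
  # ROF pattern of the truth machine reproduces the published factors
  rof_csv <- read.csv(system.file("extdata", "rof_table.csv", package = "protonmu"))
  expect_equal(rof_factor(tb, rof_csv$option), rof_csv$rof, tolerance = 1e-9)
  # missing blocks are reported by name
  expect_error(tables_from_campaign(dplyr::filter(camp, campaign != "FSF")),
               "FSF")
})

test_that("the noise-free pipeline predicts validation points to interpolation error", {
  camp <- shared_campaign0()
  tb <- tables_from_campaign(camp)
  val <- dplyr::filter(camp, campaign == "validation")
  vr <- validate_models(val, tb)
  expect_lt(max(abs(vr$pct_diff)), 0.5)
})

test_that("model fitting on a noise-free campaign recovers the truth constants", {
  truth <- shared_truth()
  camp <- shared_campaign0()
  fit <- fit_sobp_model(dplyr::filter(camp, campaign %in% c("SOBPF", "RSF")),
                        model = "B")
  p <- fit$params[order(fit$params$option), ]
  tp <- truth$params[order(truth$params$option), ]
  expect_lt(max(abs(p$a0 - tp$a0) / tp$a0), 1e-6)
  expect_lt(max(abs(p$a1 - tp$a1) / tp$a1), 1e-6)
  expect_lt(max(abs(p$s1 - tp$s1) / tp$s1), 1e-6)
  expect_lt(max(abs(p$s0 - tp$s0) / tp$s0), 1e-6)
})

test_that("unbiased measurement noise does not bias validation differences", {
  truth <- shared_truth()
  camp <- shared_campaign0()
  tb <- tables_from_campaign(camp)  # exact tables
  val <- dplyr::filter(camp, campaign == "validation")
  clean <- validate_models(val, tb)$pct_diff
  sigma <- 0.005
  set.seed(77)
  shifts <- replicate(50, {
    noisy <- val
    noisy$psi <- noisy$psi * (1 + sigma * rnorm(nrow(noisy)))
    mean(validate_models(noisy, tb)$pct_diff) - mean(clean)
  })
  # each replicate's mean shift is measurement noise alone: ~ N(0, 100*sigma/sqrt(n))
  se <- 100 * sigma / sqrt(nrow(val))
  expect_lt(max(abs(shifts)), 4 * se)
  expect_lt(abs(mean(shifts)), 3 * se / sqrt(50))
})

test_that("more measurement noise means wider validation spread", {
  truth <- shared_truth()
  sds <- vapply(c(0.002, 0.02), function(sg) {
    camp <- generate_campaign(truth, sigma = sg, seed = 5)
    tb <- tables_from_campaign(camp)
    vr <- validate_models(dplyr::filter(camp, campaign == "validation"), tb)
    sd(vr$pct_diff)
  }, numeric(1))
  expect_lt(sds[1], sds[2])
})

test_that("the warped truth keeps all models approximate but within tolerance", {
  truth <- truth_machine(seed = 3, warp = 0.005)
  camp <- generate_campaign(truth, sigma = 0, seed = 3)
  tb <- tables_from_campaign(camp)
  fit <- fit_sobp_model(dplyr::filter(camp, campaign %in% c("SOBPF", "RSF")),
                        model = "B")
  vr <- validate_models(dplyr::filter(camp, campaign == "validation"), tb,
                        fits = list(fit))
  s <- summarize_validation(vr)
  # no model is exactly true any more, but all stay clinically acceptable
  expect_gt(max(abs(vr$pct_diff[vr$model == "B"])), 0.05)
  expect_true(all(s$stats$pass))
})
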