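test_that("published factor tables are reproduced exactly at every cell", {
  tb <- s250_tables()
  rof_csv <- read.csv(system.file("extdata", "rof_table.csv", package = "protonmu"))
  expect_equal(rof_factor(tb, rof_csv$option), rof_csv$rof)
  rsf_csv <- read.csv(system.file("extdata", "rsf_table.csv", package = "protonmu"))
  got <- rsf_factor(tb, rsf_csv$option, rsf_csv$R, rsf_csv$M, detail = TRUE)
  expect_equal(got$factor, rsf_csv$factor)
  fsf_csv <- read.csv(system.file("extdata", "fsf_table.csv", package = "protonmu"))
  expect_equal(fsf_factor(tb, fsf_csv$option, fsf_csv$field), fsf_csv$factor)
})

test_that("RSF queries touching an extrapolated corner are flagged", {
  tb <- s250_tables()
  d <- rsf_factor(tb, 20, c(13.3, 15.3, 13.8), c(14.3, 2, 14.0), detail = TRUE)
  expect_true(d$placeholder[1])    # a placeholder node itself
  expect_false(d$placeholder[2])   # measured corner
  expect_true(d$placeholder[3])    # cell bracketed by a placeholder corner
})

test_that("unmeasured options map to the nearest measured option in-group for FSF", {
  tb <- s250_tables()
  # option 2 (large) has no measured FSF; nearest measured large option is 1
  expect_equal(fsf_factor(tb, 2, "circ3.5"), fsf_factor(tb, 1, "circ3.5"))
  expect_equal(fsf_factor(tb, 16, "5x5"), fsf_factor(tb, 15, "5x5"))
})

test_that("fields below the smallest measured size error unless overridden", {
  tb <- s250_tables()
  expect_error(fsf_factor(tb, 20, "2x2"), "measured directly")
  expect_no_error(fsf_factor(tb, 20, "2x2", allow_small = TRUE))
})

test_that("SOBPF interpolation is exact at nodes, linear between, strict outside", {
  tb <- toy_tables()
  expect_equal(sobpf_factor(tb, 20, c(2, 8, 10)), c(0.80, 0.97, 1))
  expect_equal(sobpf_factor(tb, 20, 3), (0.80 + 0.88) / 2)  # midpoint = mean
  expect_equal(sobpf_factor(tb, 13, 5), (0.92 + 0.96) / 2)
  expect_error(sobpf_factor(tb, 20, 16), "outside")
  expect_error(sobpf_factor(tb, 20, 1.5), "outside")
})

test_that("RSF bilinear interpolation reproduces the hand-computed midpoint", {
  tb <- s250_tables()
  # midway between the option-1 rows at 25.0 (1.0000) and 23.8 (0.9931), M = 10
  expect_equal(as.numeric(rsf_factor(tb, 1, 24.4, 10)), 0.99655)
  expect_error(rsf_factor(tb, 1, 22.0, 10), "outside")
})

test_that("placeholder filling fits c0 + c1*log(M) rows and flags the result", {
  # exact log-law row: round trip recovers the law to 1e-9
  mm <- c(2, 5, 8, 11, 14)
  law <- function(m) 1.02 - 0.03 * log(m)
  tb <- toy_tables()
  syn <- tibble::tibble(option = 20,
                        R = rep(c(12.6, 15.0), each = 5),
                        M = rep(mm, 2),
                        factor = c(law(mm), rep(1, 5)),
                        placeholder = FALSE)
  syn$factor[syn$R == 12.6 & syn$M >= 13] <- NA  # pretend not deliverable
  tb$rsf <- syn
  filled <- fill_rsf_placeholders(tb)
  got <- filled$rsf[filled$rsf$R == 12.6 & filled$rsf$M == 14, ]
  expect_equal(got$factor, law(14), tolerance = 1e-9)
  expect_true(got$placeholder)
  # complete grids are untouched
  tb2 <- toy_tables()
  expect_identical(fill_rsf_placeholders(tb2)$rsf, tb2$rsf)
  # too few measured points on an incomplete row is an error
  tb$rsf$factor[tb$rsf$R == 12.6 & tb$rsf$M %in% c(5, 8)] <- NA
  expect_error(fill_rsf_placeholders(tb), "need >= 3")
})

test_that("OCR interpolation is normalized on axis and strict off-grid", {
  tb <- toy_tables()
  expect_equal(ocr_factor(tb, 20, 0, 0), 1)
  expect_equal(ocr_factor(tb, 20, 2, -1), 1 + 0.004 + 0.001)  # grid node
  expect_error(ocr_factor(tb, 20, 5, 0), "outside")
})

test_that("asymmetric profiles give different mirror-point OCR values", {
  # a grid with a 6% left-right imbalance near the field edge
  g <- expand.grid(option = 1, x = seq(-10, 10, 5), y = seq(-10, 10, 5))
  g$factor <- 1 + 0.003 * g$x
  g$factor[g$x == 0] <- 1
  tb <- toy_tables(); tb$ocr <- g
  expect_equal(ocr_factor(tb, 1, -10, 0), 0.97)
  expect_equal(ocr_factor(tb, 1, 10, 0), 1.03)
})

test_that("profile resampling preserves planes, extent and coincident points", {
  g <- expand.grid(x = seq(-3, 3, 1), y = seq(-3, 3, 1))
  g$factor <- 1  # constant field stays constant
  out <- resample_ocr(g, spacing = 0.5)
  expect_true(all(out$factor == 1))
  g$factor <- 2 + 0.1 * g$x - 0.05 * g$y  # bilinear reproduces planes exactly
  out <- resample_ocr(g, spacing = 0.5)
  expect_equal(out$factor, 2 + 0.1 * out$x - 0.05 * out$y, tolerance = 1e-12)
  expect_equal(range(out$x), c(-3, 3))
  expect_equal(sort(unique(diff(sort(unique(out$x))))), 0.5)
  gg <- g[g$x != 2 | g$y != 0, ]
  expect_error(resample_ocr(rbind(gg, data.frame(x = 2.2, y = 0, factor = 1))),
               "uniform|rectangular")
})

test_that("GACF interpolates along the arc, across the 355 -> 0 wrap", {
  tb <- toy_tables()
  expect_equal(gacf_factor(tb, "large", 0), 1)
  # node exactness and linearity in arc position
  expect_equal(gacf_factor(tb, "small", 90), 1 - 0.02 * (95 / 190))
  mid <- gacf_factor(tb, "deep", 357)  # between 355 and 0 on the arc
  expect_equal(mid, (gacf_factor(tb, "deep", 355) * 3 / 5 +
                       1 * 2 / 5), tolerance = 1e-12)
  expect_error(gacf_factor(tb, "large", 270), "arc")
})

test_that("tables survive a write/read round trip", {
  # decimal-stored factors (the published fixture) round-trip bit-exactly
  tb <- s250_tables()
  path <- tempfile(fileext = ".json")
  write_tables(tb, path)
  tb2 <- read_tables(path)
  for (block in c("rof", "sobpf", "rsf", "ocr", "fsf", "gacf")) {
    expect_identical(tb2[[block]]$factor, tb[[block]]$factor)
  }
  expect_identical(tb2$psi_o, tb$psi_o)
  # arbitrary computed factors round-trip to full double precision
  toy <- toy_tables()
  write_tables(toy, path)
  toy2 <- read_tables(path)
  for (block in c("rof", "sobpf", "rsf", "ocr", "fsf", "gacf")) {
    expect_equal(toy2[[block]]$factor, toy[[block]]$factor, tolerance = 1e-14)
  }
})

test_that("malformed table files produce descriptive errors and warnings", {
  tb <- toy_tables()
  path <- tempfile(fileext = ".json")
  obj <- unclass(tb); obj$rof <- NULL
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  expect_error(read_tables(path), "'rof' block")
  tb$rof$factor[tb$rof$option == 20] <- 1.02
  write_tables(tb, path)
  expect_warning(read_tables(path), "ROF of calibration option")
  expect_error(read_tables("/nonexistent/tables.json"), "not found")
})

test_that("bilinear interpolation matches the brute-force oracle to 1e-12", {
  set.seed(11)
  x <- sort(runif(6, 0, 10)); y <- sort(runif(6, -5, 5))
  z <- matrix(rnorm(36), 6, 6)
  xq <- runif(1000, min(x), max(x)); yq <- runif(1000, min(y), max(y))
  expect_equal(interp_bilinear(x, y, z, xq, yq),
               brute_bilinear(x, y, z, xq, yq), tolerance = 1e-12)
  # exact at every node
  nodes <- expand.grid(i = 1:6, j = 1:6)
  expect_equal(interp_bilinear(x, y, z, x[nodes$i], y[nodes$j]),
               z[cbind(nodes$i, nodes$j)], tolerance = 1e-12)
  expect_error(interp_bilinear(x, y, z, max(x) + 1, y[1]), "outside")
})
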