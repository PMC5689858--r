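# Shared fixtures and independent oracles, built in code.

# Independent brute-force bilinear interpolation: explicit cell algebra,
# no shared code with the package's interpolator.
brute_bilinear <- function(x, y, z, xq, yq) {
  out <- numeric(length(xq))
  for (k in seq_along(xq)) {
    i <- max(which(x <= xq[k] + 1e-12)); i <- min(i, length(x) - 1)
    j <- max(which(y <= yq[k] + 1e-12)); j <- min(j, length(y) - 1)
    tx <- (xq[k] - x[i]) / (x[i + 1] - x[i])
    ty <- (yq[k] - y[j]) / (y[j + 1] - y[j])
    out[k] <- z[i, j] * (1 - tx) * (1 - ty) + z[i + 1, j] * tx * (1 - ty) +
      z[i, j + 1] * (1 - tx) * ty + z[i + 1, j + 1] * tx * ty
  }
  out
}

# A small hand-built two-option machine for unit tests: option 20 (reference)
# and option 13, with non-trivial but simple factor tables.
toy_tables <- function() {
  rsf <- rbind(
    expand.grid(option = 20, R = c(12.6, 13.8, 15.0), M = c(2, 8, 15)),
    expand.grid(option = 13, R = c(29.6, 30.8, 32.0), M = c(2, 6, 10)))
  rsf$factor <- 1
  rsf$factor[rsf$option == 20] <- c(0.95, 0.97, 1, 0.94, 0.96, 1, 0.92, 0.95, 1)
  rsf$factor[rsf$option == 13] <- c(1.001, 1.0005, 1, 1.0008, 1.0004, 1,
                                    0.9995, 0.9998, 1)
  ocr <- expand.grid(option = c(20, 13), x = -2:2, y = -2:2)
  ocr$factor <- 1 + 0.002 * ocr$x - 0.001 * ocr$y
  ocr$factor[ocr$x == 0 & ocr$y == 0] <- 1
  mu_tables(
    psi_o = 1.06,
    rof = tibble::tibble(option = c(20, 13), factor = c(1, 1.35)),
    sobpf = rbind(
      tibble::tibble(option = 20, M = c(2, 4, 6, 8, 10, 12, 15),
                     factor = c(0.80, 0.88, 0.93, 0.97, 1, 1.02, 1.05)),
      tibble::tibble(option = 13, M = c(2, 4, 6, 8, 10),
                     factor = c(0.85, 0.92, 0.96, 0.99, 1))),
    rsf = rsf,
    ocr = ocr,
    fsf = rbind(
      tibble::tibble(option = 20, field = c("circ3.5", "5x5", "10x10", "circ14"),
                     factor = c(0.94, 1.003, 1, 1)),
      tibble::tibble(option = 13, field = c("circ3.5", "5x5", "10x10", "circ14"),
                     factor = c(0.66, 0.98, 1, 1))),
    gacf = tidyr::expand_grid(group = c("large", "deep", "small"),
                              angle = c(355, 0, 45, 90, 135, 180, 185)) |>
      dplyr::mutate(factor = ifelse(angle == 0, 1,
                                    1 - 0.02 * (arc_position(angle) / 190))))
}

# Tables that are identically 1 everywhere (psi_o = 1): predictions reduce to
# the geometry factor alone.
unit_tables <- function() {
  tb <- toy_tables()
  tb$psi_o <- 1
  for (block in c("rof", "sobpf", "rsf", "ocr", "fsf", "gacf")) {
    tb[[block]]$factor <- 1
  }
  tb
}

# Shared synthetic machine and noise-free campaign (computed once per run).
shared_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- truth_machine(seed = 1)
    val
  }
})

shared_campaign0 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_campaign(shared_truth(), sigma = 0, seed = 1)
    val
  }
})
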