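test_that("the normalization factor is the mean dose ratio with strict input checks", {
  expect_equal(normalization_factor(c(1.1, 1.3), c(1, 1)), 1.2)
  expect_equal(normalization_factor(rep(0.9 * 2, 7), rep(2, 7)), 0.9)
  expect_error(normalization_factor(numeric(0), numeric(0)), "no dose pairs")
  expect_error(normalization_factor(1, c(1, 2)), "equal length")
  expect_error(normalization_factor(c(1, 1), c(1, 0)), "> 0")
})

test_that("NF correction is an algebraic identity on its own training ratios", {
  withr::with_seed(8, {
    d_wkp <- runif(40, 2, 6)
    d_sv <- d_wkp * rlnorm(40, log(0.9), 0.1)
  })
  nf <- normalization_factor(d_sv, d_wkp)
  pd <- percent_difference(apply_nf(d_sv, nf), d_wkp)
  expect_equal(mean(pd), 0, tolerance = 1e-10)
  expect_equal(apply_nf(3, 1), 3)
  expect_equal(apply_nf(3, 2), 1.5)
  expect_error(apply_nf(3, 0), "> 0")
})

test_that("percentage difference, bias and accuracy match hand values", {
  expect_equal(percent_difference(1.15, 1), 15)
  expect_equal(percent_difference(1, 1), 0)
  eps <- 0.034
  expect_equal(percent_difference(1 + eps, 1), 100 * eps)
  expect_error(percent_difference(1, 0), "> 0")

  ba <- bias_accuracy(c(10, -10))
  expect_equal(ba$bias_pct, 0)
  expect_equal(ba$accuracy_pct, sqrt(200), tolerance = 1e-12)
  expect_equal(round(ba$accuracy_pct, 2), 14.14)
  expect_equal(bias_accuracy(c(0, 0, 0)),
               tibble::tibble(bias_pct = 0, accuracy_pct = 0))
  x <- c(3, -8, 12, 5)
  expect_equal(bias_accuracy(x), bias_accuracy(rev(x)))
  expect_error(bias_accuracy(5), "at least 2")
})

test_that("Bland-Altman limits are bias +/- 1.96 SD with nominal coverage", {
  d_wkp <- c(2, 3, 4, 5)
  d_sv <- d_wkp * c(1.1, 0.95, 1.05, 1.0)
  ba <- bland_altman(d_sv, d_wkp)
  pd <- 100 * (d_sv - d_wkp) / d_wkp
  expect_equal(ba$bias_pct, mean(pd))
  expect_equal(ba$loa_low, mean(pd) - 1.96 * sd(pd), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(pd) + 1.96 * sd(pd), tolerance = 1e-12)
  # symmetric about the bias by construction
  expect_equal(ba$loa_high - ba$bias_pct, ba$bias_pct - ba$loa_low)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias_pct, same$loa_low, same$loa_high), c(0, 0, 0))

  # empirical coverage on Gaussian differences
  withr::with_seed(17, {
    ref <- rep(1, 1000)
    test <- 1 + rnorm(1000, 0.02, 0.08)
  })
  ba2 <- bland_altman(test, ref)
  inside <- mean(ba2$data$pd_pct >= ba2$loa_low & ba2$data$pd_pct <= ba2$loa_high)
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("pearson_r matches the brute-force oracle and flags degenerate input", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x), -1, tolerance = 1e-12)
  withr::with_seed(2, y <- x + rnorm(5))
  expect_equal(pearson_r(x, y), naive_pearson(x, y), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("run_sweep is deterministic, nested in k, and stratifies the NF by sigma", {
  co <- fixture_small_cohort()
  m <- protocol_preset("ASCC", noise = TRUE)
  sw1 <- run_sweep(co, m, sv_volumes = 2, n_svs = 1:3, sigmas = c(0, 4),
                   seed = 5)
  sw2 <- run_sweep(co, m, sv_volumes = 2, n_svs = 1:3, sigmas = c(0, 4),
                   seed = 5)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))

  # greedy prefix: a run asking for fewer SV counts reproduces those rows
  sw3 <- run_sweep(co, m, sv_volumes = 2, n_svs = 1:2, sigmas = c(0, 4),
                   seed = 5)
  expect_equal(
    as.data.frame(sw3),
    as.data.frame(dplyr::filter(sw1, n_svs <= 2)),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  # one NF per (sv_volume, sigma) stratum, never pooled across sigma
  nf0 <- unique(sw1$nf[sw1$sigma_mm == 0])
  nf4 <- unique(sw1$nf[sw1$sigma_mm == 4])
  expect_length(nf0, 1)
  expect_length(nf4, 1)
  expect_false(isTRUE(all.equal(nf0, nf4)))

  # in-sample mean PD over the single-SV ratios is exactly zero
  singles <- sweep_singles(sw1)
  for (sg in c(0, 4)) {
    sub <- singles[singles$sigma_mm == sg, ]
    nf <- normalization_factor(sub$d_sv, sub$d_wkp)
    expect_equal(mean(percent_difference(apply_nf(sub$d_sv, nf), sub$d_wkp)),
                 0, tolerance = 1e-10)
  }

  # a model carrying its own postfilter is rejected
  expect_error(
    run_sweep(co, protocol_preset("ASCC", postfilter_sigma_mm = 2), seed = 1),
    "postfilter 0"
  )
})

test_that("sweep output renders as a Markdown accuracy grid", {
  co <- fixture_small_cohort()
  sw <- run_sweep(co, protocol_preset("ASCC", noise = TRUE), sv_volumes = 2,
                  n_svs = 1:2, sigmas = 4, seed = 3)
  lines <- sweep_markdown(sw, sigma_mm = 4)
  expect_true(any(grepl("^\\| 2 \\|", lines)))
  expect_true(any(grepl("1 SV \\| 2 SV", lines)))
})
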