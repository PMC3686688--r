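test_that("prediction statistics match closed forms and printed arithmetic", {
  # two-point closed form (padded to the minimum n with a duplicated pair)
  s <- prediction_stats(c(0, 2, 0, 2), c(1, 3, 1, 3))
  expect_equal(s$bias, 1)
  expect_equal(s$rmsep, 1)
  expect_equal(s$sep_b, 0)
  expect_equal(s$rpd, sd(c(0, 2, 0, 2)))
  # perfect prediction: zero errors, R2 = 1, infinite RPD with a warning
  expect_warning(sp <- prediction_stats(c(1, 2, 3), c(1, 2, 3)), "infinite")
  expect_equal(sp$bias, 0)
  expect_equal(sp$sep_b, 0)
  expect_equal(sp$rmsep, 0)
  expect_equal(sp$r2, 1)
  expect_true(is.infinite(sp$rpd))
  expect_error(prediction_stats(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(prediction_stats(1:2, 1:2), "at least 3")
})

test_that("RPD arithmetic reproduces the published rows at two decimals", {
  ref <- reference_performance()
  rpd <- round_to(ref$sd / ref$rmsep, 2)
  # rows whose printed inputs reproduce the printed RPD exactly
  exact_rows <- ref$subset == "organic" |
    (ref$subset == "mineral" & ref$predictor == "rfe+sand") |
    (ref$subset == "woodland" & ref$predictor == "spc")
  expect_equal(rpd[exact_rows], ref$rpd[exact_rows])
  # remaining rows agree within rounding of the printed inputs
  expect_true(all(abs(rpd - ref$rpd) <= 0.02 + 1e-9))
})

test_that("the bias/SEP decomposition identities hold on random vectors", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    obs <- rnorm(n); pred <- rnorm(n)
    if (sd(obs) == 0) next
    s <- prediction_stats(obs, pred)
    expect_lt(abs(s$rmsep^2 - (s$bias^2 + s$sep_b^2 * (n - 1) / n)), 1e-10)
    expect_lt(abs(s$rpd * s$rmsep - s$sd_obs), 1e-10)
    # permutation invariance
    p <- sample(n)
    s2 <- prediction_stats(obs[p], pred[p])
    expect_equal(s2$rmsep, s$rmsep)
    expect_equal(s2$r2, s$r2)
  }
})

test_that("both R2 definitions are available and differ when biased", {
  obs <- c(1, 2, 3, 4)
  pred <- obs + 10           # perfectly correlated, hugely biased
  expect_equal(prediction_stats(obs, pred)$r2, 1)
  expect_lt(prediction_stats(obs, pred, r2_method = "ssr")$r2, 0)
})

test_that("SEL follows the duplicate-pair formula and estimates the lab noise", {
  expect_equal(sel_from_duplicates(cbind(c(1, 2), c(1, 2))), 0)
  expect_equal(sel_from_duplicates(cbind(c(1, 2), c(3, 2))), 1)
  expect_error(sel_from_duplicates(cbind(c(1, NA), c(2, 3))), "unpaired")
  expect_error(sel_from_duplicates(matrix(1, 2, 3)), "two replicate")
  set.seed(2)
  sigma <- 2
  truth <- runif(200, 5, 60)
  pairs <- cbind(truth + rnorm(200, 0, sigma), truth + rnorm(200, 0, sigma))
  expect_lt(abs(sel_from_duplicates(pairs) / sigma - 1), 0.25)
})

test_that("relative RMSEP per class follows the cell arithmetic", {
  obs <- c(10, 30); pred <- c(20, 20)
  out <- relative_rmsep_by_class(c(obs, obs), c(pred, pred),
                                 soc_bins = c(0, 50), covariate = rep(1, 4),
                                 cov_bins = c(0, 2))
  expect_equal(out$rmsep, 10)
  expect_equal(out$mean_obs, 20)
  expect_equal(out$relative_rmsep, 0.5)
  # perfect predictions give zero in every populated cell
  o <- runif(30, 0, 100)
  out2 <- relative_rmsep_by_class(o, o, c(0, 50, 100), runif(30),
                                  c(0, 0.5, 1))
  expect_true(all(out2$relative_rmsep[!is.na(out2$relative_rmsep)] == 0))
  # small cells are data, not errors
  out3 <- relative_rmsep_by_class(c(1, 60, 61, 62), c(1, 60, 61, 62),
                                  c(0, 50, 100), rep(0.1, 4), c(0, 1))
  expect_equal(out3$n, c(1, 3))
  expect_true(is.na(out3$relative_rmsep[1]))
  expect_error(relative_rmsep_by_class(c(1, 200), c(1, 2), c(0, 100),
                                       c(1, 1), c(0, 2)), "cover")
})

test_that("the performance report has the conventional layout and rounding", {
  lib <- generate_library(40, "mineral", seed = 41)
  m1 <- train_model(lib, "mineral", "SG1", seed = 1, grid = pls_grid(5))
  m2 <- train_model(lib, "mineral", "SG0", seed = 1, grid = pls_grid(5))
  tab <- performance_table(list(m1, m2))
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("Subset", "Treatment", "Family", "Predictor",
                             "SD", "RMSEP", "Bias", "SEP-b", "RPD", "R2",
                             "N"))
  expect_equal(tab$N, rep(length(m1$split$test), 2))
  expect_equal(tab$Predictor, c("spc", "spc"))
  # rounding convention: halves away from zero
  expect_equal(round_to(2.6164, 2), 2.62)
  expect_equal(round_to(2.615, 2), 2.62)
  expect_equal(round_to(-1.25, 1), -1.3)
  expect_equal(round_to(19.1 / 7.3, 2), 2.62)
})

test_that("the binned statistic reports sand-dependent error growth", {
  # predictions whose error SD grows with sand content: the low-SOC row of
  # the relative-RMSEP table must increase across sand bins
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 400
    sand <- runif(n, 0, 100)
    soc <- pmin(rlnorm(n, 3, 0.9), 200)
    pred <- soc + rnorm(n, 0, 1 + 4 * sand / 100)
    rel <- relative_rmsep_by_class(soc, pred, c(0, 25, 200), sand,
                                   c(0, 50, 100))
    low <- rel[rel$soc_bin == "[0,25]", ]
    if (all(!is.na(low$relative_rmsep)) &&
        low$relative_rmsep[2] > low$relative_rmsep[1])
      hits <- hits + 1L
  }
  expect_gte(hits, 80)
})
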