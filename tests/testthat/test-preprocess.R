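make_sm <- function(values, wl = NULL, mode = "reflectance") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(wl)) wl <- seq(400, by = 0.5, length.out = ncol(values))
  spectra_matrix(values, wl, mode)
}

test_that("absorbance conversion is exact and exactly invertible", {
  expect_equal(to_absorbance(make_sm(1))$values[1, 1], 0)
  expect_equal(to_absorbance(make_sm(0.1))$values[1, 1], 1)
  set.seed(1)
  R <- matrix(runif(200, 0.05, 1), 4, 50)
  m <- make_sm(R)
  back <- to_reflectance(to_absorbance(m))
  expect_lt(max(abs(back$values - R)), 1e-12)
  expect_error(to_absorbance(make_sm(matrix(0.5, 1, 5), mode = "absorbance")),
               "reflectance")
})

test_that("scan averaging flags samples by between-scan absorbance SD", {
  wl <- seq(400, by = 0.5, length.out = 30)
  mk_lib <- function(scans_list) {
    props <- sample_properties(length(scans_list), "mineral", seed = 1)
    structure(list(properties = props, wavelengths = wl,
                   scans = setNames(scans_list, props$sample_id),
                   duplicates = NULL), class = "spectral_library")
  }
  A <- matrix(0.5, 1, 30)
  same <- rbind(10^-A, 10^-A)
  # two scans differing by a constant 0.03 absorbance everywhere:
  # per-band SD = 0.03/sqrt(2) ~ 0.0212 > threshold 0.01 -> removed
  apart <- rbind(10^-A, 10^-(A + 0.03))
  res <- average_scans_qc(mk_lib(list(same, apart)), threshold = 0.01)
  expect_equal(res$qc$mean_sd, c(0, 0.03 / sqrt(2)), tolerance = 1e-12)
  expect_equal(res$qc$removed, c(FALSE, TRUE))
  expect_equal(nrow(res$spectra$values), 1)
  # infinite threshold removes nothing
  res2 <- average_scans_qc(mk_lib(list(same, apart)), threshold = Inf)
  expect_false(any(res2$qc$removed))
  # single scan passes through with a warning note
  expect_warning(res3 <- average_scans_qc(mk_lib(list(same[1, , drop = FALSE])),
                                          threshold = 0.01),
                 "single scan")
  expect_false(res3$qc$removed[1])
})

test_that("splice correction removes an additive step exactly on linear spectra", {
  wl <- seq(1000, 1200, by = 0.5)
  lin <- 0.2 + 0.001 * (wl - 1000)
  stepped <- lin + 0.02 * (wl >= 1100)
  m <- spectra_matrix(rbind(lin, stepped), wl, "absorbance")
  out <- splice_correct(m, 1100)
  expect_lt(max(abs(out$values[1, ] - lin)), 1e-12)  # continuous input unchanged
  expect_lt(max(abs(out$values[2, ] - lin)), 1e-12)  # step removed, exactly linear
  expect_error(splice_correct(m, 1000), "inside")
})

test_that("splice correction recovers the injected catalog offset", {
  lib <- generate_library(4, "mineral", seed = 6, catalog = noiseless_catalog())
  aq <- average_scans_qc(lib, Inf)
  A <- to_absorbance(aq$spectra)
  wl <- A$wavelengths
  i <- which(wl >= 1100)[1]
  raw_step <- A$values[, i] - A$values[, i - 1]
  out <- splice_correct(A, 1100)
  new_step <- out$values[, i] - out$values[, i - 1]
  # recovered offset = removed discontinuity; catalog injects 0.05
  recovered <- raw_step - new_step
  expect_true(all(abs(recovered - 0.05) < 1e-4))
})

test_that("trimming drops the artifact region with exact band arithmetic", {
  m <- make_sm(matrix(0.5, 2, 4200), wl = default_wavelengths())
  expect_equal(ncol(trim_spectra(m, 500)$values), 4000)
  expect_equal(ncol(trim_spectra(m, 400)$values), 4200)   # identity
  expect_equal(ncol(trim_spectra(m, 2000)$values), 1000)
  expect_error(trim_spectra(m, 3000), "every band")
})

test_that("Savitzky-Golay reproduces polynomials and matches local least squares", {
  wl <- seq(500, by = 0.5, length.out = 300)
  z <- seq_along(wl)
  cubic <- 1 + 0.01 * z - 2e-5 * z^2 + 1e-8 * z^3
  m <- spectra_matrix(rbind(cubic), wl, "absorbance")
  sm <- savitzky_golay(m, window = 21, polyorder = 3, deriv = 0)
  expect_lt(max(abs(sm$values[1, ] - cubic)), 1e-9)  # degree <= polyorder invariant
  lin <- 0.3 + 0.25 * z
  md <- savitzky_golay(spectra_matrix(rbind(lin), wl, "absorbance"),
                       window = 21, polyorder = 3, deriv = 1)
  expect_lt(max(abs(md$values[1, ] - 0.25)), 1e-10)  # slope per band step
  # random spectrum vs direct per-window least-squares oracle
  set.seed(42)
  x <- cumsum(rnorm(120, 0, 0.05))
  for (deriv in 0:1) {
    got <- savitzky_golay(spectra_matrix(rbind(x), wl[1:120], "absorbance"),
                          window = 5, polyorder = 2, deriv = deriv)$values[1, ]
    want <- sg_oracle(x, 5, 2, deriv)
    keep <- !is.na(want)
    expect_lt(max(abs(got[keep] - want[keep])), 1e-10)
  }
  expect_error(savitzky_golay(m, window = 100, polyorder = 3), "odd")
  expect_error(savitzky_golay(m, window = 301, polyorder = 3), "smaller")
})

test_that("SNV standardizes every spectrum and is idempotent", {
  m <- make_sm(matrix(c(1, 2, 3), 1), mode = "absorbance")
  expect_equal(snv(m)$values[1, ], c(-1, 0, 1))
  set.seed(3)
  r <- make_sm(matrix(runif(500, 0.1, 0.9), 5, 100))
  s <- snv(r)
  expect_lt(max(abs(rowMeans(s$values))), 1e-12)
  expect_lt(max(abs(apply(s$values, 1, sd) - 1)), 1e-12)
  s2 <- snv(s)
  expect_lt(max(abs(s2$values - s$values)), 1e-12)
  cm <- spectra_matrix(matrix(0.2, 2, 10),
                       seq(400, by = 1, length.out = 10), "reflectance")
  rownames(cm$values) <- c("a", "bad_sample")
  expect_error(snv(cm), "constant spectrum")
})

test_that("decimation keeps every factor-th band from the first", {
  m <- make_sm(matrix(runif(4000), 1))
  expect_equal(ncol(decimate_bands(m, 20)$values), 200)
  expect_equal(decimate_bands(m, 1)$values, m$values)
  m2 <- make_sm(matrix(runif(4001), 1))
  expect_equal(ncol(decimate_bands(m2, 20)$values), 201)
  expect_equal(decimate_bands(m, 20)$wavelengths[1:2],
               m$wavelengths[c(1, 21)])
})

test_that("continuum removal matches hand geometry and the chord oracle", {
  # linear spectrum equals its hull -> all ones
  wl <- c(500, 1000, 1500)
  lin <- make_sm(matrix(c(0.3, 0.45, 0.6), 1), wl = wl)
  expect_equal(continuum_remove(lin)$values[1, ], c(1, 1, 1))
  # one-chord geometry: hull at 1000 nm is 0.55 on the chord 0.5 -> 0.6
  tri <- make_sm(matrix(c(0.5, 0.2, 0.6), 1), wl = wl)
  expect_equal(continuum_remove(tri)$values[1, ],
               c(1, 0.2 / 0.55, 1), tolerance = 1e-12)
  # random spectra vs pairwise-chord oracle; endpoints always exactly 1
  set.seed(7)
  wl2 <- sort(runif(40, 400, 2500))
  for (rep in 1:5) {
    r <- runif(40, 0.2, 0.9)
    m <- spectra_matrix(rbind(r), wl2, "reflectance")
    got <- continuum_remove(m)$values[1, ]
    want <- r / hull_chord_oracle(wl2, r)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_equal(got[c(1, 40)], c(1, 1))
  }
})

test_that("design matrix applies the full chain with recorded provenance", {
  lib <- generate_library(30, "mineral", seed = 9)
  m <- build_design_matrix(lib, "SG1")
  expect_equal(dim(m$values), c(30, 200))
  ops <- vapply(m$provenance, `[[`, "", "op")
  expect_equal(ops, c("average_scans_qc", "to_absorbance", "splice_correct",
                      "trim", "savitzky_golay", "decimate"))
  mA <- build_design_matrix(lib, "A")
  expect_false(any(c("savitzky_golay", "snv") %in%
                     vapply(mA$provenance, `[[`, "", "op")))
  msnv <- build_design_matrix(lib, "SG1+SNV")
  # SNV precedes decimation, so rows are standardized over the full grid,
  # not over the decimated bands
  pre <- snv(savitzky_golay(trim_spectra(splice_correct(to_absorbance(
    average_scans_qc(lib, 0.01)$spectra), 1100), 500), 101, 3, 1))
  expect_lt(max(abs(rowMeans(pre$values))), 1e-12)
  expect_equal(msnv$values, decimate_bands(pre, 20)$values)
  expect_error(build_design_matrix(lib, "WAVELET"), "recipe")
})

test_that("preprocessing is shape-stable and commutes with sample subsetting", {
  lib <- generate_library(8, "mineral", seed = 11)
  m <- build_design_matrix(lib, "SG0")
  expect_equal(rownames(m$values), lib$properties$sample_id)
  sub_then <- build_design_matrix(subset_library(lib, 3:6), "SG0")
  expect_equal(sub_then$values, m$values[3:6, ], tolerance = 1e-12)
})
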