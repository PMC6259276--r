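test_that("STDEV*COEFF fields follow the hand arithmetic on a toy model", {
  # 3-column, single-channel toy: sigma_j * coef_j, filtered column -> 0
  set.seed(6)
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
           dims = c(3L, 1L, 1L), margin = 0)
  X <- matrix(rnorm(18), 6, 3)
  y <- as.numeric(X %*% c(2, 0, -1)) + rnorm(6, sd = 0.01)
  fm <- new("FieldMatrix", values = X, channels = "comsia_steric",
            grid = g, compoundIds = as.character(1:6))
  mask <- c(TRUE, FALSE, TRUE)
  m <- fitPLS(X, y, ncomp = 2, scaling = "none", mask = mask,
              channelOfColumn = rep("comsia_steric", 3))
  cf <- stdevCoeffField(m, fm, "comsia_steric")
  expect_equal(cf@values[1], sd(X[, 1]) * m@coefficients[1])
  expect_equal(cf@values[2], 0)   # filtered column contributes nothing
  expect_equal(cf@values[3], sd(X[, 3]) * m@coefficients[2])
  # negating y flips every field value
  m2 <- fitPLS(X, -y, ncomp = 2, scaling = "none", mask = mask,
               channelOfColumn = rep("comsia_steric", 3))
  cf2 <- stdevCoeffField(m2, fm, "comsia_steric")
  expect_equal(cf2@values, -cf@values, tolerance = 1e-9)
  expect_error(stdevCoeffField(m, fm, "comsia_elec"), "unknown channel")
})

test_that("contour levels implement the cumulative-contribution convention", {
  expect_equal(contourLevels(rep(0, 10)),
               c(favored = 0, disfavored = 0))
  ramp <- seq(0.1, 1, by = 0.1)
  lv <- contourLevels(ramp)
  expect_identical(lv[["disfavored"]], 0)
  expect_gt(lv[["favored"]], min(ramp))
  expect_lte(lv[["favored"]], max(ramp))
  # brute-force oracle: scan values descending until the mass target is hit
  bruteLevel <- function(v, frac) {
    v <- sort(v[v > 0], decreasing = TRUE)
    if (!length(v)) return(0)
    tot <- sum(v); acc <- 0
    for (x in v) {
      acc <- acc + x
      if (acc >= frac * tot - 1e-12) return(x)
    }
    v[length(v)]
  }
  set.seed(31)
  for (rep in 1:10) {
    v <- rnorm(200)
    lv <- contourLevels(v, favoredPct = 80, disfavoredPct = 20)
    expect_equal(lv[["favored"]], bruteLevel(v, 0.2))
    expect_equal(lv[["disfavored"]], -bruteLevel(-v, 0.2))
    # mass property: top side carries ~20% of the positive mass
    pos <- v[v > 0]
    above <- sum(pos[pos >= lv[["favored"]]])
    expect_lte(abs(above - 0.2 * sum(pos)), max(pos))
  }
})

test_that("contour fields of the fitted series behave and export", {
  run <- seriesPipeline()
  cf <- run$comfa$contours[["comfa_steric"]]
  expect_s4_class(cf, "ContourField")
  expect_gte(cf@favoredLevel, 0)
  expect_lte(cf@disfavoredLevel, 0)
  expect_equal(length(cf@values), prod(cf@grid@dims))
  # OpenDX round-trip to 1e-6
  f <- tempfile(fileext = ".dx")
  writeOpenDX(cf, f)
  back <- readOpenDX(f)
  expect_equal(back$values, cf@values, tolerance = 1e-6)
  expect_equal(back$grid@dims, cf@grid@dims)
  expect_equal(back$grid@origin, cf@grid@origin, tolerance = 1e-6)
  expect_equal(back$grid@spacing, cf@grid@spacing, tolerance = 1e-9)
})
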