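logisticProfile <- function(Tm, s, grid = seq(260, 370, by = 2),
                            noise = 0) {
  v <- 1 / (1 + exp((grid - Tm) / s))
  if (noise > 0) v <- pmin(1, pmax(0, v + rnorm(length(grid), sd = noise)))
  temperatureProfile(grid, v, "f8")
}

test_that("midpoint recovers the generator of exact logistic data", {
  p <- logisticProfile(300, 5)
  expect_equal(midpointTemperature(p), 300, tolerance = 0.1)
  ## fit and crossing agree within 1 K on a clean sigmoid
  expect_lt(abs(midpointTemperature(p, "fit") -
                midpointTemperature(p, "crossing")), 1)
  ## steep and shallow transitions alike
  for (Tm in c(270, 305, 350)) {
    for (s in c(2, 8)) {
      expect_equal(midpointTemperature(logisticProfile(Tm, s)), Tm,
                   tolerance = 0.1)
    }
  }
})

test_that("midpoint is stable under grid refinement of noise-free curves", {
  coarse <- logisticProfile(296, 6, grid = seq(260, 370, by = 10))
  fine <- logisticProfile(296, 6, grid = seq(260, 370, by = 0.5))
  expect_lt(abs(midpointTemperature(coarse) - midpointTemperature(fine)),
            0.1)
})

test_that("profiles that never cross 0.5 raise directional errors", {
  grid <- seq(260, 370, by = 5)
  expect_error(
    midpointTemperature(temperatureProfile(grid, rep(0.9, length(grid)))),
    "above grid")
  expect_error(
    midpointTemperature(temperatureProfile(grid, rep(0.1, length(grid)))),
    "below grid")
})

test_that("inflection recovers a scaled logistic and degrades gracefully", {
  grid <- seq(260, 370, by = 2)
  v <- 0.6 / (1 + exp((grid - 285) / 5)) + 0.05
  p <- temperatureProfile(grid, v, "f_beta")
  expect_equal(inflectionTemperature(p), 285, tolerance = 0.5)
  ## linear profile: no dominant inflection; warn and return mid-grid
  lin <- temperatureProfile(grid, seq(0.8, 0.2, length.out = length(grid)))
  expect_warning(ti <- inflectionTemperature(lin), "inflection")
  expect_equal(ti, 315, tolerance = 6)
  expect_error(inflectionTemperature(temperatureProfile(1:4, rep(1, 4))),
               "5 grid points")
})

test_that("heat-capacity peaks: Schottky singleton, two-Gaussian pair, monotone none", {
  grid <- seq(100, 400, by = 2)
  kB <- BOLTZMANN_KCAL
  eps <- 1.2
  schottky <- eps^2 / (kB * grid^2) /
    (1 + exp(eps / (kB * grid))) / (1 + exp(-eps / (kB * grid)))
  pk <- cvPeaks(temperatureProfile(grid, schottky))
  expect_equal(length(pk), 1L)
  Tstar <- grid[which.max(schottky)]
  expect_equal(pk, Tstar, tolerance = 2)
  ## two Gaussian bumps: both centers found, tallest first
  two <- 2 * exp(-(grid - 180)^2 / 200) + exp(-(grid - 320)^2 / 200)
  pk2 <- cvPeaks(temperatureProfile(grid, two))
  expect_equal(pk2, c(180, 320), tolerance = 2)
  ## monotone profile: no peaks
  expect_length(cvPeaks(temperatureProfile(grid, grid / 400)), 0L)
})

test_that("window convergence: identical, stationary, and drifting windows", {
  grid <- defaultLadder()
  mk <- function(v) temperatureProfile(grid, v, "f8")
  base <- 1 / (1 + exp((grid - 300) / 6))
  ## all windows identical: sigma = 0, converged
  same <- windowConvergence(list(mk(base), mk(base), mk(base), mk(base)))
  expect_equal(same$sigma, rep(0, 3))
  expect_true(same$converged)
  ## stationary noise: sigma plateaus at the noise floor, converged
  set.seed(61)
  noisy <- lapply(1:6, function(i)
    mk(pmin(1, pmax(0, base + rnorm(12, sd = 0.02)))))
  st <- windowConvergence(noisy)
  expect_true(st$converged)
  ## binomial-noise bound: with ~6000 effective snapshots the plateau sits
  ## well under 3 * sqrt(p(1-p)/6000) <= 3 * 0.5/sqrt(6000)
  p6000 <- lapply(1:6, function(i)
    mk(vapply(base, function(p) mean(rbinom(6000, 1, p)), numeric(1))))
  s6000 <- windowConvergence(p6000)$sigma
  expect_lt(max(s6000), 3 * 0.5 / sqrt(6000) * sqrt(2))  # both windows noisy
  ## monotone drift toward the last window: still decreasing, not converged
  drift <- lapply(seq(0, 0.5, by = 0.1), function(d) mk(base + d))
  dr <- windowConvergence(rev(drift))
  expect_false(dr$converged)
  expect_true(all(diff(dr$sigma) < 0))
  expect_error(windowConvergence(noisy[1:2]), "3 windows")
})

test_that("meltingSummary assembles the full pipeline on a synthetic ensemble", {
  spec <- toyModelSpec(multiplex = 1L, nSweeps = 2000L, seed = 62L)
  ens <- sampleEnsemble(spec, renderCoords = FALSE)
  w <- renderFrames(analysisWindow(ens, windowFrames = 128L, stride = 8L))
  ms <- meltingSummary(w)
  Tex <- oracleMidpoint(enumeratePartitionModel(spec))
  expect_lt(abs(ms$T8m - Tex), 8)          # small-sample smoke bound
  expect_true(ms$TiBeta >= 260 && ms$TiBeta <= 370)
  ## the beta signal decays with aggregation: its inflection cannot sit
  ## above the octamer midpoint by more than the fit scale
  expect_lt(ms$TiBeta, ms$T8m + 10)
  expect_s4_class(ms$f8Profile, "TemperatureProfile")
  expect_true(all(profileValues(ms$cvProfile) >= 0))
  ## stacked-fraction reporting at the incubation/room temperatures
  fm <- oligomerFractionMatrix(w)
  stacked <- oligomerFractionsAt(ms$weights, fm, c(298, 310))
  expect_equal(unname(rowSums(stacked)), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(stacked["310", 8]),
               profileValues(ms$f8Profile)[profileGrid(ms$f8Profile) == 310],
               tolerance = 1e-10)
})

test_that("ordinary least squares: exact lines and the descriptor regression", {
  ## hand-computable: y = 2x through the origin
  r <- linearCorrelation(c(0, 1, 2), c(0, 2, 4))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$R, 1)
  expect_equal(r$sigmaResidual, 0, tolerance = 1e-12)
  ## generator recovery at the 20 study GRAVY values: midpoints generated
  ## from a known line are recovered exactly
  g <- table1Expected()$gravy_ref
  t8m <- 14.4 * g + 315
  fit <- linearCorrelation(g, t8m)
  expect_equal(fit$slope, 14.4, tolerance = 1e-9)
  expect_equal(fit$intercept, 315, tolerance = 1e-9)
  expect_equal(fit$R, 1, tolerance = 1e-9)
  expect_error(linearCorrelation(rep(1, 5), 1:5), "zero variance")
})
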