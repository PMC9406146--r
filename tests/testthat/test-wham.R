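test_that("single-temperature WHAM degenerates to uniform weights", {
  set.seed(41)
  E <- rnorm(50, 10, 2)
  meta <- data.frame(traj = 1L, step = seq_along(E), tempIndex = 1L,
                     energy = E)
  coords <- lapply(seq_along(E), function(i) list(matrix(0, 1L, 3L)))
  ens <- ensembleSet(coords, meta, 300, boxSpec(10))
  expect_warning(wt <- solveWham(ens), "single-temperature")
  w <- snapshotWeights(wt, 300)
  expect_equal(w, rep(1 / 50, 50))
})

test_that("two-level system: reweighted averages match the closed form", {
  tl <- twoLevelEnsemble()
  wt <- solveWham(tl$ensemble, tol = 1e-14)
  for (Tt in c(120, 150, 200, 250, 300, 400)) {
    m <- sum(snapshotWeights(wt, Tt) * energies(tl$ensemble))
    expect_equal(m, tl$meanEnergy(Tt), tolerance = 1e-6)
  }
  ## occupancy of the upper level via ensembleAverage on an indicator
  up <- as.numeric(energies(tl$ensemble) > 0)
  prof <- ensembleAverage(wt, up, grid = c(150, 300))
  closed <- 1 / (1 + exp(tl$eps / (BOLTZMANN_KCAL * c(150, 300))))
  expect_equal(profileValues(prof), closed, tolerance = 1e-6)
})

test_that("weights normalize to 1 at every temperature (tight bound)", {
  set.seed(43)
  ens <- gaussianEnsemble(c(260, 300, 340), 200L)
  wt <- solveWham(ens)
  for (Tt in seq(250, 360, by = 10)) {
    w <- snapshotWeights(wt, Tt)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
  }
})

test_that("constant observables reweight to themselves; lengths are checked", {
  set.seed(44)
  ens <- gaussianEnsemble(c(280, 320), 100L)
  wt <- solveWham(ens)
  prof <- ensembleAverage(wt, rep(3.25, nFrames(ens)),
                          grid = seq(260, 340, by = 20))
  expect_equal(profileValues(prof), rep(3.25, 5), tolerance = 1e-12)
  expect_error(ensembleAverage(wt, 1:3), "one value per snapshot")
})

test_that("duplicating every snapshot changes no free energy or average", {
  set.seed(45)
  ens <- gaussianEnsemble(c(280, 320), 120L)
  wt1 <- solveWham(ens, tol = 1e-12)
  meta <- frameMeta(ens)
  meta2 <- rbind(meta, meta)
  meta2$step <- seq_len(nrow(meta2))
  coords2 <- c(ens@coords, ens@coords)
  ens2 <- ensembleSet(coords2, meta2, ladder(ens), simulationBox(ens))
  wt2 <- solveWham(ens2, tol = 1e-12)
  expect_equal(freeEnergies(wt1), freeEnergies(wt2), tolerance = 1e-8)
  v1 <- sum(snapshotWeights(wt1, 300) * energies(ens))
  v2 <- sum(snapshotWeights(wt2, 300) * energies(ens2))
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("adding a constant to all energies changes no weight", {
  set.seed(46)
  ens <- gaussianEnsemble(c(280, 320), 100L)
  wt1 <- solveWham(ens, tol = 1e-12)
  meta <- frameMeta(ens)
  meta$energy <- meta$energy + 1000
  ens2 <- ensembleSet(ens@coords, meta, ladder(ens), simulationBox(ens))
  wt2 <- solveWham(ens2, tol = 1e-12)
  for (Tt in c(270, 300, 330)) {
    expect_equal(snapshotWeights(wt1, Tt), snapshotWeights(wt2, Tt),
                 tolerance = 1e-9)
  }
})

test_that("WHAM averages agree with direct same-temperature sample means", {
  ## Gaussian-spectrum model sampled exactly at each rung; the WHAM average
  ## of a bounded observable at a well-sampled rung stays within 3 standard
  ## errors of that rung's own sample mean
  set.seed(47)
  temps <- c(270, 300, 330)
  nPer <- 600L
  ens <- gaussianEnsemble(temps, nPer)
  wt <- solveWham(ens)
  E <- energies(ens)
  obs <- as.numeric(E > 50 - 16 / (BOLTZMANN_KCAL * 300))  # bounded indicator
  for (k in seq_along(temps)) {
    own <- which(temperatureIndex(ens) == k)
    direct <- mean(obs[own])
    se <- sd(obs[own]) / sqrt(nPer)
    wham <- sum(snapshotWeights(wt, temps[k]) * obs)
    expect_lt(abs(wham - direct), 3 * se + 1e-12)
  }
})

test_that("self-consistent iteration agrees with direct likelihood optimisation", {
  set.seed(48)
  ens <- gaussianEnsemble(c(265, 290, 315, 345), 250L)
  wt <- solveWham(ens, tol = 1e-13)
  fOpt <- whamFreeEnergiesOptim(ens)
  expect_lt(max(abs(freeEnergies(wt) - fOpt)), 1e-6)
  ## and on the two-level fixture
  tl <- twoLevelEnsemble()
  wt2 <- solveWham(tl$ensemble, tol = 1e-13)
  expect_lt(max(abs(freeEnergies(wt2) - whamFreeEnergiesOptim(tl$ensemble))),
            1e-6)
})

test_that("heat capacity: Schottky peak at the closed-form maximum, Cv >= 0", {
  tl <- twoLevelEnsemble()
  wt <- solveWham(tl$ensemble, tol = 1e-13)
  grid <- seq(60, 400, by = 1)
  cv <- heatCapacity(wt, grid)
  expect_true(all(profileValues(cv) >= 0))
  ## closed form: maximise eps^2/(kB T^2) * p(1-p), p = 1/(1+exp(eps/kBT))
  kB <- BOLTZMANN_KCAL
  closed <- function(Tt) {
    p <- 1 / (1 + exp(tl$eps / (kB * Tt)))
    tl$eps^2 / (kB * Tt^2) * p * (1 - p)
  }
  Tstar <- optimize(closed, c(60, 400), maximum = TRUE)$maximum
  Tpeak <- grid[which.max(profileValues(cv))]
  expect_lt(abs(Tpeak - Tstar), 2)
  ## zero-variance energies give identically zero Cv
  E0 <- rep(5, 40)
  meta <- data.frame(traj = 1L, step = 1:40,
                     tempIndex = rep(1:2, each = 20L), energy = E0)
  coords <- lapply(1:40, function(i) list(matrix(0, 1L, 3L)))
  ens0 <- ensembleSet(coords, meta, c(280, 320), boxSpec(10))
  cv0 <- heatCapacity(solveWham(ens0), c(280, 300, 320))
  expect_equal(profileValues(cv0), rep(0, 3), tolerance = 1e-20)
})
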