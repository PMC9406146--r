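test_that("two-chain partition model matches the hand-derived closed form", {
  ## n = 2: states are {1,2} together or apart;
  ## f_2(T) = e^{beta*eps} / (e^{beta*eps} + nu)
  spec <- toyModelSpec(nChains = 2L, epsilon = 0.8, nu = 20)
  o <- enumeratePartitionModel(spec)
  for (Tt in c(200, 280, 310, 400)) {
    beta <- 1 / (BOLTZMANN_KCAL * Tt)
    closed <- exp(beta * 0.8) / (exp(beta * 0.8) + 20)
    expect_equal(oracleFractions(o, Tt)[2], closed, tolerance = 1e-12)
    expect_equal(sum(oracleFractions(o, Tt)), 1, tolerance = 1e-12)
  }
})

test_that("oracle limits: ground state at low T, pure counting at epsilon = 0", {
  spec <- toyModelSpec(nChains = 6L, epsilon = 0.7, nu = 30)
  o <- enumeratePartitionModel(spec)
  expect_gt(oracleFractions(o, 20)[6], 0.999)          # T -> 0: single n-mer
  ## f_n decreases monotonically with T
  f8 <- vapply(seq(100, 600, by = 25),
               function(Tt) oracleFractions(o, Tt)[6], numeric(1))
  expect_true(all(diff(f8) < 0))
  ## epsilon -> 0 limit: weights nu^{|P|} only, temperature-independent;
  ## checked against a direct combinatorial sum over partitions
  specFlat <- toyModelSpec(nChains = 4L, epsilon = 1e-12, nu = 3)
  oFlat <- enumeratePartitionModel(specFlat)
  parts <- aggremelt:::setPartitionsRG(4L)
  w <- vapply(parts, function(m) 3^length(unique(m)), numeric(1))
  fmFlat <- vapply(1:4, function(m) {
    sum(w * vapply(parts, function(mm) {
      sizes <- tabulate(mm)
      m * sum(sizes == m) / 4
    }, numeric(1))) / sum(w)
  }, numeric(1))
  expect_equal(unname(oracleFractions(oFlat, 260)), fmFlat, tolerance = 1e-9)
  expect_equal(oracleFractions(oFlat, 260), oracleFractions(oFlat, 370),
               tolerance = 1e-9)
})

test_that("oracle midpoint brackets the 0.5 crossing of f_n", {
  spec <- toyModelSpec()           # defaults: 8 chains, eps 0.65, nu 50
  o <- enumeratePartitionModel(spec)
  Tm <- oracleMidpoint(o)
  expect_gt(oracleFractions(o, Tm - 5)[8], 0.5)
  expect_lt(oracleFractions(o, Tm + 5)[8], 0.5)
  expect_equal(oracleFractions(o, Tm)[8], 0.5, tolerance = 1e-4)
})

test_that("Markov chain over partitions is in detailed balance (n = 3 oracle)", {
  ## stationary distribution over the 5 partitions of 3 chains vs exact
  ## weights, chi-squared-style 3-sigma bound per state
  set.seed(81)
  eps <- 0.65; nu <- 5; Tt <- 300
  beta <- 1 / (BOLTZMANN_KCAL * Tt)
  key <- function(b) paste(sort(vapply(b, function(x)
    paste(sort(x), collapse = ","), character(1))), collapse = "|")
  parts <- aggremelt:::setPartitionsRG(3L)
  keys <- vapply(parts, function(m) key(split(1:3, m)), character(1))
  exact <- vapply(parts, function(m)
    exp(aggremelt:::stateLogWeight(split(1:3, m), beta, eps, nu)),
    numeric(1))
  exact <- exact / sum(exact)
  st <- as.list(1:3)
  nSteps <- 60000L
  counts <- setNames(numeric(5), keys)
  for (i in seq_len(nSteps)) {
    st <- aggremelt:::mcmcMove(st, beta, eps, nu, 3L)
    k <- key(st)
    counts[k] <- counts[k] + 1
  }
  obs <- counts / nSteps
  ## allow 3 sigma with a crude effective-sample deflation for
  ## autocorrelation (conservative factor 10)
  for (j in 1:5) {
    se <- sqrt(exact[j] * (1 - exact[j]) / (nSteps / 10))
    expect_lt(abs(obs[j] - exact[j]), 3 * se + 0.005)
  }
})

test_that("sampled rung occupancies of f_n track the oracle", {
  spec <- toyModelSpec(multiplex = 1L, nSweeps = 1500L, seed = 82L)
  ens <- sampleEnsemble(spec, renderCoords = FALSE)
  o <- enumeratePartitionModel(spec)
  parts <- attr(ens, "partitions")
  f8 <- vapply(parts, function(st)
    sum(lengths(st) == 8) * 8 / 8, numeric(1))
  meta <- frameMeta(ens)
  equil <- meta$step > max(meta$step) / 3
  ## pooled standard error with a generous autocorrelation deflation
  for (k in c(2L, 6L, 10L)) {
    own <- which(equil & meta$tempIndex == k)
    p_exact <- oracleFractions(o, ladder(ens)[k])[8]
    se <- sqrt(p_exact * (1 - p_exact) / (length(own) / 10)) + 0.02
    expect_lt(abs(mean(f8[own]) - p_exact), 3 * se)
  }
})

test_that("the generator is bit-reproducible under its seed", {
  spec <- toyModelSpec(nChains = 4L, multiplex = 1L, nSweeps = 60L,
                       seed = 83L)
  e1 <- sampleEnsemble(spec)
  e2 <- sampleEnsemble(spec)
  expect_identical(frameMeta(e1), frameMeta(e2))
  expect_identical(e1@coords, e2@coords)
  ## a different seed gives a different stream
  e3 <- sampleEnsemble(toyModelSpec(nChains = 4L, multiplex = 1L,
                                    nSweeps = 60L, seed = 84L))
  expect_false(identical(frameMeta(e1)$energy, frameMeta(e3)$energy))
})

test_that("rendered frames encode the generating partition exactly", {
  spec <- toyModelSpec(multiplex = 1L, nSweeps = 150L, seed = 85L)
  ens <- sampleEnsemble(spec)
  parts <- attr(ens, "partitions")
  for (i in seq_len(nFrames(ens))) {
    got <- identifyOligomers(getFrame(ens, i), simulationBox(ens))
    expect_equal(canonicalBlocks(got@blocks), canonicalBlocks(parts[[i]]))
  }
  ## an over-packed box fails with a helpful error
  tiny <- toyModelSpec(multiplex = 1L, nSweeps = 20L, seed = 86L,
                       box = boxSpec(25))
  expect_error(sampleEnsemble(tiny), "too small")
})

test_that("reference geometries satisfy their analytic constraints", {
  h <- buildReferenceGeometry("ideal-helix", 12)
  bonds <- sqrt(rowSums((h[-1, ] - h[-12, ])^2))
  expect_true(all(abs(bonds - 3.8) < 0.1))
  s <- buildReferenceGeometry("extended-strand", 12)
  e2e <- sqrt(sum((s[12, ] - s[1, ])^2))
  expect_gt(e2e, 3.4 * 11)
  expect_lt(e2e, 3.6 * 11)
  expect_true(all(abs(sqrt(rowSums((s[-1, ] - s[-12, ])^2)) - 3.8) < 1e-9))
  set.seed(87)
  cl <- buildReferenceGeometry("random-coil", 15)
  expect_true(all(abs(sqrt(rowSums((cl[-1, ] - cl[-15, ])^2)) - 3.8) < 1e-9))
  D <- as.matrix(dist(cl))
  nonbonded <- D[abs(row(D) - col(D)) >= 2]
  expect_true(all(nonbonded >= 4.0 - 1e-9))
})

test_that("WHAM free energies reproduce the oracle's partition-function ratios", {
  ## f_k from the sampled ensemble vs exact -log(Z_k/Z_1) from enumeration
  spec <- toyModelSpec(multiplex = 1L, nSweeps = 2000L, seed = 88L)
  ens <- sampleEnsemble(spec, renderCoords = FALSE)
  meta <- frameMeta(ens)
  keep <- which(meta$step > max(meta$step) / 3)
  ens2 <- ensembleSet(ens@coords[keep], meta[keep, ], ladder(ens),
                      simulationBox(ens))
  wt <- solveWham(ens2)
  o <- enumeratePartitionModel(spec)
  ## exact dimensionless free energy of rung k up to the shared gauge:
  ## -log sum_P nu^{|P|} exp(-beta_k E_P), with the WHAM sign convention
  lz <- vapply(ladder(ens), function(Tt) {
    lw <- o@nBlocksP * log(o@nu) - o@energiesP / (BOLTZMANN_KCAL * Tt)
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }, numeric(1))
  exact <- -(lz - lz[1])
  est <- freeEnergies(wt)
  expect_lt(max(abs(est - exact)), 0.35)   # MC error at this sample size
})
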