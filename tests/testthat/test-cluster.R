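test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(71)
  perms5 <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms5 <- perms5[apply(perms5, 1, function(p) length(unique(p)) == 5), ]
  for (i in 1:20) {
    cost <- matrix(runif(25), 5, 5)
    got <- aggremelt:::solveAssignment(cost)
    costs <- apply(perms5, 1, function(p) sum(cost[cbind(1:5, p)]))
    expect_equal(sum(cost[cbind(1:5, got)]), min(costs), tolerance = 1e-12)
  }
})

test_that("frame distance: rigid copies, chain swaps, and a hand Kabsch case", {
  set.seed(72)
  frame <- randomFrame(3L, nRes = 5L, side = 30)
  moved <- rigidMove(frame)
  expect_equal(frameDistance(frame, moved), 0, tolerance = 1e-8)
  expect_equal(frameDistance(frame, moved, "fixed-labels"), 0,
               tolerance = 1e-8)
  ## swapping two chains: fixed-labels sees a difference, best-permutation
  ## does not
  swapped <- frame[c(2, 1, 3)]
  expect_gt(frameDistance(frame, swapped, "fixed-labels"), 1)
  expect_equal(frameDistance(frame, swapped, "best-permutation"), 0,
               tolerance = 1e-8)
  ## two-point, one-chain toy case, checked by hand: segments of length 2
  ## and 4 centered at the origin cannot be superposed; each endpoint is
  ## off by 1, so RMSD = 1
  a <- list(matrix(c(-1, 0, 0, 1, 0, 0), 2L, 3L, byrow = TRUE))
  b <- list(matrix(c(-2, 0, 0, 2, 0, 0), 2L, 3L, byrow = TRUE))
  expect_equal(frameDistance(a, b), 1, tolerance = 1e-10)
  expect_error(frameDistance(a, list(matrix(0, 3, 3))), "dimensions")
})

test_that("best-permutation distance is a symmetric pseudo-metric", {
  set.seed(73)
  for (i in 1:5) {
    fa <- randomFrame(4L, nRes = 4L, side = 25)
    fb <- randomFrame(4L, nRes = 4L, side = 25)
    dab <- frameDistance(fa, fb)
    dba <- frameDistance(fb, fa)
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_gte(dab, 0)
    ## zero on permutation-equivalent frames
    expect_equal(frameDistance(fa, rigidMove(fa[sample(4)])), 0,
                 tolerance = 1e-8)
  }
})

test_that("Ward clustering recovers five planted conformation families", {
  set.seed(74)
  pf <- plantedFamilies()
  cs <- wardCluster(pf$frames, k = 5L)
  ## perfect recovery up to label permutation
  tab <- table(clusterAssignments(cs), pf$labels)
  expect_equal(sum(tab > 0), 5L)
  expect_equal(sum(clusterProbabilities(cs)), 1, tolerance = 1e-12)
  ## uniform weights: ranking by cluster size (all equal here), and each
  ## representative belongs to its own family
  for (cl in 1:5) {
    members <- cs@frameIds[clusterAssignments(cs) == cl]
    expect_true(representatives(cs)[cl] %in% members)
    expect_equal(length(unique(pf$labels[members])), 1L)
  }
})

test_that("clustering edge cases: k = n singletons, weighted ranking", {
  set.seed(75)
  pf <- plantedFamilies(nPerFamily = 2L)
  frames <- pf$frames[1:6]
  cs <- wardCluster(frames, k = 6L)
  expect_equal(sort(representatives(cs)), 1:6)
  expect_equal(clusterProbabilities(cs), rep(1 / 6, 6))
  expect_error(wardCluster(frames, k = 10L), "fewer frames")
  ## a heavily weighted family must rank first
  w <- rep(1, 10); w[pf$labels == 3] <- 50
  cs2 <- wardCluster(pf$frames, weights = w, k = 5L)
  top <- cs2@frameIds[clusterAssignments(cs2) == 1L]
  expect_true(all(pf$labels[top] == 3L))
  expect_gt(clusterProbabilities(cs2)[1], 0.8)
})

test_that("medoid representative: singleton, collinear triple, tie-break", {
  a <- list(matrix(c(0, 0, 0, 3.8, 0, 0), 2L, 3L, byrow = TRUE))
  expect_equal(clusterRepresentative(list(a)), 1L)
  ## three frames on a line in conformation space: stretched segments of
  ## length 2, 4, 6; the middle one minimises the mean squared distance
  mk <- function(L) list(matrix(c(-L / 2, 0, 0, L / 2, 0, 0), 2L, 3L,
                                byrow = TRUE))
  expect_equal(clusterRepresentative(list(mk(2), mk(4), mk(6))), 2L)
  ## exact tie: two identical frames; lowest index wins
  expect_equal(clusterRepresentative(list(mk(2), mk(2))), 1L)
})

test_that("RMSF: rigid copies give zero; a displaced residue shows the peak", {
  set.seed(76)
  base <- buildReferenceGeometry("ideal-helix", 8)
  frames <- lapply(1:6, function(i)
    rigidMove(list(base), angle = runif(1, 0, 6), shift = runif(3, -9, 9)))
  r0 <- rmsfPerResidue(frames)
  expect_equal(r0, rep(0, 8), tolerance = 1e-6)
  ## displace residue 5 by 2 A along the local normal in half the copies:
  ## two-point mixture with means +-1 from the mean structure -> RMSF ~ 1
  shifted <- base
  shifted[5, ] <- shifted[5, ] + c(2, 0, 0)
  frames2 <- c(lapply(1:4, function(i) list(base)),
               lapply(1:4, function(i) list(shifted)))
  r1 <- rmsfPerResidue(frames2)
  expect_equal(which.max(r1), 5L)
  ## numeric oracle: the un-superposed per-residue SD (frames are already
  ## aligned) upper-bounds the post-superposition RMSF, which must still
  ## carry most of the displacement at residue 5 and dominate the rest
  stack <- vapply(c(lapply(1:4, function(i) base),
                    lapply(1:4, function(i) shifted)),
                  function(x) x[5, ], numeric(3))
  direct <- sqrt(mean(colSums((stack - rowMeans(stack))^2)))
  expect_lte(r1[5], direct + 1e-9)
  expect_gt(r1[5], 0.6 * direct)
  expect_gt(r1[5], 3 * median(r1[-5]))
})
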