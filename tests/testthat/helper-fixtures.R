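## Shared fixtures and independent oracles for the test suite.

## Reference descriptor values for the 20-peptide study set, at printed
## precision (GRAVY to 3 decimals, box side for 8 chains to 0.1 A).
table1Expected <- function() {
  tab <- readPeptideTable(system.file("extdata", "peptides.tsv",
                                      package = "aggremelt"))
  tab$gravy_ref <- c(-0.233, -0.233, 0.450, 1.800, 1.800, 0.933, 1.800,
                     1.800, 2.100, 0.383, 0.700, -2.743, -1.056, -1.055,
                     0.374, 0.160, 0.050, -0.853, -0.746, -0.840)
  tab$box_ref <- c(146.7, 146.7, 139.5, 173.0, 136.2, 184.6, 198.0, 198.0,
                   212.5, 131.9, 215.0, 223.1, 279.3, 316.0, 278.7, 285.8,
                   304.5, 162.1, 152.3, 155.7)
  tab
}

## random multi-chain frame: chains of nRes residues scattered in the box,
## each chain a compact random cloud, chain centers uniform
randomFrame <- function(nChains, nRes = 4L, side = 60) {
  lapply(seq_len(nChains), function(i) {
    ctr <- runif(3) * side
    sweep(matrix(rnorm(nRes * 3, sd = 1.5), nRes, 3L), 2L, ctr, "+")
  })
}

## brute-force connected components of the association graph (independent
## of the iterative growth in identifyOligomers): repeated closure over the
## adjacency matrix
bruteForceComponents <- function(frame, box, cutoff = 7.0) {
  n <- length(frame)
  adj <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chainsAssociated(frame[[i]], frame[[j]], box, cutoff)) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  reach <- adj
  for (k in seq_len(n)) {            # Floyd-Warshall style closure
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  unname(lapply(split(seq_len(n), comp), sort))
}

canonicalBlocks <- function(blocks) {
  sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
              character(1)))
}

## two-level system sampled at exact Boltzmann proportions at two
## temperatures (T and T/2), suitable for closed-form WHAM checks:
## energies 0 and eps = kB*T1*log(3), so the level occupancies are 3:1 at
## T1 and 9:1 at T1/2
twoLevelEnsemble <- function(T1 = 300, n1 = 1000L, n2 = 1000L) {
  kB <- BOLTZMANN_KCAL
  eps <- kB * T1 * log(3)
  stopifnot(n1 %% 4 == 0, n2 %% 10 == 0)
  E <- c(rep(0, 3 * n1 / 4), rep(eps, n1 / 4),
         rep(0, 9 * n2 / 10), rep(eps, n2 / 10))
  rung <- c(rep(2L, n1), rep(1L, n2))     # ladder is (T1/2, T1)
  meta <- data.frame(traj = 1L, step = seq_along(E), tempIndex = rung,
                     energy = E)
  coords <- lapply(seq_along(E), function(i) list(matrix(0, 1L, 3L)))
  list(ensemble = ensembleSet(coords, meta, c(T1 / 2, T1), boxSpec(10)),
       eps = eps,
       meanEnergy = function(Tt) eps / (1 + exp(eps / (kB * Tt))))
}

## Gaussian-spectrum model: density of states g(E) ~ exp(-(E-E0)^2/(2s^2)),
## so samples at inverse temperature beta are N(E0 - beta*s^2, s^2) --
## exact sampling at each rung for reweighting-consistency checks
gaussianEnsemble <- function(temps, nPer, E0 = 50, s = 4,
                             kB = BOLTZMANN_KCAL) {
  E <- unlist(lapply(seq_along(temps), function(k) {
    rnorm(nPer, mean = E0 - s^2 / (kB * temps[k]), sd = s)
  }))
  meta <- data.frame(traj = 1L, step = seq_along(E),
                     tempIndex = rep(seq_along(temps), each = nPer),
                     energy = E)
  coords <- lapply(seq_along(E), function(i) list(matrix(0, 1L, 3L)))
  ensembleSet(coords, meta, temps, boxSpec(10))
}

## small helper: place a chain's coordinates at a center
shiftChain <- function(xyz, ctr) sweep(xyz, 2L, ctr, "+")

rigidMove <- function(frame, angle = 0.7, shift = c(5, -3, 11)) {
  R <- rbind(c(cos(angle), -sin(angle), 0),
             c(sin(angle), cos(angle), 0),
             c(0, 0, 1))
  lapply(frame, function(x) sweep(x %*% t(R), 2L, shift, "+"))
}

## five well-separated conformation families rendered as rigid templates
## plus small jitter
plantedFamilies <- function(nPerFamily = 8L, jitter = 0.05) {
  templates <- lapply(1:5, function(k) {
    set.seed(100 + k)
    randomFrame(2L, nRes = 6L, side = 15)
  })
  frames <- list()
  labels <- integer(0)
  for (k in 1:5) {
    for (r in seq_len(nPerFamily)) {
      fr <- lapply(templates[[k]], function(x)
        x + matrix(rnorm(length(x), sd = jitter), nrow(x), 3L))
      frames[[length(frames) + 1L]] <- rigidMove(fr, angle = runif(1, 0, 6),
                                                 shift = runif(3, -20, 20))
      labels <- c(labels, k)
    }
  }
  list(frames = frames, labels = labels)
}
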