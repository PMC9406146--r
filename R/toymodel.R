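## Synthetic replica-exchange ensembles with exactly known aggregation
## thermodynamics.
##
## The model is a Hamiltonian over set partitions P of n chains:
##   E(P)    = -epsilon * sum over blocks b of choose(|b|, 2)
##   w(P, T) =  nu^{|P|} * exp(-E(P) / (kB T))
## nu > 0 is a translational-entropy factor per independent oligomer (the
## available volume per cluster in units of a reference volume).  With
## epsilon > 0 the ground state is the single n-mer and the fraction of
## chains in the n-mer decreases monotonically with temperature, giving a
## tunable association transition.  Because n <= 10, the partition sum is
## exactly enumerable (Bell(8) = 4140), so every reweighted profile has a
## closed-form oracle.  Sampled partitions are rendered into Calpha
## coordinates so the geometric analysis path (contact criterion, secondary
## structure) is exercised end to end.

#' Construct a synthetic-model specification
#'
#' @param nChains chains (default 8, <= 10).
#' @param residuesPerChain residues per chain (default 6).
#' @param epsilon contact energy per associated pair, kcal/mol (default
#'   0.65; with the default nu this puts the octamer midpoint near 311 K,
#'   mid-ladder and close to the 310 K incubation temperature).
#' @param nu translational-entropy factor per block (default 50).
#' @param ladder temperature ladder (default [defaultLadder()]).
#' @param nSweeps Monte Carlo sweeps per replica (default 4000).
#' @param exchangeInterval sweeps between exchange attempts; snapshots are
#'   recorded at each exchange point (default 10).
#' @param multiplex independent replica sets per ladder temperature
#'   (default 4, i.e. 48 trajectories on the 12-rung ladder).
#' @param seed RNG seed (default 1).
#' @param box simulation box (default 100 Angstrom cubic periodic).
#' @param kB Boltzmann constant (default [BOLTZMANN_KCAL]).
#' @return A [ToyModelSpec-class].
#' @export
toyModelSpec <- function(nChains = 8L, residuesPerChain = 6L, epsilon = 0.65,
                         nu = 50, ladder = defaultLadder(),
                         nSweeps = 4000L, exchangeInterval = 10L,
                         multiplex = 4L, seed = 1L, box = boxSpec(100),
                         kB = BOLTZMANN_KCAL) {
  new("ToyModelSpec", nChains = as.integer(nChains),
      residuesPerChain = as.integer(residuesPerChain),
      epsilon = epsilon, nu = nu, ladder = as.numeric(ladder),
      nSweeps = as.integer(nSweeps),
      exchangeInterval = as.integer(exchangeInterval),
      multiplex = as.integer(multiplex), seed = as.integer(seed),
      box = box, kB = kB)
}

## all set partitions of 1..n as membership vectors (restricted growth)
setPartitionsRG <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, maxb) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

partitionEnergy <- function(sizes, epsilon) {
  -epsilon * sum(choose(sizes, 2))
}

#' Enumerate the chain-partition model exactly
#'
#' Builds a [PartitionOracle-class] over all set partitions of the chains,
#' from which exact f_m(T) profiles, energy moments, heat capacity and the
#' association midpoint follow at any temperature.
#'
#' @param spec a [ToyModelSpec-class] (nChains <= 10).
#' @return A [PartitionOracle-class].
#' @export
enumeratePartitionModel <- function(spec) {
  n <- spec@nChains
  if (n > 10L) stop("nChains too large for exact enumeration")
  parts <- setPartitionsRG(n)
  P <- length(parts)
  energiesP <- numeric(P)
  nBlocksP <- integer(P)
  fmP <- matrix(0, P, n)
  for (p in seq_len(P)) {
    sizes <- tabulate(parts[[p]])
    sizes <- sizes[sizes > 0L]
    energiesP[p] <- partitionEnergy(sizes, spec@epsilon)
    nBlocksP[p] <- length(sizes)
    cnt <- tabulate(sizes, nbins = n)
    fmP[p, ] <- seq_len(n) * cnt / n
  }
  new("PartitionOracle", nChains = n, epsilon = spec@epsilon, nu = spec@nu,
      energiesP = energiesP, nBlocksP = nBlocksP, fmP = fmP, kB = spec@kB)
}

## normalized partition weights at temperature T
oracleWeights <- function(oracle, temperature) {
  lw <- oracle@nBlocksP * log(oracle@nu) -
    oracle@energiesP / (oracle@kB * temperature)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Exact oligomer-size fractions at a temperature
#'
#' @param oracle a [PartitionOracle-class].
#' @param temperature Kelvin (scalar).
#' @return numeric vector f_m, m = 1..nChains, summing to 1.
#' @export
oracleFractions <- function(oracle, temperature) {
  w <- oracleWeights(oracle, temperature)
  drop(crossprod(oracle@fmP, w))
}

#' Exact temperature profile of f_m
#'
#' @param oracle a [PartitionOracle-class].
#' @param grid temperature grid (K).
#' @param m oligomer size (default nChains).
#' @return A [TemperatureProfile-class].
#' @export
oracleProfile <- function(oracle, grid, m = oracle@nChains) {
  vals <- vapply(grid, function(Tt) oracleFractions(oracle, Tt)[m],
                 numeric(1))
  temperatureProfile(grid, vals, sprintf("exact f%d", m))
}

#' Exact heat capacity of the partition model
#'
#' @param oracle a [PartitionOracle-class].
#' @param grid temperature grid (K).
#' @return A [TemperatureProfile-class] of
#'   (<E^2> - <E>^2) / (kB T^2) per system.
#' @export
oracleHeatCapacity <- function(oracle, grid) {
  vals <- vapply(grid, function(Tt) {
    w <- oracleWeights(oracle, Tt)
    m1 <- sum(w * oracle@energiesP)
    (sum(w * oracle@energiesP^2) - m1^2) / (oracle@kB * Tt^2)
  }, numeric(1))
  temperatureProfile(grid, vals, "exact Cv")
}

#' Exact association midpoint of the partition model
#'
#' Temperature at which the fraction of chains in the full n-mer crosses
#' 0.5, found by root bracketing (f_n is monotone decreasing for
#' epsilon > 0).
#'
#' @param oracle a [PartitionOracle-class].
#' @param interval search bracket in Kelvin (default c(10, 2000)).
#' @return Midpoint temperature in Kelvin.
#' @export
oracleMidpoint <- function(oracle, interval = c(10, 2000)) {
  g <- function(Tt) oracleFractions(oracle, Tt)[oracle@nChains] - 0.5
  stats::uniroot(g, interval, tol = 1e-6)$root
}

## ---- Monte Carlo over partitions -------------------------------------

## state: list of integer blocks.  log-weight up to a constant:
##   lw(P) = |P| log(nu) + beta * epsilon * sum choose(|b|, 2)
stateLogWeight <- function(blocks, beta, epsilon, nu) {
  sizes <- lengths(blocks)
  length(blocks) * log(nu) + beta * epsilon * sum(choose(sizes, 2))
}

## one elementary Metropolis move; returns updated blocks
## move mix: 1/2 single-chain reassignment, 1/4 merge, 1/4 split, each with
## the exact Hastings correction for its proposal asymmetry.  The log-weight
## change is evaluated in O(1): removing a chain from a block of size s
## changes sum choose(|b|, 2) by -(s - 1), inserting into a block of size t
## by +t, and merging/splitting blocks of sizes s1, s2 by +-s1*s2.
mcmcMove <- function(blocks, beta, epsilon, nu, nChains) {
  r <- runif(1)
  p <- length(blocks)
  sizes <- lengths(blocks)
  be <- beta * epsilon
  lnu <- log(nu)
  if (r < 0.5) {
    ## single-chain move
    chain <- sample.int(nChains, 1L)
    bi <- 1L
    while (!any(blocks[[bi]] == chain)) bi <- bi + 1L
    s_bi <- sizes[bi]
    nd <- (p - 1L) + (s_bi > 1L)
    if (nd == 0L) return(blocks)
    dest <- if (nd == 1L) 1L else sample.int(nd, 1L)
    toNew <- dest > p - 1L
    dC <- -(s_bi - 1L)                       # leave the old block
    dp <- (s_bi == 1L) * -1L                 # old block vanished?
    if (toNew) {
      dp <- dp + 1L
      s_dest <- 0L
    } else {
      tb <- if (dest < bi) dest else dest + 1L
      s_dest <- sizes[tb]
      dC <- dC + s_dest
    }
    ## destination count of the reverse move
    p2 <- p + dp
    s_bi2 <- s_dest + 1L
    nd2 <- (p2 - 1L) + (s_bi2 > 1L)
    dlw <- dp * lnu + be * dC
    if (log(runif(1)) >= dlw + log(nd) - log(nd2)) return(blocks)
    newBlocks <- blocks
    newBlocks[[bi]] <- newBlocks[[bi]][newBlocks[[bi]] != chain]
    if (toNew) newBlocks[[p + 1L]] <- chain
    else newBlocks[[tb]] <- c(newBlocks[[tb]], chain)
    return(newBlocks[lengths(newBlocks) > 0L])
  }
  if (r < 0.75) {
    ## merge two blocks
    if (p < 2L) return(blocks)
    pair <- sample.int(p, 2L)
    s1 <- sizes[pair[1L]]; s2 <- sizes[pair[2L]]
    s <- s1 + s2
    m2p <- sum(sizes >= 2L) - (s1 >= 2L) - (s2 >= 2L) + 1L
    dlw <- -lnu + be * (s1 * s2)
    lograt <- log(p * (p - 1L) / 2) - log(m2p) - log(2^(s - 1L) - 1)
    if (log(runif(1)) >= dlw + lograt) return(blocks)
    merged <- c(blocks[[pair[1L]]], blocks[[pair[2L]]])
    return(c(blocks[-pair], list(merged)))
  }
  ## split one block into two non-empty parts
  big <- which(sizes >= 2L)
  m2 <- length(big)
  if (m2 == 0L) return(blocks)
  bi <- big[if (m2 == 1L) 1L else sample.int(m2, 1L)]
  b <- blocks[[bi]]
  s <- length(b)
  mask <- sample.int(2L^(s - 1L) - 1L, 1L)     # first element pinned to A
  bits <- as.integer(intToBits(mask))[seq_len(s - 1L)]
  sideB <- b[-1L][bits == 1L]
  s2 <- length(sideB)
  dlw <- lnu - be * (s2 * (s - s2))
  lograt <- log(m2) + log(2^(s - 1L) - 1) - log(p * (p + 1L) / 2)
  if (log(runif(1)) >= dlw + lograt) return(blocks)
  sideA <- b[-1L][bits == 0L]
  c(blocks[-bi], list(c(b[1L], sideA), sideB))
}

## ---- coordinate rendering --------------------------------------------

randomRotation <- function() {
  repeat {
    M <- matrix(rnorm(9), 3L)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    if (abs(det(Q) - 1) < 1e-8) return(Q)
  }
}

## planar zigzag strand: 3.5 A advance per residue, 3.8 A virtual bonds
extendedStrand <- function(nRes, advance = 3.5, bond = 3.8) {
  pleat <- sqrt(bond^2 - advance^2) / 2
  cbind(x = (seq_len(nRes) - 1) * advance,
        y = rep_len(c(pleat, -pleat), nRes),
        z = 0)
}

## self-avoiding random coil with fixed virtual-bond length
randomCoil <- function(nRes, bond = 3.8, minSep = 4.0, maxTry = 200L) {
  repeat {
    xyz <- matrix(0, nRes, 3L)
    ok <- TRUE
    for (i in 2:nRes) {
      placed <- FALSE
      for (tr in seq_len(maxTry)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1L, ] + bond * u
        if (i > 2L) {
          d2 <- rowSums(sweep(xyz[1:(i - 2L), , drop = FALSE], 2L, cand)^2)
          if (min(d2) < minSep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
}

#' Analytic reference Calpha geometries
#'
#' Single-chain fixtures: an ideal Calpha-trace helix (rise 1.5 Angstrom per
#' residue, radius 2.3 Angstrom, 100 degrees per residue), an ideally
#' extended strand (3.8 Angstrom virtual bonds, alternating pleat, 3.5
#' Angstrom advance per residue) or a self-avoiding random coil (3.8
#' Angstrom bonds, non-bonded separation >= 4 Angstrom).
#'
#' @param kind one of "ideal-helix", "extended-strand", "random-coil".
#' @param nRes number of residues (>= 3).
#' @return residues x 3 coordinate matrix.
#' @seealso [idealSheetFrame()] for a multi-strand in-register sheet.
#' @export
buildReferenceGeometry <- function(kind = c("ideal-helix", "extended-strand",
                                            "random-coil"), nRes) {
  kind <- match.arg(kind)
  if (nRes < 3L) stop("nRes must be >= 3")
  switch(kind,
    "ideal-helix" = {
      ## right-handed winding: virtual dihedral +50 degrees
      i <- seq_len(nRes) - 1
      th <- -i * 100 * pi / 180
      cbind(x = 2.3 * cos(th), y = 2.3 * sin(th), z = 1.5 * i)
    },
    "extended-strand" = extendedStrand(nRes),
    "random-coil" = randomCoil(nRes))
}

#' In-register sheet of parallel extended strands
#'
#' Frame (list of chains) of \code{nStrands} parallel, in-register extended
#' strands stacked \code{spacing} Angstrom apart, so interior residues
#' satisfy the beta criteria of [assignStates()] and adjacent strands
#' satisfy the association criterion.
#'
#' @param nRes residues per strand.
#' @param nStrands number of strands (default 2).
#' @param spacing inter-strand spacing in Angstrom (default 4.8).
#' @return list of residues x 3 coordinate matrices.
#' @export
idealSheetFrame <- function(nRes, nStrands = 2L, spacing = 4.8) {
  strand <- extendedStrand(nRes)
  lapply(seq_len(nStrands), function(s) {
    sweep(strand, 2L, c(0, 0, (s - 1) * spacing), "+")
  })
}

## render one partition into chain coordinates inside the box; blocks are
## strand bundles, singleton chains are coils; all inter-block Calpha
## distances exceed cutoff + margin by bounding-sphere separation
renderPartition <- function(blocks, nChains, nRes, box, cutoff = 7.0,
                            margin = 2.0, maxTry = 200L) {
  side <- box@side
  pieces <- vector("list", length(blocks))
  radii <- numeric(length(blocks))
  for (bi in seq_along(blocks)) {
    m <- length(blocks[[bi]])
    local <- if (m == 1L) {
      list(randomCoil(nRes))
    } else {
      sheet <- idealSheetFrame(nRes, m)
      sheet
    }
    all_xyz <- do.call(rbind, local)
    ctr <- colMeans(all_xyz)
    local <- lapply(local, function(x) sweep(x, 2L, ctr))
    R <- randomRotation()
    local <- lapply(local, function(x) x %*% t(R))
    pieces[[bi]] <- local
    radii[bi] <- sqrt(max(rowSums(do.call(rbind, local)^2)))
  }
  centers <- matrix(0, length(blocks), 3L)
  for (bi in seq_along(blocks)) {
    placed <- FALSE
    for (tr in seq_len(maxTry)) {
      cand <- runif(3) * side
      ok <- TRUE
      if (bi > 1L) {
        for (bj in 1:(bi - 1L)) {
          dd <- minImageDistance(cand, centers[bj, ], box)
          if (dd <= radii[bi] + radii[bj] + cutoff + margin) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) { centers[bi, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("box side ", side, " A too small to place ", length(blocks),
           " oligomer blocks with margin; increase the side")
  }
  chains <- vector("list", nChains)
  for (bi in seq_along(blocks)) {
    ids <- sort(blocks[[bi]])
    for (s in seq_along(ids)) {
      chains[[ids[s]]] <- sweep(pieces[[bi]][[s]], 2L, centers[bi, ], "+")
    }
  }
  chains
}

#' Sample a synthetic replica-exchange ensemble
#'
#' Runs, per ladder temperature and multiplex set, a Metropolis Markov chain
#' over chain partitions (single-chain reassignment plus merge/split block
#' moves, each with its exact Hastings correction), with replica-exchange
#' swaps between neighbouring temperatures every \code{exchangeInterval}
#' sweeps (standard acceptance on delta-beta * delta-E; the entropic factor
#' cancels).  Snapshots are recorded at each exchange point: the partition,
#' its energy, the replica's current ladder index, the trajectory id and the
#' sweep count.  Each snapshot is rendered into Calpha coordinates with
#' associated blocks as in-register extended-strand bundles (4.8 Angstrom
#' spacing, so the contact criterion and the beta criteria hold inside a
#' block) and free chains as self-avoiding coils, blocks separated by more
#' than cutoff + margin.  Each replica starts from an exact Boltzmann draw
#' at its own rung (the partition model is enumerable), so the chains carry
#' no burn-in bias.  Fully reproducible under the model seed.
#'
#' @param spec a [ToyModelSpec-class].
#' @param renderCoords render coordinates (TRUE, default) or emit
#'   single-point placeholder chains (FALSE, energies/metadata only; much
#'   faster when only reweighting is studied).
#' @return An [EnsembleSet-class].
#' @export
sampleEnsemble <- function(spec, renderCoords = TRUE) {
  set.seed(spec@seed)
  n <- spec@nChains
  K <- length(spec@ladder)
  beta <- 1 / (spec@kB * spec@ladder)
  nCycles <- spec@nSweeps %/% spec@exchangeInterval
  movesPerSweep <- n

  coords <- list()
  traj <- integer(0); stepv <- integer(0); tempIndex <- integer(0)
  energy <- numeric(0)
  partsOut <- list()

  ## perfect start: each replica's initial partition is drawn from the
  ## exact Boltzmann distribution at its rung (the model is enumerable for
  ## n <= 10), so no burn-in bias enters the analysis window
  parts <- setPartitionsRG(n)
  nbP <- vapply(parts, function(m) length(unique(m)), integer(1))
  scP <- vapply(parts, function(m) {
    sizes <- tabulate(m)
    sum(choose(sizes[sizes > 0L], 2))
  }, numeric(1))

  for (mset in seq_len(spec@multiplex)) {
    states <- lapply(seq_len(K), function(k) {
      lw <- nbP * log(spec@nu) + beta[k] * spec@epsilon * scP
      w <- exp(lw - max(lw))
      unname(split(seq_len(n), parts[[sample.int(length(parts), 1L,
                                                 prob = w)]]))
    })
    repTemp <- seq_len(K)                 # replica r currently at rung
    phase <- 0L
    for (cycle in seq_len(nCycles)) {
      for (r in seq_len(K)) {
        b <- beta[repTemp[r]]
        st <- states[[r]]
        for (sw in seq_len(spec@exchangeInterval * movesPerSweep)) {
          st <- mcmcMove(st, b, spec@epsilon, spec@nu, n)
        }
        states[[r]] <- st
      }
      ## exchange attempts on alternating adjacent rung pairs
      phase <- 1L - phase
      byRung <- order(repTemp)            # replica at rung k
      for (k in seq(1L + phase, K - 1L, by = 2L)) {
        ra <- byRung[k]; rb <- byRung[k + 1L]
        Ea <- partitionEnergy(lengths(states[[ra]]), spec@epsilon)
        Eb <- partitionEnergy(lengths(states[[rb]]), spec@epsilon)
        d <- (beta[k] - beta[k + 1L]) * (Ea - Eb)
        if (log(runif(1)) < d) {
          repTemp[ra] <- k + 1L
          repTemp[rb] <- k
          byRung[k] <- rb
          byRung[k + 1L] <- ra
        }
      }
      ## snapshot at the exchange point, one per replica (trajectory)
      for (r in seq_len(K)) {
        st <- states[[r]]
        traj <- c(traj, (mset - 1L) * K + r)
        stepv <- c(stepv, cycle * spec@exchangeInterval)
        tempIndex <- c(tempIndex, repTemp[r])
        energy <- c(energy, partitionEnergy(lengths(st), spec@epsilon))
        partsOut[[length(partsOut) + 1L]] <- st
      }
    }
  }

  coords <- lapply(partsOut, function(st) {
    if (renderCoords) {
      renderPartition(st, n, spec@residuesPerChain, spec@box)
    } else {
      lapply(seq_len(n), function(i) matrix(0, spec@residuesPerChain, 3L))
    }
  })
  meta <- data.frame(traj = traj, step = stepv, tempIndex = tempIndex,
                     energy = energy)
  meta$partition <- vapply(partsOut, partitionKey, character(1))
  ord <- order(meta$traj, meta$step)
  ens <- ensembleSet(coords[ord], meta[ord, , drop = FALSE], spec@ladder,
                     spec@box)
  attr(ens, "partitions") <- partsOut[ord]
  ens
}

partitionKey <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

parsePartitionKey <- function(key) {
  lapply(strsplit(key, "|", fixed = TRUE)[[1L]], function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
}

#' Render (or re-render) coordinates for a synthetic ensemble
#'
#' Synthetic ensembles sampled with \code{renderCoords = FALSE} carry their
#' chain partitions in the metadata but only placeholder coordinates.  This
#' renders every frame of the (possibly windowed) ensemble into Calpha
#' coordinates under the same layout rules as [sampleEnsemble()], which is
#' much cheaper than rendering frames that the analysis window discards.
#'
#' @param ensemble an [EnsembleSet-class] whose metadata has a
#'   \code{partition} column (as produced by [sampleEnsemble()]).
#' @param residuesPerChain residues per chain (default: taken from the
#'   ensemble).
#' @return The ensemble with rendered coordinates.
#' @export
renderFrames <- function(ensemble, residuesPerChain = NULL) {
  meta <- ensemble@meta
  if (is.null(meta$partition))
    stop("ensemble metadata has no partition column; only synthetic ",
         "ensembles can be re-rendered")
  nRes <- if (is.null(residuesPerChain)) ensemble@residuesPerChain
          else as.integer(residuesPerChain)
  coords <- lapply(meta$partition, function(key) {
    renderPartition(parsePartitionKey(key), ensemble@nChains, nRes,
                    ensemble@box)
  })
  ensembleSet(coords, meta, ensemble@ladder, ensemble@box,
              ensemble@energyUnit)
}
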