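## Central S4 containers.
##
## Coordinates are stored unwrapped per chain: a chain never straddles the
## periodic boundary in stored form, so intra-chain geometry (virtual bonds,
## dihedrals) can be read off directly; inter-chain distances always go
## through the minimum-image convention.

#' Cubic periodic simulation box
#'
#' @slot side box-side length in Angstrom.
#' @slot periodic logical flag; minimum-image distances are only defined for
#'   periodic boxes.
#' @export
setClass("BoxSpec",
  representation(side = "numeric", periodic = "logical"))

setValidity("BoxSpec", function(object) {
  if (length(object@side) != 1L || !is.finite(object@side) || object@side <= 0)
    return("side must be a single positive finite number")
  if (length(object@periodic) != 1L) return("periodic must be a single flag")
  TRUE
})

#' Construct a cubic simulation box
#'
#' @param side box-side length in Angstrom (> 0).
#' @param periodic whether the box is periodic (default TRUE).
#' @return A [BoxSpec-class] object.
#' @examples
#' boxSpec(100)
#' @export
boxSpec <- function(side, periodic = TRUE) {
  new("BoxSpec", side = as.numeric(side), periodic = periodic)
}

#' Multi-chain Calpha-trace ensemble with replica metadata
#'
#' One object holds an ordered collection of snapshots ("frames").  Each
#' frame is a list of per-chain Calpha coordinate matrices (residues x 3, in
#' Angstrom, equal residue counts across chains of a system), joined 1:1 with
#' a metadata row carrying the potential energy, the ladder temperature index
#' at which the snapshot was sampled, the trajectory id and the MD/MC step.
#'
#' @slot coords list of frames; each frame a list of chain matrices.
#' @slot meta data.frame with columns \code{traj}, \code{step},
#'   \code{tempIndex} (1-based into \code{ladder}), \code{energy}.
#' @slot ladder strictly increasing Kelvin values (length >= 1).
#' @slot box a [BoxSpec-class].
#' @slot nChains number of chains per frame.
#' @slot residuesPerChain residues per chain.
#' @slot energyUnit character; carried opaquely (only E/(kB T) ratios are
#'   consumed, with kB in matching units).  Default "kcal/mol".
#' @export
setClass("EnsembleSet",
  representation(coords = "list", meta = "data.frame", ladder = "numeric",
                 box = "BoxSpec", nChains = "integer",
                 residuesPerChain = "integer", energyUnit = "character"))

setValidity("EnsembleSet", function(object) {
  m <- object@meta
  need <- c("traj", "step", "tempIndex", "energy")
  if (!all(need %in% names(m)))
    return(paste("meta must have columns", paste(need, collapse = ", ")))
  if (length(object@coords) != nrow(m))
    return("frame count and metadata row count differ")
  if (length(object@ladder) < 1L || any(diff(object@ladder) <= 0) ||
      any(object@ladder <= 0))
    return("ladder must be strictly increasing positive temperatures")
  if (nrow(m) > 0) {
    if (any(!is.finite(m$energy))) return("non-finite energy")
    if (any(m$tempIndex < 1L | m$tempIndex > length(object@ladder)))
      return("tempIndex out of ladder range")
    f1 <- object@coords[[1L]]
    if (length(f1) != object@nChains)
      return("frame chain count != nChains")
    if (nrow(f1[[1L]]) != object@residuesPerChain)
      return("chain length != residuesPerChain")
  }
  TRUE
})

#' Construct an EnsembleSet
#'
#' @param coords list of frames, each a list of chain coordinate matrices
#'   (residues x 3).
#' @param meta data.frame with columns \code{traj}, \code{step},
#'   \code{tempIndex} (1-based), \code{energy}.
#' @param ladder temperature ladder in Kelvin.
#' @param box a [BoxSpec-class].
#' @param energyUnit declared energy unit (default "kcal/mol").
#' @return An [EnsembleSet-class].
#' @export
ensembleSet <- function(coords, meta, ladder, box, energyUnit = "kcal/mol") {
  nch <- if (length(coords)) length(coords[[1L]]) else 0L
  nres <- if (nch) nrow(coords[[1L]][[1L]]) else 0L
  meta$tempIndex <- as.integer(meta$tempIndex)
  meta$traj <- as.integer(meta$traj)
  new("EnsembleSet", coords = coords, meta = meta,
      ladder = as.numeric(ladder), box = box,
      nChains = as.integer(nch), residuesPerChain = as.integer(nres),
      energyUnit = energyUnit)
}

#' Disjoint grouping of chains into oligomers for one frame
#'
#' @slot blocks list of integer vectors partitioning 1..nChains.
#' @slot nChains number of chains.
#' @export
setClass("OligomerPartition",
  representation(blocks = "list", nChains = "integer"))

setValidity("OligomerPartition", function(object) {
  all_idx <- sort(unlist(object@blocks))
  if (!identical(all_idx, seq_len(object@nChains)))
    return("blocks must partition 1..nChains")
  TRUE
})

#' WHAM weight table
#'
#' Converged binless-WHAM solution over a multi-temperature ensemble:
#' dimensionless free energies f_k per ladder temperature (gauge f_1 = 0) and
#' everything needed to evaluate normalized snapshot weights w_i(T) at any
#' target temperature (see [snapshotWeights()]).
#'
#' @slot freeEnergies numeric f_k per ladder temperature.
#' @slot ladder ladder temperatures (K).
#' @slot energies per-snapshot potential energies.
#' @slot logDenom per-snapshot log of the WHAM mixture denominator.
#' @slot kB Boltzmann constant in the energy unit used.
#' @slot residual final self-consistency residual max|delta f|.
#' @slot iterations iterations used.
#' @export
setClass("WeightTable",
  representation(freeEnergies = "numeric", ladder = "numeric",
                 energies = "numeric", logDenom = "numeric",
                 kB = "numeric", residual = "numeric",
                 iterations = "integer"))

#' An observable evaluated on a temperature grid
#'
#' @slot grid strictly increasing Kelvin values.
#' @slot values observable per grid point.
#' @slot label short description of the observable.
#' @export
setClass("TemperatureProfile",
  representation(grid = "numeric", values = "numeric", label = "character"))

setValidity("TemperatureProfile", function(object) {
  if (length(object@grid) != length(object@values))
    return("grid and values lengths differ")
  if (any(diff(object@grid) <= 0))
    return("grid must be strictly increasing")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Construct a TemperatureProfile
#' @param grid strictly increasing Kelvin values.
#' @param values observable values, one per grid point.
#' @param label short label.
#' @return A [TemperatureProfile-class].
#' @export
temperatureProfile <- function(grid, values, label = "") {
  new("TemperatureProfile", grid = as.numeric(grid),
      values = as.numeric(values), label = label)
}

#' Ward clustering result at one target temperature
#'
#' @slot frameIds indices (into the clustered frame list) of the frames used.
#' @slot assignments cluster id per used frame.
#' @slot probabilities cumulative WHAM weight per cluster (sums to 1),
#'   clusters ordered by decreasing probability.
#' @slot representatives one frame id per cluster (medoid).
#' @slot k number of clusters.
#' @export
setClass("ClusterSet",
  representation(frameIds = "integer", assignments = "integer",
                 probabilities = "numeric", representatives = "integer",
                 k = "integer"))

setValidity("ClusterSet", function(object) {
  if (length(object@probabilities) != object@k) return("need k probabilities")
  if (abs(sum(object@probabilities) - 1) > 1e-8)
    return("cluster probabilities must sum to 1")
  for (cl in seq_len(object@k)) {
    rep <- object@representatives[cl]
    if (!(rep %in% object@frameIds[object@assignments == cl]))
      return("representative must belong to its cluster")
  }
  TRUE
})

#' Specification of the synthetic chain-partition ensemble
#'
#' The synthetic model is a Hamiltonian over set partitions of n chains:
#' E(P) = -epsilon * sum over blocks of choose(|b|, 2), with an entropic
#' factor nu^{|P|} per partition (nu encodes the translational entropy of an
#' independent oligomer, i.e. the available volume per cluster).  It is
#' sampled by Metropolis Monte Carlo with replica exchange across the ladder
#' and rendered into Calpha coordinates (associated blocks as in-register
#' extended strand bundles, free chains as self-avoiding coils).
#'
#' @slot nChains number of chains (<= 10 so exact enumeration is feasible).
#' @slot residuesPerChain residues per chain.
#' @slot epsilon contact energy per associated chain pair (kcal/mol, > 0
#'   favours association).
#' @slot nu dimensionless translational-entropy factor per oligomer block.
#' @slot ladder temperature ladder (K).
#' @slot nSweeps Monte Carlo sweeps per replica.
#' @slot exchangeInterval sweeps between replica-exchange attempts (snapshots
#'   are recorded at each exchange point).
#' @slot multiplex independent replica sets per ladder temperature
#'   (trajectories = multiplex * length(ladder)).
#' @slot seed RNG seed.
#' @slot box a [BoxSpec-class].
#' @slot kB Boltzmann constant in the energy unit.
#' @export
setClass("ToyModelSpec",
  representation(nChains = "integer", residuesPerChain = "integer",
                 epsilon = "numeric", nu = "numeric", ladder = "numeric",
                 nSweeps = "integer", exchangeInterval = "integer",
                 multiplex = "integer", seed = "integer", box = "BoxSpec",
                 kB = "numeric"))

setValidity("ToyModelSpec", function(object) {
  if (object@nChains < 1L || object@nChains > 10L)
    return("nChains must be in 1..10 (exact enumeration bound)")
  if (object@epsilon <= 0 || object@nu <= 0)
    return("epsilon and nu must be positive")
  if (length(object@ladder) < 2L || any(diff(object@ladder) <= 0))
    return("ladder must be strictly increasing, length >= 2")
  TRUE
})

#' Exact thermodynamics of the chain-partition model
#'
#' Holds one row per set partition of the chains: energy, number of blocks,
#' and the fraction of chains in m-mers, enabling exact f_m(T), energy
#' moments, heat capacity and the melting midpoint at any temperature.
#'
#' @slot nChains number of chains.
#' @slot epsilon,nu model parameters.
#' @slot energiesP energy E(P) per partition.
#' @slot nBlocksP number of blocks |P| per partition.
#' @slot fmP matrix partitions x nChains, fraction of chains in m-mers.
#' @slot kB Boltzmann constant used.
#' @export
setClass("PartitionOracle",
  representation(nChains = "integer", epsilon = "numeric", nu = "numeric",
                 energiesP = "numeric", nBlocksP = "integer", fmP = "matrix",
                 kB = "numeric"))
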