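## Generics for the S4 containers.  Accessors are exported; slot access is
## internal to the package.

#' Number of frames in an ensemble
#' @param x an [EnsembleSet-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Temperature ladder of an object
#' @param x an object carrying a ladder.
#' @return numeric Kelvin values.
#' @export
setGeneric("ladder", function(x) standardGeneric("ladder"))

#' Per-snapshot potential energies
#' @param x an [EnsembleSet-class] or [WeightTable-class].
#' @return numeric vector.
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' Per-snapshot 1-based ladder temperature indices
#' @param x an [EnsembleSet-class].
#' @return integer vector.
#' @export
setGeneric("temperatureIndex", function(x) standardGeneric("temperatureIndex"))

#' Sample counts N_k per ladder temperature
#' @param x an [EnsembleSet-class].
#' @return integer vector, one count per ladder rung (zeros included).
#' @export
setGeneric("temperatureCounts",
           function(x) standardGeneric("temperatureCounts"))

#' Extract one frame (list of chain coordinate matrices)
#' @param x an [EnsembleSet-class].
#' @param i frame index (1-based).
#' @return list of residues x 3 matrices.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Snapshot metadata
#' @param x an [EnsembleSet-class].
#' @return data.frame with columns traj, step, tempIndex, energy.
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' Simulation box of an object
#' @param x an object carrying a box.
#' @return a [BoxSpec-class].
#' @export
setGeneric("simulationBox", function(x) standardGeneric("simulationBox"))

#' Dimensionless WHAM free energies per ladder temperature
#' @param x a [WeightTable-class].
#' @return numeric vector, gauge-fixed so the first entry is 0.
#' @export
setGeneric("freeEnergies", function(x) standardGeneric("freeEnergies"))

#' Normalized snapshot weights at a target temperature
#'
#' Evaluates the binless-WHAM weights w_i(T) over all snapshots of the
#' ensemble the table was solved on; they are non-negative and sum to 1 at
#' every temperature.
#'
#' @param x a [WeightTable-class].
#' @param temperature target temperature in Kelvin (scalar).
#' @return numeric vector of weights summing to 1.
#' @export
setGeneric("snapshotWeights",
           function(x, temperature) standardGeneric("snapshotWeights"))

#' Oligomer-size counts of a partition
#' @param x an [OligomerPartition-class].
#' @return integer vector c of length nChains; c[m] = number of m-chain
#'   oligomers.
#' @export
setGeneric("sizeCounts", function(x) standardGeneric("sizeCounts"))

#' Fractions of chains in m-chain oligomers
#'
#' For a partition of n chains, f_m = m * count(m) / n; the fractions sum
#' to 1.
#'
#' @param x an [OligomerPartition-class].
#' @return numeric vector of length nChains.
#' @export
setGeneric("oligomerFractions",
           function(x) standardGeneric("oligomerFractions"))

#' Temperature grid of a profile
#' @param x a [TemperatureProfile-class].
#' @return numeric Kelvin values.
#' @export
setGeneric("profileGrid", function(x) standardGeneric("profileGrid"))

#' Values of a profile
#' @param x a [TemperatureProfile-class].
#' @return numeric vector.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Cluster probabilities (cumulative WHAM weights)
#' @param x a [ClusterSet-class].
#' @return numeric vector of length k summing to 1.
#' @export
setGeneric("clusterProbabilities",
           function(x) standardGeneric("clusterProbabilities"))

#' Representative frame ids, one per cluster
#' @param x a [ClusterSet-class].
#' @return integer vector of length k.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Cluster assignment per clustered frame
#' @param x a [ClusterSet-class].
#' @return integer vector parallel to the clustered frame ids.
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
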