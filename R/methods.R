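## Accessor and show methods.

#' @describeIn nFrames frame count of an ensemble
#' @export
setMethod("nFrames", "EnsembleSet", function(x) length(x@coords))

#' @describeIn ladder ladder of an ensemble
#' @export
setMethod("ladder", "EnsembleSet", function(x) x@ladder)

#' @describeIn ladder ladder of a weight table
#' @export
setMethod("ladder", "WeightTable", function(x) x@ladder)

#' @describeIn energies energies of an ensemble
#' @export
setMethod("energies", "EnsembleSet", function(x) x@meta$energy)

#' @describeIn energies energies backing a weight table
#' @export
setMethod("energies", "WeightTable", function(x) x@energies)

#' @describeIn temperatureIndex indices of an ensemble
#' @export
setMethod("temperatureIndex", "EnsembleSet", function(x) x@meta$tempIndex)

#' @describeIn temperatureCounts counts of an ensemble
#' @export
setMethod("temperatureCounts", "EnsembleSet", function(x) {
  tabulate(x@meta$tempIndex, nbins = length(x@ladder))
})

#' @describeIn getFrame frame of an ensemble
#' @export
setMethod("getFrame", "EnsembleSet", function(x, i) x@coords[[i]])

#' @describeIn frameMeta metadata of an ensemble
#' @export
setMethod("frameMeta", "EnsembleSet", function(x) x@meta)

#' @describeIn simulationBox box of an ensemble
#' @export
setMethod("simulationBox", "EnsembleSet", function(x) x@box)

#' @describeIn freeEnergies free energies of a weight table
#' @export
setMethod("freeEnergies", "WeightTable", function(x) x@freeEnergies)

#' @describeIn sizeCounts counts of an oligomer partition
#' @export
setMethod("sizeCounts", "OligomerPartition", function(x) {
  sizes <- lengths(x@blocks)
  tabulate(sizes, nbins = x@nChains)
})

#' @describeIn oligomerFractions fractions of an oligomer partition
#' @export
setMethod("oligomerFractions", "OligomerPartition", function(x) {
  m <- seq_len(x@nChains)
  m * sizeCounts(x) / x@nChains
})

#' @describeIn profileGrid grid of a profile
#' @export
setMethod("profileGrid", "TemperatureProfile", function(x) x@grid)

#' @describeIn profileValues values of a profile
#' @export
setMethod("profileValues", "TemperatureProfile", function(x) x@values)

#' @describeIn clusterProbabilities probabilities of a cluster set
#' @export
setMethod("clusterProbabilities", "ClusterSet", function(x) x@probabilities)

#' @describeIn representatives representatives of a cluster set
#' @export
setMethod("representatives", "ClusterSet", function(x) x@representatives)

#' @describeIn clusterAssignments assignments of a cluster set
#' @export
setMethod("clusterAssignments", "ClusterSet", function(x) x@assignments)

setMethod("show", "BoxSpec", function(object) {
  cat(sprintf("BoxSpec: cubic, side %.1f A, %s\n", object@side,
              if (object@periodic) "periodic" else "non-periodic"))
})

setMethod("show", "EnsembleSet", function(object) {
  cat(sprintf(
    "EnsembleSet: %d frames, %d chains x %d residues, %d-rung ladder (%g-%g K)\n",
    length(object@coords), object@nChains, object@residuesPerChain,
    length(object@ladder), min(object@ladder), max(object@ladder)))
  cat(sprintf("  box side %.1f A; energies in %s\n",
              object@box@side, object@energyUnit))
  nk <- tabulate(object@meta$tempIndex, nbins = length(object@ladder))
  cat("  N_k:", paste(nk, collapse = " "), "\n")
})

setMethod("show", "OligomerPartition", function(object) {
  sizes <- sort(lengths(object@blocks), decreasing = TRUE)
  cat(sprintf("OligomerPartition: %d chains as [%s]\n", object@nChains,
              paste(sizes, collapse = "+")))
})

setMethod("show", "WeightTable", function(object) {
  cat(sprintf(
    "WeightTable: %d snapshots, %d ladder temperatures, residual %.2e (%d iter)\n",
    length(object@energies), length(object@ladder), object@residual,
    object@iterations))
  cat("  f_k:", paste(sprintf("%.3f", object@freeEnergies), collapse = " "),
      "\n")
})

setMethod("show", "TemperatureProfile", function(object) {
  cat(sprintf("TemperatureProfile '%s': %d points, %g-%g K, range [%.4g, %.4g]\n",
              object@label, length(object@grid), min(object@grid),
              max(object@grid), min(object@values), max(object@values)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters over %d frames\n", object@k,
              length(object@frameIds)))
  cat("  probabilities:",
      paste(sprintf("%.3f", object@probabilities), collapse = " "), "\n")
  cat("  representatives:", paste(object@representatives, collapse = " "),
      "\n")
})

setMethod("show", "ToyModelSpec", function(object) {
  cat(sprintf(
    "ToyModelSpec: %d chains x %d residues, epsilon %.3g, nu %.3g, %d temps\n",
    object@nChains, object@residuesPerChain, object@epsilon, object@nu,
    length(object@ladder)))
  cat(sprintf("  %d sweeps, exchange every %d, multiplex %d, seed %d\n",
              object@nSweeps, object@exchangeInterval, object@multiplex,
              object@seed))
})

setMethod("show", "PartitionOracle", function(object) {
  cat(sprintf(
    "PartitionOracle: %d chains, %d partitions, epsilon %.3g, nu %.3g\n",
    object@nChains, length(object@energiesP), object@epsilon, object@nu))
})
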