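## Oligomer identification from the Calpha contact criterion.

#' Are two chains associated?
#'
#' Two chains count as associated when the distance between any Calpha atom
#' of the first and any Calpha atom of the second is strictly shorter than
#' the cutoff (default 7 Angstrom), with distances taken under the
#' minimum-image convention of the periodic box.
#'
#' @param chainA,chainB residues x 3 coordinate matrices.
#' @param box a [BoxSpec-class].
#' @param cutoff association cutoff in Angstrom (default 7).
#' @return logical flag.
#' @export
chainsAssociated <- function(chainA, chainB, box, cutoff = 7.0) {
  if (nrow(chainA) == 0L || nrow(chainB) == 0L)
    stop("chains must be non-empty")
  min(minImageCrossDist(chainA, chainB, box)) < cutoff
}

## strict-inequality pairwise association matrix for one frame
associationMatrix <- function(frame, box, cutoff = 7.0) {
  n <- length(frame)
  adj <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <- chainsAssociated(frame[[i]], frame[[j]],
                                                 box, cutoff)
    }
  }
  adj
}

#' Identify oligomers in a snapshot
#'
#' Iterative growth procedure: starting from the lowest-indexed unassigned
#' chain, the remaining chains are scanned in index order for the first one
#' associated with any current member; the oligomer grows until no further
#' chain attaches, then the search restarts from the next unassigned chain.
#' The result equals the connected components of the pairwise association
#' graph.
#'
#' @param frame list of chain coordinate matrices.
#' @param box a [BoxSpec-class].
#' @param cutoff association cutoff in Angstrom (default 7).
#' @return An [OligomerPartition-class].
#' @export
identifyOligomers <- function(frame, box, cutoff = 7.0) {
  n <- length(frame)
  adj <- associationMatrix(frame, box, cutoff)
  unassigned <- rep(TRUE, n)
  blocks <- list()
  while (any(unassigned)) {
    seed <- which(unassigned)[1L]
    members <- seed
    unassigned[seed] <- FALSE
    repeat {
      remaining <- which(unassigned)
      grown <- FALSE
      for (cand in remaining) {       # scan in index order
        if (any(adj[cand, members])) {
          members <- c(members, cand)
          unassigned[cand] <- FALSE
          grown <- TRUE
          break                        # restart the scan after each addition
        }
      }
      if (!grown) break
    }
    blocks[[length(blocks) + 1L]] <- sort(members)
  }
  new("OligomerPartition", blocks = blocks, nChains = as.integer(n))
}

#' Ensemble-averaged oligomer fractions at chosen temperatures
#'
#' WHAM-averages the per-frame fraction matrix at each requested
#' temperature, giving the stacked-fraction table (monomers to n-mers)
#' reported at, e.g., the 310 K incubation and 298 K room temperatures.
#'
#' @param weights a [WeightTable-class].
#' @param fractionMatrix per-frame fractions from
#'   [oligomerFractionMatrix()].
#' @param temperatures Kelvin values (default c(298, 310)).
#' @return matrix temperatures x m; each row sums to 1.
#' @export
oligomerFractionsAt <- function(weights, fractionMatrix,
                                temperatures = c(298, 310)) {
  out <- t(vapply(temperatures, function(Tt) {
    colSums(snapshotWeights(weights, Tt) * fractionMatrix)
  }, numeric(ncol(fractionMatrix))))
  rownames(out) <- as.character(temperatures)
  out
}

#' Per-frame oligomer-size fractions for a whole ensemble
#'
#' Applies [identifyOligomers()] to every frame and returns the matrix of
#' fractions f_mi of chains in m-chain oligomers (rows = frames, columns =
#' m = 1..nChains; every row sums to 1).
#'
#' @param ensemble an [EnsembleSet-class].
#' @param cutoff association cutoff in Angstrom (default 7).
#' @return numeric matrix nFrames x nChains.
#' @export
oligomerFractionMatrix <- function(ensemble, cutoff = 7.0) {
  n <- nFrames(ensemble)
  out <- matrix(0, n, ensemble@nChains)
  for (i in seq_len(n)) {
    out[i, ] <- oligomerFractions(
      identifyOligomers(ensemble@coords[[i]], ensemble@box, cutoff))
  }
  colnames(out) <- paste0("f", seq_len(ensemble@nChains))
  out
}
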