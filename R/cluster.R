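## Conformational clustering at a target temperature and per-residue RMSF.

## Kabsch: RMSD of B onto A after optimal rigid superposition (proper
## rotation; reflections excluded via the determinant correction).
kabschRmsd <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- Ac - Bc %*% t(R)
  sqrt(sum(diffs^2) / nrow(A))
}

## rotate+center B onto A (returns transformed B)
kabschFit <- function(A, B) {
  muA <- colMeans(A)
  Bc <- sweep(B, 2L, colMeans(B))
  Ac <- sweep(A, 2L, muA)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Bc %*% t(R), 2L, muA, "+")
}

## Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths).
## Minimises the total cost of a square assignment; n is small (chains).
solveAssignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)                    # p[j]: row assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1L)) perm[p[j]] <- j - 1L   # perm[row] = column
  perm
}

## flatten a frame (list of chains) to one coordinate matrix, optionally
## permuting chain order
stackFrame <- function(frame, perm = seq_along(frame)) {
  do.call(rbind, frame[perm])
}

## all permutations of 1..n (n small)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in allPermutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

frameDistanceOneWay <- function(a, b, mode) {
  nch <- length(a)
  if (mode == "fixed-labels" || nch == 1L) {
    return(kabschRmsd(stackFrame(a), stackFrame(b)))
  }
  if (nch <= 5L) {
    ## exact minimum over chain relabelings (<= 120 superpositions)
    A <- stackFrame(a)
    return(min(vapply(allPermutations(nch), function(p)
      kabschRmsd(A, stackFrame(b, p)), numeric(1))))
  }
  A <- stackFrame(a)
  best <- kabschRmsd(A, stackFrame(b))     # identity start
  ## assignment over chain centroids of the centered frames, then refined
  centA <- t(vapply(a, colMeans, numeric(3)))
  centA <- sweep(centA, 2L, colMeans(do.call(rbind, a)))
  centB0 <- t(vapply(b, colMeans, numeric(3)))
  centB0 <- sweep(centB0, 2L, colMeans(do.call(rbind, b)))
  perm <- seq_len(nch)
  for (it in 1:5) {
    Bfit <- kabschFit(A, stackFrame(b, perm))
    nres <- nrow(a[[1L]])
    centB <- t(vapply(seq_len(nch), function(ci) {
      colMeans(Bfit[((ci - 1L) * nres + 1L):(ci * nres), , drop = FALSE])
    }, numeric(3)))
    ## centB rows follow perm order; map back to original chain ids
    cost <- matrix(0, nch, nch)
    for (i in seq_len(nch)) for (j in seq_len(nch)) {
      cost[i, j] <- sum((centA[i, ] - centB[j, ])^2)
    }
    reorder <- solveAssignment(cost)       # reorder[i]: position in perm
    newPerm <- perm[reorder]
    d <- kabschRmsd(A, stackFrame(b, newPerm))
    if (d < best) best <- d
    if (identical(newPerm, perm)) break
    perm <- newPerm
  }
  best
}

#' Distance between two multi-chain frames
#'
#' All-chain Calpha RMSD after optimal rigid superposition (Kabsch).  In
#' \code{best-permutation} mode (the default; chains of identical sequence
#' are interchangeable) the RMSD is additionally minimised over chain
#' relabelings, found by Hungarian assignment over chain centroids and
#' iteratively refined; the value is symmetrised by taking the smaller of
#' the two directed searches, making it a pseudo-metric that vanishes on
#' permutation-equivalent frames.
#'
#' For five chains or fewer the minimum over relabelings is exact
#' (exhaustive); beyond that the assignment heuristic is used.
#'
#' @param a,b frames (lists of chain coordinate matrices of equal shape).
#' @param mode "best-permutation" or "fixed-labels".
#' @return RMSD in Angstrom.
#' @export
frameDistance <- function(a, b, mode = c("best-permutation",
                                         "fixed-labels")) {
  mode <- match.arg(mode)
  if (length(a) != length(b) || nrow(a[[1L]]) != nrow(b[[1L]]))
    stop("frames have different dimensions")
  if (mode == "fixed-labels") return(frameDistanceOneWay(a, b, mode))
  min(frameDistanceOneWay(a, b, mode), frameDistanceOneWay(b, a, mode))
}

## pairwise distance matrix over a list of frames
frameDistanceMatrix <- function(frames, mode = "best-permutation") {
  n <- length(frames)
  D <- matrix(0, n, n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- frameDistance(frames[[i]], frames[[j]], mode)
    }
  }
  D
}

#' Ward clustering of frames with WHAM-weighted ranking
#'
#' Agglomerative Ward (minimum-variance) clustering on the pairwise frame
#' RMSD matrix, cut at \code{k} clusters.  Clusters are ranked by the
#' cumulative normalized weight of their member frames (descending) and each
#' receives a representative: the medoid, i.e. the member minimising the
#' mean squared distance to the other members (ties break to the lowest
#' frame index).  When more than \code{maxFrames} frames are supplied, a
#' weighted subsample of size \code{maxFrames} is drawn first (without
#' replacement, probability proportional to weight) to bound the O(n^2)
#' distance matrix.
#'
#' @param frames list of frames.
#' @param weights per-frame weights (e.g. \code{snapshotWeights(wt, T)});
#'   uniform when NULL.
#' @param k number of clusters (default 5).
#' @param mode frame-distance mode (see [frameDistance()]).
#' @param maxFrames subsample bound (default 600).
#' @param seed RNG seed for the subsample draw.
#' @return A [ClusterSet-class]; frame ids refer to the input list.
#' @export
wardCluster <- function(frames, weights = NULL, k = 5L,
                        mode = c("best-permutation", "fixed-labels"),
                        maxFrames = 600L, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(frames)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("need one weight per frame")
  weights <- weights / sum(weights)
  if (n < k) stop("fewer frames (", n, ") than clusters (", k, ")")
  ids <- seq_len(n)
  if (n > maxFrames) {
    set.seed(seed)
    ids <- sort(sample.int(n, maxFrames, prob = weights))
  }
  D <- frameDistanceMatrix(frames[ids], mode)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  w_used <- weights[ids] / sum(weights[ids])
  probs <- vapply(seq_len(k), function(cl) sum(w_used[raw == cl]),
                  numeric(1))
  ## rank clusters by cumulative probability, ties to lowest member index
  first_member <- vapply(seq_len(k), function(cl) min(ids[raw == cl]),
                         numeric(1))
  ord <- order(-probs, first_member)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- relabel[raw]
  probs <- probs[ord]
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(assignments == cl)
    if (length(members) == 1L) return(ids[members])
    sub <- D[members, members, drop = FALSE]
    msq <- rowSums(sub^2) / (length(members) - 1L)
    ids[members[which.min(msq)]]       # which.min: lowest index on ties
  }, integer(1))
  new("ClusterSet", frameIds = as.integer(ids),
      assignments = as.integer(assignments),
      probabilities = probs, representatives = reps, k = as.integer(k))
}

#' Medoid representative of a set of frames
#'
#' The member minimising the mean squared frame distance to all other
#' members under the same metric used for clustering; ties break to the
#' lowest index.
#'
#' @param frames list of frames (non-empty).
#' @param mode frame-distance mode.
#' @return index of the representative within \code{frames}.
#' @export
clusterRepresentative <- function(frames, mode = c("best-permutation",
                                                   "fixed-labels")) {
  mode <- match.arg(mode)
  if (!length(frames)) stop("empty cluster")
  if (length(frames) == 1L) return(1L)
  D <- frameDistanceMatrix(frames, mode)
  msq <- rowSums(D^2) / (length(frames) - 1L)
  which.min(msq)
}

#' Per-residue RMSF over chains and models
#'
#' Pools every chain of every supplied frame, superposes them onto the
#' evolving mean chain (iterated Kabsch superposition until the mean
#' stabilises), and returns per residue the root-mean-square deviation of
#' the Calpha position from the mean chain.
#'
#' @param frames list of frames (e.g. the five cluster representatives); all
#'   chains must have the same length.
#' @param tol convergence tolerance on the mean-chain displacement
#'   (default 1e-8).
#' @param maxIter iteration cap (default 200).
#' @return numeric vector of per-residue RMSF values (Angstrom, >= 0).
#' @export
rmsfPerResidue <- function(frames, tol = 1e-8, maxIter = 200L) {
  chains <- unlist(frames, recursive = FALSE)
  nres <- nrow(chains[[1L]])
  if (!all(vapply(chains, nrow, integer(1)) == nres))
    stop("all chains must have the same length")
  mean_chain <- chains[[1L]]
  for (it in seq_len(maxIter)) {
    fitted <- lapply(chains, function(ch) kabschFit(mean_chain, ch))
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(mean((new_mean - mean_chain)^2))
    mean_chain <- new_mean
    if (shift < tol) break
  }
  fitted <- lapply(chains, function(ch) kabschFit(mean_chain, ch))
  sq <- vapply(fitted, function(ch) rowSums((ch - mean_chain)^2),
               numeric(nres))
  if (nres == 1L) sq <- matrix(sq, nrow = 1L)
  sqrt(rowMeans(sq))
}
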