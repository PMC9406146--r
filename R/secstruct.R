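## Coarse-grained secondary-structure assignment from the Calpha trace.
##
## A residue is assigned alpha, beta or statistical coil (c) from two
## ingredients, mirroring assignment schemes for Calpha-only models that
## combine local virtual-bond geometry with a backbone-interaction
## (hydrogen-bond proxy) pattern:
##  - local geometry: the virtual dihedral over Calpha(i-1..i+2) and the
##    Calpha(i)-Calpha(i+3) distance;
##  - interaction pattern: proximity of pseudo-peptide centers (midpoints of
##    consecutive Calpha atoms), which stand in for the peptide groups that
##    carry the hydrogen bonds.
## Every threshold is a named parameter of secstructParams(); chain ends with
## undefined geometry default to coil.

#' Thresholds for secondary-structure assignment
#'
#' @param helixDihedralMin,helixDihedralMax helical band for the signed
#'   virtual dihedral, degrees (default 30-70; an ideal Calpha-trace helix
#'   sits near 50).
#' @param helixD13Max maximum Calpha(i)-Calpha(i+3) distance for helix,
#'   Angstrom (default 6; ideal helix ~5.05).
#' @param extendedDihedralMin minimum |virtual dihedral| for the extended
#'   band, degrees (default 120; planar zigzag is 180).
#' @param hbondCutoff hydrogen-bond proxy: maximum pseudo-peptide-center
#'   distance, Angstrom (default 5.5; in-register strands 4.8 apart and
#'   helical i,i+3 center pairs ~4.7 both qualify).
#' @param minLadder minimum number of consecutive center-pair rungs for a
#'   beta ladder (default 2).
#' @param minSeqSep minimum |i-j| between pseudo-peptide centers of the same
#'   chain to count as a strand pairing (default 4, excludes local contacts).
#' @return named list of thresholds.
#' @export
secstructParams <- function(helixDihedralMin = 30, helixDihedralMax = 70,
                            helixD13Max = 6.0, extendedDihedralMin = 120,
                            hbondCutoff = 5.5, minLadder = 2L,
                            minSeqSep = 4L) {
  list(helixDihedralMin = helixDihedralMin,
       helixDihedralMax = helixDihedralMax,
       helixD13Max = helixD13Max,
       extendedDihedralMin = extendedDihedralMin,
       hbondCutoff = hbondCutoff, minLadder = as.integer(minLadder),
       minSeqSep = as.integer(minSeqSep))
}

## signed torsion angle (degrees) over four points
virtualDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## per-chain residue dihedrals; NA where undefined (residues 1, n-1, n)
chainDihedrals <- function(xyz) {
  n <- nrow(xyz)
  d <- rep(NA_real_, n)
  if (n >= 4L) {
    for (i in 2:(n - 2L)) {
      d[i] <- virtualDihedral(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ],
                              xyz[i + 2L, ])
    }
  }
  d
}

#' Assign beta/alpha/coil states to every residue of a frame
#'
#' A residue is alpha only if its local virtual-bond geometry is helical
#' (dihedral in the helical band and Calpha(i)-Calpha(i+3) close) AND its
#' pseudo-peptide center participates in an i,i+3 contact; beta only if
#' locally extended AND a flanking pseudo-peptide center pairs with another
#' strand's centers (different chain, or same chain at sequence separation
#' >= minSeqSep, under minimum image) in a ladder of at least
#' \code{minLadder} consecutive rungs; otherwise coil.  Chains shorter than
#' 5 residues are all coil.
#'
#' @param frame list of chain coordinate matrices.
#' @param box a [BoxSpec-class].
#' @param params thresholds from [secstructParams()].
#' @return list with \code{states} (chains x residues character matrix with
#'   entries "a", "b", "c") and \code{fractions} (chains x 3 matrix of
#'   per-chain f_alpha, f_beta, f_c; rows sum to 1).
#' @export
assignStates <- function(frame, box, params = secstructParams()) {
  nch <- length(frame)
  nres <- nrow(frame[[1L]])
  states <- matrix("c", nch, nres)

  ## pseudo-peptide centers per chain: (nres-1) x 3
  centers <- lapply(frame, function(xyz) {
    (xyz[-nrow(xyz), , drop = FALSE] + xyz[-1L, , drop = FALSE]) / 2
  })

  ## rungs: center a of chain ca pairs with center b of chain cb
  ## laddered[[chain]][center] = TRUE when the center sits in a >=minLadder
  ## run of consecutive rungs with partner indices stepping by +-1
  laddered <- lapply(frame, function(xyz) rep(FALSE, nrow(xyz) - 1L))
  if (nres >= 2L) {
    for (ca in seq_len(nch)) {
      for (cb in seq_len(nch)) {
        if (cb < ca) next
        D <- minImageCrossDist(centers[[ca]], centers[[cb]], box)
        if (ca == cb) {
          sep <- abs(outer(seq_len(nrow(D)), seq_len(ncol(D)), "-"))
          D[sep < params$minSeqSep] <- Inf
        }
        rung <- D < params$hbondCutoff
        if (!any(rung)) next
        for (s in c(1L, -1L)) {
          ## runs of consecutive rungs (a, b), (a+1, b+s), ...
          run <- rung
          idx <- which(run, arr.ind = TRUE)
          for (r in seq_len(nrow(idx))) {
            a <- idx[r, 1L]; b <- idx[r, 2L]
            len <- 1L
            while (a + len <= nrow(run) &&
                   b + s * len >= 1L && b + s * len <= ncol(run) &&
                   run[a + len, b + s * len]) len <- len + 1L
            if (len >= params$minLadder) {
              span <- a:(a + len - 1L)
              laddered[[ca]][span] <- TRUE
              bspan <- b + s * (0:(len - 1L))
              laddered[[cb]][bspan] <- TRUE
            }
          }
        }
      }
    }
  }

  for (ci in seq_len(nch)) {
    xyz <- frame[[ci]]
    if (nres < 5L) next                       # too short: all coil
    dih <- chainDihedrals(xyz)
    cen <- centers[[ci]]
    for (i in seq_len(nres)) {
      if (is.na(dih[i])) next
      helical_geom <- dih[i] >= params$helixDihedralMin &&
        dih[i] <= params$helixDihedralMax &&
        i + 3L <= nres &&
        sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2)) < params$helixD13Max
      if (helical_geom) {
        ## i,i+3 / i,i+4-type backbone contact through the peptide centers
        cand <- c(
          if (i + 3L <= nrow(cen)) sqrt(sum((cen[i, ] - cen[i + 3L, ])^2)),
          if (i - 1L >= 1L && i + 2L <= nrow(cen))
            sqrt(sum((cen[i - 1L, ] - cen[i + 2L, ])^2)))
        if (length(cand) && min(cand) < params$hbondCutoff) {
          states[ci, i] <- "a"
          next
        }
      }
      extended <- abs(dih[i]) > params$extendedDihedralMin
      if (extended) {
        flank <- c(i - 1L, i)
        flank <- flank[flank >= 1L & flank <= nrow(cen)]
        if (any(laddered[[ci]][flank])) states[ci, i] <- "b"
      }
    }
  }

  fractions <- t(apply(states, 1L, function(s) {
    c(alpha = mean(s == "a"), beta = mean(s == "b"), coil = mean(s == "c"))
  }))
  if (nch == 1L) {
    fractions <- matrix(fractions, 1L, 3L,
                        dimnames = list(NULL, c("alpha", "beta", "coil")))
  }
  list(states = states, fractions = fractions)
}

#' Per-chain secondary-structure fractions
#'
#' @param assignment result of [assignStates()].
#' @return chains x 3 matrix of (f_alpha, f_beta, f_c); rows sum to 1.
#' @export
stateFractions <- function(assignment) assignment$fractions

#' Chain-averaged state fractions per frame for a whole ensemble
#'
#' For each frame, the per-chain fractions are averaged over chains, giving
#' one (f_alpha, f_beta, f_c) triple per snapshot ready for ensemble
#' reweighting.
#'
#' @param ensemble an [EnsembleSet-class].
#' @param params thresholds from [secstructParams()].
#' @return numeric matrix nFrames x 3 (columns alpha, beta, coil).
#' @export
stateFractionMatrix <- function(ensemble, params = secstructParams()) {
  n <- nFrames(ensemble)
  out <- matrix(0, n, 3L, dimnames = list(NULL, c("alpha", "beta", "coil")))
  for (i in seq_len(n)) {
    fr <- assignStates(ensemble@coords[[i]], ensemble@box, params)$fractions
    out[i, ] <- colMeans(fr)
  }
  out
}
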