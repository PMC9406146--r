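## Physical constants and default parameter sets.

#' Boltzmann constant in kcal/(mol K)
#'
#' Default energy unit of the package is kcal/mol; all beta = 1/(kB T)
#' factors use this value unless a different \code{kB} is passed explicitly.
#'
#' @format A length-one numeric.
#' @export
BOLTZMANN_KCAL <- 0.0019872041

## Avogadro constant (exact SI value), 1/mol
AVOGADRO <- 6.02214076e23

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices over the 20 canonical amino acids
#' (one-letter codes).  Positive values are hydrophobic.  This is the default
#' scale for [computeGravy()].
#'
#' @return Named numeric vector of length 20.
#' @examples
#' kyteDoolittle()[["W"]]
#' @export
kyteDoolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Default pKa set for net-charge estimation
#'
#' pKa values for the ionizable side chains (D, E, C, Y, H, K, R) and the
#' free alpha-amino ("nterm") and alpha-carboxyl ("cterm") groups, with a
#' flag marking each group basic (protonated form charged +1) or acidic
#' (deprotonated form charged -1).  The set is injectable everywhere a charge
#' is computed, so alternative conventions can be swapped in.
#'
#' @return A data.frame with columns \code{group}, \code{pKa}, \code{basic}.
#' @examples
#' defaultPka()
#' @export
defaultPka <- function() {
  data.frame(
    group = c("D", "E", "C", "Y", "H", "K", "R", "nterm", "cterm"),
    pKa   = c(3.65, 4.25, 8.3, 10.07, 6.0, 10.53, 12.48, 9.0, 3.6),
    basic = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default replica-exchange temperature ladder
#'
#' The 12-rung ladder (Kelvin) used throughout: 260-370 K, spaced more densely
#' around the melting region.
#'
#' @return Strictly increasing numeric vector of length 12.
#' @export
defaultLadder <- function() {
  c(260, 272, 279, 284, 288, 291, 294, 298, 308, 322, 341, 370)
}

#' Round half away from zero
#'
#' Rounding convention used for comparisons against printed reference
#' tables (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' roundHalfAway(-1.0545, 3)   # -1.055
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
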