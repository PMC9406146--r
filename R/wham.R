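## Binless WHAM over the multi-temperature ensemble.
##
## Self-consistency, with beta_k = 1/(kB T_k) and counts N_k per ladder rung:
##   exp(-f_k) = sum_i exp(-beta_k E_i) / sum_l N_l exp(f_l - beta_l E_i)
## weights at a target temperature T (beta = 1/(kB T)):
##   w_i(T) proportional to exp(-beta E_i) / sum_l N_l exp(f_l - beta_l E_i)
## All exponentials are evaluated in log space; the gauge is f_1 = 0.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## column-wise log-sum-exp of a small-row-count matrix
colLogSumExp <- function(M) {
  cmax <- M[1L, ]
  if (nrow(M) > 1L) for (k in 2:nrow(M)) cmax <- pmax(cmax, M[k, ])
  cmax + log(colSums(exp(M - rep(cmax, each = nrow(M)))))
}

#' Solve the binless WHAM equations
#'
#' Self-consistent iteration for the dimensionless free energies f_k of each
#' ladder temperature, stabilised with log-sum-exp.  Convergence is declared
#' when max|delta f_k| drops below \code{tol}.  A single-temperature input is
#' degenerate (uniform weights) and returns with a warning.
#'
#' @param ensemble an [EnsembleSet-class] (only energies, temperature indices
#'   and the ladder are consumed).
#' @param tol convergence tolerance on max|delta f| (default 1e-10).
#' @param maxIter iteration cap (default 100000).
#' @param kB Boltzmann constant in the ensemble's energy unit
#'   (default [BOLTZMANN_KCAL]).
#' @return A [WeightTable-class].
#' @export
solveWham <- function(ensemble, tol = 1e-10, maxIter = 100000L,
                      kB = BOLTZMANN_KCAL) {
  E <- energies(ensemble)
  ti <- temperatureIndex(ensemble)
  temps <- ladder(ensemble)
  if (any(!is.finite(E))) stop("energies must be finite")
  Nk <- tabulate(ti, nbins = length(temps))
  used <- which(Nk > 0L)
  if (length(used) < 2L) {
    warning("single-temperature input: degenerate WHAM, uniform weights")
    if (length(used) < 1L) stop("ensemble has no samples")
    f <- rep(0, length(temps))
    beta1 <- 1 / (kB * temps[used])
    return(new("WeightTable", freeEnergies = f, ladder = temps,
               energies = E, logDenom = log(Nk[used]) - beta1 * E,
               kB = kB, residual = 0, iterations = 0L))
  }
  beta <- 1 / (kB * temps[used])
  logN <- log(Nk[used])
  B <- -outer(beta, E)                 # K x N matrix of -beta_k E_i
  f <- rep(0, length(used))
  iter <- 0L
  resid <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    logD <- colLogSumExp((logN + f) + B)       # sum_l N_l exp(f_l - b_l E_i)
    fnew <- -vapply(seq_along(used),
                    function(k) logSumExp(B[k, ] - logD), numeric(1))
    fnew <- fnew - fnew[1L]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop("WHAM did not converge in ", maxIter,
         " iterations (residual ", signif(resid, 3), ")")
  logD <- colLogSumExp((logN + f) + B)
  fAll <- rep(NA_real_, length(temps))
  fAll[used] <- f
  new("WeightTable", freeEnergies = fAll, ladder = temps, energies = E,
      logDenom = logD, kB = kB, residual = resid, iterations = iter)
}

#' @describeIn snapshotWeights normalized binless-WHAM weights at temperature
#'   \code{temperature} (Kelvin)
#' @export
setMethod("snapshotWeights", "WeightTable", function(x, temperature) {
  if (length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a positive scalar")
  beta <- 1 / (x@kB * temperature)
  lw <- -beta * x@energies - x@logDenom
  w <- exp(lw - logSumExp(lw))
  w / sum(w)
})

#' WHAM-averaged temperature profile of an observable
#'
#' Evaluates sum_i w_i(T) v_i on a temperature grid, where v_i is one value
#' per snapshot (an oligomer fraction, a chain-averaged state fraction, ...).
#'
#' @param weights a [WeightTable-class].
#' @param perFrameValues numeric vector, one value per snapshot.
#' @param grid temperature grid in Kelvin (default: the ladder).
#' @param label profile label.
#' @return A [TemperatureProfile-class].
#' @export
ensembleAverage <- function(weights, perFrameValues, grid = ladder(weights),
                            label = "") {
  if (length(perFrameValues) != length(weights@energies))
    stop("need one value per snapshot (", length(weights@energies),
         "), got ", length(perFrameValues))
  vals <- vapply(grid, function(Tt) {
    sum(snapshotWeights(weights, Tt) * perFrameValues)
  }, numeric(1))
  temperatureProfile(grid, vals, label)
}

#' Heat-capacity profile from energy fluctuations
#'
#' C_v(T) = (<E^2>_T - <E>_T^2) / (kB T^2) with <.>_T the WHAM average over
#' the ensemble; reported per system in the declared energy unit per Kelvin.
#'
#' @param weights a [WeightTable-class].
#' @param grid temperature grid in Kelvin (default: the ladder).
#' @return A [TemperatureProfile-class].
#' @export
heatCapacity <- function(weights, grid = ladder(weights)) {
  E <- weights@energies
  vals <- vapply(grid, function(Tt) {
    w <- snapshotWeights(weights, Tt)
    m1 <- sum(w * E)
    v <- sum(w * (E - m1)^2)
    v / (weights@kB * Tt^2)
  }, numeric(1))
  temperatureProfile(grid, vals, "Cv")
}

## Independent route to the same estimator: minimise the convex UWHAM/MBAR
## objective  phi(f) = sum_i log sum_l N_l exp(f_l - beta_l E_i) - sum_k N_k f_k
## over f (gauge f_1 = 0) with BFGS.  Used as a cross-check in the tests;
## exported so the comparison is reproducible by users.

#' Free energies by direct likelihood optimisation (cross-check)
#'
#' Minimises the convex multistate-reweighting objective whose stationary
#' point is the binless WHAM solution, using BFGS instead of self-consistent
#' iteration.  Serves as an independent numerical route for validating
#' [solveWham()].
#'
#' @inheritParams solveWham
#' @return numeric free energies per ladder temperature (gauge: first
#'   populated rung = 0).
#' @export
whamFreeEnergiesOptim <- function(ensemble, kB = BOLTZMANN_KCAL) {
  E <- energies(ensemble)
  ti <- temperatureIndex(ensemble)
  temps <- ladder(ensemble)
  Nk <- tabulate(ti, nbins = length(temps))
  used <- which(Nk > 0L)
  beta <- 1 / (kB * temps[used])
  logN <- log(Nk[used])
  B <- -outer(beta, E)
  K <- length(used)
  obj <- function(th) {
    f <- c(0, th)
    sum(colLogSumExp((logN + f) + B)) - sum(Nk[used] * f)
  }
  grd <- function(th) {
    f <- c(0, th)
    logD <- colLogSumExp((logN + f) + B)
    g <- vapply(seq_len(K), function(k) {
      Nk[used][k] * sum(exp(f[k] + B[k, ] - logD)) - Nk[used][k]
    }, numeric(1))
    g[-1L]
  }
  fit <- stats::optim(rep(0, K - 1L), obj, grd, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  ## restart once from the solution: BFGS can stall just above the
  ## tolerance on nearly flat convex objectives
  fit <- stats::optim(fit$par, obj, grd, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  fAll <- rep(NA_real_, length(temps))
  fAll[used] <- c(0, fit$par)
  fAll
}
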