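## Melting statistics: sigmoid midpoints, inflection points, heat-capacity
## peaks, window-convergence diagnostics and the descriptor regression.

#' Midpoint temperature of a sigmoidal melting profile
#'
#' Fits the logistic f(T) = 1 / (1 + exp((T - Tm) / s)) by least squares and
#' returns Tm.  If the fit fails to converge, falls back (with a warning) to
#' the monotone-interpolated 0.5 crossing.  The profile must span the 0.5
#' crossing; otherwise an out-of-range error says whether the midpoint lies
#' above or below the grid.
#'
#' @param profile a [TemperatureProfile-class] of a fraction in [0, 1],
#'   decreasing with temperature.
#' @param method "fit" (logistic least squares, default) or "crossing"
#'   (interpolated 0.5 crossing); the two agree within ~1 K on clean
#'   sigmoids.
#' @return Midpoint temperature in Kelvin.
#' @export
midpointTemperature <- function(profile, method = c("fit", "crossing")) {
  method <- match.arg(method)
  Tg <- profile@grid
  v <- profile@values
  if (min(v) > 0.5)
    stop("profile never crosses 0.5: midpoint above grid")
  if (max(v) < 0.5)
    stop("profile never crosses 0.5: midpoint below grid")
  cross <- crossingTemperature(Tg, v, 0.5)
  if (method == "crossing") return(cross)
  start_s <- max((max(Tg) - min(Tg)) / 20, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ 1 / (1 + exp((Tg - Tm) / s)),
                      start = list(Tm = cross, s = start_s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic fit failed; returning interpolated 0.5 crossing")
    return(cross)
  }
  unname(coef(fit)[["Tm"]])
}

## linear interpolation of the level crossing on a monotone-smoothed curve
crossingTemperature <- function(Tg, v, level) {
  vm <- cummin(rev(cummax(rev(v))))  # monotone non-increasing envelope
  idx <- which(vm[-length(vm)] >= level & vm[-1L] < level)
  if (!length(idx)) {
    idx <- which.min(abs(vm - level))
    return(Tg[idx])
  }
  i <- idx[1L]
  if (vm[i] == vm[i + 1L]) return((Tg[i] + Tg[i + 1L]) / 2)
  Tg[i] + (vm[i] - level) / (vm[i] - vm[i + 1L]) * (Tg[i + 1L] - Tg[i])
}

#' Inflection temperature of a scaled sigmoidal profile
#'
#' Fits a / (1 + exp((T - Ti) / s)) + b and returns Ti (the point of maximum
#' |slope|).  Intended for profiles, such as the beta-structure fraction,
#' that decay with temperature but never reach 1.  When the fit fails, or
#' when no dominant inflection exists, a derivative-based estimate of a
#' lightly smoothed profile is returned with a warning; exact slope ties
#' break to the middle of the tied range.
#'
#' @param profile a [TemperatureProfile-class] with at least 5 grid points.
#' @return Inflection temperature in Kelvin.
#' @export
inflectionTemperature <- function(profile) {
  Tg <- profile@grid
  v <- profile@values
  if (length(Tg) < 5L) stop("need at least 5 grid points")
  slope <- diff(v) / diff(Tg)
  mid <- (Tg[-length(Tg)] + Tg[-1L]) / 2
  Ti0 <- mid[which.max(abs(slope))]
  a0 <- max(v) - min(v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a / (1 + exp((Tg - Ti) / s)) + b,
                      start = list(a = a0, b = min(v), Ti = Ti0,
                                   s = max((max(Tg) - min(Tg)) / 20, 1)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ## a dominant inflection means a genuine sigmoid inside the window:
  ## positive amplitude, Ti on the grid, and a transition width well below
  ## the grid span (otherwise the curve is indistinguishable from a line)
  ok <- !is.null(fit) &&
    coef(fit)[["a"]] > 0 &&
    abs(coef(fit)[["s"]]) <= (max(Tg) - min(Tg)) / 3 &&
    coef(fit)[["Ti"]] >= min(Tg) && coef(fit)[["Ti"]] <= max(Tg)
  if (ok) return(unname(coef(fit)[["Ti"]]))
  warning("no dominant sigmoidal inflection; derivative-based estimate")
  ## moving-average smoothing, then argmax |slope| with mid-range tie-break
  vs <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  vs[1L] <- v[1L]; vs[length(v)] <- v[length(v)]
  slope <- abs(diff(as.numeric(vs)) / diff(Tg))
  tied <- which(abs(slope - max(slope)) <= 1e-12 * max(1, max(slope)))
  mid[tied[ceiling(length(tied) / 2)]]
}

#' Heat-capacity peak temperatures
#'
#' Local maxima of the profile with topographic prominence above
#' \code{minProminence} times the profile range, sorted by peak height
#' descending.  A monotone profile has no peaks.
#'
#' @param profile a [TemperatureProfile-class] with at least 5 grid points.
#' @param minProminence minimum prominence as a fraction of the value range
#'   (default 0.05).
#' @return numeric vector of peak temperatures (possibly empty).
#' @export
cvPeaks <- function(profile, minProminence = 0.05) {
  Tg <- profile@grid
  v <- profile@values
  if (length(Tg) < 5L) stop("need at least 5 grid points")
  rng <- diff(range(v))
  if (rng == 0) return(numeric(0))
  n <- length(v)
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(numeric(0))
  prom <- vapply(peaks, function(i) {
    left <- v[1:i]
    higher_l <- which(left > v[i])
    base_l <- if (length(higher_l)) min(v[max(higher_l):i]) else min(left)
    right <- v[i:n]
    higher_r <- which(right > v[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    v[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- peaks[prom >= minProminence * rng]
  if (!length(keep)) return(numeric(0))
  keep <- keep[order(v[keep], decreasing = TRUE)]
  Tg[keep]
}

#' Window-convergence diagnostic for f8 profiles
#'
#' For consecutive simulation windows, the RMS deviation sigma_f8 of each
#' window's octamer-fraction profile from the final window's is computed over
#' the shared temperature grid (the last window is excluded from the series
#' by construction).  The run counts as converged when sigma_f8 has stopped
#' decreasing: the final two values differ by less than \code{relTol}
#' relative, the tail is non-decreasing, or the series is identically zero.
#'
#' @param perWindowProfiles list of [TemperatureProfile-class], one per
#'   window in time order (>= 3 windows).
#' @param relTol relative tolerance of the tail rule (default 0.1).
#' @return list with \code{sigma} (length windows-1) and \code{converged}.
#' @export
windowConvergence <- function(perWindowProfiles, relTol = 0.1) {
  W <- length(perWindowProfiles)
  if (W < 3L) stop("need at least 3 windows")
  grids <- lapply(perWindowProfiles, profileGrid)
  for (w in 2:W) {
    if (!isTRUE(all.equal(grids[[1L]], grids[[w]])))
      stop("window ", w, " is on a different temperature grid")
  }
  last <- profileValues(perWindowProfiles[[W]])
  sigma <- vapply(seq_len(W - 1L), function(w) {
    sqrt(mean((profileValues(perWindowProfiles[[w]]) - last)^2))
  }, numeric(1))
  s_prev <- sigma[W - 2L]
  s_last <- sigma[W - 1L]
  converged <- (s_prev == 0 && s_last == 0) ||
    s_last >= s_prev ||
    abs(s_last - s_prev) <= relTol * max(s_prev, s_last)
  list(sigma = sigma, converged = converged)
}

#' Ordinary least-squares correlation of two vectors
#'
#' Returns the OLS slope and intercept of y on x, the Pearson correlation
#' coefficient R, and the residual standard deviation with an n - 2
#' denominator.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{slope}, \code{intercept}, \code{R},
#'   \code{sigmaResidual}.
#' @export
linearCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with at least 3 points")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       R = stats::cor(x, y),
       sigmaResidual = sqrt(sum(resid(fit)^2) / (length(x) - 2L)))
}

#' Melting summary of an ensemble
#'
#' Convenience wrapper: runs WHAM, builds the octamer (largest-oligomer),
#' beta-fraction and heat-capacity profiles on a grid, and extracts T8m, the
#' beta inflection temperature and the Cv peak temperatures.
#'
#' @param ensemble an [EnsembleSet-class] (already windowed).
#' @param grid temperature grid (default: 1 K steps across the ladder span).
#' @param cutoff association cutoff (default 7 Angstrom).
#' @param params secondary-structure thresholds.
#' @param kB Boltzmann constant in the energy unit.
#' @return list with T8m, TiBeta, cvPeaks, and the three profiles.
#' @export
meltingSummary <- function(ensemble, grid = NULL, cutoff = 7.0,
                           params = secstructParams(),
                           kB = BOLTZMANN_KCAL) {
  if (is.null(grid))
    grid <- seq(min(ladder(ensemble)), max(ladder(ensemble)), by = 1)
  wt <- solveWham(ensemble, kB = kB)
  fm <- oligomerFractionMatrix(ensemble, cutoff)
  fs <- stateFractionMatrix(ensemble, params)
  n <- ensemble@nChains
  f8 <- ensembleAverage(wt, fm[, n], grid, label = paste0("f", n))
  fb <- ensembleAverage(wt, fs[, "beta"], grid, label = "f_beta")
  cv <- heatCapacity(wt, grid)
  list(T8m = midpointTemperature(f8),
       TiBeta = suppressWarnings(inflectionTemperature(fb)),
       cvPeaks = cvPeaks(cv),
       f8Profile = f8, betaProfile = fb, cvProfile = cv,
       weights = wt)
}
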