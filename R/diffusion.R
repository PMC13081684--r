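# Lateral diffusion: MSD curves and 2D diffusion coefficients.
#
# The ensemble-origin estimator is the literal definition
#   MSD(t) = (1/N) sum_j |r_j(t) - r_j(0)|^2,
# the average over trajectories of the squared displacement from the first
# frame. The time-averaged estimator additionally averages over all time
# origins within each trajectory and is the default (lower variance; both
# are tested against brute force). In two dimensions D = MSD(t) / (4 t) in
# the long-time limit, so D is slope/4 of a linear MSD fit.

#' Mean-squared-displacement curve of 2D trajectories
#'
#' @param xy one \code{n x 2} matrix of unwrapped in-plane positions, or a
#'   list of such matrices (trajectories must share length and time step).
#' @param dt frame spacing (ns); ignored when \code{times} is given.
#' @param times optional explicit frame times (ns); must be uniform --
#'   non-uniform sampling is a hard error, never silently interpolated.
#' @param mode \code{"time_averaged"} (all origins; default) or
#'   \code{"ensemble_origin"} (origins at t = 0 only).
#' @param maxLagFraction largest lag as a fraction of the trajectory
#'   duration.
#' @return an \linkS4class{MSDCurve}.
#' @export
msdCurve <- function(xy, dt = 1, times = NULL,
                     mode = c("time_averaged", "ensemble_origin"),
                     maxLagFraction = 0.5) {
  mode <- match.arg(mode)
  if (!is.list(xy)) xy <- list(xy)
  xy <- lapply(xy, as.matrix)
  n <- nrow(xy[[1]])
  if (n < 2L) stop("need >= 2 frames")
  if (any(vapply(xy, nrow, integer(1)) != n))
    stop("all trajectories must have the same number of frames")
  if (!is.null(times)) {
    if (length(times) != n) stop("times length mismatch")
    steps <- diff(times)
    if (max(steps) - min(steps) > 1e-8 * max(abs(steps)))
      stop("resampling error: non-uniform time step; resample explicitly before computing MSDs")
    dt <- steps[1]
  }
  duration <- (n - 1L) * dt
  K <- max(1L, floor(maxLagFraction * (n - 1L)))
  msd <- numeric(K + 1L); npairs <- numeric(K + 1L)
  npairs[1] <- length(xy) * if (mode == "time_averaged") n else 1L
  for (k in seq_len(K)) {
    s <- 0; cnt <- 0L
    for (traj in xy) {
      if (mode == "time_averaged") {
        d <- traj[(1L + k):n, , drop = FALSE] - traj[1L:(n - k), , drop = FALSE]
        s <- s + sum(d * d)
        cnt <- cnt + (n - k)
      } else {
        d <- traj[1L + k, ] - traj[1L, ]
        s <- s + sum(d * d)
        cnt <- cnt + 1L
      }
    }
    msd[k + 1L] <- s / cnt
    npairs[k + 1L] <- cnt
  }
  new("MSDCurve", lags = (0:K) * dt, msd = msd, nPairs = npairs,
      mode = mode, duration = duration)
}

#' Fit a 2D diffusion coefficient to an MSD curve
#'
#' Least-squares line through the MSD over a lag window; in two dimensions
#' \code{D = slope / 4}. The default window is 2--20 percent of the
#' trajectory duration, avoiding both the short-lag regime and the noisy
#' long-lag tail, and the fit is origin-free (an intercept absorbs
#' localization-like offsets; set \code{throughOrigin = TRUE} to force the
#' line through zero). A negative fitted slope is clipped to D = 0 with a
#' warning.
#'
#' @param curve an \linkS4class{MSDCurve}.
#' @param fitWindow lag window in ns, \code{c(lagMin, lagMax)}; default
#'   \code{c(0.02, 0.20) * duration}.
#' @param throughOrigin force a zero intercept.
#' @return a \linkS4class{DiffusionEstimate}.
#' @export
fitDiffusion <- function(curve, fitWindow = NULL, throughOrigin = FALSE) {
  stopifnot(is(curve, "MSDCurve"))
  if (is.null(fitWindow)) fitWindow <- c(0.02, 0.20) * curve@duration
  sel <- curve@lags >= fitWindow[1] & curve@lags <= fitWindow[2]
  if (sum(sel) < 2L)
    stop("need >= 2 lag points inside the fit window [",
         fitWindow[1], ", ", fitWindow[2], "] ns")
  lag <- curve@lags[sel]; msd <- curve@msd[sel]
  if (all(msd == 0)) {
    return(new("DiffusionEstimate", D = 0, stderr = 0,
               fitWindow = as.numeric(fitWindow), rSquared = 1,
               log10D = NA_real_))
  }
  fit <- if (throughOrigin) stats::lm(msd ~ lag + 0) else stats::lm(msd ~ lag)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact lines
  co <- stats::coef(sm)
  slope <- co["lag", "Estimate"]; se <- co["lag", "Std. Error"]
  r2 <- sm$r.squared
  D <- slope / 4
  if (D < 0) {
    warning("negative MSD slope; clipping D to 0")
    D <- 0
  }
  new("DiffusionEstimate", D = D, stderr = se / 4,
      fitWindow = as.numeric(fitWindow), rSquared = r2,
      log10D = if (D > 0) log10(D) else NA_real_)
}

#' Per-replica diffusion coefficients from unwrapped 2D paths
#'
#' @param xyList list of unwrapped \code{n x 2} trajectories.
#' @param dt frame spacing (ns).
#' @param mode MSD mode (\code{\link{msdCurve}}).
#' @param fitWindow lag window (ns); default 2--20 percent of duration.
#' @param maxLagFraction see \code{\link{msdCurve}}.
#' @return list of \linkS4class{DiffusionEstimate}, one per trajectory.
#' @export
estimateDiffusion <- function(xyList, dt = 1, mode = "time_averaged",
                              fitWindow = NULL, maxLagFraction = 0.25) {
  if (!is.list(xyList)) xyList <- list(xyList)
  lapply(xyList, function(xy)
    fitDiffusion(msdCurve(xy, dt = dt, mode = mode,
                          maxLagFraction = maxLagFraction),
                 fitWindow = fitWindow))
}

#' Summarize per-replica diffusivities by condition
#'
#' Per condition: replica count, mean D, standard error of the mean over
#' replicas (NA for a single replica), and quartiles of log10 D for box
#' plots. The full long-format table (condition, replica, D, log10 D) is
#' attached as attribute \code{detail}. Empty conditions are dropped with
#' a warning.
#'
#' @param estimates list of \linkS4class{DiffusionEstimate} or numeric
#'   vector of D values.
#' @param grouping condition label per estimate.
#' @return data.frame with one row per condition, columns \code{condition},
#'   \code{n}, \code{meanD}, \code{sem}, \code{log10Q1}, \code{log10Median},
#'   \code{log10Q3}.
#' @export
summarizeDiffusivity <- function(estimates, grouping) {
  D <- if (is.numeric(estimates)) estimates
       else vapply(estimates, function(e) e@D, numeric(1))
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == length(D))
  keep <- !is.na(D)
  if (!all(keep)) warning("dropping ", sum(!keep), " NA estimates")
  D <- D[keep]; grouping <- grouping[keep]
  if (!length(D)) stop("no estimates to summarize")
  conds <- unique(grouping)
  rows <- lapply(conds, function(cond) {
    d <- D[grouping == cond]
    lg <- log10(d[d > 0])
    q <- if (length(lg)) stats::quantile(lg, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(condition = cond, n = length(d), meanD = mean(d),
               sem = if (length(d) >= 2L) stats::sd(d) / sqrt(length(d)) else NA_real_,
               log10Q1 = q[1], log10Median = q[2], log10Q3 = q[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "detail") <- data.frame(
    condition = grouping,
    replica = stats::ave(seq_along(D), grouping, FUN = seq_along),
    D = D, log10D = ifelse(D > 0, log10(D), NA_real_))
  out
}
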