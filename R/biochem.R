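#' Fraction of receptor bound from a supernatant measurement
#'
#' In the supernatant-depletion assay, activator-coated beads pull the
#' Arp2/3 complex out of solution; the fraction bound is the depleted share
#' of the total: `F_b = (theta0 - supernatant) / theta0`, clipped to
#' \[0, 1\].
#'
#' @param receptor_total total receptor concentration theta0 (> 0).
#' @param supernatant receptor concentration remaining in the supernatant
#'   (same units).
#' @return fraction bound in \[0, 1\].
#' @export
fraction_bound <- function(receptor_total, supernatant) {
  if (any(receptor_total <= 0)) stop("receptor_total must be > 0")
  if (any(supernatant < 0)) stop("supernatant must be >= 0")
  pmin(pmax((receptor_total - supernatant) / receptor_total, 0), 1)
}

#' Quadratic tight-binding (ligand-depletion) bound fraction
#'
#' Predicted fraction of receptor bound when ligand depletion cannot be
#' neglected (total concentrations comparable to K_D):
#' `([L]+[R]+K_D - sqrt(([L]+[R]+K_D)^2 - 4 [L][R])) / (2 [R])`.
#' Continuous in all arguments; reduces to the hyperbola `L / (L + K_D)`
#' in the ligand-excess limit R -> 0.
#'
#' @param L total ligand concentration(s).
#' @param R total receptor concentration (> 0).
#' @param K_D dissociation constant (>= 0); all in the same units.
#' @return bound fraction(s) in \[0, 1\].
#' @export
quadratic_fraction <- function(L, R, K_D) {
  if (any(L < 0) || any(R <= 0) || any(K_D < 0))
    stop("require L >= 0, R > 0, K_D >= 0")
  s <- L + R + K_D
  disc <- pmax(s^2 - 4 * L * R, 0)   # analytically >= 0; guard rounding
  (s - sqrt(disc)) / (2 * R)
}

#' Fit K_D to fraction-bound titration data
#'
#' Nonlinear least squares of the quadratic tight-binding model over K_D
#' only, with the receptor total fixed at its known design concentration.
#' Multi-start on K_D keeps the best sum of squared errors.
#'
#' @param measurements data frame with columns `ligand_uM` and
#'   `fraction_bound`.
#' @param receptor_total fixed total receptor concentration (uM).
#' @param starts,bounds K_D starting values and box bounds (uM).
#' @return list of class `binding_fit`: `K_D` (uM), `K_D_se`,
#'   `receptor_total`, `residuals`, `sse`, `at_bound` flag.
#' @export
fit_kd <- function(measurements, receptor_total = 0.05,
                   starts = c(0.01, 0.1, 1), bounds = c(1e-6, 1e3)) {
  stopifnot(is.data.frame(measurements),
            all(c("ligand_uM", "fraction_bound") %in% names(measurements)))
  if (nrow(measurements) < 4)
    stop("need at least 4 titration points to fit K_D")
  L <- measurements$ligand_uM
  fb <- measurements$fraction_bound
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fb ~ quadratic_fraction(L, receptor_total, K_D),
                        start = list(K_D = s0),
                        lower = bounds[1], upper = bounds[2],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("K_D fit failed to converge from all starts")
  kd <- unname(stats::coef(best$fit)[["K_D"]])
  se <- tryCatch(unname(summary(best$fit)$coefficients["K_D", "Std. Error"]),
                 error = function(e) NA_real_)
  at_bound <- kd <= bounds[1] * 1.001 || kd >= bounds[2] * 0.999
  if (at_bound) warning("fitted K_D is pinned at a bound")
  structure(list(K_D = kd, K_D_se = se, receptor_total = receptor_total,
                 residuals = unname(stats::residuals(best$fit)),
                 sse = best$sse, at_bound = at_bound),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_D = %.4g uM (se %.3g), R fixed at %.4g uM\n",
              x$K_D, x$K_D_se, x$receptor_total))
  invisible(x)
}

#' Time to reach binding equilibrium
#'
#' Earliest observed time after which the signal stays within 5% of its
#' final value for the rest of the series (so a mono-exponential approach
#' with time constant tau plateaus at about 3 tau). A series whose approach
#' is substantially non-monotone is flagged with a warning and an
#' attribute.
#'
#' @param time_min observation times (minutes), increasing.
#' @param signal supernatant signal at those times.
#' @param tolerance relative band around the final value (default 0.05).
#' @return plateau time (minutes), with attribute `nonmonotone`.
#' @export
equilibration_time <- function(time_min, signal, tolerance = 0.05) {
  stopifnot(length(time_min) == length(signal))
  if (length(time_min) < 4)
    stop("need at least 4 time points to locate a plateau")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("time points must be strictly increasing")
  final <- signal[length(signal)]
  ok <- abs(signal - final) <= tolerance * abs(final)
  # earliest index from which every later point is inside the band
  inside_tail <- rev(cumall(rev(ok)))
  idx <- which(inside_tail)[1]
  # monotonicity check against the overall direction of approach
  dirn <- sign(final - signal[1])
  excursion <- if (dirn >= 0) max(cummax(signal) - signal) else
    max(signal - cummin(signal))
  nonmono <- excursion > tolerance * abs(final)
  if (nonmono)
    warning("signal is non-monotone beyond the plateau tolerance; ",
            "equilibration time may be unreliable")
  structure(time_min[idx], nonmonotone = nonmono)
}

cumall <- function(x) cumsum(!x) == 0

#' Convert a fluorescence trace to polymer concentration
#'
#' Anchors the trace linearly between a baseline (no polymer) and a plateau
#' (fully polymerized) fluorescence:
#' `polymer(t) = (F(t) - baseline) / (plateau - baseline) * pool`.
#'
#' @param trace data frame with `time_s` and `rfu`.
#' @param baseline,plateau anchor fluorescence values (RFU); `plateau` may
#'   be `NULL` to use the mean of the final 5% of the trace.
#' @param polymerizable_nM size of the polymerizable actin pool (nM).
#' @return the trace with a `polymer_nM` column.
#' @export
convert_rfu_to_polymer <- function(trace, baseline, plateau = NULL,
                                   polymerizable_nM) {
  stopifnot(all(c("time_s", "rfu") %in% names(trace)))
  if (is.null(plateau)) {
    k <- max(1L, ceiling(0.05 * nrow(trace)))
    plateau <- mean(utils::tail(trace$rfu, k))
  }
  if (plateau <= baseline) stop("plateau must exceed baseline")
  trace$polymer_nM <- (trace$rfu - baseline) / (plateau - baseline) *
    polymerizable_nM
  trace
}

#' Maximum polymerization rate (MPR) of a time course
#'
#' The slope is evaluated at every time point as the least-squares slope in
#' a sliding window (default 5 points); the MPR is the maximum of those
#' local slopes. On a noiseless logistic time course the estimate is within
#' 1% of the analytic maximum `r * P_total / 4`.
#'
#' @param trace data frame with `time_s` and a value column.
#' @param value column to differentiate (default `polymer_nM`, falling back
#'   to `rfu`).
#' @param window sliding-window length in points (>= 2).
#' @return list: `mpr` (units of value per second), `t_at_max` (s), and the
#'   per-window `slopes` data frame. A non-positive MPR (monotone
#'   decreasing trace) triggers a warning.
#' @export
max_polymerization_rate <- function(trace, value = NULL, window = 5L) {
  stopifnot("time_s" %in% names(trace), window >= 2L)
  if (is.null(value))
    value <- if ("polymer_nM" %in% names(trace)) "polymer_nM" else "rfu"
  y <- trace[[value]]
  t <- trace$time_s
  n <- length(y)
  if (n < window) stop("trace shorter than the slope window")
  nw <- n - window + 1L
  slopes <- numeric(nw); mids <- numeric(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- y[idx]
    tc <- tt - mean(tt)
    slopes[i] <- sum(tc * yy) / sum(tc^2)
    mids[i] <- mean(tt)
  }
  k <- which.max(slopes)
  mpr <- slopes[k]
  if (mpr <= 0)
    warning("maximum local slope is non-positive (decreasing trace)")
  list(mpr = mpr, t_at_max = mids[k],
       slopes = data.frame(time_s = mids, slope = slopes))
}

#' Fit an MPR-versus-activator saturation curve
#'
#' Least-squares fit of `Y = Ymax * [Las17] / (K1/2 + [Las17]) + Yo` to a
#' titration of maximum polymerization rates against activator
#' concentration, with non-negative bounds and multi-start on K1/2.
#'
#' @param points data frame with columns `las17_nM` and `mpr_nM_per_s`.
#' @return list of class `titration_fit`: `Ymax`, `K_half` (nM), `Yo`,
#'   `residuals`, `sse`, `unidentifiable` flag (set when the response is
#'   flat and K1/2 is meaningless).
#' @export
fit_mpr_titration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("las17_nM", "mpr_nM_per_s") %in% names(points)))
  if (nrow(points) < 4)
    stop("need at least 4 titration points")
  L <- points$las17_nM
  Y <- points$mpr_nM_per_s
  if (diff(range(Y)) <= 1e-10 * max(abs(Y), 1)) {
    warning("flat titration: Ymax ~ 0, K1/2 unidentifiable")
    return(structure(list(Ymax = 0, K_half = NA_real_, Yo = mean(Y),
                          residuals = Y - mean(Y), sse = sum((Y - mean(Y))^2),
                          unidentifiable = TRUE),
                     class = "titration_fit"))
  }
  yo0 <- max(min(Y), 0)
  ymax0 <- max(max(Y) - yo0, 1e-9)
  lpos <- L[L > 0]
  k_starts <- if (length(lpos)) stats::median(lpos) * c(0.1, 1, 10) else 1
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ Ymax * L / (K_half + L) + Yo,
                        start = list(Ymax = ymax0, K_half = k0, Yo = yo0),
                        lower = c(0, 1e-9, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("titration fit failed to converge")
  co <- stats::coef(best$fit)
  unident <- co[["Ymax"]] < 1e-6 * max(abs(Y), 1) ||
    stats::sd(Y) < 1e-12 * max(abs(Y), 1)
  if (unident) warning("flat titration: Ymax ~ 0, K1/2 unidentifiable")
  structure(list(Ymax = unname(co[["Ymax"]]),
                 K_half = unname(co[["K_half"]]),
                 Yo = unname(co[["Yo"]]),
                 residuals = unname(stats::residuals(best$fit)),
                 sse = best$sse, unidentifiable = unident),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> Ymax = %.4g nM/s, K1/2 = %.4g nM, Yo = %.4g nM/s\n",
              x$Ymax, x$K_half, x$Yo))
  invisible(x)
}

#' Percent activity of a mutant complex relative to wild type
#'
#' `%activity = (MPR_mutant - MPR_actin) / (MPR_WT - MPR_actin) * 100`,
#' with all three maximum polymerization rates measured at the same
#' activator concentration. Invariant to any common rescaling of the three
#' inputs.
#'
#' @param mpr_mutant,mpr_wt,mpr_actin maximum polymerization rates (nM/s)
#'   for the mutant complex, the wild-type complex, and actin alone.
#' @return percent activity.
#' @export
percent_activity <- function(mpr_mutant, mpr_wt, mpr_actin) {
  denom <- mpr_wt - mpr_actin
  if (any(denom <= 0))
    stop("MPR of the WT complex must exceed the actin-alone MPR")
  (mpr_mutant - mpr_actin) / denom * 100
}
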