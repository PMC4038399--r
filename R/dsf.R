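#' Thermal melt curve
#'
#' A single well's fluorescence trace over a heating ramp. The standard
#' acquisition is one reading per 1 degree C from 25 to 74 degrees C; any
#' strictly increasing uniform grid of at least 10 points is accepted.
#'
#' @param temperature ascending uniform temperature grid, degrees C.
#' @param intensity fluorescence readings, same length.
#' @param well plate coordinate (e.g. "A01").
#' @param condition one of `"protein"`, `"protein+ligand"`, `"dye-only"`,
#'   `"drug+dye"`.
#' @param ligand_id ligand identifier, or NA for ligand-free wells.
#' @param replicate replicate index (>= 1).
#' @return list of class `melt_curve`.
#' @export
melt_curve <- function(temperature, intensity, well = NA_character_,
                       condition = "protein", ligand_id = NA_character_,
                       replicate = 1L) {
  temperature <- as.numeric(temperature)
  intensity <- as.numeric(intensity)
  if (length(temperature) < 10L)
    stop("a melt curve needs at least 10 points")
  if (length(temperature) != length(intensity))
    stop("temperature and intensity lengths differ")
  dt <- diff(temperature)
  if (any(dt <= 0)) stop("temperatures must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop("temperature grid must have a constant step")
  condition <- match.arg(condition,
                         c("protein", "protein+ligand", "dye-only", "drug+dye"))
  structure(list(temperature = temperature, intensity = intensity,
                 well = well, condition = condition, ligand_id = ligand_id,
                 replicate = as.integer(replicate)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve %s [%s%s] rep %d: %.0f-%.0f C, %d points>\n",
              x$well, x$condition,
              if (is.na(x$ligand_id)) "" else paste0(":", x$ligand_id),
              x$replicate, min(x$temperature), max(x$temperature),
              length(x$temperature)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$temperature) == length(b$temperature) &&
    all(abs(a$temperature - b$temperature) < 1e-8)
}

#' Subtract a dye/background control curve
#'
#' Fluorescent dyes interact with some compounds; protein and protein-drug
#' curves are therefore reported after subtracting the matched dye-alone or
#' drug-dye control recorded on the same grid. The sample's metadata is
#' retained.
#'
#' @param sample,control `melt_curve` objects on identical temperature grids.
#' @return corrected `melt_curve`.
#' @export
subtract_control <- function(sample, control) {
  stopifnot(inherits(sample, "melt_curve"), inherits(control, "melt_curve"))
  if (!same_grid(sample, control))
    stop("sample and control temperature grids differ")
  out <- sample
  out$intensity <- sample$intensity - control$intensity
  out
}

#' Average replicate melt curves pointwise
#'
#' Acquisition uses a minimum of two replicates, whose pointwise mean is
#' carried into fitting. A single curve passes through with a warning.
#'
#' @param curves list of `melt_curve` objects sharing condition, ligand and
#'   grid.
#' @return mean `melt_curve`; attribute `n_replicates` records the count.
#' @export
average_replicates <- function(curves) {
  stopifnot(length(curves) >= 1L)
  ref <- curves[[1L]]
  for (cv in curves[-1L]) {
    if (!same_grid(ref, cv)) stop("replicates on differing temperature grids")
    if (!identical(ref$condition, cv$condition) ||
        !identical(is.na(ref$ligand_id), is.na(cv$ligand_id)) ||
        (!is.na(ref$ligand_id) && ref$ligand_id != cv$ligand_id))
      stop("replicates mix conditions or ligands")
  }
  if (length(curves) == 1L)
    warning("single replicate; protocol expects at least two")
  out <- ref
  out$intensity <- rowMeans(vapply(curves, function(cv) cv$intensity,
                                   numeric(length(ref$intensity))))
  out$replicate <- 1L
  attr(out, "n_replicates") <- length(curves)
  out
}

#' Boltzmann sigmoid
#'
#' \deqn{I(T) = I_{min} + \frac{I_{max} - I_{min}}{1 + e^{(T_m - T)/a}}}
#' Fluorescence rises on unfolding (exposed hydrophobic surface binds the
#' dye), so \eqn{I \to I_{max}} for \eqn{T \gg T_m}; `a` sets the breadth
#' of the transition and equals the inverse slope at the midpoint.
#'
#' @param t temperature(s), degrees C.
#' @param i_min,i_max asymptotic intensities.
#' @param t_m transition midpoint, degrees C.
#' @param a slope parameter, degrees C (> 0).
#' @return intensity value(s).
#' @export
boltzmann <- function(t, i_min, i_max, t_m, a) {
  i_min + (i_max - i_min) / (1 + exp((t_m - t) / a))
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the two-state
#' [boltzmann()] model. Points after the global intensity maximum are
#' excluded by default: post-peak signal decay reflects aggregation of the
#' unfolded state, which the two-state model does not describe. Starting
#' values come from the data (asymptotes from the first/last deciles of the
#' trace, midpoint from the half-amplitude crossing, `a` = 1 degree C).
#' Failure to converge, or a fit violating `i_max > i_min`, `a > 0`,
#' midpoint inside the observed window, or amplitude resolvable above the
#' residual noise, yields `converged = FALSE` rather than an error.
#'
#' @param curve a `melt_curve`.
#' @param truncate_after_peak drop points beyond the global maximum.
#' @param min_points minimum usable points (error below this).
#' @return list of class `boltzmann_fit`: `i_min`, `i_max`, `t_m`, `a`,
#'   `rmse`, `converged`, `n_used`, `curve`.
#' @export
fit_boltzmann <- function(curve, truncate_after_peak = TRUE, min_points = 5L) {
  stopifnot(inherits(curve, "melt_curve"))
  t <- curve$temperature
  y <- curve$intensity
  if (truncate_after_peak) {
    keep <- seq_len(which.max(y))
    if (length(keep) >= min_points) {
      t <- t[keep]
      y <- y[keep]
    }
  }
  if (length(t) < min_points)
    stop("fewer than ", min_points, " usable points")
  fail <- structure(list(i_min = NA_real_, i_max = NA_real_, t_m = NA_real_,
                         a = NA_real_, rmse = NA_real_, converged = FALSE,
                         n_used = length(t), curve = curve),
                    class = "boltzmann_fit")
  k <- max(1L, floor(length(y) / 10))
  start <- list(i_min = mean(y[seq_len(k)]),
                i_max = mean(y[seq.int(length(y) - k + 1L, length(y))]),
                t_m = NA_real_, a = 1)
  half <- (start$i_min + start$i_max) / 2
  cross <- which(y >= half)
  start$t_m <- if (length(cross)) t[cross[1L]] else stats::median(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ boltzmann(t, i_min, i_max, t_m, a),
      start = start,
      lower = c(i_min = -Inf, i_max = -Inf, t_m = min(t), a = 1e-3),
      upper = c(i_min = Inf, i_max = Inf, t_m = max(t), a = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- as.list(stats::coef(fit))
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  amp <- p$i_max - p$i_min
  # noise scale from the full (untruncated) differenced trace: robust to the
  # transition step and immune to overfitting of a short truncated prefix
  sigma_hat <- stats::mad(diff(curve$intensity)) / sqrt(2)
  # fraction of the amplitude actually traversed inside the fitted window;
  # a real transition is resolved there, a noise ramp is not
  traversal <- if (amp != 0)
    (boltzmann(max(t), p$i_min, p$i_max, p$t_m, p$a) -
     boltzmann(min(t), p$i_min, p$i_max, p$t_m, p$a)) / amp else 0
  ok <- amp > 0 &&
    p$a > 0 &&
    p$t_m >= min(t) && p$t_m <= max(t) &&
    amp > 4 * rmse &&        # amplitude must stand clear of the fit residue
    amp > 6 * sigma_hat &&   # ... and of the trace's own noise level
    traversal > 0.8
  structure(list(i_min = p$i_min, i_max = p$i_max, t_m = p$t_m, a = p$a,
                 rmse = rmse, converged = ok, n_used = length(t),
                 curve = curve),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<boltzmann_fit: Tm=%.2f C, a=%.2f, amplitude=%.1f, rmse=%.2f>\n",
                x$t_m, x$a, x$i_max - x$i_min, x$rmse))
  else cat("<boltzmann_fit: not converged>\n")
  invisible(x)
}

#' Curve quality score Q
#'
#' Q is the ratio of the melting-associated fluorescence increase (the
#' fitted transition amplitude) to the total observed fluorescence range,
#' clamped to \[0, 1\]. Q = 1 marks a clean single transition spanning the
#' whole signal; Q = 0 means no thermal transition (unconverged fit or a
#' flat trace).
#'
#' @param curve the observed `melt_curve`.
#' @param fit its [fit_boltzmann()] result.
#' @return Q in \[0, 1\].
#' @export
q_score <- function(curve, fit) {
  stopifnot(inherits(curve, "melt_curve"), inherits(fit, "boltzmann_fit"))
  if (!fit$converged) return(0)
  total <- max(curve$intensity) - min(curve$intensity)
  if (total <= 0) return(0)
  min(1, max(0, (fit$i_max - fit$i_min) / total))
}

#' Count thermal transitions and classify a melt curve
#'
#' The smoothed first derivative dI/dT is scanned for peaks: local maxima
#' exceeding `peak_frac` of the strongest slope, separated by at least
#' `min_sep` degrees C, and standing above the differenced-noise floor.
#' Zero peaks classify the curve as `"none"`, one as `"single"`, two or
#' more as `"multi"` (multi-step unfolding); only single-transition curves
#' go on to thermodynamic analysis.
#'
#' @param curve a `melt_curve`.
#' @param peak_frac fraction of the maximum slope a peak must reach.
#' @param min_sep minimum separation of distinct transitions, degrees C.
#' @param smooth_k moving-average window (points) for the derivative.
#' @return list of class `curve_quality`: `verdict`, `n_transitions`,
#'   `peak_temperatures`.
#' @export
classify_curve <- function(curve, peak_frac = 0.25, min_sep = 5,
                           smooth_k = 5L) {
  stopifnot(inherits(curve, "melt_curve"))
  t <- curve$temperature
  y <- curve$intensity
  step <- t[2L] - t[1L]
  d <- diff(y) / step
  tm_grid <- (t[-1L] + t[-length(t)]) / 2
  k <- min(smooth_k, length(d))
  s <- as.numeric(stats::filter(d, rep(1 / k, k), sides = 2))
  tm_grid <- tm_grid[!is.na(s)]
  s <- s[!is.na(s)]
  # smoothing over k points shrinks iid differenced noise by sqrt(k)
  noise_floor <- 3 * stats::mad(diff(y)) / step / sqrt(k)
  thr <- max(peak_frac * max(s), noise_floor, 0)
  is_peak <- s > thr &
    s >= c(-Inf, s[-length(s)]) & s >= c(s[-1L], -Inf)
  peaks <- tm_grid[is_peak]
  sl <- s[is_peak]
  # enforce minimum separation, keeping the stronger peak
  if (length(peaks) > 1L) {
    ord <- order(-sl)
    kept <- numeric(0)
    for (p in peaks[ord])
      if (!length(kept) || min(abs(kept - p)) >= min_sep) kept <- c(kept, p)
    peaks <- sort(kept)
  }
  n <- length(peaks)
  structure(list(
    verdict = if (n == 0L) "none" else if (n == 1L) "single" else "multi",
    n_transitions = n, peak_temperatures = peaks),
    class = "curve_quality")
}

#' Melting-temperature shift
#'
#' @param sample_fit converged [fit_boltzmann()] of the protein-ligand
#'   curve.
#' @param reference_fit converged fit of the ligand-free protein curve.
#' @return list with `delta_tm` (degrees C, sign preserved) and
#'   `destabilizer` (TRUE when negative).
#' @export
delta_tm <- function(sample_fit, reference_fit) {
  stopifnot(inherits(sample_fit, "boltzmann_fit"),
            inherits(reference_fit, "boltzmann_fit"))
  if (!sample_fit$converged || !reference_fit$converged)
    stop("delta Tm requires converged fits on both curves")
  d <- sample_fit$t_m - reference_fit$t_m
  list(delta_tm = d, destabilizer = d < 0)
}

# gas constant, cal / (mol K); Celsius-to-Kelvin offset
.R_CAL <- 1.987
.T_KELVIN <- 273.15

#' Van't Hoff unfolding enthalpy from a Boltzmann fit
#'
#' The two-state model implies \eqn{\ln K_{unfold}(T) = (T - T_m)/a}, whose
#' temperature derivative at the midpoint gives the van't Hoff enthalpy
#' \deqn{\Delta H = R\, T_m^2 / a} with \eqn{T_m} and `a` in Kelvin and
#' R = 1.987 cal/(mol K). A broad transition (large `a`) implies a small
#' unfolding enthalpy.
#'
#' @param fit converged [fit_boltzmann()] (temperatures in degrees C).
#' @return enthalpy in cal/mol.
#' @export
vant_hoff_enthalpy <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!fit$converged) stop("van't Hoff enthalpy requires a converged fit")
  if (fit$a <= 0) stop("slope parameter must be positive")
  tm_k <- fit$t_m + .T_KELVIN
  .R_CAL * tm_k^2 / fit$a
}

#' Ligand affinity from the melting-temperature shift
#'
#' With the heat-capacity change ignored, the association constant at the
#' shifted midpoint follows the van't Hoff relation
#' \deqn{K_L(T_m) = \frac{\exp\{-\frac{\Delta H}{R}
#'   (\frac{1}{T_m} - \frac{1}{T_0})\}}{[L]}}
#' where \eqn{T_0} is the ligand-free midpoint and \eqn{[L]} the free
#' ligand concentration at \eqn{T_m}, approximated by the total ligand
#' concentration when ligand is in large excess over protein. The
#' dissociation constant is \eqn{K_D = 1/K_L}; with no shift,
#' \eqn{K_D = [L]}.
#'
#' @param delta_h unfolding enthalpy of the reference protein, cal/mol.
#' @param t_m midpoint of the protein-ligand curve, Kelvin.
#' @param t0 midpoint of the ligand-free protein curve, Kelvin.
#' @param ligand_conc total ligand concentration, molar (> 0).
#' @return list with `k_l` (1/M) and `k_d` (M).
#' @export
kd_estimate <- function(delta_h, t_m, t0, ligand_conc) {
  stopifnot(t_m > 0, t0 > 0)
  if (ligand_conc <= 0) stop("ligand concentration must be positive")
  k_l <- exp(-delta_h / .R_CAL * (1 / t_m - 1 / t0)) / ligand_conc
  list(k_l = k_l, k_d = 1 / k_l)
}
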