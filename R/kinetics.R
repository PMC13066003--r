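# Enzymology fits: initial rates, Michaelis-Menten, phosphopeptide
# activation profiles, 4PL IC50 and DSF melting temperature.

#' Initial reaction rate from a progress curve
#'
#' Ordinary least-squares slope over the initial near-linear window: the
#' earliest points whose cumulative signal change is at most
#' `window_frac` of the total signal range, extended forward if needed so
#' the window holds at least `min_points` points.
#'
#' @param times time values (monotone increasing, seconds).
#' @param signal signal values (same length).
#' @param window_frac fraction of the total signal change defining the
#'   initial window (default 0.10).
#' @param min_points minimum points in the window (default 4).
#' @return slope (signal units per time unit).
#' @export
initial_rate <- function(times, signal, window_frac = 0.10, min_points = 4L) {
  if (length(times) != length(signal))
    abort("'times' and 'signal' must have equal length")
  if (length(times) < min_points)
    abort("need at least ", min_points, " time points")
  if (is.unsorted(times, strictly = TRUE))
    abort("'times' must be strictly increasing")
  total <- max(signal) - min(signal)
  in_win <- abs(signal - signal[1L]) <= window_frac * total
  # the window is the initial contiguous run, padded to min_points
  k <- which(!in_win)[1L]
  n_win <- if (is.na(k)) length(times) else k - 1L
  n_win <- max(n_win, min_points)
  t <- times[seq_len(n_win)]; y <- signal[seq_len(n_win)]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `Y = Vmax * X / (Km + X)` (port algorithm,
#' positivity bounds). Initial guesses: `Vmax` = maximum observed rate,
#' `Km` = concentration nearest half-maximal rate. The turnover number is
#' `kcat = Vmax / [E]` and the catalytic efficiency `kcat / Km`.
#'
#' @param substrate substrate concentrations (uM); at least 5 distinct
#'   values are required.
#' @param rate measured initial rates (same length; replicate points are
#'   pooled).
#' @param enzyme_conc total enzyme concentration `[E]` (uM).
#' @return an object of class `mm_fit`: list with `vmax`, `km`, `kcat`,
#'   `efficiency`, `se` (named vector for vmax/km), `converged`,
#'   `diagnostics`.
#' @export
fit_michaelis_menten <- function(substrate, rate, enzyme_conc) {
  assert_scalar_number(enzyme_conc, "enzyme_conc", positive = TRUE)
  if (length(substrate) != length(rate))
    abort("'substrate' and 'rate' must have equal length")
  if (any(substrate < 0)) abort("substrate concentrations must be >= 0")
  if (length(unique(substrate)) < 5L)
    abort("need at least 5 distinct substrate concentrations")

  vmax0 <- max(rate)
  km0 <- substrate[which.min(abs(rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(substrate[substrate > 0])
  dat <- data.frame(x = substrate, y = rate)
  fit <- tryCatch(
    stats::nls(y ~ vmax * x / (km + x), data = dat,
               start = list(vmax = vmax0, km = km0),
               algorithm = "port", lower = c(vmax = 1e-12, km = 1e-12),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(vmax = NA_real_, km = NA_real_, kcat = NA_real_,
                          efficiency = NA_real_, se = c(vmax = NA, km = NA),
                          enzyme_conc = enzyme_conc, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "mm_fit"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  boundary <- cf[["km"]] <= 2e-12 || cf[["vmax"]] <= 2e-12
  kcat <- cf[["vmax"]] / enzyme_conc
  structure(list(
    vmax = cf[["vmax"]], km = cf[["km"]], kcat = kcat,
    efficiency = kcat / cf[["km"]],
    se = c(vmax = unname(se[1L]), km = unname(se[2L])),
    enzyme_conc = enzyme_conc,
    converged = !boundary,
    diagnostics = if (boundary) "parameter pinned at lower bound" else "ok"),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  cat(sprintf("  Vmax = %.6g  Km = %.6g uM\n", x$vmax, x$km))
  cat(sprintf("  kcat = %.6g /s  kcat/Km = %.6g /(uM s)\n",
              x$kcat, x$efficiency))
  invisible(x)
}

#' Catalytic-efficiency fold change between two fits
#'
#' `(kcat/Km)_variant / (kcat/Km)_reference`. Antisymmetric under argument
#' swap: `r(A, B) * r(B, A) = 1`.
#'
#' @param fit_variant,fit_reference converged [fit_michaelis_menten()] fits.
#' @return fold change (numeric scalar).
#' @export
efficiency_ratio <- function(fit_variant, fit_reference) {
  stopifnot(inherits(fit_variant, "mm_fit"), inherits(fit_reference, "mm_fit"))
  if (!fit_variant$converged || !fit_reference$converged)
    abort("both fits must have converged")
  if (fit_reference$efficiency == 0)
    abort("reference efficiency is zero")
  fit_variant$efficiency / fit_reference$efficiency
}

#' Phosphopeptide activation profile
#'
#' Fold activation of endpoint phosphatase activity relative to the
#' zero-peptide baseline. Profiles whose maximum fold activation is below
#' `flat_threshold` are flagged flat ("could not be activated").
#'
#' @param peptide_concs peptide concentrations (uM); must include 0.
#' @param activities endpoint activities (AU), same length.
#' @param flat_threshold fold-activation threshold for the flat flag
#'   (default 1.2).
#' @return an object of class `activation_profile`: list with
#'   `concentration`, `fold_activation` (baseline rows removed), `baseline`,
#'   `max_fold`, `flat`.
#' @export
activation_profile <- function(peptide_concs, activities,
                               flat_threshold = 1.2) {
  if (length(peptide_concs) != length(activities))
    abort("'peptide_concs' and 'activities' must have equal length")
  base_idx <- peptide_concs == 0
  if (!any(base_idx)) abort("a zero-concentration baseline is required")
  baseline <- mean(activities[base_idx])
  if (baseline <= 0) abort("baseline activity must be > 0")
  conc <- peptide_concs[!base_idx]
  fold <- activities[!base_idx] / baseline
  ord <- order(conc)
  structure(list(concentration = conc[ord], fold_activation = fold[ord],
                 baseline = baseline, max_fold = max(fold),
                 flat = max(fold) < flat_threshold),
            class = "activation_profile")
}

#' Fit a four-parameter logistic inhibition curve
#'
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` fitted
#' by nonlinear least squares on the dose scale (equivalent to a 4PL in
#' log10 dose). The fitted response at `dose = ic50` is the plateau
#' midpoint `(top + bottom) / 2`. Requires at least 6 distinct positive
#' doses spanning the transition.
#'
#' @param doses inhibitor concentrations (uM, > 0).
#' @param responses measured responses (same length).
#' @return an object of class `ic50_fit`: list with `ic50`, `hill`, `top`,
#'   `bottom`, `converged`, `diagnostics`.
#' @export
fit_ic50 <- function(doses, responses) {
  if (length(doses) != length(responses))
    abort("'doses' and 'responses' must have equal length")
  if (any(doses <= 0)) abort("doses must be > 0 (log-dose model)")
  if (length(unique(doses)) < 6L)
    abort("need at least 6 distinct doses")

  ord_means <- tapply(responses, doses, mean)
  dvals <- as.numeric(names(ord_means))
  o <- order(dvals)
  dvals <- dvals[o]; mns <- as.numeric(ord_means)[o]
  top0 <- mns[1L]; bot0 <- mns[length(mns)]
  fail <- function(msg)
    structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                   bottom = NA_real_, converged = FALSE, diagnostics = msg),
              class = "ic50_fit")
  if (top0 <= bot0) return(fail("no decreasing transition in dose range"))
  mid0 <- (top0 + bot0) / 2
  ic0 <- dvals[which.min(abs(mns - mid0))]
  dat <- data.frame(x = doses, y = responses)
  fit <- tryCatch(
    stats::nls(y ~ bottom + (top - bottom) / (1 + (x / ic50)^hill),
               data = dat,
               start = list(top = top0, bottom = bot0, ic50 = ic0, hill = 1),
               algorithm = "port",
               lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12,
                         hill = 1e-3),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  cf <- stats::coef(fit)
  if (cf[["bottom"]] >= cf[["top"]])
    return(fail("fitted bottom >= top"))
  if (cf[["ic50"]] < min(doses) / 10 || cf[["ic50"]] > max(doses) * 10)
    return(fail("fitted IC50 outside the dosed range"))
  structure(list(ic50 = cf[["ic50"]], hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 converged = TRUE, diagnostics = "ok"),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("4PL inhibition fit", if (!x$converged) " (NOT converged)" else "",
      "\n", sep = "")
  cat(sprintf("  IC50 = %.6g uM  hill = %.4g  top = %.6g  bottom = %.6g\n",
              x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

# Savitzky-Golay first-derivative by local quadratic fit on a centered
# window of odd length w (dense, evenly spaced grids assumed)
sg_first_derivative <- function(x, y, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  d <- rep(NA_real_, n)
  for (i in (half + 1L):(n - half)) {
    idx <- (i - half):(i + half)
    t <- x[idx] - x[i]
    fit <- stats::lm.fit(cbind(1, t, t^2), y[idx])
    d[i] <- fit$coefficients[2L]
  }
  d
}

#' Melting temperature from a DSF fluorescence melt curve
#'
#' Tm is the inflection point of the fluorescence-versus-temperature
#' trace: the argmax of the smoothed first derivative (Savitzky-Golay
#' local quadratic, `window` points), refined by quadratic interpolation
#' around the discrete peak. The estimate is invariant to affine
#' transformations of the signal. Traces with no interior derivative peak
#' (e.g. strictly linear) raise a "no transition" error.
#'
#' @param temperatures monotone increasing temperature grid (deg C).
#' @param fluorescence fluorescence values (same length).
#' @param window odd Savitzky-Golay window size (default 41 points,
#'   about 4 degC on the typical 0.1 degC instrument ramp; wide enough
#'   that derivative noise at a few percent of the transition amplitude
#'   does not displace the peak).
#' @return an object of class `melt_result`: list with `tm`,
#'   `derivative_peak_height`, `fit_window` (temperature bounds of the
#'   smoothing window around the peak).
#' @export
melt_tm <- function(temperatures, fluorescence, window = 41L) {
  if (length(temperatures) != length(fluorescence))
    abort("'temperatures' and 'fluorescence' must have equal length")
  if (is.unsorted(temperatures, strictly = TRUE))
    abort("'temperatures' must be strictly increasing")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (length(temperatures) < window + 2L)
    abort("trace shorter than the smoothing window")

  d <- sg_first_derivative(temperatures, fluorescence, window)
  valid <- which(!is.na(d))
  peak <- valid[which.max(d[valid])]
  # a real transition must stand out from the baseline derivative level
  med <- stats::median(d[valid]); disp <- stats::mad(d[valid])
  if (peak == valid[1L] || peak == valid[length(valid)] ||
      (d[peak] - med) <= 3 * disp + 1e-12)
    abort("no transition: no interior derivative peak found")

  # quadratic refinement on the three points around the peak
  t3 <- temperatures[(peak - 1L):(peak + 1L)]
  d3 <- d[(peak - 1L):(peak + 1L)]
  cf <- unname(stats::lm.fit(cbind(1, t3, t3^2), d3)$coefficients)
  tm <- if (is.na(cf[3L]) || cf[3L] >= 0) temperatures[peak]
        else -cf[2L] / (2 * cf[3L])
  if (tm < temperatures[peak - 1L] || tm > temperatures[peak + 1L])
    tm <- temperatures[peak]
  structure(list(tm = tm, derivative_peak_height = d[peak],
                 fit_window = c(temperatures[max(1L, peak - (window - 1L) %/% 2L)],
                                temperatures[min(length(temperatures),
                                                 peak + (window - 1L) %/% 2L)])),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("DSF melt: Tm = %.2f degC (derivative peak %.4g)\n",
              x$tm, x$derivative_peak_height))
  invisible(x)
}
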