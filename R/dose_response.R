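#' Mg2+ concentration after adding stock solution
#'
#' Both the exact dilution value,
#' `(baseline * V_medium + stock * V_added) / (V_medium + V_added)`,
#' and the nominal protocol value, `baseline + stock * V_added / V_medium`,
#' are returned. The standard protocol starts from 0.81 mM in 1.1 ml of
#' medium and adds 2.75 ul of 1 M MgCl2 per step, a nominal increment of
#' 2.5 mM per addition (0.81 -> 3.31 -> 5.81 -> 8.31 -> 10.81 mM).
#' Curves are indexed by the nominal concentration, which is what
#' dose-response axes report; the exact value is always slightly lower
#' because the added volume dilutes the medium.
#'
#' @param baseline_mM concentration before the addition, mM.
#' @param medium_volume_ul medium volume before the addition, ul.
#' @param added_volume_ul stock volume added, ul (0 allowed).
#' @param stock_mM stock concentration, mM (1 M = 1000 mM).
#' @return list with `exact_mM`, `nominal_mM` and `volume_after_ul`.
#' @examples
#' concentration_after_addition(0.81, 1100, 2.75, 1000)$nominal_mM  # 3.31
#' @export
concentration_after_addition <- function(baseline_mM, medium_volume_ul,
                                         added_volume_ul, stock_mM) {
  if (baseline_mM < 0 || stock_mM < 0 || medium_volume_ul <= 0 ||
      added_volume_ul < 0)
    stop("volumes must be positive and concentrations non-negative")
  exact <- (baseline_mM * medium_volume_ul + stock_mM * added_volume_ul) /
    (medium_volume_ul + added_volume_ul)
  nominal <- baseline_mM + stock_mM * added_volume_ul / medium_volume_ul
  list(exact_mM = exact, nominal_mM = nominal,
       volume_after_ul = medium_volume_ul + added_volume_ul)
}

#' Build a dose-response curve
#'
#' Mean and SEM of a per-electrode metric (MFR or induced spikes per
#' stimulus) at each concentration of an ordered addition series, plus an
#' optional recovery point measured after the final medium change back to
#' baseline.
#'
#' @param concentrations strictly increasing Mg2+ concentrations, mM
#'   (nominal values).
#' @param values list of numeric vectors, one per concentration
#'   (per-electrode metric values).
#' @param recovery_values optional numeric vector for the post-recovery
#'   session.
#' @return An object of class `dose_response_curve`: data frame with
#'   columns `concentration`, `mean`, `sem`, `n`, and attribute
#'   `recovery` (list with mean/sem/n/values or NULL).
#' @export
build_curve <- function(concentrations, values, recovery_values = NULL) {
  if (length(concentrations) < 2L) stop("need at least 2 concentrations")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (length(values) != length(concentrations))
    stop("need one value vector per concentration")
  if (any(!lengths(values))) stop("each concentration needs >= 1 value")
  cur <- data.frame(concentration = as.numeric(concentrations),
                    mean = vapply(values, mean, numeric(1)),
                    sem = vapply(values, sem, numeric(1)),
                    n = lengths(values))
  attr(cur, "values") <- values
  attr(cur, "recovery") <- if (!is.null(recovery_values))
    list(mean = mean(recovery_values), sem = sem(recovery_values),
         n = length(recovery_values), values = recovery_values)
  class(cur) <- c("dose_response_curve", "data.frame")
  cur
}

#' Fit an exponential decay to a dose-response mean trace
#'
#' Least-squares fit of `mean(c) = A * exp(-c / tau)` to the mean trace,
#' concentrations in mM. Deterministic initialisation (`A0` = mean at the
#' lowest concentration, `tau0` = concentration span) refined by
#' Levenberg-Marquardt to a relative tolerance of 1e-8. An essentially
#' flat trace is reported as `no_decay` (tau is not identifiable);
#' non-positive means make the log-scale sanity check impossible and
#' trigger a direct nonlinear fit with a warning.
#'
#' @param curve a [build_curve()] result, or a data frame with columns
#'   `concentration` and `mean` (>= 3 points).
#' @return An object of class `exp_fit`: list with `A`, `tau`, `rss`,
#'   `no_decay` and `fitted`.
#' @export
fit_exponential <- function(curve) {
  conc <- curve$concentration
  y <- curve$mean
  if (length(conc) < 3L) stop("need >= 3 concentration points")
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    return(structure(list(A = mean(y), tau = Inf, rss = 0,
                          no_decay = TRUE, fitted = rep(mean(y), length(y))),
                     class = "exp_fit"))
  }
  if (any(y <= 0))
    warning("non-positive means: fitting directly on the linear scale")
  a0 <- y[1]
  tau0 <- diff(range(conc))
  fit <- minpack.lm::nlsLM(y ~ A * exp(-conc / tau),
                           start = list(A = a0, tau = tau0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-8, ptol = 1e-8))
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), tau = unname(cf["tau"]),
                 rss = sum(stats::residuals(fit)^2), no_decay = FALSE,
                 fitted = stats::fitted(fit)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$no_decay) cat("<exp_fit> flat trace: no decay (tau -> Inf)\n")
  else cat(sprintf("<exp_fit> A = %.4g, tau = %.4g mM (RSS %.3g)\n",
                   x$A, x$tau, x$rss))
  invisible(x)
}

#' Mann-Kendall trend test on a dose-response mean trace
#'
#' @param curve a [build_curve()] result.
#' @param sided default "less": tests for a decreasing trend with
#'   concentration (suppression).
#' @return A `mea_test`.
#' @export
trend_test <- function(curve, sided = "less") {
  mann_kendall(curve$mean, sided = sided)
}

#' Compare initial and post-recovery metric values
#'
#' Two-sided Mann-Whitney U test between the per-electrode values of the
#' initial (pre-magnesium) session and the session recorded after the
#' final medium change back to baseline.
#'
#' @param initial,recovery numeric vectors (length >= 2 each).
#' @param sided test sidedness, default two-sided.
#' @return A `mea_test`.
#' @export
recovery_comparison <- function(initial, recovery, sided = "two.sided") {
  if (length(initial) < 2L || length(recovery) < 2L)
    stop("need >= 2 values in each sample")
  mann_whitney_u(initial, recovery, sided = sided)
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` across repeated perturbations (e.g. sequential
#' medium changes); used to compare the stability of spontaneous versus
#' stimulation-induced activity.
#'
#' @param values numeric vector, n >= 2, mean != 0.
#' @return CV in percent.
#' @export
stability_cv <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is 0: CV undefined")
  100 * stats::sd(values) / m
}

#' Plot a dose-response curve with its recovery point
#' @param x a `dose_response_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dose_response_curve <- function(x, ...) {
  graphics::plot(x$concentration, x$mean, type = "b", pch = 16,
                 xlab = "Mg2+ concentration (mM)", ylab = "mean metric", ...)
  graphics::arrows(x$concentration, x$mean - x$sem, x$concentration,
                   x$mean + x$sem, angle = 90, code = 3, length = 0.03)
  rec <- attr(x, "recovery")
  if (!is.null(rec))
    graphics::points(x$concentration[1], rec$mean, pch = 1, cex = 1.4)
  invisible(x)
}
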