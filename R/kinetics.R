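#' Fit a fluorescence standard curve
#'
#' Ordinary least squares of signal on concentration. The curve is fitted
#' with an intercept, but only the slope is used downstream to convert
#' background-subtracted signal to concentration: background handling stays
#' explicit instead of being absorbed into the intercept.
#'
#' @param conc known concentrations (uM), >= 3 values spanning > 0.
#' @param signal measured fluorescence (AU).
#' @return object of class `standard_curve` with slope (AU/uM), intercept,
#'   `r_squared` and a `negative_slope` flag.
#' @export
fit_standard_curve <- function(conc, signal) {
  if (length(conc) != length(signal)) stop("conc and signal lengths differ")
  if (length(conc) < 3L) stop("need >= 3 standard points")
  if (stats::var(conc) == 0) stop("standard concentrations have zero variance")
  fit <- stats::lm(signal ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  neg <- slope <= 0
  if (neg) warning("standard curve has non-positive slope; conversions will be invalid")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 conc = conc, signal = signal, negative_slope = neg),
            class = "standard_curve")
}

#' Convert plate fluorescence to reaction rates
#'
#' Implements the plate-assay arithmetic: rate = (signal - background) /
#' standard-curve slope / reaction time. Negative net signals are clipped
#' to rate 0 and flagged.
#'
#' @param plate long-format data.frame with columns `condition_label`,
#'   `replicate_id`, `substrate_conc` (uM), `signal` (AU),
#'   `background_signal` (AU, matched per condition), `time_h` (h, > 0).
#' @param curve a [fit_standard_curve()] result with positive slope.
#' @return `plate` with added columns `rate` (uM/h) and `rate_clipped`.
#' @export
signal_to_rate <- function(plate, curve) {
  stopifnot(is.data.frame(plate), inherits(curve, "standard_curve"))
  req <- c("condition_label", "replicate_id", "substrate_conc", "signal",
           "background_signal", "time_h")
  miss <- setdiff(req, names(plate))
  if (length(miss)) stop("plate lacks columns: ", paste(miss, collapse = ", "))
  if (curve$negative_slope || curve$slope <= 0)
    stop("standard-curve slope must be > 0 for conversion")
  bad_bg <- is.na(plate$background_signal)
  if (any(bad_bg))
    stop("missing background for condition(s): ",
         paste(unique(plate$condition_label[bad_bg]), collapse = ", "))
  if (any(plate$time_h <= 0)) stop("reaction time must be > 0")
  net <- plate$signal - plate$background_signal
  rate <- net / curve$slope / plate$time_h
  plate$rate_clipped <- rate < 0
  plate$rate <- pmax(rate, 0)
  plate
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of v = Vmax * S / (Km + S) via damped
#' (Levenberg-Marquardt) least squares. Initialization: Vmax0 = 1.2 *
#' max(v), Km0 = substrate concentration nearest the half-maximal rate.
#' Parameter standard errors come from the Jacobian at the solution.
#'
#' @param S substrate concentrations (uM), >= 4 distinct values.
#' @param v rates (uM/h, >= 0).
#' @param condition_label carried through to the result.
#' @return object of class `mm_fit`: `vmax`, `km`, `vmax_se`, `km_se`,
#'   `boundary_warning`, plus `kcat`/`efficiency` slots filled by
#'   [catalytic_efficiency()].
#' @export
fit_michaelis_menten <- function(S, v, condition_label = "") {
  if (length(S) != length(v)) stop("S and v lengths differ")
  if (length(unique(S)) < 4L) stop("need >= 4 distinct substrate concentrations")
  if (any(v < 0)) stop("rates must be >= 0")
  vc <- max(v)
  if (vc <= 0) stop("all rates are zero; nothing to fit")
  # fit on rates normalized by their maximum: conditions the problem and
  # makes the fit exactly equivariant under rescaling of the rate axis
  vs <- v / vc
  km0 <- max(S[which.min(abs(vs - 0.5))], 1e-3)  # guard S = 0 as the start
  fit <- tryCatch(
    minpack.lm::nlsLM(vs ~ Vmax * S / (Km + S),
                      start = list(Vmax = 1.2, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-12, ftol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  } else {
    # damped least squares can hit a singular Jacobian on degenerate data
    # (e.g. a fully saturated, flat rate profile); fall back to bounded
    # direct SSE minimization, which pins Km at its boundary instead
    sse <- function(p) sum((vs - p[1] * S / (p[2] + S))^2)
    op <- tryCatch(
      stats::optim(c(1.2, km0), sse, method = "L-BFGS-B",
                   lower = c(0, 0), control = list(factr = 1e3, maxit = 2000)),
      error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    est <- c(Vmax = op$par[1L], Km = op$par[2L])
    se <- c(Vmax = NA_real_, Km = NA_real_)
  }
  est["Vmax"] <- est[["Vmax"]] * vc
  se["Vmax"] <- se[["Vmax"]] * vc
  boundary <- est[["Km"]] <= 1e-6 || est[["Km"]] >= 100 * max(S)
  if (boundary)
    warning(sprintf("Km driven to a boundary (%.3g uM); data may not constrain it",
                    est[["Km"]]))
  structure(list(vmax = est[["Vmax"]], km = est[["Km"]],
                 vmax_se = unname(se["Vmax"]), km_se = unname(se["Km"]),
                 kcat = NA_real_, efficiency = NA_real_,
                 enzyme_conc = NA_real_,
                 boundary_warning = boundary,
                 condition_label = condition_label,
                 S = S, v = v),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit>%s Vmax = %.4g +/- %.2g uM/h, Km = %.4g +/- %.2g uM",
              if (nzchar(x$condition_label)) paste0(" ", x$condition_label, ":") else "",
              x$vmax, x$vmax_se, x$km, x$km_se))
  if (is.finite(x$efficiency))
    cat(sprintf(", kcat/Km = %.4g 1/(uM h)", x$efficiency))
  cat("\n")
  invisible(x)
}

#' Catalytic efficiency from a Michaelis-Menten fit
#'
#' kcat = Vmax / enzyme concentration; efficiency = kcat / Km. Ratios of
#' efficiencies between conditions do not depend on the enzyme
#' concentration, which is why percent comparisons stay valid even when the
#' enzyme's molar concentration is only approximate.
#'
#' @param fit an `mm_fit`.
#' @param enzyme_conc enzyme molar concentration (uM, > 0).
#' @return the fit with `kcat` (1/h) and `efficiency` (1/(uM h)) filled in.
#' @export
catalytic_efficiency <- function(fit, enzyme_conc) {
  stopifnot(inherits(fit, "mm_fit"))
  if (!is.numeric(enzyme_conc) || enzyme_conc <= 0)
    stop("enzyme_conc must be > 0")
  fit$enzyme_conc <- enzyme_conc
  fit$kcat <- fit$vmax / enzyme_conc
  fit$efficiency <- fit$kcat / fit$km
  fit
}

# round half away from zero to the nearest step
round_half_away <- function(x, step) sign(x) * floor(abs(x) / step + 0.5) * step

#' Percent change of a treated value over control
#'
#' `100 * (treated - control) / control`, optionally rounded
#' half-away-from-zero to the nearest `round_to` percent step -- the
#' convention used when kinetic-parameter increases are quoted in round
#' tens (e.g. Vmax 15.70 over control 6.76 is +132.2%, quoted as +130%).
#'
#' @param treated,control numeric values; `control > 0`.
#' @param round_to rounding step in percent (default 10); `NULL` for the
#'   raw value.
#' @return percent change.
#' @export
percent_change <- function(treated, control, round_to = 10) {
  if (any(control <= 0)) stop("control must be > 0")
  pc <- 100 * (treated - control) / control
  if (is.null(round_to)) pc else round_half_away(pc, round_to)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' 4PL on log10 concentration: resp = bottom + (top - bottom) /
#' (1 + 10^((log10 EC50 - log10 C) * hill)). Zero-dose wells inform the
#' bottom initialization but are excluded from the log-scale regression.
#' Initialization: bottom0 = mean zero-dose response (else 100), top0 =
#' max(resp), hill0 = 1, EC50_0 = geometric mid-concentration. A fit whose
#' dynamic range (top - bottom) falls below `flat_tol` is flagged
#' `no_effect` (the behaviour expected of an inactive compound); an EC50
#' outside the tested range raises an extrapolation warning.
#'
#' @param conc concentrations (uM); >= 5 nonzero values spanning about 3
#'   log-decades (the reference design uses 0.001-10 uM); zero allowed.
#' @param response percent of no-PAM control (control = 100).
#' @param fix_bottom fix the bottom asymptote at this value (e.g. 100);
#'   `NULL` (default) leaves it free.
#' @param flat_tol dynamic range (percent points) below which the compound
#'   is flagged as having no effect (default 5).
#' @return object of class `dose_response_fit`: `ec50`, `hill`, `top`,
#'   `bottom`, `ec50_se`, `no_effect`, `extrapolated`.
#' @export
fit_dose_response <- function(conc, response, fix_bottom = NULL,
                              flat_tol = 5) {
  if (length(conc) != length(response)) stop("conc and response lengths differ")
  nz <- conc > 0
  if (length(unique(conc[nz])) < 5L)
    stop("need >= 5 distinct nonzero concentrations")
  lc <- log10(conc[nz]); y <- response[nz]
  # a response without measurable dynamic range cannot constrain EC50 or
  # hill; report "no effect" instead of attempting a degenerate fit
  if (diff(range(y)) < flat_tol) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_,
                          top = max(y), bottom = min(y),
                          ec50_se = NA_real_, no_effect = TRUE,
                          extrapolated = FALSE,
                          bottom_fixed = !is.null(fix_bottom)),
                     class = "dose_response_fit"))
  }
  b0 <- if (!is.null(fix_bottom)) fix_bottom
        else if (any(!nz)) mean(response[!nz]) else 100
  start <- list(top = max(y), lec50 = mean(range(lc)), hill = 1)
  if (is.null(fix_bottom)) start$bottom <- b0

  form <- if (is.null(fix_bottom))
    y ~ bottom + (top - bottom) / (1 + 10^((lec50 - lc) * hill))
  else
    stats::as.formula(sprintf(
      "y ~ %.10g + (top - %.10g) / (1 + 10^((lec50 - lc) * hill))",
      fix_bottom, fix_bottom))

  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-10, ftol = 1e-10)),
    error = function(e) stop("dose-response fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(est)),
                                                     names(est)))
  ec50 <- 10^est[["lec50"]]
  ec50_se <- log(10) * ec50 * unname(se["lec50"])  # delta method
  bottom <- if (is.null(fix_bottom)) est[["bottom"]] else fix_bottom
  no_effect <- abs(est[["top"]] - bottom) < flat_tol
  extrapolated <- !no_effect &&
    (ec50 < min(conc[nz]) || ec50 > max(conc[nz]))
  if (extrapolated)
    warning(sprintf("EC50 %.3g uM lies outside the tested range [%.3g, %.3g]",
                    ec50, min(conc[nz]), max(conc[nz])))
  structure(list(ec50 = ec50, hill = est[["hill"]], top = est[["top"]],
                 bottom = bottom, ec50_se = ec50_se,
                 no_effect = no_effect, extrapolated = extrapolated,
                 bottom_fixed = !is.null(fix_bottom)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$no_effect) {
    cat(sprintf("<dose_response_fit> no effect (dynamic range %.2g%%)\n",
                x$top - x$bottom))
  } else {
    cat(sprintf("<dose_response_fit> EC50 = %.4g uM (SE %.2g), hill = %.3g, top = %.4g%%, bottom = %.4g%%%s\n",
                x$ec50, x$ec50_se, x$hill, x$top, x$bottom,
                if (x$extrapolated) " [extrapolated]" else ""))
  }
  invisible(x)
}
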