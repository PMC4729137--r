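#' Four-parameter logistic (4PL) dose-response function
#'
#' \code{bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) - log10(conc))))}.
#' At zero concentration the response is \code{bottom} (for positive
#' \code{hill}); a negative \code{hill} gives a descending (inhibition) curve.
#'
#' @param conc concentrations (same unit as \code{ec50}); zero allowed.
#' @param bottom,top asymptotic responses (percent of reference activity).
#' @param ec50 half-maximal concentration.
#' @param hill Hill slope (sign sets direction).
#' @return responses.
#' @export
four_pl <- function(conc, bottom, top, ec50, hill) {
  out <- numeric(length(conc))
  z <- conc == 0
  out[z] <- if (hill > 0) bottom else top
  out[!z] <- bottom + (top - bottom) /
    (1 + 10^(hill * (log10(ec50) - log10(conc[!z]))))
  out
}

#' Construct a dose-response curve
#'
#' Responses are percentages of the reference activity: for activation assays
#' the wild-type receptor stimulated by 500 nM of the same steroid defines
#' 100\%; for inhibition assays the stimulated (no-drug) control is 100\%.
#'
#' @param concentrations ascending concentrations in nM, at least 5 points
#'   including 0.
#' @param responses matching responses (percent), finite and non-negative.
#' @param direction \code{"activation"} or \code{"inhibition"}.
#' @param max_tested highest tested concentration; defaults to
#'   \code{max(concentrations)}.
#' @return an object of class \code{"dose_response_curve"}.
#' @export
dose_response <- function(concentrations, responses,
                          direction = c("activation", "inhibition"),
                          max_tested = max(concentrations)) {
  direction <- match.arg(direction)
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 5L || concentrations[1] != 0)
    stop("need at least 5 concentrations including 0")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly ascending")
  if (any(!is.finite(responses)) || any(responses < 0))
    stop("responses must be finite and non-negative")
  structure(list(concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses),
                 direction = direction,
                 max_tested = as.numeric(max_tested)),
            class = "dose_response_curve")
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares 4PL fit on the log-concentration axis (Levenberg-Marquardt,
#' via \pkg{minpack.lm}). The zero dose is excluded from the log axis but
#' anchors the zero-drug asymptote's starting value (the bottom for
#' activation, the top for inhibition).
#'
#' The half-max is censored — reported only as "> max tested" — when
#' \itemize{
#'   \item the fitted half-max exceeds the highest tested concentration;
#'   \item an activation curve never reaches \code{weak_cutoff} (default
#'     20\% of reference) at any tested dose — "no activation or very weak
#'     activation in the studied range"; or
#'   \item the optimizer fails to converge (with a warning, never an error).
#' }
#'
#' @param curve a [dose_response()] curve.
#' @param weak_cutoff weak-activation cutoff in percent of reference.
#' @return an object of class \code{"dose_response_fit"}: \code{halfmax}
#'   (EC50 or IC50, \code{NA} when censored), \code{hill}, \code{top},
#'   \code{bottom}, \code{censored}, \code{censor_bound}, \code{direction}.
#' @examples
#' conc <- c(0, 1, 3, 10, 30, 100, 500)
#' fit <- fit_dose_response(dose_response(conc, four_pl(conc, 0, 100, 10, 1)))
#' coef(fit)
#' @export
fit_dose_response <- function(curve, weak_cutoff = 20) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentrations
  resp <- curve$responses
  pos <- conc > 0
  act <- curve$direction == "activation"

  if (act && max(resp) < weak_cutoff)
    return(new_dr_fit(NA, NA, NA, NA, TRUE, curve,
                      reason = "weak activation in the tested range"))

  logc <- log10(conc[pos])
  y <- resp[pos]
  anchor <- resp[1]                      # zero-dose response
  start <- if (act) c(bottom = anchor, top = max(resp),
                      logec50 = stats::median(logc), hill = 1)
           else c(bottom = min(resp), top = anchor,
                  logec50 = stats::median(logc), hill = -1)
  residual <- function(p)
    y - (p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - logc))))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = residual,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3) {
    warning("4PL fit did not converge; reporting a censored half-max")
    return(new_dr_fit(NA, NA, NA, NA, TRUE, curve, reason = "non-convergence"))
  }
  p <- fit$par
  halfmax <- 10^p[["logec50"]]
  censored <- halfmax > curve$max_tested
  new_dr_fit(if (censored) NA else halfmax,
             p[["hill"]], p[["top"]], p[["bottom"]], censored, curve,
             reason = if (censored) "fitted half-max beyond tested range")
}

new_dr_fit <- function(halfmax, hill, top, bottom, censored, curve,
                       reason = NULL) {
  structure(list(halfmax = halfmax, hill = hill, top = top, bottom = bottom,
                 censored = censored, censor_bound = curve$max_tested,
                 direction = curve$direction, reason = reason, curve = curve),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  what <- if (x$direction == "activation") "EC50" else "IC50"
  if (x$censored) {
    cat(sprintf("%s > %g (censored: %s)\n", what, x$censor_bound,
                x$reason %||% "outside tested range"))
  } else {
    cat(sprintf("%s = %.4g, hill %.3g, top %.3g, bottom %.3g\n",
                what, x$halfmax, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(halfmax = object$halfmax, hill = object$hill,
    top = object$top, bottom = object$bottom)
}

#' @export
predict.dose_response_fit <- function(object, conc = object$curve$concentrations,
                                      ...) {
  if (object$censored || is.na(object$halfmax))
    stop("no point prediction from a censored fit")
  four_pl(conc, object$bottom, object$top, object$halfmax, object$hill)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify agonist conversion from an inhibition-mode curve
#'
#' Operationalizes the published qualitative rule — a drug is a partial
#' agonist of a mutant when it inhibits at low concentrations but stimulates
#' at high concentrations — with a symmetric tolerance band of \code{delta}
#' percent around the 100\% stimulated-control baseline:
#' \itemize{
#'   \item \code{"No"}: responses never exceed \code{100 + delta};
#'   \item \code{"Yes"} (full agonist): responses never drop below
#'     \code{100 - delta} and the terminal response exceeds \code{100 + delta};
#'   \item \code{"Partial"}: some response falls below \code{100 - delta} and
#'     the terminal response exceeds \code{100 + delta}.
#' }
#' A shape matching none of these (e.g. stimulation at intermediate doses
#' that vanishes at the top dose) returns \code{"No"} with attribute
#' \code{anomaly = TRUE} and a warning. The verdict depends only on response
#' shape, so it is invariant to rescaling the concentration axis.
#'
#' @param curve an inhibition-mode [dose_response()] curve (baseline 100\%).
#' @param delta band half-width in percent. Default 10.
#' @return \code{"Yes"}, \code{"Partial"} or \code{"No"} (with attribute
#'   \code{anomaly} when no rule matched).
#' @export
classify_agonist <- function(curve, delta = 10) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (curve$direction != "inhibition")
    stop("agonist classification requires an inhibition-mode curve")
  r <- curve$responses
  terminal <- r[length(r)]
  hi <- 100 + delta
  lo <- 100 - delta
  if (max(r) <= hi) return("No")
  if (terminal > hi) {
    if (min(r) < lo) return("Partial")
    return("Yes")
  }
  warning("dose-response shape matches no agonist class (rise then fall); ",
          "returning 'No' with anomaly flag")
  structure("No", anomaly = TRUE)
}
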