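#' Percent inhibition from plate signals
#'
#' `100 * (1 - (test - blank) / (control - blank))`. Applies equally to
#' fluorescence readings (e.g. 390/460 nm excitation/emission) and MTT
#' absorbance at 570 nm; the blank defaults to 0 for readouts reported
#' without blank subtraction.
#'
#' @param test Signal(s) of the treated wells (vectorised).
#' @param control Signal of the untreated control wells.
#' @param blank Background signal (default 0). Must differ from `control`.
#' @return Percent inhibition (0 when test equals control, 100 when test
#'   equals blank).
#' @export
inhibition_rate <- function(test, control, blank = 0) {
  if (isTRUE(all.equal(control, blank)))
    stop("control and blank signals are equal; inhibition undefined")
  100 * (1 - (test - blank) / (control - blank))
}

#' Dose-response data set
#'
#' @param concentrations Molar concentrations (> 0); replicates are repeated
#'   entries.
#' @param responses Percent inhibition (or viability) matching
#'   `concentrations` in length.
#' @return A `dose_response_data`.
#' @export
dose_response_data <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0), all(is.finite(concentrations)))
  if (any(!is.finite(responses))) stop("non-finite responses")
  structure(list(concentrations = concentrations, responses = responses),
            class = "dose_response_data")
}

#' Fit a sigmoidal (four-parameter logistic) dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (ic50 / c)^hill)`
#' with the concentration on a log scale, the standard sigmoidal
#' dose-response model for IC50 estimation. Initialisation is multi-start:
#' the IC50 is seeded at the concentration whose response is nearest the
#' half-maximal level and the Hill slope at each of 0.5, 1 and 2; the
#' lowest-RSS converged fit is returned. The `converged` flag is honest:
#' degenerate data (e.g. constant responses) yield `converged = FALSE`.
#'
#' @param data A [dose_response_data()] with at least 4 distinct
#'   concentrations.
#' @param constrain_top,constrain_bottom Optional fixed plateau values
#'   (e.g. 100 and 0 for percent inhibition).
#' @return A `sigmoid_fit` list: `ic50` (molar), `hill`, `top`, `bottom`,
#'   `rss`, `converged`.
#' @export
fit_sigmoid <- function(data, constrain_top = NULL, constrain_bottom = NULL) {
  stopifnot(inherits(data, "dose_response_data"))
  conc <- data$concentrations
  resp <- data$responses
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations to fit")

  failed <- structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                           bottom = NA_real_, rss = NA_real_,
                           converged = FALSE),
                      class = "sigmoid_fit")
  if (stats::sd(resp) < 1e-9) return(failed)  # unidentifiable plateau

  lc <- log10(conc)
  top0 <- if (is.null(constrain_top)) max(resp) else constrain_top
  bot0 <- if (is.null(constrain_bottom)) min(resp) else constrain_bottom
  half <- (top0 + bot0) / 2
  p0 <- lc[which.min(abs(resp - half))]  # log10 IC50 seed

  model_rhs <- function(p, h, top, bottom, lcv)
    bottom + (top - bottom) / (1 + 10^(h * (p - lcv)))

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch({
      if (is.null(constrain_top) && is.null(constrain_bottom)) {
        minpack.lm::nlsLM(
          resp ~ bottom + (top - bottom) / (1 + 10^(h * (p - lc))),
          start = list(p = p0, h = h0, top = top0, bottom = bot0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else if (!is.null(constrain_top) && !is.null(constrain_bottom)) {
        minpack.lm::nlsLM(
          resp ~ constrain_bottom +
            (constrain_top - constrain_bottom) / (1 + 10^(h * (p - lc))),
          start = list(p = p0, h = h0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else if (!is.null(constrain_top)) {
        minpack.lm::nlsLM(
          resp ~ bottom + (constrain_top - bottom) / (1 + 10^(h * (p - lc))),
          start = list(p = p0, h = h0, bottom = bot0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          resp ~ constrain_bottom +
            (top - constrain_bottom) / (1 + 10^(h * (p - lc))),
          start = list(p = p0, h = h0, top = top0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed)

  cf <- stats::coef(best$fit)
  top <- if (is.null(constrain_top)) unname(cf["top"]) else constrain_top
  bottom <- if (is.null(constrain_bottom)) unname(cf["bottom"])
            else constrain_bottom
  out <- list(ic50 = 10^unname(cf["p"]), hill = unname(cf["h"]),
              top = top, bottom = bottom, rss = best$rss,
              converged = isTRUE(best$fit$convInfo$isConv) &&
                top > bottom && is.finite(cf["p"]))
  structure(out, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> not converged\n")
  } else {
    cat(sprintf(
      "<sigmoid_fit> IC50 = %.4g M, hill = %.3g, top = %.3g, bottom = %.3g, rss = %.4g\n",
      x$ic50, x$hill, x$top, x$bottom, x$rss))
  }
  invisible(x)
}

#' Potency ratio of two inhibitors
#'
#' Ratio of a reference compound's IC50 to a candidate's, rounded to one
#' decimal — the conventional "n times more potent than the positive
#' control" statement.
#'
#' @param reference_ic50,candidate_ic50 IC50 values in the same units
#'   (> 0).
#' @return Ratio rounded to 1 decimal place.
#' @examples
#' potency_ratio(5.97, 3.71)  # 1.6
#' @export
potency_ratio <- function(reference_ic50, candidate_ic50) {
  if (any(reference_ic50 <= 0) || any(candidate_ic50 <= 0))
    stop("IC50 values must be positive")
  round(reference_ic50 / candidate_ic50, 1)
}

#' Xenograft tumour volume from calliper diameters
#'
#' `(c * c * d) / 2` with `c` the smallest and `d` the largest diameter in
#' mm; the standard ellipsoid approximation for subcutaneous tumours.
#'
#' @param c_mm Smallest diameter (mm), `0 <= c_mm <= d_mm`.
#' @param d_mm Largest diameter (mm).
#' @return Volume in cubic mm.
#' @export
tumour_volume <- function(c_mm, d_mm) {
  if (any(c_mm < 0)) stop("diameters must be non-negative")
  if (any(c_mm > d_mm))
    stop("smallest diameter exceeds largest; arguments swapped?")
  c_mm^2 * d_mm / 2
}
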