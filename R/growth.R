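# Culture growth kinetics and ammonia elimination.

#' Fit an exponential growth curve and derive the doubling time
#'
#' Assumes exponential expansion y(t) = y0 * exp(rate * t). The growth rate is
#' estimated by least squares on log(count) versus time; with exactly two
#' observations this reduces to the closed form rate = log(y/y0) / t. The
#' doubling time is ln(2) / rate.
#'
#' @param time Hours, strictly increasing.
#' @param count Cell counts, all positive.
#' @return List with `rate` (per hour), `doubling_time` (hours; `NA` when the
#'   fitted rate is not positive), `y0` (fitted intercept count), `n`.
#' @examples
#' fit_growth(c(0, 72), c(3000, 24000))$doubling_time  # 24 h: 3 doublings
#' @export
fit_growth <- function(time, count) {
  stopifnot(length(time) == length(count), length(time) >= 2)
  if (any(count <= 0)) stop("domain error: cell counts must be positive")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  fit <- stats::lm(log(count) ~ time)
  rate <- unname(stats::coef(fit)[2])
  list(rate = rate,
       doubling_time = if (rate > 0) log(2) / rate else NA_real_,
       y0 = exp(unname(stats::coef(fit)[1])),
       n = length(time))
}

#' Ammonia elimination rate
#'
#' Converts medium concentrations to absolute amounts (concentration times
#' medium volume; 1 nM x 1 ml = 1 pmol), fits the amount-versus-time slope by
#' ordinary least squares (or endpoint differencing), and normalizes by time
#' and cell number. The reported unit is nM/h/million cells referred to 1 ml
#' of medium (numerically pmol/h/million cells).
#'
#' @param time Hours.
#' @param concentration Ammonia concentration in the medium at each time point.
#' @param unit Concentration unit: `"mM"`, `"uM"` or `"nM"`.
#' @param volume_ml Medium volume in ml.
#' @param cells Cell number in the well.
#' @param method `"ols"` (default; least squares over all time points) or
#'   `"endpoint"` (first/last differencing).
#' @return Elimination rate in nM/h/million cells (positive = elimination).
#' @examples
#' ammonia_rate(c(0, 24), c(1.5, 1.0), unit = "mM",
#'              volume_ml = 1, cells = 1e6)  # ~20833
#' @export
ammonia_rate <- function(time, concentration, unit = c("mM", "uM", "nM"),
                         volume_ml, cells, method = c("ols", "endpoint")) {
  stopifnot(length(time) == length(concentration), length(time) >= 2,
            volume_ml > 0, cells > 0)
  if (any(diff(time) <= 0)) stop("times must be increasing")
  unit <- match.arg(unit)
  method <- match.arg(method)
  to_nM <- c(mM = 1e6, uM = 1e3, nM = 1)[[unit]]
  amount <- concentration * to_nM * volume_ml  # pmol
  slope <- if (method == "ols") {
    unname(stats::coef(stats::lm(amount ~ time))[2])
  } else {
    (amount[length(amount)] - amount[1]) / (time[length(time)] - time[1])
  }
  -slope / (cells / 1e6)
}
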