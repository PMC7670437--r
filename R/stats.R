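# Model-vs-experiment error statistics: absolute average percentage
# deviation, root-mean-square error, and the fit-style goodness measures
# (MSE, NRMSE, NMSE) in the convention where 1 is a perfect fit and values
# can be negative.

#' Paired calculated/experimental series
#'
#' @param calculated model values \eqn{\Omega_{cal}}.
#' @param experimental reference values \eqn{\Omega_{exp}}; same length.
#' @return data frame of class `paired_series`.
#' @export
paired_series <- function(calculated, experimental) {
  if (length(calculated) != length(experimental)) {
    stop("calculated and experimental must have the same length")
  }
  if (length(calculated) < 1L) stop("at least one pair is required")
  structure(data.frame(calculated = calculated, experimental = experimental),
            class = c("paired_series", "data.frame"))
}

#' Absolute average percentage deviation
#'
#' \deqn{\%AAD = \frac{100}{n}\sum_i
#'   \left|\frac{\Omega_{i,cal} - \Omega_{i,exp}}{\Omega_{i,exp}}\right|.}
#' Scale-invariant: rescaling both series by a common nonzero factor leaves
#' it unchanged.
#'
#' @param s a [paired_series()].
#' @return the deviation in percent.
#' @export
aad_percent <- function(s) {
  zero <- which(s$experimental == 0)
  if (length(zero) > 0L) {
    stop("experimental value is zero at index ",
         paste(utils::head(zero, 5L), collapse = ", "),
         "; %AAD is undefined there")
  }
  mean(abs((s$calculated - s$experimental) / s$experimental)) * 100
}

#' Root mean square error
#'
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum_i (\Omega_{i,cal} - \Omega_{i,exp})^2},}
#' in the units of \eqn{\Omega}.
#'
#' @param s a [paired_series()].
#' @return the root-mean-square deviation (>= 0; 0 iff the series agree).
#' @export
rmse <- function(s) {
  sqrt(mean((s$calculated - s$experimental)^2))
}

#' Fit-style goodness measures
#'
#' \deqn{MSE = \frac{1}{n}\sum_i e_i^2, \quad
#'   NRMSE = 1 - \frac{\lVert e \rVert}{\lVert \Omega_{exp} - \bar\Omega_{exp} \rVert},
#'   \quad NMSE = 1 - \frac{\lVert e \rVert^2}{\lVert \Omega_{exp} - \bar\Omega_{exp} \rVert^2},}
#' with \eqn{e = \Omega_{exp} - \Omega_{cal}}.  These are the normalized
#' conventions in which 1 means a perfect fit, the reference is the
#' experimental series, and values go negative when the model is worse than
#' the experimental mean; they satisfy the identity
#' \eqn{NMSE = 1 - (1 - NRMSE)^2}.
#'
#' @param s a [paired_series()] with at least two pairs and a non-constant
#'   experimental series.
#' @return named vector `c(mse, nrmse, nmse)`.
#' @export
fit_metrics <- function(s) {
  if (nrow(s) < 2L) stop("fit metrics need at least two pairs")
  e <- s$experimental - s$calculated
  ref <- s$experimental - mean(s$experimental)
  ss_ref <- sum(ref^2)
  if (ss_ref == 0) {
    stop("experimental series is constant; NRMSE/NMSE are undefined")
  }
  ss_e <- sum(e^2)
  c(mse = ss_e / nrow(s),
    nrmse = 1 - sqrt(ss_e / ss_ref),
    nmse = 1 - ss_e / ss_ref)
}
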