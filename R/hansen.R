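# Hansen solubility parameters and the Flory-Huggins activity model built
# on them, plus the embedded substance table and the partition-coefficient
# reference report.

R_JOULE <- 8.314  # J/(mol K); delta^2 in MPa = J/cm^3, V in cm^3/mol

#' Hansen parameter record for one substance
#'
#' @param name substance name.
#' @param delta_d,delta_p,delta_h dispersion, polar and hydrogen-bonding
#'   solubility parameters (MPa^0.5).
#' @param delta_t total solubility parameter; computed as
#'   \eqn{(\delta_d^2+\delta_p^2+\delta_h^2)^{1/2}} when omitted.
#' @param V molar volume used by the Flory-Huggins model (cm^3/mol).
#' @param V_cosmo cavity-derived molar volume (cm^3/mol), informational.
#' @return a one-row data frame of class `hansen_record`.
#' @export
hansen_record <- function(name, delta_d, delta_p, delta_h, delta_t = NULL,
                          V, V_cosmo = NA_real_) {
  if (V <= 0) stop("molar volume must be positive")
  if (is.null(delta_t)) delta_t <- hansen_delta_t(delta_d, delta_p, delta_h)
  structure(data.frame(name = name, delta_d = delta_d, delta_p = delta_p,
                       delta_h = delta_h, delta_t = delta_t, V = V,
                       V_cosmo = V_cosmo, stringsAsFactors = FALSE),
            class = c("hansen_record", "data.frame"))
}

#' Total Hansen parameter from its components
#'
#' @param delta_d,delta_p,delta_h component parameters (MPa^0.5).
#' @return \eqn{\delta_t = (\delta_d^2 + \delta_p^2 + \delta_h^2)^{1/2}}.
#' @export
hansen_delta_t <- function(delta_d, delta_p, delta_h) {
  sqrt(delta_d^2 + delta_p^2 + delta_h^2)
}

#' Hansen parameters from group contributions
#'
#' Applies the group-contribution composition rules
#' \deqn{\delta_d = \frac{\sum_i F_{d,i}}{\sum_i V_i},\quad
#'   \delta_p = \frac{(\sum_i F_{p,i}^2)^{1/2}}{\sum_i V_i},\quad
#'   \delta_h = \frac{(\sum_i E_{h,i})^{1/2}}{\sum_i V_i},}
#' and \eqn{\delta_t} from the components.  Group values (molar attraction
#' constants and volumes) are user input.
#'
#' @param groups data frame with columns `F_d`, `F_p`, `E_h`, `V` — one row
#'   per structural group occurrence.
#' @param name substance name for the resulting record.
#' @return a [hansen_record()].
#' @export
hansen_from_groups <- function(groups, name = "substance") {
  groups <- as.data.frame(groups)
  if (nrow(groups) < 1L) stop("at least one group is required")
  if (any(groups$V <= 0)) stop("group volumes must be positive")
  Vsum <- sum(groups$V)
  hansen_record(name,
                delta_d = sum(groups$F_d) / Vsum,
                delta_p = sqrt(sum(groups$F_p^2)) / Vsum,
                delta_h = sqrt(sum(groups$E_h)) / Vsum,
                V = Vsum)
}

.as_hansen_df <- function(records) {
  if (inherits(records, "data.frame")) return(as.data.frame(records))
  do.call(rbind, lapply(records, as.data.frame))
}

#' Flory-Huggins interaction parameter from Hansen parameters
#'
#' \deqn{\chi_{ij} = \frac{V_i}{RT}\left[(\delta_{d,i}-\delta_{d,j})^2
#'   + 0.25(\delta_{p,i}-\delta_{p,j})^2
#'   + 0.25(\delta_{h,i}-\delta_{h,j})^2\right],}
#' with \eqn{R = 8.314} J/(mol K), \eqn{\delta^2} in MPa = J/cm^3 and
#' \eqn{V_i} in cm^3/mol, so \eqn{\chi} is dimensionless.  Note the
#' asymmetry: \eqn{\chi_{ij}} carries \eqn{V_i}, so
#' \eqn{\chi_{ji} = \chi_{ij} V_j / V_i}.
#'
#' @param rec_i,rec_j [hansen_record()]s (or one-row data frames with the
#'   same columns).
#' @param T temperature (K).
#' @return the dimensionless interaction parameter.
#' @export
fh_chi <- function(rec_i, rec_j, T) {
  if (T <= 0) stop("temperature must be positive")
  i <- as.data.frame(rec_i); j <- as.data.frame(rec_j)
  i$V / (R_JOULE * T) *
    ((i$delta_d - j$delta_d)^2 +
       0.25 * (i$delta_p - j$delta_p)^2 +
       0.25 * (i$delta_h - j$delta_h)^2)
}

#' Hansen-parameter Flory-Huggins activity model
#'
#' Activity coefficients from
#' \deqn{\ln\gamma_i = \ln\frac{\phi_i}{x_i} + 1 - \frac{\phi_i}{x_i}
#'   + 2 V_i \sum_j \chi_{ij}\phi_j^2 - V_i \sum_j\sum_k \phi_j\phi_k\chi_{jk},}
#' with volume fractions \eqn{\phi_i = x_i V_i / \sum_j x_j V_j}.  Because
#' \eqn{\chi_{ij}} of [fh_chi()] already contains \eqn{V_i}, the equation as
#' written multiplies by a volume twice; under the default
#' `convention = "per-volume"` the symmetric kernel \eqn{\chi_{ij}/V_i} is
#' used inside the \eqn{V_i}-weighted sums, restoring dimensional
#' consistency, while `"as-printed"` evaluates the expression literally.
#' Components at exactly zero mole fraction give infinite-dilution
#' coefficients.
#'
#' @param records list of [hansen_record()]s or a data frame with columns
#'   `name`, `delta_d`, `delta_p`, `delta_h`, `V` — the mixture's
#'   components, in order.
#' @param convention `"per-volume"` (default) or `"as-printed"`.
#' @return an `activity_model`; evaluate with [lngamma()].
#' @export
flory_huggins <- function(records, convention = c("per-volume", "as-printed")) {
  convention <- match.arg(convention)
  df <- .as_hansen_df(records)
  if (any(df$V <= 0)) stop("molar volumes must be positive")
  structure(list(records = df, convention = convention),
            class = c("flory_huggins", "activity_model"))
}

#' @rdname lngamma
#' @export
lngamma.flory_huggins <- function(model, x, T, ...) {
  df <- model$records
  k <- nrow(df)
  x <- .check_x(x, k)
  V <- df$V
  vbar <- sum(x * V)
  phi <- x * V / vbar
  phi_over_x <- V / vbar
  chi <- outer(seq_len(k), seq_len(k), function(i, j) {
    V[i] / (R_JOULE * T) *
      ((df$delta_d[i] - df$delta_d[j])^2 +
         0.25 * (df$delta_p[i] - df$delta_p[j])^2 +
         0.25 * (df$delta_h[i] - df$delta_h[j])^2)
  })
  kern <- if (model$convention == "per-volume") chi / V else chi
  quad <- as.numeric(t(phi) %*% kern %*% phi)
  pair <- as.vector(kern %*% phi^2)
  log(phi_over_x) + 1 - phi_over_x + 2 * V * pair - V * quad
}
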