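# Activity-coefficient models behind one `lngamma(model, x, T)` interface:
# the original segment-activity-coefficient model (51-bin profile, fixed
# exchange-energy constants), its temperature-dependent revision (NHB/OH/OT
# split), and the Hansen-parameter Flory-Huggins model (see R/hansen.R for
# the Hansen-specific pieces).

#' Staverman-Guggenheim combinatorial activity coefficient
#'
#' \deqn{\ln\gamma^C_i = \ln\frac{\phi_i}{x_i} + \frac{z}{2} q_i
#'   \ln\frac{\theta_i}{\phi_i} + l_i - \frac{\phi_i}{x_i}\sum_j x_j l_j,}
#' with \eqn{\theta_i = x_i q_i / \sum_j x_j q_j},
#' \eqn{\phi_i = x_i r_i / \sum_j x_j r_j} and
#' \eqn{l_i = \frac{z}{2}(r_i - q_i) - (r_i - 1)}.  The ratios
#' \eqn{\phi_i/x_i} and \eqn{\theta_i/\phi_i} are evaluated analytically so
#' components at exactly zero mole fraction (infinite dilution) are
#' supported without division by zero.
#'
#' @param x mole fractions summing to 1 (zeros allowed).
#' @param r normalized volumes.
#' @param q normalized surface areas.
#' @param z coordination number (default 10).
#' @return vector of \eqn{\ln\gamma^C_i}.
#' @export
combinatorial_lngamma <- function(x, r, q, z = 10) {
  if (abs(sum(x) - 1) > 1e-8) stop("mole fractions must sum to 1")
  if (any(r <= 0) || any(q <= 0)) stop("r and q must be strictly positive")
  rbar <- sum(x * r)
  qbar <- sum(x * q)
  l <- (z / 2) * (r - q) - (r - 1)
  phi_over_x <- r / rbar
  theta_over_phi <- (q / qbar) / phi_over_x
  log(phi_over_x) + (z / 2) * q * log(theta_over_phi) + l -
    phi_over_x * sum(x * l)
}

#' Segment exchange energy, original model
#'
#' \deqn{\Delta W(\sigma_m, \sigma_n) = \frac{\alpha'}{2}(\sigma_m+\sigma_n)^2
#'   + c_{hb}\,\max(0, \sigma_{acc}-\sigma_{hb})\,\min(0, \sigma_{don}+\sigma_{hb}),}
#' with \eqn{\sigma_{acc} = \max(\sigma_m,\sigma_n)} and
#' \eqn{\sigma_{don} = \min(\sigma_m,\sigma_n)}; symmetric in its arguments,
#' and the hydrogen-bond term is attractive (non-positive).
#'
#' @param sigma_m,sigma_n charge densities (e/A^2); vectorized.
#' @param params a [cosmosac2002_params()].
#' @return energies in kcal/mol per segment pair.
#' @export
exchange_energy_2002 <- function(sigma_m, sigma_n,
                                 params = cosmosac2002_params()) {
  acc <- pmax(sigma_m, sigma_n)
  don <- pmin(sigma_m, sigma_n)
  (params$alpha_prime / 2) * (sigma_m + sigma_n)^2 +
    params$c_hb * pmax(0, acc - params$sigma_hb) * pmin(0, don + params$sigma_hb)
}

#' Segment exchange energy, revised model
#'
#' \deqn{\Delta W = (A_{ES} + B_{ES}/T^2)(\sigma_m+\sigma_n)^2
#'   + s\,c_{hb}(t, s)\,(\sigma_m-\sigma_n)^2,}
#' where the hydrogen-bond constant is class-pair specific and nonzero only
#' for OH/OT pairs of segments with opposite-signed charge densities, and
#' the sign factor is `params$hb_sign` (default attractive, -1).
#'
#' @param sigma_m,sigma_n charge densities (e/A^2); vectorized.
#' @param class_m,class_n segment classes, each `"NHB"`, `"OH"` or `"OT"`.
#' @param T temperature (K).
#' @param params a [cosmosac2010_params()].
#' @return energies in kcal/mol per segment pair.
#' @export
exchange_energy_2010 <- function(sigma_m, sigma_n, class_m, class_n, T,
                                 params = cosmosac2010_params()) {
  ok <- c("NHB", "OH", "OT")
  if (!all(class_m %in% ok) || !all(class_n %in% ok)) {
    stop("segment classes must be NHB, OH or OT")
  }
  es <- (params$A_ES + params$B_ES / T^2) * (sigma_m + sigma_n)^2
  chb <- rep(0, length(es))
  opp <- sigma_m * sigma_n < 0
  oh_oh <- class_m == "OH" & class_n == "OH"
  ot_ot <- class_m == "OT" & class_n == "OT"
  oh_ot <- (class_m == "OH" & class_n == "OT") |
    (class_m == "OT" & class_n == "OH")
  chb[oh_oh & opp] <- params$c_OH_OH
  chb[ot_ot & opp] <- params$c_OT_OT
  chb[oh_ot & opp] <- params$c_OH_OT
  es + params$hb_sign * chb * (sigma_m - sigma_n)^2
}

#' Self-consistent segment activity coefficients
#'
#' Solves the fixed point
#' \deqn{\ln\Gamma(\sigma_m) = -\ln \sum_n p(\sigma_n)\,\Gamma(\sigma_n)
#'   \exp(-\Delta W(\sigma_m,\sigma_n)/RT)}
#' by damped successive substitution (damping 0.5 on the update), declared
#' converged when the undamped candidate changes by less than `tol` in
#' relative terms.
#'
#' @param p probability vector of the (possibly stacked split) profile,
#'   summing to 1.
#' @param W exchange-energy matrix (kcal/mol), `W[m, n]`.
#' @param T temperature (K).
#' @param R gas constant matching `W`'s units (kcal/(mol K)).
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxit maximum iterations before an error reporting the residual.
#' @param damping fraction of the new iterate accepted per step.
#' @return vector of segment activity coefficients \eqn{\Gamma}.
#' @export
segment_gamma <- function(p, W, T, R = 0.001987, tol = 1e-8, maxit = 1000L,
                          damping = 0.5) {
  if (T <= 0) stop("temperature must be positive")
  E <- exp(-W / (R * T))
  gam <- rep(1, length(p))
  for (it in seq_len(maxit)) {
    cand <- 1 / as.vector(E %*% (p * gam))
    rel <- max(abs(cand - gam) / gam)
    if (rel < tol) return(cand)
    gam <- (1 - damping) * gam + damping * cand
  }
  stop(sprintf("segment activity coefficients did not converge in %d iterations (residual %.3e)",
               maxit, rel))
}

#' Precompute sigma-profile components of a molecule
#'
#' Runs the charge averaging, histogramming and hydrogen-bonding split for
#' one molecule and records the molecular surface area and cavity volume
#' the activity models normalize with.
#'
#' @param mol a [cosmo_molecule()] with a known cavity volume.
#' @param r_ave averaging radius (A), see [average_charges()].
#' @param sigma0 split threshold (e/A^2), see [split_profile()].
#' @param grid charge-density grid.
#' @return object of class `cosmo_component`: list with `name`, `area`
#'   (A^2), `volume` (A^3), `profile` and `split`.
#' @export
cosmo_component <- function(mol, r_ave = 0.81764, sigma0 = 0.007,
                            grid = sigma_grid()) {
  if (is.null(mol$cavity_volume) || is.na(mol$cavity_volume)) {
    stop("molecule needs a cavity volume for the combinatorial term")
  }
  avg <- average_charges(mol, r_ave = r_ave)
  structure(list(name = mol$name,
                 area = mol$total_area,
                 volume = mol$cavity_volume,
                 profile = build_profile(avg, grid = grid),
                 split = split_profile(avg, sigma0 = sigma0, grid = grid)),
            class = "cosmo_component")
}

.as_components <- function(components, ...) {
  lapply(components, function(cc) {
    if (inherits(cc, "cosmo_component")) cc
    else if (inherits(cc, "cosmo_molecule")) cosmo_component(cc, ...)
    else stop("components must be cosmo_molecule or cosmo_component objects")
  })
}

#' Segment-activity-coefficient model over a fixed component list
#'
#' Builds an activity model for a mixture of the given molecules.  Version
#' `"2002"` operates on the plain 51-bin profile with fixed exchange-energy
#' constants; version `"2010"` couples the NHB/OH/OT parts of the split
#' profile with temperature-dependent electrostatics.  Evaluate with
#' [lngamma()].
#'
#' @param components list of [cosmo_molecule()] or [cosmo_component()]
#'   objects (the mixture's components, in order).
#' @param version `"2002"` or `"2010"`.
#' @param params model parameters; defaults to the version's standard set.
#' @param r_ave averaging radius used when raw molecules are supplied.
#' @return an `activity_model` object.
#' @export
cosmosac <- function(components, version = c("2002", "2010"), params = NULL,
                     r_ave = 0.81764) {
  version <- match.arg(version)
  if (is.null(params)) {
    params <- if (version == "2002") cosmosac2002_params() else cosmosac2010_params()
  }
  sigma0 <- if (version == "2010") params$sigma0 else 0.007
  comps <- .as_components(components, r_ave = r_ave, sigma0 = sigma0)
  grid <- comps[[1L]]$profile$grid
  structure(list(components = comps, params = params, grid = grid),
            class = c(paste0("cosmosac", version), "activity_model"))
}

#' Activity coefficients of a model at a composition
#'
#' Common interface of all activity models: returns the vector
#' \eqn{\ln\gamma_i} for the model's components at mole fractions `x` and
#' temperature `T`.  Exact zeros in `x` give infinite-dilution coefficients.
#'
#' @param model an `activity_model` (from [cosmosac()], [flory_huggins()]
#'   or [ideal_model()]).
#' @param x mole fractions summing to 1.
#' @param T temperature (K).
#' @param ... passed to methods.
#' @return numeric vector of \eqn{\ln\gamma_i}.
#' @export
lngamma <- function(model, x, T, ...) UseMethod("lngamma")

.check_x <- function(x, k) {
  if (length(x) != k) stop("x must have one mole fraction per component")
  if (any(x < -1e-12)) stop("mole fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-8) stop("mole fractions must sum to 1")
  pmax(x, 0)
}

#' @rdname lngamma
#' @export
lngamma.cosmosac2002 <- function(model, x, T, ...) {
  comps <- model$components
  p <- model$params
  x <- .check_x(x, length(comps))
  A <- vapply(comps, `[[`, 0, "area")
  V <- vapply(comps, `[[`, 0, "volume")
  r <- V / p$r0
  q <- A / p$q0
  n_i <- A / p$a_eff
  comb <- combinatorial_lngamma(x, r, q, z = p$z)

  W <- outer(model$grid, model$grid,
             function(a, b) exchange_energy_2002(a, b, p))
  mix <- mixture_profile(lapply(comps, `[[`, "profile"), x, areas = A)
  gam_S <- log(segment_gamma(mix$p, W, T, R = p$R))
  res <- vapply(seq_along(comps), function(i) {
    pi_ <- comps[[i]]$profile$p
    gam_i <- log(segment_gamma(pi_, W, T, R = p$R))
    n_i[i] * sum(pi_ * (gam_S - gam_i))
  }, 0)
  comb + res
}

.stack_split <- function(split) c(split$nhb, split$oh, split$ot)

#' @rdname lngamma
#' @export
lngamma.cosmosac2010 <- function(model, x, T, ...) {
  comps <- model$components
  p <- model$params
  x <- .check_x(x, length(comps))
  A <- vapply(comps, `[[`, 0, "area")
  V <- vapply(comps, `[[`, 0, "volume")
  r <- V / p$r0
  q <- A / p$q0
  n_i <- A / p$a_eff
  comb <- combinatorial_lngamma(x, r, q, z = p$z)

  nb <- length(model$grid)
  sig <- rep(model$grid, 3L)
  cls <- rep(c("NHB", "OH", "OT"), each = nb)
  W <- matrix(exchange_energy_2010(rep(sig, times = 3L * nb),
                                   rep(sig, each = 3L * nb),
                                   rep(cls, times = 3L * nb),
                                   rep(cls, each = 3L * nb),
                                   T, p),
              nrow = 3L * nb)
  mix <- mixture_profile(lapply(comps, `[[`, "split"), x, areas = A)
  p_mix <- .stack_split(mix)
  gam_S <- log(segment_gamma(p_mix, W, T, R = p$R))
  res <- vapply(seq_along(comps), function(i) {
    pi_ <- .stack_split(comps[[i]]$split)
    gam_i <- log(segment_gamma(pi_, W, T, R = p$R))
    n_i[i] * sum(pi_ * (gam_S - gam_i))
  }, 0)
  comb + res
}

#' Ideal-solution model
#'
#' An activity model with \eqn{\gamma_i \equiv 1}; useful as the reference
#' limit in solubility and cocrystal calculations and in tests.
#'
#' @param n_components number of components.
#' @return an `activity_model`.
#' @export
ideal_model <- function(n_components) {
  structure(list(n = as.integer(n_components)),
            class = c("ideal_model", "activity_model"))
}

#' @rdname lngamma
#' @export
lngamma.ideal_model <- function(model, x, T, ...) {
  x <- .check_x(x, model$n)
  rep(0, model$n)
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model: %s> %d component(s)\n", class(x)[1L],
              if (!is.null(x$components)) length(x$components)
              else if (!is.null(x$records)) nrow(x$records) else x$n))
  invisible(x)
}
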