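# Solid-liquid equilibria: ideal and activity-corrected solubility,
# octanol/water partition coefficients at infinite dilution, and cocrystal
# thermodynamics (solubility product, invariant points, cocrystal line,
# ternary diagrams).

R_GAS <- 8.314  # J/(mol K)

#' Fusion properties of a solid
#'
#' @param dHm fusion enthalpy (J/mol), > 0.
#' @param Tm melting temperature (K), > 0.
#' @param dCp solid-liquid heat-capacity difference (J/(mol K)); the
#'   default 0 drops the heat-capacity term of the equilibrium condition.
#' @return list of class `fusion_properties`.
#' @export
fusion_properties <- function(dHm, Tm, dCp = 0) {
  if (dHm <= 0 || Tm <= 0) stop("dHm and Tm must be positive")
  structure(list(dHm = dHm, Tm = Tm, dCp = dCp), class = "fusion_properties")
}

#' Ideal logarithmic solubility
#'
#' Right-hand side of the solid-liquid equilibrium condition with
#' \eqn{\gamma = 1}:
#' \deqn{\ln x = \frac{\Delta H_m}{R}\left(\frac{1}{T_m} - \frac{1}{T}\right)
#'   - \frac{\Delta C_p}{R}\left(1 - \frac{T_m}{T} - \ln\frac{T}{T_m}\right).}
#' The heat-capacity term vanishes identically at \eqn{T = T_m} and is zero
#' when `dCp = 0`.
#'
#' @param fus a [fusion_properties()].
#' @param T temperature (K).
#' @return \eqn{\ln x} of the ideal saturation mole fraction.
#' @export
ideal_ln_solubility <- function(fus, T) {
  if (any(T <= 0)) stop("temperature must be positive")
  fus$dHm / R_GAS * (1 / fus$Tm - 1 / T) -
    fus$dCp / R_GAS * (1 - fus$Tm / T - log(T / fus$Tm))
}

#' Saturation mole fraction of a solid in a (mixed) solvent
#'
#' Solves \eqn{\ln x = \ln x_{ideal} - \ln\gamma_{solute}(x)} by damped
#' fixed-point iteration: at each step the solvent mole fractions are the
#' solute-free fractions rescaled by \eqn{1 - x}.
#'
#' @param model an `activity_model` whose components are (solute, solvents
#'   ...) — the solute is component `solute`, the remaining components are
#'   the solvents in order.
#' @param fus [fusion_properties()] of the solute.
#' @param T temperature (K).
#' @param solvent_x solute-free solvent fractions (length = components - 1),
#'   summing to 1.
#' @param solute index of the solute component (default 1).
#' @param tol absolute tolerance on x (default 1e-8).
#' @param maxit maximum iterations.
#' @param damping fraction of the new iterate accepted per step.
#' @return the saturation mole fraction in (0, 1]; attribute `iterations`
#'   records the iteration count, `lngamma` the solute's \eqn{\ln\gamma} at
#'   saturation.  If the ideal term already exceeds 1 (T above the melting
#'   point) the value is clamped to 1 with a warning.
#' @export
solve_solubility <- function(model, fus, T, solvent_x = 1, solute = 1L,
                             tol = 1e-8, maxit = 500L, damping = 0.5) {
  n_comp <- .model_size(model)
  if (length(solvent_x) != n_comp - 1L) {
    stop("solvent_x must have one entry per non-solute component")
  }
  if (abs(sum(solvent_x) - 1) > 1e-8) stop("solvent_x must sum to 1")
  ideal <- ideal_ln_solubility(fus, T)
  if (ideal >= 0) {
    warning("ideal term gives x >= 1 (T >= Tm); returning x = 1")
    return(structure(1, iterations = 0L, lngamma = 0))
  }
  compose <- function(xs) {
    full <- numeric(n_comp)
    full[solute] <- xs
    full[-solute] <- (1 - xs) * solvent_x
    full
  }
  x <- exp(ideal)
  lng <- NA_real_
  for (it in seq_len(maxit)) {
    lng <- lngamma(model, compose(x), T)[solute]
    cand <- min(exp(ideal - lng), 1)
    if (abs(cand - x) < tol) {
      return(structure(cand, iterations = it, lngamma = lng))
    }
    x <- (1 - damping) * x + damping * cand
  }
  stop(sprintf("solubility iteration did not converge in %d steps (last x = %.6g)",
               maxit, x))
}

.model_size <- function(model) {
  if (!is.null(model$components)) length(model$components)
  else if (!is.null(model$records)) nrow(model$records)
  else model$n
}

#' Octanol/water partition specification
#'
#' The mutual-saturation state the partition coefficient refers to: the
#' octanol-rich phase contains `water_frac` mole fraction water (default
#' 0.275, remainder octanol), the water-rich phase is pure water, and the
#' total-concentration ratio of the two phases is `conc_ratio`
#' \eqn{= C_{o,W}/C_{o,O}} (default 0.151).
#'
#' @param water_frac mole fraction of water in the octanol-rich phase.
#' @param conc_ratio total concentration ratio water-rich / octanol-rich.
#' @return list of class `partition_spec`.
#' @export
partition_spec <- function(water_frac = 0.275, conc_ratio = 0.151) {
  if (water_frac < 0 || water_frac > 1) stop("water_frac must lie in [0, 1]")
  if (conc_ratio <= 0) stop("conc_ratio must be positive")
  structure(list(water_frac = water_frac, conc_ratio = conc_ratio),
            class = "partition_spec")
}

#' Partition coefficient from the two infinite-dilution coefficients
#'
#' \deqn{\log K_{OW} = \log_{10}\left(\frac{C_{o,W}\,\gamma^{W,\infty}}
#'   {C_{o,O}\,\gamma^{O,\infty}}\right).}
#' Invariant under rescaling both activity coefficients by a common factor;
#' equal coefficients give \eqn{\log_{10}} of the concentration ratio.
#'
#' @param gamma_w infinite-dilution activity coefficient in the water-rich
#'   phase.
#' @param gamma_o infinite-dilution activity coefficient in the
#'   octanol-rich phase.
#' @param conc_ratio total-concentration ratio \eqn{C_{o,W}/C_{o,O}}.
#' @return \eqn{\log_{10} K_{OW}}.
#' @export
kow_from_gammas <- function(gamma_w, gamma_o, conc_ratio = 0.151) {
  if (any(c(gamma_w, gamma_o, conc_ratio) <= 0)) {
    stop("activity coefficients and conc_ratio must be positive")
  }
  log10(conc_ratio * gamma_w / gamma_o)
}

#' Octanol/water partition coefficient of a solute
#'
#' Evaluates the solute's infinite-dilution activity coefficient in pure
#' water (`model_water`, components solute + water, at x = (0, 1)) and in
#' the water-saturated octanol phase (`model_octanol`, components solute +
#' water + octanol, at x = (0, water_frac, 1 - water_frac)), then combines
#' them with the concentration ratio.
#'
#' @param model_water `activity_model` over (solute, water).
#' @param model_octanol `activity_model` over (solute, water, octanol).
#' @param T temperature (K).
#' @param spec a [partition_spec()].
#' @param solute index of the solute in both models (default 1).
#' @return \eqn{\log_{10} K_{OW}}.
#' @export
log_kow <- function(model_water, model_octanol, T, spec = partition_spec(),
                    solute = 1L) {
  xw <- numeric(.model_size(model_water)); xw[-solute] <- 1
  ln_gw <- lngamma(model_water, xw, T)[solute]
  n_o <- .model_size(model_octanol)
  if (n_o != 3L) stop("model_octanol must have exactly 3 components (solute, water, octanol)")
  xo <- numeric(3L)
  xo[-solute] <- c(spec$water_frac, 1 - spec$water_frac)
  ln_go <- lngamma(model_octanol, xo, T)[solute]
  # combined in log space so extreme activity coefficients cannot overflow
  log10(spec$conc_ratio) + (ln_gw - ln_go) / log(10)
}

#' Cocrystal specification
#'
#' Stoichiometry \eqn{A_a B_b} and the temperature-specific solubility
#' product \eqn{K_{CC} = (x_A\gamma_A)^a (x_B\gamma_B)^b}, constant along
#' the cocrystal line and independent of the solvent.
#'
#' @param a,b positive integer stoichiometric coefficients.
#' @param K_cc solubility product (dimensionless activity product), > 0.
#' @return list of class `cocrystal_spec`.
#' @export
cocrystal_spec <- function(a = 1L, b = 1L, K_cc) {
  if (a < 1 || b < 1 || a != round(a) || b != round(b)) {
    stop("a and b must be positive integers")
  }
  if (K_cc <= 0) stop("K_cc must be positive")
  structure(list(a = as.integer(a), b = as.integer(b), K_cc = K_cc),
            class = "cocrystal_spec")
}

#' Solubility product from one saturation point
#'
#' \eqn{K_{CC} = (x_A\gamma_A)^a (x_B\gamma_B)^b}.  This is how the product
#' is calibrated from a single measured cocrystal solubility point.
#'
#' @param x_A,x_B mole fractions of the two formers, > 0.
#' @param gamma_A,gamma_B their activity coefficients, > 0.
#' @param a,b stoichiometric coefficients.
#' @return the activity product.
#' @export
kcc_from_point <- function(x_A, x_B, gamma_A, gamma_B, a = 1L, b = 1L) {
  if (any(c(x_A, x_B, gamma_A, gamma_B) <= 0)) {
    stop("mole fractions and activity coefficients must be positive")
  }
  (x_A * gamma_A)^a * (x_B * gamma_B)^b
}

# Saturated composition of solid `solid` (1 = A, 2 = B) when the solute-free
# liquid contains the OTHER former at fraction w (rest solvent).
.saturation_at <- function(model, fus, T, solid, w, ...) {
  other <- if (solid == 1L) 2L else 1L
  # components are (A, B, solvent); the non-solute components, in component
  # order, are (co-former, solvent) for either solid, so solvent_x = (w, 1-w)
  xs <- solve_solubility(model, fus, T, solvent_x = c(w, 1 - w),
                         solute = solid, ...)
  x <- numeric(3L)
  x[solid] <- as.numeric(xs)
  x[other] <- (1 - xs) * w
  x[3L] <- (1 - xs) * (1 - w)
  x
}

.kcc_residual <- function(model, spec, T, x) {
  lg <- lngamma(model, x, T)
  spec$a * (log(x[1L]) + lg[1L]) + spec$b * (log(x[2L]) + lg[2L]) -
    log(spec$K_cc)
}

#' Invariant points of a cocrystal ternary system
#'
#' Finds the two compositions where a pure-solid solubility line meets the
#' cocrystal line, i.e. where the pure solid (A on the first point, B on
#' the second) and the cocrystal saturate simultaneously.  Each point is
#' located by deterministic bisection along the corresponding solubility
#' line (parameterized by the co-former fraction in the solute-free
#' liquid), on a bracket found by a coarse scan.
#'
#' @param model `activity_model` over (A, B, solvent).
#' @param fus_A,fus_B [fusion_properties()] of the two formers.
#' @param spec a [cocrystal_spec()].
#' @param T temperature (K).
#' @param tol residual tolerance on \eqn{\ln} of the activity product.
#' @param n_scan points of the bracketing scan along each line.
#' @return data frame with rows `on_A_line` (the A-rich point, first) and
#'   `on_B_line`: columns `x_A`, `x_B`, `x_solvent`, `residual`.
#' @export
invariant_points <- function(model, fus_A, fus_B, spec, T,
                             tol = 1e-8, n_scan = 40L) {
  locate <- function(solid, fus) {
    f <- function(w) {
      .kcc_residual(model, spec, T, .saturation_at(model, fus, T, solid, w))
    }
    eps <- 1e-9
    ws <- seq(eps, 1 - eps, length.out = n_scan)
    vals <- vapply(ws, f, 0)
    sgn <- sign(vals)
    flip <- which(sgn[-1L] * sgn[-length(sgn)] <= 0 & is.finite(vals[-1L]))
    if (length(flip) == 0L) {
      stop("no invariant point; cocrystal region may not exist at T = ", T)
    }
    lo <- ws[flip[1L]]; hi <- ws[flip[1L] + 1L]
    flo <- vals[flip[1L]]
    repeat {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < tol || (hi - lo) < 1e-14) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    x <- .saturation_at(model, fus, T, solid, mid)
    c(x, fm)
  }
  pa <- locate(1L, fus_A)
  pb <- locate(2L, fus_B)
  out <- data.frame(x_A = c(pa[1L], pb[1L]), x_B = c(pa[2L], pb[2L]),
                    x_solvent = c(pa[3L], pb[3L]),
                    residual = c(pa[4L], pb[4L]),
                    row.names = c("on_A_line", "on_B_line"))
  # canonical order: the A-rich point first
  if (out$x_A[2L] > out$x_A[1L]) out <- out[c(2L, 1L), ]
  out
}

#' Cocrystal line between the invariant points
#'
#' For each \eqn{x_A} on a grid between the invariant points, solves the
#' solubility-product condition for \eqn{x_B} with activity coefficients
#' re-evaluated at the running composition (damped inner fixed point).
#' Endpoints equal the invariant points; `n_points = 2` returns exactly
#' those.
#'
#' @inheritParams invariant_points
#' @param invariants optional precomputed [invariant_points()] result.
#' @param n_points number of grid points (>= 2).
#' @param maxit inner iteration cap.
#' @return data frame with columns `x_A`, `x_B`, `x_solvent`, `residual`.
#' @export
cocrystal_line <- function(model, fus_A, fus_B, spec, T, invariants = NULL,
                           n_points = 25L, tol = 1e-8, maxit = 500L) {
  if (n_points < 2L) stop("n_points must be at least 2")
  if (is.null(invariants)) {
    invariants <- invariant_points(model, fus_A, fus_B, spec, T, tol = tol)
  }
  xa_grid <- seq(invariants$x_A[1L], invariants$x_A[2L], length.out = n_points)
  xb <- invariants$x_B[1L]
  m <- matrix(NA_real_, nrow = n_points, ncol = 4L)
  for (k in seq_along(xa_grid)) {
    xa <- xa_grid[k]
    converged <- FALSE
    for (it in seq_len(maxit)) {
      lg <- lngamma(model, c(xa, xb, 1 - xa - xb), T)
      res <- spec$a * (log(xa) + lg[1L]) + spec$b * (log(xb) + lg[2L]) -
        log(spec$K_cc)
      cand <- (spec$K_cc / (xa * exp(lg[1L]))^spec$a)^(1 / spec$b) / exp(lg[2L])
      if (abs(res) < tol) {
        # final undamped step: exact for the current activity coefficients
        xb <- cand
        converged <- TRUE
        break
      }
      xb <- 0.5 * xb + 0.5 * cand
    }
    if (!converged) {
      stop("cocrystal line iteration did not converge at grid index ", k)
    }
    res <- .kcc_residual(model, spec, T, c(xa, xb, 1 - xa - xb))
    m[k, ] <- c(xa, xb, 1 - xa - xb, res)
  }
  data.frame(x_A = m[, 1L], x_B = m[, 2L], x_solvent = m[, 3L],
             residual = m[, 4L])
}

#' Full cocrystal ternary phase diagram
#'
#' Assembles the two pure-solid solubility lines (saturation of A and of B
#' across a grid of solute-free liquid compositions up to the respective
#' invariant point), the cocrystal line between the invariant points, and
#' the invariant points themselves.  With `units = "mass"` all fractions
#' are converted using the supplied molar masses.
#'
#' @inheritParams invariant_points
#' @param n_points grid points per line.
#' @param units `"mole"` (default) or `"mass"`.
#' @param molar_masses named vector `c(A=, B=, solvent=)` (g/mol), required
#'   for mass fractions.
#' @return object of class `ternary_diagram`: list with data frames
#'   `solubility_A`, `solubility_B`, `cocrystal`, `invariant_points`, and
#'   the `units` flag.
#' @export
ternary_diagram <- function(model, fus_A, fus_B, spec, T, n_points = 25L,
                            units = c("mole", "mass"), molar_masses = NULL,
                            tol = 1e-8) {
  units <- match.arg(units)
  inv <- invariant_points(model, fus_A, fus_B, spec, T, tol = tol)
  sol_line <- function(solid, fus, w_max) {
    ws <- seq(0, w_max, length.out = n_points)
    m <- t(vapply(ws, function(w) {
      .saturation_at(model, fus, T, solid, w, tol = tol)
    }, numeric(3L)))
    data.frame(x_A = m[, 1L], x_B = m[, 2L], x_solvent = m[, 3L])
  }
  # solute-free co-former fraction w at each invariant point
  w_A <- inv["on_A_line", "x_B"] / (1 - inv["on_A_line", "x_A"])
  w_B <- inv["on_B_line", "x_A"] / (1 - inv["on_B_line", "x_B"])
  dia <- list(
    solubility_A = sol_line(1L, fus_A, w_A),
    solubility_B = sol_line(2L, fus_B, w_B),
    cocrystal = cocrystal_line(model, fus_A, fus_B, spec, T,
                               invariants = inv, n_points = n_points,
                               tol = tol)[, 1:3],
    invariant_points = inv,
    units = "mole"
  )
  if (units == "mass") {
    if (is.null(molar_masses) || length(molar_masses) != 3L) {
      stop("mass fractions need molar_masses = c(A=, B=, solvent=)")
    }
    to_mass <- function(df) {
      mm <- df
      tot <- df$x_A * molar_masses[1L] + df$x_B * molar_masses[2L] +
        df$x_solvent * molar_masses[3L]
      mm$x_A <- df$x_A * molar_masses[1L] / tot
      mm$x_B <- df$x_B * molar_masses[2L] / tot
      mm$x_solvent <- df$x_solvent * molar_masses[3L] / tot
      mm
    }
    dia$solubility_A <- to_mass(dia$solubility_A)
    dia$solubility_B <- to_mass(dia$solubility_B)
    dia$cocrystal <- to_mass(dia$cocrystal)
    dia$invariant_points[, 1:3] <- to_mass(dia$invariant_points[, 1:3])
    dia$units <- "mass"
  }
  structure(dia, class = "ternary_diagram")
}

#' @export
print.ternary_diagram <- function(x, ...) {
  cat(sprintf("<ternary_diagram> (%s fractions)\n", x$units))
  cat(sprintf("  solubility lines: %d + %d points; cocrystal line: %d points\n",
              nrow(x$solubility_A), nrow(x$solubility_B), nrow(x$cocrystal)))
  cat("  invariant points:\n")
  print(x$invariant_points[, 1:3], digits = 5)
  invisible(x)
}

#' @export
as.data.frame.ternary_diagram <- function(x, ...) {
  rbind(
    cbind(line = "solubility_A", x$solubility_A),
    cbind(line = "solubility_B", x$solubility_B),
    cbind(line = "cocrystal", x$cocrystal)
  )
}

#' Quick-look plot of a ternary diagram
#'
#' Base-graphics triangular plot: the A apex on top, B bottom-right,
#' solvent bottom-left.  Solubility lines solid, cocrystal line dashed,
#' invariant points as filled circles.
#'
#' @param x a [ternary_diagram()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ternary_diagram <- function(x, ...) {
  tri <- function(df) {
    cbind(df$x_B + df$x_A / 2, df$x_A * sqrt(3) / 2)
  }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, sqrt(3) / 2), asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), border = "grey40")
  graphics::lines(tri(x$solubility_A), col = "steelblue", lwd = 2)
  graphics::lines(tri(x$solubility_B), col = "firebrick", lwd = 2)
  graphics::lines(tri(x$cocrystal), col = "darkgreen", lwd = 2, lty = 2)
  graphics::points(tri(x$invariant_points), pch = 19)
  graphics::text(c(0.5, 1, 0), c(sqrt(3) / 2 + 0.03, -0.03, -0.03),
                 c("A", "B", "solvent"), xpd = NA)
  invisible(x)
}
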