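# Synthetic inputs: toy cavity-surface molecules with controlled charge
# structure (a stand-in for quantum-chemistry COSMO output that exercises
# the math, not the chemistry), noisy solubility studies with a stated
# noise model, and the embedded substance parameter table.

#' Generate a toy COSMO molecule
#'
#' Places `n_segments` equal-area segments on a sphere whose area is
#' `total_area` and draws charge densities per `pattern`:
#' * `"neutral-apolar"` — uniform draws in ±0.004 e/A^2 then shifted to an
#'   exactly zero net charge, so every |sigma| stays below the 0.0084
#'   hydrogen-bonding cutoff and hydrogen-bond energies are identically
#'   zero for this molecule.
#' * `"donor-acceptor-pair"` — two contiguous polar caps of opposite charge
#'   density ±`patch_sigma` (default 0.012, beyond the cutoff, so
#'   hydrogen-bond terms activate) over `2 * patch_fraction` of the
#'   segments, the rest weakly charged; net charge shifted to zero on the
#'   non-patch segments.
#' * `"uniform"` — every segment at `sigma_uniform`; feasible only while
#'   the implied net charge stays within the 0.01 e neutrality tolerance.
#'
#' When `hb_fraction > 0`, the segments nearest the +z pole (half the
#' tagged area) sit above an O/H atom pair (class OH) and those nearest the
#' -z pole above a nitrogen (class OT); the remainder sit above carbon.
#' Deterministic for a given `seed`; different seeds give different segment
#' positions.
#'
#' @param n_segments number of surface segments (>= 1).
#' @param total_area cavity surface area (A^2).
#' @param cavity_volume cavity volume (A^3).
#' @param pattern charge pattern, see above.
#' @param hb_fraction fraction of the area tagged OH/OT (in `[0, 1]`).
#' @param patch_sigma magnitude of the donor/acceptor charge density.
#' @param patch_fraction fraction of segments in each polar cap.
#' @param sigma_uniform charge density of the `"uniform"` pattern.
#' @param seed RNG seed (default 0); the global RNG state is untouched.
#' @param name molecule label.
#' @return a valid [cosmo_molecule()].
#' @export
make_toy_molecule <- function(n_segments = 60L, total_area = 120,
                              cavity_volume = 100,
                              pattern = c("neutral-apolar",
                                          "donor-acceptor-pair", "uniform"),
                              hb_fraction = 0, patch_sigma = 0.012,
                              patch_fraction = 0.2, sigma_uniform = 0,
                              seed = 0L, name = NULL) {
  pattern <- match.arg(pattern)
  if (n_segments < 1L) stop("n_segments must be at least 1")
  if (total_area <= 0 || cavity_volume <= 0) {
    stop("total_area and cavity_volume must be positive")
  }
  if (hb_fraction < 0 || hb_fraction > 1) stop("hb_fraction must lie in [0, 1]")
  if (hb_fraction > 0 && n_segments < 2L) {
    stop("infeasible pattern: hb_fraction > 0 needs at least 2 segments")
  }
  if (pattern == "uniform" &&
      abs(sigma_uniform) * total_area > 0.01) {
    stop("infeasible pattern: uniform sigma of ", sigma_uniform,
         " over ", total_area, " A^2 violates net-charge neutrality")
  }
  radius <- sqrt(total_area / (4 * pi))
  area <- rep(total_area / n_segments, n_segments)

  withr::with_seed(seed, {
    dirs <- matrix(rnorm(3L * n_segments), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- dirs * radius

    sigma <- switch(pattern,
      "neutral-apolar" = {
        s <- runif(n_segments, -0.004, 0.004)
        s - sum(s * area) / sum(area)
      },
      "donor-acceptor-pair" = {
        if (n_segments < 4L) {
          stop("infeasible pattern: donor-acceptor-pair needs at least 4 segments")
        }
        k <- max(1L, round(patch_fraction * n_segments))
        ord <- order(pos[, 3L])
        s <- runif(n_segments, -0.002, 0.002)
        plus <- utils::tail(ord, k)    # nearest +z pole
        minus <- utils::head(ord, k)   # nearest -z pole
        rest <- setdiff(seq_len(n_segments), c(plus, minus))
        s[plus] <- patch_sigma
        s[minus] <- -patch_sigma
        # patches cancel exactly (equal areas); neutralize on the rest
        if (length(rest) > 0L) {
          s[rest] <- s[rest] - sum(s[rest] * area[rest]) / sum(area[rest])
        }
        s
      },
      "uniform" = rep(sigma_uniform, n_segments)
    )
  })

  # atoms beneath the segments: carbon core, plus O-H (OH class) near the
  # +z pole and N (OT class) near the -z pole when hb area is requested
  atoms <- data.frame(element = "C", x = 0, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  atom_index <- rep(1L, n_segments)
  if (hb_fraction > 0) {
    oz <- 0.9 * radius
    atoms <- rbind(atoms,
                   data.frame(element = c("O", "H", "N"),
                              x = c(0, 0.3, 0),
                              y = c(0, 0, 0),
                              z = c(oz, oz + 0.8, -oz)))
    n_hb <- max(1L, round(hb_fraction * n_segments / 2))
    ord <- order(pos[, 3L])
    top <- utils::tail(ord, n_hb)
    bottom <- utils::head(ord, n_hb)
    atom_index[top] <- rep(c(2L, 3L), length.out = n_hb)  # O and its H
    atom_index[bottom] <- 4L                              # N
  }

  if (is.null(name)) name <- sprintf("toy-%s-seed%d", pattern, seed)
  segments <- data.frame(atom_index = atom_index,
                         x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                         charge = sigma * area, area = area,
                         charge_density = sigma, potential = 0)
  cosmo_molecule(name, atoms, segments, total_area = total_area,
                 cavity_volume = cavity_volume)
}

#' Generate a synthetic noisy solubility study
#'
#' The ground truth is the van 't Hoff solubility curve of a solid with the
#' given fusion properties (ideal solution unless `lngamma_fun` supplies an
#' activity correction); "experimental" points are the truth times
#' multiplicative log-normal noise, \eqn{x_{obs} = x_{true} e^{\epsilon}},
#' \eqn{\epsilon \sim N(0, sd^2)}.  Under this noise model the expected
#' absolute relative deviation of the truth from the data is
#' \eqn{E|e^{\epsilon} - 1| \approx sd\sqrt{2/\pi}} for small `sd` (about
#' 8% at `sd = 0.1`).
#'
#' @param fus [fusion_properties()] of the generating solid.
#' @param temperatures sampling temperatures (K).
#' @param sd standard deviation of the log-normal noise (>= 0).
#' @param lngamma_fun optional function of temperature returning the
#'   solute's \eqn{\ln\gamma} at saturation (default: ideal, 0).
#' @param seed RNG seed; same seed reproduces the dataset, different seeds
#'   change only the noise, never the truth.
#' @return list of class `solubility_study` with `data` (data frame `T`,
#'   `x_true`, `x_obs`), the generating `fus`, `sd` and `seed`.
#' @export
make_solubility_dataset <- function(fus,
                                    temperatures = seq(278.15, 323.15, by = 5),
                                    sd = 0.1, lngamma_fun = NULL, seed = 0L) {
  if (sd < 0) stop("sd must be non-negative")
  lng <- if (is.null(lngamma_fun)) function(T) 0 else lngamma_fun
  x_true <- vapply(temperatures,
                   function(T) exp(ideal_ln_solubility(fus, T) - lng(T)), 0)
  eps <- withr::with_seed(seed, rnorm(length(temperatures), 0, sd))
  structure(list(
    data = data.frame(T = temperatures, x_true = x_true,
                      x_obs = x_true * exp(eps)),
    fus = fus, sd = sd, seed = seed
  ), class = "solubility_study")
}

#' Recover the fusion enthalpy from a noisy solubility curve
#'
#' Least-squares fit of the ideal van 't Hoff line
#' \eqn{\ln x = \frac{\Delta H_m}{R}(1/T_m - 1/T)} (no intercept, melting
#' point known) to the observed solubilities.  Used for parameter-recovery
#' checks: at moderate noise the estimate falls within two standard errors
#' of the generating value.
#'
#' @param study a [make_solubility_dataset()] result.
#' @return named vector `c(estimate, se)` in J/mol.
#' @export
fit_fusion_enthalpy <- function(study) {
  z <- (1 / study$fus$Tm - 1 / study$data$T) / R_GAS
  fit <- lm(log(study$data$x_obs) ~ 0 + z)
  est <- coef(fit)[[1L]]
  se <- sqrt(diag(stats::vcov(fit)))[[1L]]
  c(estimate = est, se = se)
}

#' The embedded Hansen parameter table
#'
#' Hand-transcribed substance table: 13 solvents and 29 drug-like
#' compounds with total/dispersion/polar/hydrogen-bonding solubility
#' parameters (MPa^0.5), the molar volume used by the Flory-Huggins model
#' and the cavity-derived molar volume (cm^3/mol).  Rows whose source
#' digits are typographically ambiguous carry `ambiguous = TRUE` and are
#' excluded from consistency checks; shipped as a plain CSV under
#' `extdata/hansen_parameters.csv` (columns in the order printed here).
#'
#' @return data frame with columns `name`, `kind` (`solvent`/`drug`),
#'   `delta_t`, `delta_d`, `delta_p`, `delta_h`, `V`, `V_cosmo`,
#'   `ambiguous`.
#' @export
bundled_hansen_table <- function() {
  path <- system.file("extdata", "hansen_parameters.csv", package = "cosmopharm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$ambiguous <- as.logical(df$ambiguous)
  df
}

#' Look up one substance in the embedded Hansen table
#'
#' @param name substance name as printed in the table (case-insensitive).
#' @param table the table to search, default [bundled_hansen_table()].
#' @return a [hansen_record()].
#' @export
hansen_lookup <- function(name, table = bundled_hansen_table()) {
  hit <- which(tolower(table$name) == tolower(name))
  if (length(hit) == 0L) {
    stop("substance not found in the Hansen table: '", name, "'")
  }
  r <- table[hit[1L], ]
  hansen_record(r$name, r$delta_d, r$delta_p, r$delta_h,
                delta_t = r$delta_t, V = r$V, V_cosmo = r$V_cosmo)
}

#' The embedded octanol/water partition reference values
#'
#' Literature comparison table for the partition-coefficient workflow:
#' per-compound \eqn{\log_{10} K_{OW}} from the segment-activity model, the
#' Flory-Huggins model, and experiment.  Used by [fh_logkow_report()].
#'
#' @return data frame with columns `name`, `logkow_cosmosac`, `logkow_fh`,
#'   `logkow_exp`.
#' @export
bundled_logkow_reference <- function() {
  path <- system.file("extdata", "logkow_reference.csv", package = "cosmopharm",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Flory-Huggins partition coefficient of a named substance
#'
#' Convenience wrapper: builds the (solute, water) and (solute, water,
#' octanol) Flory-Huggins models from the embedded Hansen table and
#' evaluates [log_kow()].
#'
#' @param solute substance name in the Hansen table.
#' @param T temperature (K); 298.15 by default (ambient standard — the
#'   partition reference values state no temperature).
#' @param convention passed to [flory_huggins()].
#' @param spec a [partition_spec()].
#' @param table Hansen table to draw records from.
#' @return \eqn{\log_{10} K_{OW}}.
#' @export
fh_log_kow <- function(solute, T = 298.15,
                       convention = c("per-volume", "as-printed"),
                       spec = partition_spec(),
                       table = bundled_hansen_table()) {
  convention <- match.arg(convention)
  rec <- list(hansen_lookup(solute, table),
              hansen_lookup("Water", table),
              hansen_lookup("Octanol", table))
  mw <- flory_huggins(rec[1:2], convention = convention)
  mo <- flory_huggins(rec, convention = convention)
  log_kow(mw, mo, T, spec = spec)
}

#' Per-compound comparison of Flory-Huggins partition coefficients with
#' the reference table
#'
#' Computes \eqn{\log_{10} K_{OW}} for every reference compound available
#' in the embedded Hansen table under both interaction-parameter
#' conventions and reports the deviation from the tabulated Flory-Huggins
#' value per compound, rather than absorbing it into a single statistic.
#' A compound agrees when either convention reproduces the tabulated value
#' within `tol`.
#'
#' @param T temperature (K).
#' @param tol agreement tolerance on \eqn{\log_{10} K_{OW}}.
#' @return data frame with one row per compound: computed values under
#'   both conventions, the tabulated value, the smaller absolute deviation
#'   (`min_abs_dev`), the `agrees` flag and the Hansen-row `ambiguous`
#'   flag.
#' @export
fh_logkow_report <- function(T = 298.15, tol = 0.05) {
  ref <- bundled_logkow_reference()
  han <- bundled_hansen_table()
  keep <- ref$name %in% han$name
  ref <- ref[keep, ]
  pv <- vapply(ref$name, function(nm) {
    fh_log_kow(nm, T, convention = "per-volume", table = han)
  }, 0)
  ap <- vapply(ref$name, function(nm) {
    fh_log_kow(nm, T, convention = "as-printed", table = han)
  }, 0)
  dev <- pmin(abs(pv - ref$logkow_fh), abs(ap - ref$logkow_fh))
  data.frame(name = ref$name,
             computed_per_volume = unname(pv),
             computed_as_printed = unname(ap),
             reference_fh = ref$logkow_fh,
             min_abs_dev = unname(dev),
             agrees = unname(dev <= tol),
             ambiguous = han$ambiguous[match(ref$name, han$name)],
             stringsAsFactors = FALSE)
}
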