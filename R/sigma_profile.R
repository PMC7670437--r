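# Sigma-profile generation: Gaussian-distance averaging of raw segment
# charge densities, 51-bin histogramming with linear apportioning, the
# NHB/OH/OT hydrogen-bonding split, and mixture profiles.

#' The standard sigma-profile grid
#'
#' 51 charge densities from -0.025 to 0.025 e/A^2 in steps of 0.001.
#'
#' @param sigma_max half-width of the grid (e/A^2).
#' @param n_bins number of grid points (odd, so 0 is a grid point).
#' @return numeric vector of charge densities.
#' @export
sigma_grid <- function(sigma_max = 0.025, n_bins = 51L) {
  # rounded so grid values compare equal to their decimal literals
  round(seq(-sigma_max, sigma_max, length.out = n_bins), 10)
}

#' Average raw segment charge densities
#'
#' Replaces each segment's raw screening-charge density \eqn{\sigma^*_n} by a
#' Gaussian-distance-weighted mean over all segments,
#' \deqn{\sigma_m = \frac{\sum_n \sigma^*_n f_{mn}}{\sum_n f_{mn}}, \quad
#'   f_{mn} = \frac{r_{ave}^2 r_n^2}{r_{ave}^2 + r_n^2}
#'   \exp\!\left(-\frac{d_{mn}^2}{r_{ave}^2 + r_n^2}\right),}
#' with \eqn{r_n = (A_n/\pi)^{1/2}} the segment radius and \eqn{d_{mn}} the
#' distance between segment centres.  The segment itself (\eqn{d_{mm}=0})
#' is included in both sums.
#'
#' @param mol a [cosmo_molecule()] with at least one segment.
#' @param r_ave averaging radius in A; the default 0.81764 is the value used
#'   with the public sigma-profile databases.
#' @return data frame of averaged segments with columns `charge_density`
#'   (\eqn{\sigma_m}), `area` (A^2) and `hb_class`.
#' @export
average_charges <- function(mol, r_ave = 0.81764) {
  seg <- mol$segments
  if (nrow(seg) < 1L) stop("molecule has no segments")
  if (any(seg$area <= 0)) stop("zero or negative segment area")
  if (r_ave <= 0) stop("r_ave must be positive")
  pos <- as.matrix(seg[, c("x", "y", "z")])
  rn2 <- seg$area / pi
  denom <- r_ave^2 + rn2                       # length n, indexed by column n
  d2 <- as.matrix(stats::dist(pos))^2
  # weight matrix f[m, n]: row m is the target segment, column n the source
  f <- sweep(exp(-sweep(d2, 2L, denom, `/`)), 2L,
             r_ave^2 * rn2 / denom, `*`)
  sigma_m <- as.vector(f %*% seg$charge_density) / rowSums(f)
  data.frame(charge_density = sigma_m,
             area = seg$area,
             hb_class = segment_hb_classes(mol),
             stringsAsFactors = FALSE)
}

.bin_areas <- function(sigma, area, grid) {
  step <- grid[2L] - grid[1L]
  lo <- grid[1L]; hi <- grid[length(grid)]
  out <- numeric(length(grid))
  if (any(sigma < lo - 1e-15 | sigma > hi + 1e-15)) {
    warning(sprintf("%d segment(s) with |sigma| beyond %.3f e/A^2 clamped to the edge bins",
                    sum(sigma < lo | sigma > hi), hi))
    sigma <- pmin(pmax(sigma, lo), hi)
  }
  pos <- (sigma - lo) / step
  left <- pmin(floor(pos + 1e-12), length(grid) - 1L)  # 0-based left bin
  w <- pos - left                                      # in [0, 1)
  for (k in seq_along(sigma)) {
    i <- left[k] + 1L
    out[i] <- out[i] + (1 - w[k]) * area[k]
    if (w[k] > 0) out[i + 1L] <- out[i + 1L] + w[k] * area[k]
  }
  out
}

#' Build a sigma profile from averaged segments
#'
#' Each segment's area is linearly apportioned between the two bracketing
#' grid points: with \eqn{w = (\sigma - \sigma_{left})/0.001}, a fraction
#' \eqn{1-w} of the area goes to the left grid point and \eqn{w} to the
#' right, so the profile's mean charge density is conserved.  Probabilities
#' are the binned areas normalized to 1.  Segments outside the grid are
#' clamped to the edge bins with a warning.
#'
#' @param segments data frame from [average_charges()] (columns
#'   `charge_density`, `area`), or any data frame shaped like it.
#' @param grid charge-density grid, default [sigma_grid()].
#' @return an object of class `sigma_profile`: list with `grid`, `p`
#'   (probabilities summing to 1) and `total_area` (A^2), so the area
#'   profile is `p * total_area`.
#' @export
build_profile <- function(segments, grid = sigma_grid()) {
  A <- .bin_areas(segments$charge_density, segments$area, grid)
  total <- sum(A)
  structure(list(grid = grid, p = A / total, total_area = total),
            class = "sigma_profile")
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf("<sigma_profile> %d bins, total area %.3f A^2, sum(p) = %.6f\n",
              length(x$grid), x$total_area, sum(x$p)))
  invisible(x)
}

#' @export
as.data.frame.sigma_profile <- function(x, ...) {
  data.frame(sigma = x$grid, p = x$p, area = x$p * x$total_area)
}

#' Split a sigma profile into NHB, OH and OT parts
#'
#' The hydrogen-bonding split used by the revised activity model: in each
#' bin, the OH- and OT-tagged area is moved out of the NHB part with the
#' Gaussian weight \eqn{g(\sigma) = 1 - \exp(-\sigma^2/\sigma_o^2)} and is
#' divided between the OH and OT parts in proportion to the bin-wise tagged
#' areas \eqn{A^{OH}(\sigma)/(A^{OH}(\sigma)+A^{OT}(\sigma))}.  The three
#' parts sum to the unsplit profile exactly, and the OH/OT parts vanish at
#' \eqn{\sigma = 0} where \eqn{g = 0}.
#'
#' @param segments averaged segments from [average_charges()], carrying
#'   `hb_class` tags.
#' @param sigma0 hydrogen-bonding threshold \eqn{\sigma_o} (e/A^2),
#'   default 0.007.
#' @param grid charge-density grid.
#' @return an object of class `split_sigma_profile`: list with `grid`,
#'   probability vectors `nhb`, `oh`, `ot`, `total_area` and `sigma0`.
#' @export
split_profile <- function(segments, sigma0 = 0.007, grid = sigma_grid()) {
  if (sigma0 <= 0) stop("sigma0 must be positive")
  cls <- as.character(segments$hb_class)
  if (is.null(cls) || anyNA(cls)) cls <- rep("NHB", nrow(segments))
  bin_for <- function(keep) {
    if (!any(keep)) return(numeric(length(grid)))
    .bin_areas(segments$charge_density[keep], segments$area[keep], grid)
  }
  # suppress duplicate clamp warnings: clamping is reported by the total binning
  A_all <- .bin_areas(segments$charge_density, segments$area, grid)
  A_oh <- suppressWarnings(bin_for(cls == "OH"))
  A_ot <- suppressWarnings(bin_for(cls == "OT"))
  total <- sum(A_all)
  p <- A_all / total
  g <- 1 - exp(-grid^2 / sigma0^2)
  hb <- A_oh + A_ot
  frac_oh <- ifelse(hb > 0, A_oh / hb, 0)
  p_oh <- g * frac_oh * hb / total
  p_ot <- g * (1 - frac_oh) * hb / total
  p_ot[hb == 0] <- 0
  p_nhb <- p - p_oh - p_ot
  structure(list(grid = grid, nhb = p_nhb, oh = p_oh, ot = p_ot,
                 total_area = total, sigma0 = sigma0),
            class = "split_sigma_profile")
}

#' @export
print.split_sigma_profile <- function(x, ...) {
  cat(sprintf("<split_sigma_profile> total area %.3f A^2; part weights NHB %.3f / OH %.3f / OT %.3f\n",
              x$total_area, sum(x$nhb), sum(x$oh), sum(x$ot)))
  invisible(x)
}

#' @export
as.data.frame.split_sigma_profile <- function(x, ...) {
  data.frame(sigma = x$grid, nhb = x$nhb, oh = x$oh, ot = x$ot)
}

#' Mixture sigma profile
#'
#' Area-weighted mixing rule
#' \deqn{p_S(\sigma) = \frac{\sum_i x_i A_i p_i(\sigma)}{\sum_i x_i A_i},}
#' with \eqn{A_i} the total molecular surface areas.  Works for both plain
#' and split profiles (the split parts are mixed with the same weights).
#'
#' @param profiles list of `sigma_profile` (or all `split_sigma_profile`)
#'   objects on the same grid.
#' @param x mole fractions (non-negative, summing to 1).
#' @param areas molecular surface areas (A^2); defaults to the profiles'
#'   `total_area`.
#' @return a mixture profile of the same class as the inputs.
#' @export
mixture_profile <- function(profiles, x,
                            areas = vapply(profiles, `[[`, 0, "total_area")) {
  k <- length(profiles)
  if (length(x) != k || length(areas) != k) {
    stop("profiles, x and areas must have the same length")
  }
  if (any(x < -1e-12)) stop("mole fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-8) stop("mole fractions must sum to 1")
  w <- x * areas
  w <- w / sum(w)
  grid <- profiles[[1L]]$grid
  for (pr in profiles) {
    if (length(pr$grid) != length(grid) || any(abs(pr$grid - grid) > 1e-12)) {
      stop("all profiles must share the same grid")
    }
  }
  if (inherits(profiles[[1L]], "split_sigma_profile")) {
    mix_part <- function(part) {
      Reduce(`+`, Map(function(pr, wi) wi * pr[[part]], profiles, w))
    }
    structure(list(grid = grid, nhb = mix_part("nhb"), oh = mix_part("oh"),
                   ot = mix_part("ot"), total_area = sum(x * areas),
                   sigma0 = profiles[[1L]]$sigma0),
              class = "split_sigma_profile")
  } else {
    p <- Reduce(`+`, Map(function(pr, wi) wi * pr$p, profiles, w))
    structure(list(grid = grid, p = p, total_area = sum(x * areas)),
              class = "sigma_profile")
  }
}

#' Write a sigma profile as plain text
#'
#' 51 rows of `sigma  area` (A^2 per bin) for a plain profile; split
#' profiles add one area column per part (`nhb`, `oh`, `ot`).
#'
#' @param profile a `sigma_profile` or `split_sigma_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  if (inherits(profile, "split_sigma_profile")) {
    df <- data.frame(sigma = profile$grid,
                     nhb = profile$nhb * profile$total_area,
                     oh = profile$oh * profile$total_area,
                     ot = profile$ot * profile$total_area)
  } else {
    df <- data.frame(sigma = profile$grid,
                     area = profile$p * profile$total_area)
  }
  utils::write.table(format(df, digits = 10, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
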