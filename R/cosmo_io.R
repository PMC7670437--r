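# COSMO file input/output and hydrogen-bonding classification of surface
# segments.  Internal canonical units are Angstrom (lengths), A^2 (areas),
# A^3 (volumes) and elementary charge e; dialects that store atomic units
# are converted once, at parse time.

BOHR_TO_ANGSTROM <- 0.52917721067

# Covalent radii (A) used for bond detection; values for the elements the
# hydrogen-bonding classification needs.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  S = 1.05, Cl = 1.02, P = 1.07, Br = 1.20, I = 1.39
)

#' Construct a COSMO molecule object
#'
#' A `cosmo_molecule` bundles what the activity models need from a COSMO
#' calculation: the cavity's total surface area \eqn{A} and volume \eqn{V},
#' the atom list, and the segment table with per-segment position, charge,
#' area and screening-charge density \eqn{\sigma^* = q/a}.
#'
#' @param name molecule label.
#' @param atoms data frame with columns `element`, `x`, `y`, `z` (A).
#' @param segments data frame with columns `atom_index` (1-based row into
#'   `atoms`), `x`, `y`, `z` (A), `charge` (e), `area` (A^2),
#'   `charge_density` (e/A^2) and optionally `potential` (kept but unused).
#'   `charge_density` is filled from `charge/area` when missing.
#' @param total_area cavity surface area in A^2; defaults to the sum of
#'   segment areas.
#' @param cavity_volume cavity volume in A^3.
#' @param validate check the structural invariants (default `TRUE`).
#'
#' @return an object of class `cosmo_molecule`.
#' @export
cosmo_molecule <- function(name, atoms, segments,
                           total_area = NULL, cavity_volume = NULL,
                           validate = TRUE) {
  atoms <- as.data.frame(atoms)
  segments <- as.data.frame(segments)
  if (is.null(segments$charge_density)) {
    segments$charge_density <- segments$charge / segments$area
  }
  if (is.null(segments$charge)) {
    segments$charge <- segments$charge_density * segments$area
  }
  if (is.null(segments$potential)) segments$potential <- 0
  if (is.null(total_area)) total_area <- sum(segments$area)
  mol <- structure(
    list(name = as.character(name), total_area = total_area,
         cavity_volume = cavity_volume, atoms = atoms, segments = segments),
    class = "cosmo_molecule"
  )
  if (validate) validate_cosmo_molecule(mol)
  mol
}

#' Validate the invariants of a COSMO molecule
#'
#' Checks segment areas are positive, stored charge densities agree with
#' `charge/area`, the header area agrees with the segment table within 2%,
#' atom indices resolve, and the net surface charge is below 0.01 e (the
#' conductor neutralizes the molecule).
#'
#' @param mol a [cosmo_molecule()].
#' @param charge_tol permitted magnitude of the net surface charge (e).
#' @return `mol`, invisibly.
#' @export
validate_cosmo_molecule <- function(mol, charge_tol = 0.01) {
  seg <- mol$segments
  if (nrow(seg) < 1L) stop("cosmo_molecule has no segments")
  if (any(seg$area <= 0)) stop("segment areas must be strictly positive")
  rel <- abs(seg$charge_density - seg$charge / seg$area) /
    pmax(abs(seg$charge_density), 1e-12)
  bad <- which(abs(seg$charge) > 1e-12 & rel > 1e-6)
  if (length(bad) > 0L) {
    stop("charge_density inconsistent with charge/area at segment(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sum_area <- sum(seg$area)
  if (abs(mol$total_area - sum_area) > 0.02 * sum_area) {
    stop(sprintf(
      "header area %.4f A^2 differs from segment-table sum %.4f A^2 by more than 2%%",
      mol$total_area, sum_area))
  }
  if (nrow(mol$atoms) > 0L &&
      (any(seg$atom_index < 1L) || any(seg$atom_index > nrow(mol$atoms)))) {
    stop("segment atom_index points outside the atom list")
  }
  net <- sum(seg$charge)
  if (abs(net) > charge_tol) {
    stop(sprintf("net surface charge %.5f e exceeds tolerance %.3f e",
                 net, charge_tol))
  }
  invisible(mol)
}

#' @export
print.cosmo_molecule <- function(x, ...) {
  cat(sprintf("<cosmo_molecule> %s\n", x$name))
  cat(sprintf("  area %.3f A^2, volume %.3f A^3, %d atoms, %d segments, net charge %.2e e\n",
              x$total_area, x$cavity_volume, nrow(x$atoms),
              nrow(x$segments), sum(x$segments$charge)))
  invisible(x)
}

.extract_header_number <- function(lines, key) {
  hit <- grep(key, lines, ignore.case = TRUE, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  m <- regmatches(hit[1L],
                  regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?\\s*$", hit[1L]))
  if (length(m) == 0L) return(NA_real_)
  as.numeric(m)
}

.block_lines <- function(lines, sentinel) {
  start <- grep(sentinel, lines, fixed = TRUE)
  if (length(start) == 0L) return(NULL)
  start <- start[1L]
  ends <- grep("^\\s*\\$end", lines)
  end <- ends[ends > start]
  end <- if (length(end) == 0L) length(lines) + 1L else end[1L]
  if (end - start <= 1L) return(character(0))
  lines[(start + 1L):(end - 1L)]
}

#' Parse a COSMO file
#'
#' Reads the text of a continuum-solvation output file and returns a
#' [cosmo_molecule()].  Two layouts are supported: the `dmol3` flavour
#' written by [write_cosmo_file()] (all quantities already in A / A^2 / e)
#' and a `vt`-database flavour in which positions, areas, volumes and charge
#' densities are stored in atomic units (bohr) and converted here.  With
#' `dialect = "auto"` the atomic-unit layout is recognised by an `[au]` or
#' `(au)` marker.
#'
#' @param text file content as a single string or a character vector of lines.
#' @param dialect one of `"auto"`, `"dmol3"`, `"vt"`.
#' @param name molecule label; defaults to a name parsed from the file, else
#'   `"cosmo-molecule"`.
#' @param validate check invariants after parsing (default `TRUE`).
#' @return a [cosmo_molecule()].
#' @seealso [read_cosmo_file()] to parse directly from a path.
#' @export
parse_cosmo_file <- function(text, dialect = c("auto", "dmol3", "vt"),
                             name = NULL, validate = TRUE) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  if (dialect == "auto") {
    dialect <- if (any(grepl("\\[au\\]|\\(au\\)", lines))) "vt" else "dmol3"
  }
  seg_lines <- .block_lines(lines, "$segment_information")
  if (is.null(seg_lines)) {
    stop("no $segment_information block found: segment information section is missing")
  }
  seg_lines <- seg_lines[!grepl("^\\s*(#|!)", seg_lines) & nzchar(trimws(seg_lines))]
  if (length(seg_lines) == 0L) {
    stop("segment information section is present but empty")
  }
  seg <- do.call(rbind, lapply(seg_lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  }))
  if (ncol(seg) < 8L) stop("segment rows must have at least 8 columns")
  segments <- data.frame(
    atom_index = as.integer(seg[, 2L]),
    x = seg[, 3L], y = seg[, 4L], z = seg[, 5L],
    charge = seg[, 6L], area = seg[, 7L], charge_density = seg[, 8L],
    potential = if (ncol(seg) >= 9L) seg[, 9L] else 0
  )

  atom_lines <- .block_lines(lines, "$coordinates")
  atoms <- data.frame(element = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0))
  if (!is.null(atom_lines)) {
    atom_lines <- atom_lines[!grepl("^\\s*#", atom_lines) & nzchar(trimws(atom_lines))]
    if (length(atom_lines) > 0L) {
      parts <- lapply(atom_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
      atoms <- data.frame(
        element = vapply(parts, `[`, "", 1L),
        x = vapply(parts, function(p) as.numeric(p[2L]), 0),
        y = vapply(parts, function(p) as.numeric(p[3L]), 0),
        z = vapply(parts, function(p) as.numeric(p[4L]), 0)
      )
    }
  }

  total_area <- .extract_header_number(lines, "area")
  cavity_volume <- .extract_header_number(lines, "volume")

  if (dialect == "vt") {
    b <- BOHR_TO_ANGSTROM
    segments$x <- segments$x * b
    segments$y <- segments$y * b
    segments$z <- segments$z * b
    segments$area <- segments$area * b^2
    segments$charge_density <- segments$charge_density / b^2
    atoms$x <- atoms$x * b; atoms$y <- atoms$y * b; atoms$z <- atoms$z * b
    if (!is.na(total_area)) total_area <- total_area * b^2
    if (!is.na(cavity_volume)) cavity_volume <- cavity_volume * b^3
  }
  if (is.na(total_area)) total_area <- sum(segments$area)
  if (is.na(cavity_volume)) cavity_volume <- NA_real_

  if (is.null(name)) {
    nm <- grep("^\\s*\\$name", lines)
    name <- if (length(nm) > 0L && nm[1L] < length(lines)) {
      trimws(lines[nm[1L] + 1L])
    } else "cosmo-molecule"
  }
  cosmo_molecule(name, atoms, segments, total_area = total_area,
                 cavity_volume = cavity_volume, validate = validate)
}

#' Read a COSMO file from disk
#'
#' @param path file path.
#' @inheritParams parse_cosmo_file
#' @return a [cosmo_molecule()].
#' @export
read_cosmo_file <- function(path, dialect = c("auto", "dmol3", "vt"),
                            validate = TRUE) {
  parse_cosmo_file(readLines(path, warn = FALSE), dialect = match.arg(dialect),
                   validate = validate)
}

#' Write a COSMO molecule to the dmol3-flavoured text layout
#'
#' Emits the layout [parse_cosmo_file()] reads back losslessly (numbers at 9
#' decimal places, so a round trip agrees within 1e-9).  Output is
#' deterministic: equal molecules give byte-identical text.
#'
#' @param mol a valid [cosmo_molecule()].
#' @param path optional output path; when given the text is also written there.
#' @return the file content as a single string, invisibly when `path` is given.
#' @export
write_cosmo_file <- function(mol, path = NULL) {
  validate_cosmo_molecule(mol)
  seg <- mol$segments
  atom_rows <- if (nrow(mol$atoms) > 0L) {
    sprintf("%-2s %15.9f %15.9f %15.9f",
            mol$atoms$element, mol$atoms$x, mol$atoms$y, mol$atoms$z)
  } else character(0)
  seg_rows <- sprintf("%5d %5d %20.12e %20.12e %20.12e %20.12e %20.12e %20.12e %20.12e",
                      seq_len(nrow(seg)), seg$atom_index, seg$x, seg$y, seg$z,
                      seg$charge, seg$area, seg$charge_density, seg$potential)
  lines <- c(
    "COSMO Results (dmol3 flavour)",
    "$name",
    mol$name,
    "$cosmo_data",
    sprintf("  nps            = %d", nrow(seg)),
    sprintf("  Total surface area of cavity (A**2)   = %.12e", mol$total_area),
    sprintf("  Total volume of cavity (A**3)         = %.12e",
            if (is.null(mol$cavity_volume) || is.na(mol$cavity_volume)) 0
            else mol$cavity_volume),
    "$coordinates [A]",
    atom_rows,
    "$end",
    "$segment_information [A]",
    "#  n  atom        x               y               z            charge          area        charge/area      potential",
    seg_rows,
    "$end"
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Hydrogen-bonding class of every atom
#'
#' Classifies atoms into the three surface classes used by the
#' hydrogen-bonding split of the sigma profile: `"OH"` for oxygen and for
#' hydrogen covalently bonded to oxygen, `"OT"` for nitrogen and fluorine and
#' for hydrogen bonded to N or F, `"NHB"` otherwise.  Covalent bonds are
#' inferred from interatomic distances below 1.25 times the sum of covalent
#' radii.  A hydrogen bonded to both O and N/F is assigned `"OH"`.
#'
#' @param mol a [cosmo_molecule()] whose atom list is non-empty.
#' @param bond_scale multiplier on the sum of covalent radii (default 1.25).
#' @return character vector, one class per atom.
#' @export
atom_hb_classes <- function(mol, bond_scale = 1.25) {
  at <- mol$atoms
  n <- nrow(at)
  if (n == 0L) return(character(0))
  el <- as.character(at$element)
  radii <- .covalent_radii[el]
  if (anyNA(radii)) {
    radii[is.na(radii)] <- 0.75  # fallback for exotic elements: mid-range radius
  }
  pos <- as.matrix(at[, c("x", "y", "z")])
  cls <- rep("NHB", n)
  cls[el == "O"] <- "OH"
  cls[el %in% c("N", "F")] <- "OT"
  hyd <- which(el == "H")
  if (length(hyd) > 0L && n > 1L) {
    d <- as.matrix(stats::dist(pos))
    cutoff <- outer(radii, radii, `+`) * bond_scale
    for (h in hyd) {
      bonded <- which(d[h, ] < cutoff[h, ] & seq_len(n) != h)
      if (any(el[bonded] == "O")) {
        cls[h] <- "OH"
      } else if (any(el[bonded] %in% c("N", "F"))) {
        cls[h] <- "OT"
      }
    }
  }
  cls
}

#' Hydrogen-bonding class of every surface segment
#'
#' Each segment inherits the class of the atom beneath it (its
#' `atom_index`).  Molecules without an atom list get all-`"NHB"` segments.
#'
#' @inheritParams atom_hb_classes
#' @return character vector, one class per segment.
#' @export
segment_hb_classes <- function(mol, bond_scale = 1.25) {
  if (nrow(mol$atoms) == 0L) return(rep("NHB", nrow(mol$segments)))
  atom_hb_classes(mol, bond_scale)[mol$segments$atom_index]
}
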