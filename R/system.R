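#' Molecular systems with classical nuclei and quantum protons
#'
#' A `neo_system` divides a molecule into `N_e` electrons, `N_p` quantum
#' protons, and `N_c` classical point-charge nuclei. Quantum protons carry no
#' classical point charge anywhere: their charge enters the energy only
#' through their density. Positions are stored in bohr.
#'
#' @param classical data frame with columns `element`, `Z`, `x`, `y`, `z`
#'   (positions in bohr). May have zero rows.
#' @param protons matrix (`N_p` x 3) of quantum-proton basis-center positions
#'   in bohr, or `NULL` for none.
#' @param charge total molecular charge.
#' @param proton_mass quantum proton mass in units of the electron mass.
#' @return An object of class `neo_system` with fields `classical`,
#'   `proton_centers`, `n_electrons`, `n_protons`, `charge`, `proton_mass`.
#' @export
neo_system <- function(classical, protons = NULL, charge = 0,
                       proton_mass = PROTON_MASS) {
  if (is.null(classical)) {
    classical <- data.frame(element = character(), Z = numeric(),
                            x = numeric(), y = numeric(), z = numeric())
  }
  stopifnot(all(c("element", "Z", "x", "y", "z") %in% names(classical)))
  if (nrow(classical) > 0) {
    if (any(classical$Z <= 0)) stop("classical nuclear charges must be positive")
    if (!all(is.finite(as.matrix(classical[, c("x", "y", "z")])))) {
      stop("classical nuclear positions must be finite")
    }
  }
  if (is.null(protons)) protons <- matrix(numeric(), 0, 3)
  protons <- matrix(as.numeric(protons), ncol = 3)
  if (!all(is.finite(protons))) stop("quantum proton centers must be finite")
  if (proton_mass <= 1) stop("quantum proton mass must exceed the electron mass")
  n_p <- nrow(protons)
  n_e <- sum(classical$Z) + n_p - charge
  if (n_e < 2 || n_e %% 2 != 0) {
    stop("restricted closed-shell treatment requires an even electron count; ",
         "got N_e = ", n_e)
  }
  structure(
    list(classical = classical, proton_centers = protons,
         n_electrons = as.integer(n_e), n_protons = as.integer(n_p),
         charge = charge, proton_mass = proton_mass),
    class = "neo_system"
  )
}

#' @export
print.neo_system <- function(x, ...) {
  cat(sprintf("<neo_system: %d classical nuclei, %d quantum protons, N_e = %d, charge = %+d>\n",
              nrow(x$classical), x$n_protons, x$n_electrons, x$charge))
  invisible(x)
}

#' Read an XYZ geometry with quantum-proton tags
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom. Hydrogens are
#' promoted to quantum protons either through `quantum_tags` or through a
#' trailing `Q` token on the atom line (the file dialect).
#'
#' @param text XYZ content as a single string or character vector of lines;
#'   alternatively a file path.
#' @param quantum_tags `"all-H"`, an integer vector of 1-based atom indices
#'   (which must be hydrogens), or `NULL` to rely on `Q` suffix tokens.
#' @param charge total molecular charge.
#' @param proton_mass quantum proton mass (electron masses).
#' @return A [neo_system]. Coordinates are converted to bohr.
#' @export
read_xyz <- function(text, quantum_tags = NULL, charge = 0,
                     proton_mass = PROTON_MASS) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  if (length(lines) < 3) stop("XYZ parse error: fewer than 3 lines")
  n_atoms <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_atoms)) stop("XYZ parse error at line 1: atom count expected")
  if (length(lines) < 2 + n_atoms) {
    stop("XYZ parse error: expected ", n_atoms, " atom lines")
  }
  elements <- character(n_atoms)
  coords <- matrix(NA_real_, n_atoms, 3)
  tagged <- logical(n_atoms)
  for (i in seq_len(n_atoms)) {
    ln <- trimws(lines[2 + i])
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error at line ", 2 + i, ": expected 'element x y z'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("XYZ parse error at line ", 2 + i, ": non-numeric coordinate")
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
    if (length(tok) >= 5 && toupper(tok[5]) == "Q") tagged[i] <- TRUE
  }
  if (!is.null(quantum_tags)) {
    if (identical(quantum_tags, "all-H")) {
      tagged <- elements == "H"
    } else {
      idx <- as.integer(quantum_tags)
      if (any(idx < 1 | idx > n_atoms)) stop("quantum tag index out of range")
      if (any(elements[idx] != "H")) {
        stop("quantum tags must reference hydrogen atoms; offending index: ",
             paste(idx[elements[idx] != "H"], collapse = ", "))
      }
      tagged <- seq_len(n_atoms) %in% idx
    }
  }
  if (any(tagged & elements != "H")) {
    stop("only hydrogens can be tagged as quantum protons")
  }
  coords_bohr <- angstrom_to_bohr(coords)
  classical <- data.frame(
    element = elements[!tagged],
    Z = element_charge(elements[!tagged]),
    x = coords_bohr[!tagged, 1], y = coords_bohr[!tagged, 2],
    z = coords_bohr[!tagged, 3]
  )
  neo_system(classical, protons = coords_bohr[tagged, , drop = FALSE],
             charge = charge, proton_mass = proton_mass)
}

#' Write a system back to XYZ text
#'
#' Quantum protons are written as `H` lines carrying the `Q` suffix token.
#' Coordinates are emitted in Angstrom with enough digits to round-trip.
#'
#' @param system a [neo_system].
#' @param comment comment line content.
#' @return XYZ text (single string).
#' @export
write_xyz <- function(system, comment = "") {
  cl <- system$classical
  pr <- system$proton_centers
  n <- nrow(cl) + nrow(pr)
  fmt <- function(el, xyz, q = FALSE) {
    sprintf("%-2s %18.12f %18.12f %18.12f%s", el,
            bohr_to_angstrom(xyz[1]), bohr_to_angstrom(xyz[2]),
            bohr_to_angstrom(xyz[3]), if (q) " Q" else "")
  }
  lines <- c(as.character(n), comment)
  for (i in seq_len(nrow(cl))) {
    lines <- c(lines, fmt(cl$element[i], as.numeric(cl[i, c("x", "y", "z")])))
  }
  for (i in seq_len(nrow(pr))) {
    lines <- c(lines, fmt("H", pr[i, ], q = TRUE))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
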