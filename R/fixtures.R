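# Built-in molecular fixtures with every proton treated quantum mechanically.
# Geometries are standard experimental-style internal coordinates, hard-coded
# here (documented per fixture); the convergence and representation
# comparisons the package targets are made at fixed geometry, so literature
# equilibrium values are sufficient.

# unit vector at polar angle theta (deg, from +z) and azimuth phi (deg)
polar_dir <- function(theta, phi) {
  t <- theta * pi / 180; p <- phi * pi / 180
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

fixture_geometry <- function(name) {
  A <- function(el, xyz) list(element = el, xyz = xyz)
  switch(name,
    "h2" = {
      # r(HH) = 0.74 A
      list(atoms = list(A("H", c(0, 0, 0)), A("H", c(0, 0, 0.74))),
           charge = 0)
    },
    "water" = {
      # r(OH) = 0.9572 A, HOH = 104.52 deg
      half <- 104.52 / 2
      list(atoms = list(
        A("O", c(0, 0, 0)),
        A("H", 0.9572 * polar_dir(half, 0)),
        A("H", 0.9572 * polar_dir(-half, 0))
      ), charge = 0)
    },
    "h3o+" = {
      # C3v pyramid: r(OH) = 0.98 A, HOH = 111.6 deg
      cos_hoh <- cos(111.6 * pi / 180)
      cos_t <- sqrt((1 + 2 * cos_hoh) / 3) # polar angle from the C3 axis
      theta <- acos(cos_t) * 180 / pi
      list(atoms = c(list(A("O", c(0, 0, 0))),
                     lapply(c(0, 120, 240), function(phi) {
                       A("H", 0.98 * polar_dir(theta, phi))
                     })), charge = 1)
    },
    "acetylene" = {
      # r(CC) = 1.203 A, r(CH) = 1.0605 A, linear
      zc <- 1.203 / 2; zh <- zc + 1.0605
      list(atoms = list(A("C", c(0, 0, zc)), A("C", c(0, 0, -zc)),
                        A("H", c(0, 0, zh)), A("H", c(0, 0, -zh))),
           charge = 0)
    },
    "water_dimer" = {
      # planar-donor arrangement, r(OO) = 2.98 A along +x, monomer
      # r(OH) = 0.9572 A, HOH = 104.52 deg
      roh <- 0.9572; hoh <- 104.52 * pi / 180
      o1 <- c(0, 0, 0); o2 <- c(2.98, 0, 0)
      hd <- o1 + roh * c(1, 0, 0)                        # donor H on the O-O axis
      hb <- o1 + roh * c(cos(hoh), 0, sin(hoh))          # back H of the donor
      ha1 <- o2 + roh * c(cos(hoh / 2), sin(hoh / 2), 0) # acceptor Hs, xy plane
      ha2 <- o2 + roh * c(cos(hoh / 2), -sin(hoh / 2), 0)
      list(atoms = list(A("O", o1), A("O", o2), A("H", hd), A("H", hb),
                        A("H", ha1), A("H", ha2)), charge = 0)
    },
    "h5o2+" = {
      # Zundel cation: r(OO) = 2.40 A, shared proton midway; outer
      # r(OH) = 0.97 A at 55 deg off the O-O axis, perpendicular planes
      o1 <- c(0, 0, 0); o2 <- c(2.40, 0, 0)
      t <- 55 * pi / 180
      list(atoms = list(
        A("O", o1), A("O", o2),
        A("H", c(1.20, 0, 0)),
        A("H", o1 + 0.97 * c(-cos(t), 0, sin(t))),
        A("H", o1 + 0.97 * c(-cos(t), 0, -sin(t))),
        A("H", o2 + 0.97 * c(cos(t), sin(t), 0)),
        A("H", o2 + 0.97 * c(cos(t), -sin(t), 0))
      ), charge = 1)
    },
    "h9o4+" = {
      # Eigen cation: central hydronium (r(OH) = 1.0 A, flattened C3v),
      # three acceptor waters at r(OO) = 2.57 A along the O-H directions
      cos_hoh <- cos(109 * pi / 180)
      cos_t <- sqrt((1 + 2 * cos_hoh) / 3)
      theta <- acos(cos_t) * 180 / pi
      roh <- 0.9572; hoh <- 104.52 * pi / 180
      atoms <- list(A("O", c(0, 0, 0)))
      for (phi in c(0, 120, 240)) {
        u <- polar_dir(theta, phi)
        atoms <- c(atoms, list(A("H", 1.0 * u)))
        ow <- 2.57 * u
        atoms <- c(atoms, list(A("O", ow)))
        # acceptor water Hs: symmetric about the O-O axis, tilted back
        perp <- polar_dir(theta + 90, phi)
        for (sgn in c(1, -1)) {
          d <- cos(hoh / 2) * u + sgn * sin(hoh / 2) * perp
          atoms <- c(atoms, list(A("H", ow + roh * d)))
        }
      }
      list(atoms = atoms, charge = 1)
    },
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "))
  )
}

#' Names of the built-in fixtures
#'
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("h2", "water", "h3o+", "acetylene", "water_dimer", "h5o2+", "h9o4+")
}

#' Built-in molecular fixture
#'
#' Returns a deterministic geometry with all hydrogens promoted to quantum
#' protons, the built-in minimal electronic basis, and an even-tempered
#' protonic basis (defaults of [make_even_tempered_protonic]) on every proton
#' center.
#'
#' @param name one of [fixture_names()].
#' @param protonic list of even-tempered parameters (`n_s`, `n_p`, `alpha0`,
#'   `beta`) overriding the defaults.
#' @param electronic_basis built-in electronic basis name.
#' @return List with `system`, `basisdef`, `protonic_shells`, `name`.
#' @export
fixture <- function(name, protonic = list(), electronic_basis = "sto-3g") {
  geom <- fixture_geometry(name)
  elements <- vapply(geom$atoms, `[[`, character(1), "element")
  coords <- do.call(rbind, lapply(geom$atoms, `[[`, "xyz"))
  xyz_text <- paste(c(length(elements), name,
                      sprintf("%s %.10f %.10f %.10f%s", elements,
                              coords[, 1], coords[, 2], coords[, 3],
                              ifelse(elements == "H", " Q", ""))),
                    collapse = "\n")
  system <- read_xyz(xyz_text, charge = geom$charge)
  basisdef <- builtin_basis(electronic_basis)
  et <- modifyList(list(n_s = 4, n_p = 3, alpha0 = 4.0, beta = 2.5), protonic)
  protonic_shells <- lapply(seq_len(system$n_protons), function(i) {
    make_even_tempered_protonic(system$proton_centers[i, ], n_s = et$n_s,
                                n_p = et$n_p, alpha0 = et$alpha0,
                                beta = et$beta)
  })
  list(system = system, basisdef = basisdef,
       protonic_shells = protonic_shells, name = name)
}
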