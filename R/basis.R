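#' Contracted Cartesian Gaussian shells
#'
#' Shells carry a center (bohr), an angular momentum `l` (0, 1, or 2 giving
#' 1, 3, or 6 Cartesian components), primitive exponents (bohr^-2), and
#' contraction coefficients. Construction normalizes every contracted
#' Cartesian component to unit self-overlap.
#'
#' @param center numeric length-3, bohr.
#' @param l angular momentum, 0 (s), 1 (p) or 2 (d).
#' @param exponents positive primitive exponents.
#' @param coeffs contraction coefficients (same length as `exponents`).
#' @param kind `"electronic"` or `"protonic"`.
#' @return A list of class `gaussian_shell` with a per-component
#'   normalization vector `norms`.
#' @export
gaussian_shell <- function(center, l, exponents, coeffs,
                           kind = c("electronic", "protonic")) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  stopifnot(length(center) == 3, is.finite(center))
  l <- as.integer(l)
  if (l < 0 || l > 2) stop("unsupported angular momentum: l = ", l,
                           " (only s, p, d shells are implemented)")
  exponents <- as.numeric(exponents)
  coeffs <- as.numeric(coeffs)
  if (length(exponents) < 1) stop("a shell needs at least one primitive")
  if (any(exponents <= 0)) stop("primitive exponents must be positive")
  if (length(coeffs) != length(exponents)) {
    stop("exponents and coefficients must have equal length")
  }
  ord <- order(exponents, decreasing = TRUE)
  sh <- list(center = center, l = l, exponents = exponents[ord],
             coeffs = coeffs[ord], norms = rep(1, c(1, 3, 6)[l + 1]),
             kind = kind)
  class(sh) <- "gaussian_shell"
  sh$norms <- 1 / sqrt(shell_self_overlap_cpp(unclass(sh)))
  sh
}

n_components <- function(shell) c(1L, 3L, 6L)[shell$l + 1L]

n_basis_functions <- function(shells) {
  sum(vapply(shells, n_components, integer(1)))
}

# shift a shell to a new center, keeping normalization (translation invariant)
shell_at <- function(shell, center) {
  shell$center <- as.numeric(center)
  shell
}

#' Read a basis-set definition file
#'
#' The file maps element symbols to shell lists in JSON or YAML:
#' `{"H": [{"l": 0, "exponents": [...], "coeffs": [...]}], ...}`.
#' Shell templates are centered at the origin; they are placed on atoms when
#' a system is paired with the definition (see [electronic_shells]).
#'
#' @param text file path or literal JSON/YAML text.
#' @param kind particle kind for the resulting shells.
#' @return Named list: element symbol -> list of [gaussian_shell] templates.
#' @export
read_basis <- function(text, kind = c("electronic", "protonic")) {
  kind <- match.arg(kind)
  if (length(text) == 1 && !grepl("[\n{]", text) && file.exists(text)) {
    raw <- paste(readLines(text), collapse = "\n")
  } else {
    raw <- paste(text, collapse = "\n")
  }
  parsed <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                     error = function(e) yaml::yaml.load(raw))
  if (!is.list(parsed) || is.null(names(parsed))) {
    stop("basis file must map element symbols to shell lists")
  }
  lapply(parsed, function(shells) {
    lapply(shells, function(sh) {
      gaussian_shell(c(0, 0, 0), sh$l, unlist(sh$exponents),
                     unlist(sh$coeffs), kind = kind)
    })
  })
}

#' Even-tempered protonic basis generator
#'
#' Exponents follow the geometric progression `alpha0 * beta^k`,
#' `k = 0..n-1`, independently for the s and p sets. The defaults give a
#' compact 4s3p set appropriate for a proton bound to a first-row heavy atom.
#' All primitives are uncontracted.
#'
#' @param center proton basis center (bohr).
#' @param n_s,n_p number of s and p shells.
#' @param alpha0 smallest exponent (bohr^-2), > 0.
#' @param beta progression ratio, > 1.
#' @return List of protonic [gaussian_shell]s (length `n_s + n_p`).
#' @export
make_even_tempered_protonic <- function(center, n_s = 4, n_p = 3,
                                        alpha0 = 4.0, beta = 2.5) {
  if (alpha0 <= 0) stop("alpha0 must be positive")
  if (beta <= 1) stop("beta must exceed 1")
  n_s <- as.integer(n_s); n_p <- as.integer(n_p)
  if (n_s < 1 || n_p < 0) stop("need n_s >= 1 and n_p >= 0")
  shells <- list()
  for (k in seq_len(n_s) - 1) {
    shells <- c(shells, list(gaussian_shell(center, 0, alpha0 * beta^k, 1,
                                            kind = "protonic")))
  }
  for (k in seq_len(n_p) - 1) {
    shells <- c(shells, list(gaussian_shell(center, 1, alpha0 * beta^k, 1,
                                            kind = "protonic")))
  }
  shells
}

#' Place electronic shells on every atom of a system
#'
#' Classical nuclei and quantum-proton centers both carry electronic basis
#' functions (a quantum proton remains a basis center for the electrons).
#'
#' @param system a [neo_system].
#' @param basisdef element -> shell templates, from [read_basis] or
#'   [builtin_basis].
#' @return Flat list of electronic shells.
#' @export
electronic_shells <- function(system, basisdef) {
  shells <- list()
  cl <- system$classical
  for (i in seq_len(nrow(cl))) {
    el <- cl$element[i]
    if (is.null(basisdef[[el]])) stop("no basis entry for element ", el)
    at <- as.numeric(cl[i, c("x", "y", "z")])
    shells <- c(shells, lapply(basisdef[[el]], shell_at, center = at))
  }
  for (i in seq_len(system$n_protons)) {
    if (is.null(basisdef[["H"]])) stop("no basis entry for element H")
    shells <- c(shells, lapply(basisdef[["H"]], shell_at,
                               center = system$proton_centers[i, ]))
  }
  shells
}

#' Built-in electronic basis sets
#'
#' `"sto-3g"` ships with the package (H, C, N, O) as a plain JSON file under
#' `extdata`.
#'
#' @param name basis name.
#' @return Element -> shell templates.
#' @export
builtin_basis <- function(name = "sto-3g") {
  path <- system.file("extdata", paste0("basis-", tolower(name), ".json"),
                      package = "neoscf")
  if (path == "") stop("unknown built-in basis: ", name)
  read_basis(path, kind = "electronic")
}

#' Basis layout across representations
#'
#' Maps each quantum proton to the nuclear basis-function indices its
#' orbitals may occupy. Under `"SD"` all protons share one block spanning
#' every nuclear function. Under `"HP"`/`"HPstar"` each proton is restricted
#' by default to the shells centered on it; `shared_hp_layout = TRUE` gives
#' every proton the full shared set instead, so HP and SD can be compared in
#' an identical variational space.
#'
#' @param system a [neo_system].
#' @param protonic_shells list over protons: each element the shell list for
#'   that proton (typically from [make_even_tempered_protonic]).
#' @param representation `"SD"`, `"HP"`, or `"HPstar"`.
#' @param shared_hp_layout give each HP proton the full shared function set.
#' @return List with `shells` (flattened), `nbf`, `ranges` (per-proton index
#'   vectors), `representation`, `shared`.
#' @export
basis_layout <- function(system, protonic_shells,
                         representation = c("SD", "HP", "HPstar"),
                         shared_hp_layout = FALSE) {
  representation <- match.arg(representation)
  if (length(protonic_shells) != system$n_protons) {
    stop("protonic_shells must have one shell list per quantum proton")
  }
  counts <- vapply(protonic_shells, n_basis_functions, numeric(1))
  if (any(counts == 0)) stop("every quantum proton needs at least one basis function")
  shells <- do.call(c, protonic_shells)
  nbf <- sum(counts)
  ends <- cumsum(counts)
  starts <- c(1, head(ends, -1) + 1)
  own <- lapply(seq_along(counts), function(i) seq(starts[i], ends[i]))
  if (representation == "SD" || shared_hp_layout) {
    ranges <- rep(list(seq_len(nbf)), system$n_protons)
  } else {
    ranges <- own
  }
  list(shells = shells, nbf = nbf, ranges = ranges, own_ranges = own,
       representation = representation,
       shared = representation == "SD" || shared_hp_layout)
}
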