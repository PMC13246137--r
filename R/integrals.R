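#' Boys function
#'
#' `F_n(x) = integral_0^1 t^(2n) exp(-x t^2) dt`, the kernel of every
#' Gaussian Coulomb integral. Series/downward-recursion branch for moderate
#' `x`, erf closed form with upward recursion for large `x` (protonic
#' exponents routinely push `x` past 10^2).
#'
#' @param n order, non-negative integer.
#' @param x argument(s), `>= 0`.
#' @return `F_n(x)`, vectorized over `x`.
#' @export
boys <- function(n, x) {
  if (any(x < 0)) stop("boys: x must be >= 0")
  boys_cpp(as.integer(n), as.numeric(x))
}

strip_shells <- function(shells) lapply(shells, unclass)

#' Overlap and mass-scaled kinetic matrices
#'
#' @param shells list of [gaussian_shell]s.
#' @param mass particle mass in electron masses (1 for electrons, `m_p` for
#'   protons); the kinetic matrix carries the `1/mass` factor.
#' @return List with matrices `S` and `T`.
#' @export
overlap_kinetic <- function(shells, mass = 1) {
  stopifnot(mass > 0)
  overlap_kinetic_cpp(strip_shells(shells), mass)
}

#' Point-charge Coulomb matrix
#'
#' `V[mu, nu] = sign * sum_A Z_A <mu| 1 / |r - R_A| |nu>`; `sign = -1` for
#' electrons (attraction), `+1` for protons (repulsion).
#'
#' @param shells list of [gaussian_shell]s.
#' @param charges numeric charges `Z_A`.
#' @param centers matrix (`length(charges)` x 3) of charge positions, bohr.
#' @param sign -1 or +1.
#' @return Symmetric matrix `V`.
#' @export
point_charge_matrix <- function(shells, charges, centers, sign = -1) {
  stopifnot(sign %in% c(-1, 1))
  charges <- as.numeric(charges)
  centers <- matrix(as.numeric(centers), ncol = 3)
  stopifnot(nrow(centers) == length(charges))
  point_charge_cpp(strip_shells(shells), centers, charges, sign)
}

#' Two-cloud Coulomb repulsion tensor
#'
#' Chemist-ordered `(mu nu | la si)` over the 1/r12 kernel. The kernel is
#' particle-agnostic; interaction signs are applied by the Fock builders.
#' Schwarz screening drops shell quartets below `schwarz_thresh`.
#'
#' @param shells_bra,shells_ket shell lists for the two charge clouds; pass
#'   the same list (and the default `same = NULL`) for ee/pp tensors.
#' @param same force/deny 8-fold symmetry; by default inferred from identity
#'   of the two lists.
#' @param schwarz_thresh screening threshold.
#' @return 4-index array, dims `(n_bra, n_bra, n_ket, n_ket)`.
#' @export
coulomb_tensor <- function(shells_bra, shells_ket = shells_bra, same = NULL,
                           schwarz_thresh = 1e-14) {
  if (is.null(same)) same <- identical(shells_bra, shells_ket)
  eri_cpp(strip_shells(shells_bra), strip_shells(shells_ket), same,
          schwarz_thresh)
}

# reshape a (n1,n1,n2,n2) tensor into the (n1^2 x n2^2) J-contraction matrix
eri_as_matrix <- function(G) {
  d <- dim(G)
  matrix(G, d[1] * d[2], d[3] * d[4])
}

# K-contraction matrix for a same-kind tensor:
# K[mu,nu] = sum_{la,si} (mu la | si nu) D[la,si]
# Build M_K[(mu,nu),(la,si)] = G[mu,la,si,nu]
eri_k_matrix <- function(G) {
  d <- dim(G)[1]
  matrix(aperm(G, c(1, 4, 2, 3)), d * d, d * d)
}

contract_J <- function(M, D) {
  n <- as.integer(sqrt(nrow(M)))
  matrix(M %*% as.vector(D), n, n)
}

contract_J_ket <- function(M, D_bra) {
  n <- as.integer(sqrt(ncol(M)))
  matrix(crossprod(M, as.vector(D_bra)), n, n)
}

#' Assemble all integral tables for a NEO system
#'
#' Computes the one-body matrices (`Se`, `Te`, `Ve`, `he`, and the protonic
#' analogues with the `1/m_p` kinetic factor and repulsive classical-nucleus
#' sign) plus the ee, pp, and ep Coulomb tensors, pre-reshaped for J/K
#' contractions. Only classical nuclei enter the point-charge matrices and
#' the classical-classical repulsion `E_cc`; quantum protons interact through
#' their densities alone.
#'
#' @param system a [neo_system].
#' @param e_shells electronic shell list.
#' @param layout nuclear [basis_layout] (provides the protonic shells).
#' @return List of class `integral_tables`.
#' @export
integral_tables <- function(system, e_shells, layout) {
  p_shells <- layout$shells
  cl <- system$classical
  centers <- as.matrix(cl[, c("x", "y", "z")])
  charges <- cl$Z

  st_e <- overlap_kinetic(e_shells, mass = 1)
  st_p <- overlap_kinetic(p_shells, mass = system$proton_mass)
  ne <- nrow(st_e$S); np <- nrow(st_p$S)
  if (length(charges) > 0) {
    Ve <- point_charge_matrix(e_shells, charges, centers, sign = -1)
    Vp <- point_charge_matrix(p_shells, charges, centers, sign = +1)
    rr <- as.matrix(dist(centers))
    Ecc <- sum(outer(charges, charges)[upper.tri(rr)] / rr[upper.tri(rr)])
  } else {
    Ve <- matrix(0, ne, ne)
    Vp <- matrix(0, np, np)
    Ecc <- 0
  }
  Gee <- coulomb_tensor(e_shells)
  Gpp <- coulomb_tensor(p_shells)
  Gep <- coulomb_tensor(e_shells, p_shells, same = FALSE)

  tabs <- list(
    Se = st_e$S, Te = st_e$T, Ve = Ve, he = st_e$T + Ve,
    Sp = st_p$S, Tp = st_p$T, Vp = Vp, hp = st_p$T + Vp,
    Jee = eri_as_matrix(Gee), Kee = eri_k_matrix(Gee),
    Jpp = eri_as_matrix(Gpp), Kpp = eri_k_matrix(Gpp),
    Jep = eri_as_matrix(Gep),
    n_e_basis = ne, n_p_basis = np, Ecc = Ecc,
    Xe = sym_inv_sqrt(st_e$S),
    layout = layout, system = system
  )
  # per-block orthogonalizers for the nuclear subsystem
  tabs$Xp_blocks <- lapply(layout$ranges, function(r) {
    sym_inv_sqrt(st_p$S[r, r, drop = FALSE])
  })
  tabs$Xp <- sym_inv_sqrt(st_p$S)
  class(tabs) <- "integral_tables"
  tabs
}
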