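#' Initial-guess specification
#'
#' @param electronic `"core"` or `"sad"`.
#' @param nuclear `"core"` or `"sad"`.
#' @param perturb amplitude of a seeded random orthogonal perturbation of the
#'   guess orbitals (0 disables; used for robustness sweeps).
#' @param seed integer seed for the perturbation.
#' @param block_diagonal_core use the block-diagonalized nuclear core guess
#'   (one block per proton center); `FALSE` diagonalizes the full nuclear
#'   core Hamiltonian, which can localize several protons onto one center
#'   (kept available for pathological-guess experiments).
#' @return A `guess_spec` list.
#' @export
guess_spec <- function(electronic = c("sad", "core"),
                       nuclear = c("sad", "core"),
                       perturb = 0, seed = 1L, block_diagonal_core = TRUE) {
  electronic <- match.arg(electronic)
  nuclear <- match.arg(nuclear)
  if (perturb < 0) stop("perturbation amplitude must be >= 0")
  list(electronic = electronic, nuclear = nuclear, perturb = perturb,
       seed = as.integer(seed), block_diagonal_core = block_diagonal_core)
}

#' Electronic core (one-electron) guess
#'
#' Diagonalizes `h^e` (kinetic plus classical-nucleus attraction) in the
#' overlap metric. Known to be a poor guess; kept as the baseline.
#'
#' @param tabs [integral_tables].
#' @return List with `C` (all orbitals, aufbau order) and `values`.
#' @export
core_guess_electronic <- function(tabs) {
  generalized_eigen(tabs$he, tabs$Se, tabs$Xe)
}

# lowest generalized eigenvector of h restricted to index range r
lowest_block_orbital <- function(h, S, r) {
  es <- generalized_eigen(h[r, r, drop = FALSE], S[r, r, drop = FALSE])
  es$vectors[, 1]
}

#' Nuclear core guess
#'
#' Block-diagonalized variant: the inter-center blocks of `h^p` are zeroed
#' and each proton center's block is diagonalized separately, so no two
#' protons can localize onto the same basis-function center. For the
#' Hartree-product representations each proton's guess lives in its own
#' layout block. `block_diagonal = FALSE` diagonalizes the full core
#' Hamiltonian over each proton's block instead.
#'
#' @param tabs [integral_tables].
#' @param block_diagonal logical, see above.
#' @return Nuclear coefficients: for SD one full matrix (occupied first);
#'   for HP/HPstar a list of per-block matrices (occupied orbital first).
#' @export
core_guess_nuclear <- function(tabs, block_diagonal = TRUE) {
  layout <- tabs$layout
  np <- length(layout$ranges)
  n <- layout$nbf
  if (layout$representation == "SD") {
    if (block_diagonal) {
      occ <- matrix(0, n, np)
      for (i in seq_len(np)) {
        r <- layout$own_ranges[[i]]
        occ[r, i] <- lowest_block_orbital(tabs$hp, tabs$Sp, r)
      }
      occ <- orthonormalize_columns(occ, tabs$Sp)
      complete_orbitals(occ, tabs$Sp, tabs$Xp)
    } else {
      es <- generalized_eigen(tabs$hp, tabs$Sp, tabs$Xp)
      es$vectors
    }
  } else {
    lapply(seq_len(np), function(i) {
      rb <- layout$ranges[[i]]
      if (block_diagonal) {
        ro <- layout$own_ranges[[i]]
        v <- matrix(0, length(rb), 1)
        v[match(ro, rb), 1] <- lowest_block_orbital(tabs$hp, tabs$Sp, ro)
        v <- orthonormalize_columns(v, tabs$Sp[rb, rb, drop = FALSE])
        complete_orbitals(v, tabs$Sp[rb, rb, drop = FALSE],
                          tabs$Xp_blocks[[i]])
      } else {
        es <- generalized_eigen(tabs$hp[rb, rb, drop = FALSE],
                                tabs$Sp[rb, rb, drop = FALSE],
                                tabs$Xp_blocks[[i]])
        es$vectors
      }
    })
  }
}

# ---------------------------------------------------------------------------
# SAD: spherically averaged fractional-occupation atomic SCF per element
# ---------------------------------------------------------------------------

.sad_cache <- new.env(parent = emptyenv())

# degeneracy-averaged aufbau occupations (max 2 per orbital)
fractional_occupations <- function(eps, n_el, degeneracy_tol = 1e-6) {
  occ <- numeric(length(eps))
  remaining <- n_el
  i <- 1
  while (remaining > 1e-12 && i <= length(eps)) {
    group <- which(abs(eps - eps[i]) < degeneracy_tol & seq_along(eps) >= i)
    group <- group[group >= i]
    cap <- 2 * length(group)
    fill <- min(remaining, cap)
    occ[group] <- fill / length(group)
    remaining <- remaining - fill
    i <- max(group) + 1
  }
  occ
}

# converged spherically-averaged atomic density for one element in the given
# electronic basis templates; cached per element + basis signature
atomic_density <- function(element, templates, n_el = NULL) {
  key <- paste(element, paste(unlist(lapply(templates, function(s) {
    c(s$l, signif(s$exponents, 12), signif(s$coeffs, 12))
  })), collapse = ","), sep = "|")
  if (!is.null(.sad_cache[[key]])) return(.sad_cache[[key]])
  if (is.null(n_el)) n_el <- element_charge(element)
  shells <- lapply(templates, shell_at, center = c(0, 0, 0))
  st <- overlap_kinetic(shells, 1)
  V <- point_charge_matrix(shells, element_charge(element),
                           matrix(0, 1, 3), -1)
  h <- st$T + V
  S <- st$S
  X <- sym_inv_sqrt(S)
  G <- coulomb_tensor(shells)
  MJ <- eri_as_matrix(G); MK <- eri_k_matrix(G)
  es <- generalized_eigen(h, S, X)
  occ <- fractional_occupations(es$values, n_el)
  D <- es$vectors %*% (occ * t(es$vectors))
  E_old <- Inf
  converged <- FALSE
  for (it in 1:300) {
    F <- h + contract_J(MJ, D) - 0.5 * contract_J(MK, D)
    E <- 0.5 * sum(D * (h + F))
    es <- generalized_eigen(F, S, X)
    occ <- fractional_occupations(es$values, n_el)
    D_new <- es$vectors %*% (occ * t(es$vectors))
    D <- 0.7 * D_new + 0.3 * D    # mild damping keeps fractional SCF stable
    if (abs(E - E_old) < 1e-10 && it > 3) { converged <- TRUE; break }
    E_old <- E
  }
  if (!converged) {
    warning("atomic SCF for ", element,
            " did not converge; falling back to the core density")
    es <- generalized_eigen(h, S, X)
    occ <- fractional_occupations(es$values, n_el)
    D <- es$vectors %*% (occ * t(es$vectors))
  }
  .sad_cache[[key]] <- D
  D
}

#' Electronic SAD (superposition of atomic densities) guess
#'
#' Runs a spherically averaged, fractional-occupation atomic SCF per distinct
#' element in the system's own electronic basis (cached), assembles the
#' block-diagonal density over all atoms, and rescales it globally so
#' `Tr(D S) = N_e`. Quantum-proton centers contribute a hydrogen atomic
#' density for the electron they carry.
#'
#' @param system a [neo_system].
#' @param basisdef element -> electronic shell templates.
#' @param tabs [integral_tables] for the assembled system.
#' @return Electronic density matrix `D^e_SAD`.
#' @export
sad_guess_electronic <- function(system, basisdef, tabs) {
  cl <- system$classical
  elements <- c(cl$element, rep("H", system$n_protons))
  n <- tabs$n_e_basis
  D <- matrix(0, n, n)
  off <- 0
  for (el in elements) {
    templates <- basisdef[[el]]
    nb <- n_basis_functions(templates)
    idx <- off + seq_len(nb)
    D[idx, idx] <- atomic_density(el, templates)
    off <- off + nb
  }
  tr <- sum(D * tabs$Se)
  if (tr > 0) D <- D * (system$n_electrons / tr)
  D
}

#' Nuclear SAD guess
#'
#' Each proton's guess orbital is the ground state of
#' `h^p - J^pe[D^e_SAD]` restricted to the shells on its own center: a
#' one-proton problem in the frozen SAD electronic field. Inter-proton
#' Coulomb is deliberately omitted from the frozen field.
#'
#' @param tabs [integral_tables].
#' @param De_sad electronic SAD density.
#' @return Nuclear coefficients in the same shape as [core_guess_nuclear].
#' @export
sad_guess_nuclear <- function(tabs, De_sad) {
  layout <- tabs$layout
  np <- length(layout$ranges)
  hfield <- tabs$hp - contract_J_ket(tabs$Jep, De_sad)
  if (layout$representation == "SD") {
    occ <- matrix(0, layout$nbf, np)
    for (i in seq_len(np)) {
      r <- layout$own_ranges[[i]]
      occ[r, i] <- lowest_block_orbital(hfield, tabs$Sp, r)
    }
    occ <- orthonormalize_columns(occ, tabs$Sp)
    complete_orbitals(occ, tabs$Sp, tabs$Xp)
  } else {
    lapply(seq_len(np), function(i) {
      rb <- layout$ranges[[i]]
      ro <- layout$own_ranges[[i]]
      v <- matrix(0, length(rb), 1)
      v[match(ro, rb), 1] <- lowest_block_orbital(hfield, tabs$Sp, ro)
      v <- orthonormalize_columns(v, tabs$Sp[rb, rb, drop = FALSE])
      complete_orbitals(v, tabs$Sp[rb, rb, drop = FALSE],
                        tabs$Xp_blocks[[i]])
    })
  }
}

# seeded random orthogonal perturbation of a coefficient matrix (mixes
# occupied and virtual spaces through exp of a random skew generator)
perturb_coefficients <- function(C, S, amplitude, rng) {
  n <- ncol(C)
  if (amplitude == 0 || n < 2) return(C)
  K <- matrix(rng(n * n, amplitude), n, n)
  K <- K - t(K)
  orthonormalize_columns(C %*% skew_exp(K), S)
}

#' Assemble initial orbitals from a guess specification
#'
#' @param system a [neo_system].
#' @param basisdef electronic basis definition (needed for SAD).
#' @param tabs [integral_tables].
#' @param spec a [guess_spec].
#' @return List with electronic coefficients `Ce` and nuclear coefficients
#'   `Cp` (matrix for SD, list of block matrices for HP/HPstar).
#' @export
build_guess <- function(system, basisdef, tabs, spec = guess_spec()) {
  De_sad <- NULL
  if (spec$electronic == "sad" || spec$nuclear == "sad") {
    De_sad <- sad_guess_electronic(system, basisdef, tabs)
  }
  Ce <- if (spec$electronic == "core") {
    core_guess_electronic(tabs)$vectors
  } else {
    # orbitals of the Fock operator built from the SAD density (no proton
    # field yet): standard first diagonalization of the SAD guess
    Fe <- build_electronic_fock(tabs, De_sad, list())
    generalized_eigen(Fe, tabs$Se, tabs$Xe)$vectors
  }
  Cp <- if (spec$nuclear == "core") {
    core_guess_nuclear(tabs, block_diagonal = spec$block_diagonal_core)
  } else {
    sad_guess_nuclear(tabs, De_sad)
  }
  if (spec$perturb > 0) {
    set.seed(spec$seed)
    rng <- function(n, amp) rnorm(n, sd = amp)
    Ce <- perturb_coefficients(Ce, tabs$Se, spec$perturb, rng)
    if (is.matrix(Cp)) {
      Cp <- perturb_coefficients(Cp, tabs$Sp, spec$perturb, rng)
    } else {
      Cp <- lapply(seq_along(Cp), function(i) {
        rb <- tabs$layout$ranges[[i]]
        perturb_coefficients(Cp[[i]], tabs$Sp[rb, rb, drop = FALSE],
                             spec$perturb, rng)
      })
    }
  }
  list(Ce = Ce, Cp = Cp)
}
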