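# SCF state: orbital coefficients, densities, Fock matrices and energy for
# the electronic subsystem plus the nuclear subsystem in its representation
# (one shared block for SD, one block per proton for HP/HPstar).

n_occupied_electronic <- function(tabs) tabs$system$n_electrons / 2

# per-proton full-dimension densities from the nuclear coefficients
proton_densities <- function(tabs, Cp) {
  layout <- tabs$layout
  np <- length(layout$ranges)
  if (np == 0) return(list())
  if (is.matrix(Cp)) { # SD: occupied orbitals are the first Np columns
    lapply(seq_len(np), function(i) tcrossprod(Cp[, i]))
  } else {
    lapply(seq_len(np), function(i) {
      embed_block(tcrossprod(Cp[[i]][, 1]), layout$ranges[[i]], layout$nbf)
    })
  }
}

# full state (densities, Focks, energy) from orbital coefficients
state_from_coeffs <- function(tabs, Ce, Cp) {
  layout <- tabs$layout
  rep <- layout$representation
  De <- density_from_coeffs(Ce, n_occupied_electronic(tabs), 2)
  Dp_list <- proton_densities(tabs, Cp)
  Fe <- build_electronic_fock(tabs, De, Dp_list)
  Fp <- NULL
  if (length(Dp_list) > 0) {
    if (rep == "SD") {
      Fp <- build_nuclear_fock_sd(tabs, De, Reduce(`+`, Dp_list))
    } else {
      Fp <- lapply(seq_along(Dp_list), function(i) {
        build_nuclear_fock_hp(tabs, De, Dp_list, i,
                              include_self = (rep == "HPstar"))
      })
    }
  }
  report <- total_energy(tabs, De, Dp_list, rep)
  list(Ce = Ce, Cp = Cp, De = De, Dp_list = Dp_list, Fe = Fe, Fp = Fp,
       energy = report$total, report = report)
}

#' DIIS error vector
#'
#' `e = S^(-1/2) (F D S - S D F) S^(-1/2)`, the density-Fock commutator
#' transformed to an orthonormal basis, flattened.
#'
#' @param F,D,S Fock, density and overlap matrices of one subsystem block.
#' @param X optional cached `S^(-1/2)`.
#' @return Numeric vector.
#' @export
diis_error_vector <- function(F, D, S, X = NULL) {
  if (is.null(X)) X <- sym_inv_sqrt(S)
  as.vector(t(X) %*% (F %*% D %*% S - S %*% D %*% F) %*% X)
}

# electronic and nuclear error vectors for the current state
state_errors <- function(tabs, state) {
  layout <- tabs$layout
  e_e <- diis_error_vector(state$Fe, state$De, tabs$Se, tabs$Xe)
  if (length(state$Dp_list) == 0) {
    return(list(e = e_e, p = numeric(0)))
  }
  if (layout$representation == "SD") {
    Dp_tot <- Reduce(`+`, state$Dp_list)
    e_p <- diis_error_vector(state$Fp, Dp_tot, tabs$Sp, tabs$Xp)
  } else {
    e_p <- unlist(lapply(seq_along(state$Dp_list), function(i) {
      r <- layout$ranges[[i]]
      Db <- tcrossprod(state$Cp[[i]][, 1])
      diis_error_vector(state$Fp[[i]], Db, tabs$Sp[r, r, drop = FALSE],
                        tabs$Xp_blocks[[i]])
    }))
  }
  list(e = e_e, p = e_p)
}

rms <- function(x) if (length(x) == 0) 0 else sqrt(mean(x * x))

# maximum-overlap reassignment: pick n_occ columns of C maximizing overlap
# with the previous occupied space, then order them by eigenvalue
select_occupied_mom <- function(C, eps, S, C_prev_occ, n_occ) {
  O <- t(C) %*% S %*% C_prev_occ
  score <- rowSums(O * O)
  sel <- order(score, decreasing = TRUE)[seq_len(n_occ)]
  sel <- sel[order(eps[sel])]
  rest <- setdiff(seq_along(eps), sel)
  cbind(C[, sel, drop = FALSE], C[, rest, drop = FALSE])
}

# Mulliken-style population of orbital columns on each proton center
center_assignments <- function(C_occ, S, own_ranges) {
  vapply(seq_len(ncol(C_occ)), function(k) {
    w <- C_occ[, k] * (S %*% C_occ[, k])
    which.max(vapply(own_ranges, function(r) sum(w[r]), numeric(1)))
  }, integer(1))
}

# diagonalize given Fock matrices and reoccupy. Electrons and Hartree-product
# protons fill by aufbau. SD protons fill by aufbau too, falling back to
# maximum-overlap reassignment against the previous occupied space when the
# aufbau set localizes two protons onto the same basis-function center.
diagonalize_focks <- function(tabs, Fe, Fp, prev_Cp = NULL) {
  layout <- tabs$layout
  es_e <- generalized_eigen(Fe, tabs$Se, tabs$Xe)
  Ce <- es_e$vectors
  np <- length(layout$ranges)
  if (np == 0) return(list(Ce = Ce, Cp = NULL))
  if (layout$representation == "SD") {
    es_p <- generalized_eigen(Fp, tabs$Sp, tabs$Xp)
    Cp <- es_p$vectors
    if (np > 1 && !is.null(prev_Cp)) {
      centers <- center_assignments(Cp[, seq_len(np), drop = FALSE], tabs$Sp,
                                    layout$own_ranges)
      if (anyDuplicated(centers) > 0) {
        Cp <- select_occupied_mom(Cp, es_p$values, tabs$Sp,
                                  prev_Cp[, seq_len(np), drop = FALSE], np)
      }
    }
  } else {
    Cp <- lapply(seq_len(np), function(i) {
      r <- layout$ranges[[i]]
      es <- generalized_eigen(Fp[[i]], tabs$Sp[r, r, drop = FALSE],
                              tabs$Xp_blocks[[i]])
      es$vectors
    })
  }
  list(Ce = Ce, Cp = Cp)
}

# ---------------------------------------------------------------------------
# Orbital-rotation parameterization: packed occupied-virtual step vectors
# ---------------------------------------------------------------------------

# description of every rotation block: electrons first, then nuclear blocks
rotation_blocks <- function(tabs, state) {
  layout <- tabs$layout
  blocks <- list(list(kind = "e", occ = 2, no = n_occupied_electronic(tabs),
                      nb = tabs$n_e_basis, C = state$Ce, F = state$Fe,
                      S = tabs$Se))
  np <- length(layout$ranges)
  if (np > 0) {
    if (layout$representation == "SD") {
      blocks <- c(blocks, list(list(kind = "p", occ = 1, no = np,
                                    nb = layout$nbf, C = state$Cp,
                                    F = state$Fp, S = tabs$Sp)))
    } else {
      for (i in seq_len(np)) {
        r <- layout$ranges[[i]]
        blocks <- c(blocks, list(list(
          kind = "p", occ = 1, no = 1, nb = length(r), C = state$Cp[[i]],
          F = state$Fp[[i]], S = tabs$Sp[r, r, drop = FALSE])))
      }
    }
  }
  blocks
}

block_sizes <- function(blocks) {
  vapply(blocks, function(b) (b$nb - b$no) * b$no, numeric(1))
}

unpack_step <- function(s, blocks) {
  sizes <- block_sizes(blocks)
  stopifnot(length(s) == sum(sizes))
  out <- vector("list", length(blocks))
  off <- 0
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    out[[k]] <- matrix(s[off + seq_len(sizes[k])], b$nb - b$no, b$no)
    off <- off + sizes[k]
  }
  out
}

pack_step <- function(mats) unlist(lapply(mats, as.vector))

#' Stacked orbital-rotation gradient
#'
#' First derivative of the NEO energy with respect to the skew-symmetric
#' occupied-virtual rotation generators, `g_ai = 2 * occ * F^MO_ai`,
#' evaluated per subsystem and concatenated (electronic block first, nuclear
#' block(s) after; one block per proton under HP/HPstar).
#'
#' @param tabs [integral_tables].
#' @param state SCF state whose Fock matrices are consistent with its
#'   densities.
#' @return Packed numeric gradient.
#' @export
orbital_gradient <- function(tabs, state) {
  blocks <- rotation_blocks(tabs, state)
  pack_step(lapply(blocks, function(b) {
    Fmo <- crossprod(b$C, b$F %*% b$C)
    2 * b$occ * Fmo[b$no + seq_len(b$nb - b$no), seq_len(b$no), drop = FALSE]
  }))
}

#' Apply a packed orbital rotation
#'
#' `C <- C exp(kappa)` per subsystem block, with `kappa` the skew-symmetric
#' matrix whose occupied-virtual block is the unpacked step. Orthonormality
#' is restored by symmetric re-orthogonalization when drift exceeds 1e-10.
#'
#' @param tabs [integral_tables].
#' @param state current state.
#' @param s packed step (same layout as [orbital_gradient]).
#' @return New state (densities, Focks and energy rebuilt).
#' @export
apply_rotation <- function(tabs, state, s) {
  blocks <- rotation_blocks(tabs, state)
  steps <- unpack_step(s, blocks)
  new_C <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    K <- matrix(0, b$nb, b$nb)
    iv <- b$no + seq_len(b$nb - b$no)
    io <- seq_len(b$no)
    K[iv, io] <- steps[[k]]
    K[io, iv] <- -t(steps[[k]])
    Cn <- b$C %*% skew_exp(K)
    drift <- max(abs(crossprod(Cn, b$S %*% Cn) - diag(b$nb)))
    if (drift > 1e-10) Cn <- orthonormalize_columns(Cn, b$S)
    new_C[[k]] <- Cn
  }
  Ce <- new_C[[1]]
  layout <- tabs$layout
  np <- length(layout$ranges)
  Cp <- state$Cp
  if (np > 0) {
    if (layout$representation == "SD") {
      Cp <- new_C[[2]]
    } else {
      Cp <- new_C[-1]
    }
  }
  state_from_coeffs(tabs, Ce, Cp)
}

#' Exact coupled orbital Hessian action (Slater-determinant representation)
#'
#' Computes `H v` for the full electronic+nuclear orbital Hessian at the
#' current state, assembled from Fock-like contractions of the first-order
#' (rotated) densities; the electron-proton blocks couple the two subsystems.
#' Available for the SD representation (the HP off-diagonal coupling blocks
#' are out of scope, matching the solver support).
#'
#' @param tabs [integral_tables].
#' @param state SCF state.
#' @param v packed direction (same layout as the gradient).
#' @return Packed `H v`.
#' @export
hessian_vector_product <- function(tabs, state, v) {
  if (tabs$layout$representation != "SD" && length(tabs$layout$ranges) > 0) {
    stop("hessian_vector_product supports the SD representation only")
  }
  blocks <- rotation_blocks(tabs, state)
  Vs <- unpack_step(v, blocks)
  np <- length(tabs$layout$ranges)
  # antisymmetric MO matrices and first-order AO densities per subsystem
  Vfull <- vector("list", length(blocks))
  Xao <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    V <- matrix(0, b$nb, b$nb)
    iv <- b$no + seq_len(b$nb - b$no); io <- seq_len(b$no)
    V[iv, io] <- Vs[[k]]
    V[io, iv] <- -t(Vs[[k]])
    Vfull[[k]] <- V
    P <- diag(c(rep(1, b$no), rep(0, b$nb - b$no)))
    Xao[[k]] <- b$occ * b$C %*% (V %*% P - P %*% V) %*% t(b$C)
  }
  # response Fock matrices from the two-particle kernels
  Xe <- Xao[[1]]
  Ft <- vector("list", length(blocks))
  Ft[[1]] <- contract_J(tabs$Jee, Xe) - 0.5 * contract_J(tabs$Kee, Xe)
  if (np > 0) {
    Xp <- Xao[[2]]
    Ft[[1]] <- Ft[[1]] - contract_J(tabs$Jep, Xp)
    Ft[[2]] <- contract_J(tabs$Jpp, Xp) - contract_J(tabs$Kpp, Xp) -
      contract_J_ket(tabs$Jep, Xe)
  }
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    V <- Vfull[[k]]
    P <- diag(c(rep(1, b$no), rep(0, b$nb - b$no)))
    Fmo <- crossprod(b$C, b$F %*% b$C)
    Ftmo <- crossprod(b$C, Ft[[k]] %*% b$C)
    Q <- P %*% Fmo + Fmo %*% P
    W <- b$occ * (0.5 * (V %*% Q + Q %*% V) - P %*% V %*% Fmo -
                  Fmo %*% V %*% P + P %*% Ftmo - Ftmo %*% P)
    A <- t(W) - W
    out[[k]] <- A[b$no + seq_len(b$nb - b$no), seq_len(b$no), drop = FALSE]
  }
  pack_step(out)
}

# approximate Hessian diagonal from MO Fock diagonals (orbital-energy
# differences), used as Davidson preconditioner and GDM preconditioner
hessian_diagonal <- function(tabs, state, floor_at = 0.05) {
  blocks <- rotation_blocks(tabs, state)
  pack_step(lapply(blocks, function(b) {
    Fmo <- crossprod(b$C, b$F %*% b$C)
    eps <- diag(Fmo)
    d <- outer(eps[b$no + seq_len(b$nb - b$no)], eps[seq_len(b$no)], `-`)
    matrix(pmax(2 * b$occ * d, floor_at), b$nb - b$no, b$no)
  }))
}
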