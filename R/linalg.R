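# Dense symmetric linear algebra helpers shared by the SCF machinery.

# S^(-1/2) by eigendecomposition; warns on near linear dependence.
sym_inv_sqrt <- function(S, lindep_tol = 1e-8) {
  if (nrow(S) == 0) return(S)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(es$values) <= 0) {
    stop("overlap matrix is numerically singular (min eigenvalue ",
         format(min(es$values)), ")")
  }
  if (min(es$values) < lindep_tol) {
    warning("near linear dependence in basis: smallest overlap eigenvalue ",
            format(min(es$values)))
  }
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

# Generalized symmetric eigenproblem F C = S C eps via symmetric
# orthogonalization. Returns orthonormal coefficients (C^T S C = I) and
# ascending eigenvalues.
generalized_eigen <- function(F, S, X = NULL) {
  if (is.null(X)) X <- sym_inv_sqrt(S)
  Fp <- t(X) %*% ((F + t(F)) / 2) %*% X
  es <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  list(values = es$values[ord], vectors = X %*% es$vectors[, ord, drop = FALSE])
}

# Symmetric (Loewdin) re-orthonormalization of coefficient columns against S.
orthonormalize_columns <- function(C, S) {
  M <- t(C) %*% S %*% C
  C %*% sym_inv_sqrt((M + t(M)) / 2)
}

# Given n_occ S-orthonormal occupied columns, complete to a full orthonormal
# set by projecting the occupied space out of the S^(-1/2) columns.
complete_orbitals <- function(C_occ, S, X = NULL) {
  n <- nrow(S)
  n_occ <- ncol(C_occ)
  if (n_occ == n) return(C_occ)
  if (is.null(X)) X <- sym_inv_sqrt(S)
  P <- C_occ %*% t(C_occ) %*% S       # S-orthogonal projector onto occupied
  resid <- X - P %*% X
  # pick the n - n_occ most independent residual columns by pivoted QR of
  # the S-metric Gram factor
  G <- t(resid) %*% S %*% resid
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eg$vectors[, seq_len(n - n_occ), drop = FALSE]
  Cv <- resid %*% keep
  Cv <- orthonormalize_columns(Cv, S)
  cbind(C_occ, Cv)
}

# Matrix exponential of a (small, dense) skew-symmetric matrix via its
# eigendecomposition; result is orthogonal to round-off.
skew_exp <- function(K) {
  n <- nrow(K)
  if (n == 0) return(matrix(0, 0, 0))
  if (max(abs(K)) < 1e-300) return(diag(n))
  es <- eigen(K)                        # purely imaginary spectrum
  E <- es$vectors %*% (exp(es$values) * solve(es$vectors))
  Re(E)
}

frobenius_rms <- function(M) sqrt(sum(M * M) / length(M))
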