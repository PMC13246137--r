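# Simultaneous (coupled) DIIS: one shared coefficient vector extrapolates
# the electronic and nuclear Fock matrices together, with the combined Gram
# matrix <e_k^e|e_l^e> + <e_k^p|e_l^p>.

#' Create an empty DIIS history
#'
#' @param cap subspace size limit.
#' @return `diis_history` object.
#' @export
diis_history <- function(cap = 15) {
  structure(list(entries = list(), cap = cap), class = "diis_history")
}

#' Push a Fock/error snapshot onto the DIIS history
#'
#' @param history a [diis_history].
#' @param Fe electronic Fock matrix.
#' @param Fp nuclear Fock (matrix for SD, list of block matrices for HP).
#' @param e_e,e_p electronic and nuclear error vectors.
#' @return Updated history (oldest entry dropped at the cap).
#' @export
diis_push <- function(history, Fe, Fp, e_e, e_p) {
  history$entries <- c(history$entries,
                       list(list(Fe = Fe, Fp = Fp, e_e = e_e, e_p = e_p)))
  if (length(history$entries) > history$cap) {
    history$entries <- history$entries[-1]
  }
  history
}

# weighted Fock combination; handles matrix or per-block list nuclear Focks
combine_focks <- function(entries, cc) {
  Fe <- Reduce(`+`, Map(function(en, w) w * en$Fe, entries, cc))
  Fp <- NULL
  if (!is.null(entries[[1]]$Fp)) {
    if (is.matrix(entries[[1]]$Fp)) {
      Fp <- Reduce(`+`, Map(function(en, w) w * en$Fp, entries, cc))
    } else {
      nb <- length(entries[[1]]$Fp)
      Fp <- lapply(seq_len(nb), function(i) {
        Reduce(`+`, Map(function(en, w) w * en$Fp[[i]], entries, cc))
      })
    }
  }
  list(Fe = Fe, Fp = Fp)
}

#' DIIS extrapolation with a shared coefficient set
#'
#' Solves the constrained least-squares problem on the combined error Gram
#' matrix and applies one coefficient vector to both subsystems' Fock
#' matrices. An ill-conditioned Gram matrix (condition number above 1e12)
#' drops the oldest entries and retries; a fully degenerate subspace resets
#' the history and returns the latest Fock matrices unchanged.
#'
#' @param history a [diis_history] with at least one stored pair.
#' @return List with `Fe`, `Fp`, `coefficients`, and the (possibly pruned)
#'   `history`.
#' @export
diis_extrapolate <- function(history) {
  entries <- history$entries
  if (length(entries) == 0) stop("DIIS history is empty")
  repeat {
    m <- length(entries)
    if (m == 1) {
      return(c(combine_focks(entries, 1), list(coefficients = 1,
                                               history = history)))
    }
    B <- matrix(0, m, m)
    for (k in seq_len(m)) {
      for (l in seq_len(k)) {
        v <- sum(entries[[k]]$e_e * entries[[l]]$e_e) +
          sum(entries[[k]]$e_p * entries[[l]]$e_p)
        B[k, l] <- v; B[l, k] <- v
      }
    }
    # scale the Gram block to O(1) before conditioning checks: the raw
    # entries shrink quadratically with the error norm and would otherwise
    # dominate the condition number of the augmented (Lagrange) system
    scale <- max(abs(B))
    if (scale == 0) {
      return(c(combine_focks(entries[m], 1),
               list(coefficients = 1, history = diis_history(history$cap))))
    }
    A <- rbind(cbind(B / scale, 1), c(rep(1, m), 0))
    ok <- kappa(A, exact = TRUE) < 1e12
    if (ok) {
      sol <- tryCatch(solve(A, c(rep(0, m), 1)), error = function(e) NULL)
      if (!is.null(sol)) {
        cc <- sol[seq_len(m)]
        history$entries <- entries
        return(c(combine_focks(entries, cc),
                 list(coefficients = cc, history = history)))
      }
    }
    entries <- entries[-1] # drop oldest and retry
  }
}
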