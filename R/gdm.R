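# GDM-style quasi-Newton orbital optimizer: preconditioned limited-memory
# BFGS over the stacked electronic+nuclear rotation parameters, with an
# Armijo backtracking line search and a trust-radius fallback. Curvature
# pairs from previous iterations are reused unchanged in the current orbital
# frame (a transport approximation, adequate for the small accepted steps).

#' Create a GDM optimizer state
#'
#' @param memory maximum number of stored curvature pairs.
#' @return `gdm_state` object.
#' @export
gdm_state <- function(memory = 20) {
  structure(list(pairs = list(), memory = memory), class = "gdm_state")
}

#' Record an accepted step and gradient change
#'
#' The (s, y) pair is kept only when the curvature condition `s.y > 0`
#' holds (relative to the vector magnitudes), so the implicit BFGS Hessian
#' stays positive definite.
#'
#' @param gs a [gdm_state].
#' @param s accepted packed step.
#' @param y gradient change `g_new - g_old`.
#' @return Updated state.
#' @export
gdm_update <- function(gs, s, y) {
  sy <- sum(s * y)
  if (sy > 1e-12 * sqrt(sum(s * s)) * sqrt(sum(y * y)) && sy > 0) {
    gs$pairs <- c(gs$pairs, list(list(s = s, y = y, rho = 1 / sy)))
    if (length(gs$pairs) > gs$memory) gs$pairs <- gs$pairs[-1]
  }
  gs
}

#' Quasi-Newton direction `-B^-1 g` (two-loop recursion)
#'
#' @param gs a [gdm_state].
#' @param g current packed gradient.
#' @param h0 diagonal initial Hessian (orbital-energy differences floored at
#'   0.05 Hartree; see `hessian_diagonal`).
#' @return Packed descent direction.
#' @export
gdm_step <- function(gs, g, h0) {
  q <- g
  pairs <- gs$pairs
  m <- length(pairs)
  alpha <- numeric(m)
  for (k in rev(seq_len(m))) {
    alpha[k] <- pairs[[k]]$rho * sum(pairs[[k]]$s * q)
    q <- q - alpha[k] * pairs[[k]]$y
  }
  r <- q / h0
  for (k in seq_len(m)) {
    beta <- pairs[[k]]$rho * sum(pairs[[k]]$y * r)
    r <- r + pairs[[k]]$s * (alpha[k] - beta)
  }
  -r
}

# Armijo backtracking with trust-radius fallback; returns the accepted state
# or NULL when even the smallest step fails to descend
gdm_line_search <- function(tabs, state, g, d, c1 = 1e-4, trust_cap = 0.5,
                            max_backtracks = 12) {
  gd <- sum(g * d)
  t <- 1
  rejections <- 0
  for (k in seq_len(max_backtracks)) {
    s_try <- t * d
    if (rejections >= 2) {
      nrm <- sqrt(sum(s_try * s_try))
      if (nrm > trust_cap) s_try <- s_try * (trust_cap / nrm)
    }
    trial <- apply_rotation(tabs, state, s_try)
    if (trial$energy <= state$energy + c1 * sum(g * s_try)) {
      return(list(state = trial, step = s_try))
    }
    rejections <- rejections + 1
    t <- t / 2
  }
  NULL
}
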