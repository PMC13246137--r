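# Trust-radius augmented Hessian solver: the lowest eigenpair of the
# alpha-scaled augmented matrix [[0, a g^T], [a g, H]] gives a level-shifted
# Newton step (H - mu) x = -a g; alpha is tuned so the step length lands in
# the trust region. The eigenpair is found by a Davidson iteration using
# only Hessian-vector products.

# Davidson for the lowest eigenpair of a symmetric operator given by
# apply_A; diag_A preconditions the residual.
davidson_lowest <- function(apply_A, n, diag_A, start, tol = 1e-9,
                            max_iter = 200, max_subspace = 100) {
  max_subspace <- min(max_subspace, n)
  V <- NULL
  W <- NULL
  add_vec <- function(v) {
    if (!is.null(V)) {
      for (rep in 1:2) v <- v - V %*% crossprod(V, v)
    }
    nv <- sqrt(sum(v * v))
    if (nv < 1e-10) return(FALSE)
    v <- v / nv
    V <<- cbind(V, as.vector(v))
    W <<- cbind(W, apply_A(as.vector(v)))
    TRUE
  }
  for (v in start) add_vec(v)
  if (is.null(V)) stop("Davidson: no valid start vectors")
  last <- NULL
  for (it in seq_len(max_iter)) {
    Tm <- crossprod(V, W)
    Tm <- (Tm + t(Tm)) / 2
    es <- eigen(Tm, symmetric = TRUE)
    ord <- order(es$values)
    theta <- es$values[ord[1]]
    x <- as.vector(V %*% es$vectors[, ord[1]])
    r <- as.vector(W %*% es$vectors[, ord[1]]) - theta * x
    last <- list(value = theta, vector = x, iterations = it,
                 converged = FALSE, residual = sqrt(sum(r * r)))
    if (last$residual < tol * max(1, abs(theta))) {
      last$converged <- TRUE
      return(last)
    }
    if (ncol(V) >= max_subspace) { # restart, keeping the best Ritz vectors
      keep <- es$vectors[, ord[seq_len(min(3, length(ord)))], drop = FALSE]
      Vk <- V %*% keep
      V <- NULL; W <- NULL
      for (j in seq_len(ncol(Vk))) add_vec(Vk[, j])
    }
    denom <- diag_A - theta
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-300) * 1e-8
    if (!add_vec(r / denom) && !add_vec(r)) {
      # subspace is numerically exhausted at this precision
      return(last)
    }
  }
  stop("Davidson did not converge within ", max_iter,
       " microiterations (last residual ", format(last$residual),
       ", theta ", format(last$value), ")")
}

# lowest eigenpair of the alpha-scaled augmented Hessian; returns the level
# shift mu and the step x_tilde (eigenvector scaled so its first component
# is one)
augmented_hessian_solve <- function(g, hess_vec, hdiag, alpha,
                                    tol = 1e-9, max_iter = 200,
                                    warm = NULL) {
  n <- length(g)
  apply_A <- function(x) {
    c(alpha * sum(g * x[-1]), alpha * x[1] * g + hess_vec(x[-1]))
  }
  gn <- sqrt(sum(g * g))
  start <- list(c(1, rep(0, n)))
  if (gn > 0) start <- c(start, list(c(0, -g / gn)))
  if (!is.null(warm)) start <- c(list(warm), start)
  sol <- davidson_lowest(apply_A, n + 1, c(0, hdiag), start, tol = tol,
                         max_iter = max_iter)
  y0 <- sol$vector[1]
  if (abs(y0) < 1e-12) { # gradient-dominated: fall back to steepest descent
    x <- -g / max(gn, 1e-12)
  } else {
    x <- sol$vector[-1] / y0
  }
  list(mu = sol$value, x = x, iterations = sol$iterations,
       converged = sol$converged)
}

#' Trust-radius augmented Hessian step
#'
#' Solves the alpha-scaled augmented eigenproblem by Davidson iteration; the
#' update is `s = x_tilde(alpha) / alpha`, which satisfies the level-shifted
#' Newton equation `(H - mu I) s = -g`. If the unscaled (`alpha = 1`) step is
#' already interior it is taken as is (for a positive-definite Hessian and a
#' small gradient it approaches the exact Newton step); otherwise `alpha` is
#' adjusted by bisection on `log(alpha)` (clamped to [-6, 6]) until the step
#' norm lands in `[0.8 trust, trust]`. Raising `alpha` deepens the level
#' shift and monotonically shortens the step, so the bisection works on the
#' strongly coupled side where the Davidson iteration is well conditioned;
#' consecutive probes are warm-started with the previous eigenvector.
#'
#' @param problem list with `g` (packed gradient), `hess_vec`
#'   (function `v -> H v`), `hdiag` (Hessian diagonal approximation for the
#'   Davidson preconditioner), `trust` (radius).
#' @return List with the step `s`, level shift `mu`, `alpha`, and the step
#'   norm.
#' @export
trah_step <- function(problem) {
  g <- problem$g
  trust <- problem$trust
  warm <- NULL
  solve_at <- function(alpha) {
    sol <- augmented_hessian_solve(g, problem$hess_vec, problem$hdiag, alpha,
                                   warm = warm)
    # warm-start the next alpha probe with the current eigenvector estimate
    warm <<- c(1, sol$x) / sqrt(1 + sum(sol$x * sol$x))
    sol$s <- sol$x / alpha
    sol$norm <- sqrt(sum(sol$s * sol$s))
    sol$alpha <- alpha
    sol
  }
  sol <- solve_at(1)
  if (sol$norm <= trust) {
    return(list(s = sol$s, mu = sol$mu, alpha = 1, norm = sol$norm))
  }
  lo <- 0; hi <- 6 # log(alpha); the step shortens as alpha grows
  best <- NULL
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    sol <- solve_at(exp(max(-6, min(6, mid))))
    if (sol$norm >= 0.8 * trust && sol$norm <= trust) {
      return(list(s = sol$s, mu = sol$mu, alpha = sol$alpha, norm = sol$norm))
    }
    if (sol$norm <= trust) {
      best <- sol
      hi <- mid
    } else {
      lo <- mid
    }
    if (hi - lo < 1e-8) break
  }
  if (is.null(best)) { # even the most level-shifted probe is too long
    best <- sol
  }
  if (best$norm > trust) {
    best$s <- best$s * (trust / best$norm)
    best$norm <- trust
  }
  list(s = best$s, mu = best$mu, alpha = best$alpha, norm = best$norm)
}
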