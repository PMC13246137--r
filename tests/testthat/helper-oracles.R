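# Independent numerical oracles. Everything here is built from adaptive 1D
# quadrature (stats::integrate) and textbook definitions only -- none of the
# package's Hermite/Boys machinery is reused.

# Boys function by direct quadrature of the defining integral
oracle_boys <- function(n, x) {
  integrate(function(t) t^(2 * n) * exp(-x * t^2), 0, 1,
            rel.tol = 1e-13, abs.tol = 0)$value
}

# primitive Cartesian Gaussian radial normalization (standard closed form)
prim_norm <- function(a, q) {
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  (2 * a / pi)^0.75 * (4 * a)^(sum(q) / 2) /
    sqrt(dfact(2 * q[1] - 1) * dfact(2 * q[2] - 1) * dfact(2 * q[3] - 1))
}

# an "oracle function": list(center, q = cartesian powers, exps, coeffs)
# representing sum_k c_k N_k (x-A)^qx (y-A)^qy (z-A)^qz exp(-a_k r_A^2)
ofun <- function(center, q, exps, coeffs) {
  list(A = center, q = q, exps = exps,
       cc = coeffs * vapply(exps, prim_norm, numeric(1), q = q))
}

# 1D factor of an oracle function along dimension d, one primitive
of_dim <- function(f, d, k) {
  force(f); force(d); force(k)
  function(x) (x - f$A[d])^(f$q[d]) * exp(-f$exps[k] * (x - f$A[d])^2)
}

# second derivative of the 1D factor (analytic polynomial form)
of_dim_dd <- function(f, d, k) {
  force(f); force(d); force(k)
  j <- f$q[d]; b <- f$exps[k]; B <- f$A[d]
  function(x) {
    t <- x - B
    (ifelse(j >= 2, j * (j - 1) * t^max(j - 2, 0), 0) -
       2 * b * (2 * j + 1) * t^j + 4 * b^2 * t^(j + 2)) * exp(-b * t^2)
  }
}

int1d <- function(fn, rel.tol = 1e-12) {
  integrate(fn, -Inf, Inf, rel.tol = rel.tol, abs.tol = 1e-14)$value
}

# raw (unnormalized-contraction) overlap over all primitive pairs
oracle_overlap_raw <- function(f, g) {
  out <- 0
  for (k in seq_along(f$exps)) {
    for (l in seq_along(g$exps)) {
      v <- f$cc[k] * g$cc[l]
      for (d in 1:3) {
        fk <- of_dim(f, d, k); gl <- of_dim(g, d, l)
        v <- v * int1d(function(x) fk(x) * gl(x))
      }
      out <- out + v
    }
  }
  out
}

# raw kinetic integral -1/(2m) <f | lap | g>
oracle_kinetic_raw <- function(f, g, mass = 1) {
  out <- 0
  for (k in seq_along(f$exps)) {
    for (l in seq_along(g$exps)) {
      s1 <- t1 <- numeric(3)
      for (d in 1:3) {
        fk <- of_dim(f, d, k); gl <- of_dim(g, d, l)
        gl2 <- of_dim_dd(g, d, l)
        s1[d] <- int1d(function(x) fk(x) * gl(x))
        t1[d] <- int1d(function(x) fk(x) * gl2(x))
      }
      out <- out + f$cc[k] * g$cc[l] *
        (t1[1] * s1[2] * s1[3] + s1[1] * t1[2] * s1[3] +
           s1[1] * s1[2] * t1[3])
    }
  }
  -out / (2 * mass)
}

# adaptive quadrature recentered on the integrand's Gaussian width: the
# integrand must decay at least like exp(-q (x - x0)^2); substituting
# x = x0 + s/sqrt(q) keeps narrow kernels resolved at any q
int1d_centered <- function(fn, x0, q, rel.tol = 1e-10) {
  rq <- sqrt(q)
  f <- function(s) fn(x0 + s / rq) / rq
  for (tol in c(rel.tol, 1e-8, 1e-6)) {
    out <- tryCatch(integrate(f, -15, 15, rel.tol = tol, abs.tol = tol * 1e-4),
                    error = function(e) NULL)
    if (!is.null(out)) return(out$value)
  }
  stop("centered quadrature failed")
}

# raw point-charge integral <f| 1/|r - C| |g> via the Gaussian transform
# 1/r = 2/sqrt(pi) * int_0^inf exp(-u^2 r^2) du, with u = t/(1-t)
oracle_point_charge_raw <- function(f, g, C) {
  out <- 0
  for (k in seq_along(f$exps)) {
    for (l in seq_along(g$exps)) {
      af <- f$exps[k]; ag <- g$exps[l]
      inner <- function(u) {
        v <- 1
        for (d in 1:3) {
          fk <- of_dim(f, d, k); gl <- of_dim(g, d, l)
          q <- af + ag + u^2
          x0 <- (af * f$A[d] + ag * g$A[d] + u^2 * C[d]) / q
          v <- v * int1d_centered(function(x) {
            fk(x) * gl(x) * exp(-u^2 * (x - C[d])^2)
          }, x0, q)
        }
        v
      }
      ov <- integrate(function(tv) {
        vapply(tv, function(t) {
          u <- t / (1 - t)
          inner(u) / (1 - t)^2
        }, numeric(1))
      }, 0, 1, rel.tol = 1e-10, abs.tol = 1e-14)$value
      out <- out + f$cc[k] * g$cc[l] * 2 / sqrt(pi) * ov
    }
  }
  out
}

# raw two-cloud repulsion (f g | h w) via the same Gaussian transform; the
# inner 6D integral factorizes into three 2D integrals evaluated by nested
# adaptive quadrature (inner integral recentered on its Gaussian product)
oracle_eri_raw <- function(f, g, h, w) {
  out <- 0
  for (kf in seq_along(f$exps)) for (kg in seq_along(g$exps)) {
    for (kh in seq_along(h$exps)) for (kw in seq_along(w$exps)) {
      af <- f$exps[kf]; ag <- g$exps[kg]; ah <- h$exps[kh]; aw <- w$exps[kw]
      two_d <- function(d, u) {
        f1 <- of_dim(f, d, kf); g1 <- of_dim(g, d, kg)
        h1 <- of_dim(h, d, kh); w1 <- of_dim(w, d, kw)
        q1 <- af + ag
        x01 <- (af * f$A[d] + ag * g$A[d]) / q1
        q2 <- ah + aw + u^2
        int1d_centered(function(x1v) {
          vapply(x1v, function(x1) {
            x02 <- (ah * h$A[d] + aw * w$A[d] + u^2 * x1) / q2
            f1(x1) * g1(x1) *
              int1d_centered(function(x2) {
                h1(x2) * w1(x2) * exp(-u^2 * (x1 - x2)^2)
              }, x02, q2, rel.tol = 1e-9)
          }, numeric(1))
        }, x01, q1, rel.tol = 1e-8)
      }
      ov <- integrate(function(tv) {
        vapply(tv, function(t) {
          u <- t / (1 - t)
          (two_d(1, u) * two_d(2, u) * two_d(3, u)) / (1 - t)^2
        }, numeric(1))
      }, 0, 1, rel.tol = 1e-8, abs.tol = 1e-12)$value
      out <- out + f$cc[kf] * g$cc[kg] * h$cc[kh] * w$cc[kw] *
        2 / sqrt(pi) * ov
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Independent conventional-RHF oracle: Roothaan fixed-point iteration with
# its own energy expression, taking raw integral matrices as input.
# ---------------------------------------------------------------------------
oracle_rhf <- function(S, h, G, n_occ, e_nn = 0, max_iter = 300,
                       tol = 1e-12) {
  n <- nrow(S)
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  D <- matrix(0, n, n)
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    Fm <- h
    for (mu in 1:n) for (nu in 1:n) {
      Fm[mu, nu] <- h[mu, nu] +
        sum(D * (G[mu, nu, , ] - 0.5 * G[mu, , , nu]))
    }
    E <- 0.5 * sum(D * (h + Fm)) + e_nn
    ee <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    C <- X %*% ee$vectors[, order(ee$values), drop = FALSE]
    D <- 2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE])
    if (abs(E - E_old) < tol) break
    E_old <- E
  }
  list(energy = E, D = D, F = Fm, C = C)
}
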