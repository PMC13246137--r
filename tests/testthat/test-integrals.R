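test_that("Boys function matches closed forms and quadrature over both branches", {
  expect_equal(boys(0, 0), 1)
  for (n in c(1, 3, 7)) expect_equal(boys(n, 0), 1 / (2 * n + 1))
  expect_error(boys(0, -1), "x")
  # series branch, asymptotic branch, and the protonic large-x regime
  for (x in c(1e-3, 0.5, 1, 12, 34.9, 35.1, 80, 200)) {
    for (n in c(0, 2, 6)) {
      expect_equal(boys(n, x), oracle_boys(n, x), tolerance = 1e-12,
                   label = sprintf("F_%d(%g)", n, x))
    }
  }
})

test_that("overlap and kinetic integrals match closed forms and scaling", {
  s1 <- gaussian_shell(c(0, 0, 0), 0, 1.3, 1)
  st <- overlap_kinetic(list(s1), 1)
  expect_equal(st$S, matrix(1, 1, 1), tolerance = 1e-13)

  # two equal-exponent s primitives at separation R: S12 = exp(-a R^2 / 2)
  a <- 0.8; R <- 1.7
  sh <- list(gaussian_shell(c(0, 0, 0), 0, a, 1),
             gaussian_shell(c(0, 0, R), 0, a, 1))
  st <- overlap_kinetic(sh, 1)
  expect_equal(st$S[1, 2], exp(-a * R^2 / 2), tolerance = 1e-12)

  # kinetic energy scales as 1/mass
  stm <- overlap_kinetic(sh, 1836.15267343)
  expect_equal(stm$T * 1836.15267343, st$T, tolerance = 1e-12)
})

test_that("point-charge matrices match the Gaussian <1/r> closed form and signs", {
  a <- 2.3
  sh <- list(gaussian_shell(c(0, 0, 0), 0, a, 1))
  Vm <- point_charge_matrix(sh, 1, matrix(0, 1, 3), sign = -1)
  expect_equal(Vm[1, 1], -2 * sqrt(2 * a / pi), tolerance = 1e-12)
  Vp <- point_charge_matrix(sh, 1, matrix(0, 1, 3), sign = +1)
  expect_equal(Vp, -Vm)
  V0 <- point_charge_matrix(sh, numeric(0), matrix(numeric(0), 0, 3))
  expect_equal(V0, matrix(0, 1, 1))
})

test_that("repulsion tensor matches the coincident and two-cloud closed forms", {
  a <- 1.9
  sh <- list(gaussian_shell(c(0, 0, 0), 0, a, 1))
  G <- coulomb_tensor(sh)
  expect_equal(G[1, 1, 1, 1], 2 * sqrt(a / pi), tolerance = 1e-12)

  # two unit s-clouds with total exponents p, q at distance R repel as
  # erf(sqrt(p q / (p + q)) R) / R
  p <- 1.4; q <- 3.7; R <- 2.1
  shp <- list(gaussian_shell(c(0, 0, 0), 0, p / 2, 1),
              gaussian_shell(c(0, 0, R), 0, q / 2, 1))
  G2 <- coulomb_tensor(shp)
  # (11|22): each diagonal product density is a unit cloud with exponent p, q
  expect_equal(G2[1, 1, 2, 2],
               pracma::erf(sqrt(p * q / (p + q)) * R) / R,
               tolerance = 1e-12)
})

test_that("tensors obey permutational symmetry and the Schwarz bound", {
  set.seed(42)
  centers <- matrix(rnorm(9, sd = 0.8), 3, 3)
  sh <- list(gaussian_shell(centers[1, ], 0, c(1.1, 0.3), c(0.7, 0.5)),
             gaussian_shell(centers[2, ], 1, 0.9, 1),
             gaussian_shell(centers[3, ], 2, 1.7, 1))
  G <- coulomb_tensor(sh)
  n <- dim(G)[1]
  expect_equal(n, 10)
  expect_equal(G, aperm(G, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(G, aperm(G, c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_equal(G, aperm(G, c(3, 4, 1, 2)), tolerance = 1e-12)
  for (k in 1:50) {
    idx <- sample(n, 4, replace = TRUE)
    lhs <- abs(G[idx[1], idx[2], idx[3], idx[4]])
    rhs <- sqrt(G[idx[1], idx[2], idx[1], idx[2]] *
                  G[idx[3], idx[4], idx[3], idx[4]])
    expect_lte(lhs, rhs + 1e-12)
  }
})

test_that("one-body matrices are symmetric and S is positive definite", {
  fx <- cached_fixture("water")
  for (M in list(fx$tabs$Se, fx$tabs$Te, fx$tabs$Ve, fx$tabs$Sp, fx$tabs$Tp,
                 fx$tabs$Vp)) {
    expect_lt(max(abs(M - t(M))), 1e-12)
  }
  expect_gt(min(eigen(fx$tabs$Se, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_gt(min(eigen(fx$tabs$Sp, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("integrals are invariant under rigid translation", {
  shift <- c(0.37, -1.2, 0.85)
  mk <- function(off) {
    list(gaussian_shell(c(0, 0, 0) + off, 0, c(1.2, 0.4), c(0.6, 0.6)),
         gaussian_shell(c(0.9, 0.2, -0.4) + off, 1, 0.8, 1))
  }
  s0 <- mk(c(0, 0, 0)); s1 <- mk(shift)
  st0 <- overlap_kinetic(s0, 1); st1 <- overlap_kinetic(s1, 1)
  expect_lt(max(abs(st0$S - st1$S)), 1e-11)
  expect_lt(max(abs(st0$T - st1$T)), 1e-11)
  expect_lt(max(abs(coulomb_tensor(s0) - coulomb_tensor(s1))), 1e-11)
  # V moves consistently with the shifted charge
  C0 <- matrix(c(0.2, 0.1, 0.5), 1, 3)
  V0 <- point_charge_matrix(s0, 2, C0)
  V1 <- point_charge_matrix(s1, 2, C0 + rep(shift, each = 1))
  expect_lt(max(abs(V0 - V1)), 1e-11)
})

test_that("every integral class matches adaptive quadrature on random primitives", {
  set.seed(11)
  # random 1-2 primitive shells spanning s, p, d components
  cases <- list(
    list(q1 = c(0, 0, 0), e1 = c(1.3, 0.5), c1 = c(0.8, 0.4),
         q2 = c(0, 0, 0), e2 = 0.9, c2 = 1),
    list(q1 = c(1, 0, 0), e1 = 1.1, c1 = 1,
         q2 = c(0, 1, 0), e2 = c(2.0, 0.7), c2 = c(0.5, 0.7)),
    list(q1 = c(2, 0, 0), e1 = 1.6, c1 = 1,
         q2 = c(1, 0, 1), e2 = 0.8, c2 = 1)
  )
  comp_index <- function(q) {
    l <- sum(q)
    tab <- list(`0` = list(c(0, 0, 0)),
                `1` = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                `2` = list(c(2, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 2, 0),
                           c(0, 1, 1), c(0, 0, 2)))[[as.character(l)]]
    which(vapply(tab, function(t) all(t == q), logical(1)))
  }
  for (cs in cases) {
    A <- rnorm(3, sd = 0.5); B <- rnorm(3, sd = 0.5)
    shA <- gaussian_shell(A, sum(cs$q1), cs$e1, cs$c1)
    shB <- gaussian_shell(B, sum(cs$q2), cs$e2, cs$c2)
    fA <- ofun(A, cs$q1, cs$e1, cs$c1)
    fB <- ofun(B, cs$q2, cs$e2, cs$c2)
    nA <- sqrt(oracle_overlap_raw(fA, fA))
    nB <- sqrt(oracle_overlap_raw(fB, fB))
    i1 <- comp_index(cs$q1); i2 <- comp_index(cs$q2)
    st <- overlap_kinetic(list(shA, shB), mass = 3.5)
    o1 <- neoscf:::n_components(shA)
    expect_equal(st$S[i1, o1 + i2], oracle_overlap_raw(fA, fB) / (nA * nB),
                 tolerance = 1e-8)
    expect_equal(st$T[i1, o1 + i2],
                 oracle_kinetic_raw(fA, fB, mass = 3.5) / (nA * nB),
                 tolerance = 1e-8)
    Cq <- rnorm(3, sd = 0.4)
    V <- point_charge_matrix(list(shA, shB), 1.5, matrix(Cq, 1, 3),
                             sign = -1)
    expect_equal(V[i1, o1 + i2],
                 -1.5 * oracle_point_charge_raw(fA, fB, Cq) / (nA * nB),
                 tolerance = 1e-8)
  }
  # repulsion: one single-primitive case with a p function (6D quadrature
  # via nested 1D rules is slow, so keep it small)
  A <- c(0.1, -0.2, 0.3); B <- c(0.8, 0.4, -0.1)
  shA <- gaussian_shell(A, 0, 1.1, 1)
  shB <- gaussian_shell(B, 1, 0.9, 1)
  fA <- ofun(A, c(0, 0, 0), 1.1, 1)
  fB <- ofun(B, c(0, 0, 1), 0.9, 1) # z component
  nA <- sqrt(oracle_overlap_raw(fA, fA))
  nB <- sqrt(oracle_overlap_raw(fB, fB))
  G <- coulomb_tensor(list(shA, shB))
  expect_equal(G[1, 4, 1, 4],
               oracle_eri_raw(fA, fB, fA, fB) / (nA * nB)^2,
               tolerance = 1e-8)
  expect_equal(G[1, 1, 4, 4],
               oracle_eri_raw(fA, fA, fB, fB) / (nA^2 * nB^2),
               tolerance = 1e-8)
})
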