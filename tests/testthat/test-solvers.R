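test_that("Roothaan iteration solves the frozen-field proton problem in one step", {
  # a single Hartree-product proton in a frozen electronic field is a linear
  # problem: one diagonalization reaches the stationary point
  opw <- one_proton_water()
  hp_layout <- basis_layout(opw$system, opw$protonic_shells, "HP")
  tabs <- neoscf:::retarget_tables(opw$tabs, hp_layout)
  st <- initial_state(opw$system, opw$basisdef, tabs, guess_spec())
  r <- tabs$layout$ranges[[1]]
  es <- neoscf:::generalized_eigen(st$Fp[[1]], tabs$Sp[r, r],
                                   tabs$Xp_blocks[[1]])
  Dnew <- tcrossprod(es$vectors[, 1])
  # rebuilt Fock (same frozen electrons, no other protons) commutes with the
  # new density
  err <- diis_error_vector(st$Fp[[1]], Dnew, tabs$Sp[r, r])
  expect_lt(neoscf:::rms(err), 1e-12)
})

test_that("a converged state is a Roothaan fixed point", {
  r <- cached_run("water", "SD", "diis")
  st2 <- roothaan_step(r$tabs, r$state)
  expect_lt(abs(st2$energy - r$final_energy), 1e-12)
})

test_that("pure Roothaan descends from the core guess on H2", {
  fx <- cached_fixture("h2")
  st <- initial_state(fx$system, fx$basisdef, fx$tabs,
                      guess_spec("core", "core"))
  e <- st$energy
  for (k in 1:3) {
    st <- roothaan_step(fx$tabs, st)
    expect_lt(st$energy, e)
    e <- st$energy
  }
})

test_that("DIIS error vectors vanish for commuting Fock and density", {
  D <- diag(c(1, 1, 0, 0))
  F <- diag(c(-2, -1, 0.5, 3))
  expect_equal(diis_error_vector(F, D, diag(4)), rep(0, 16))
  # the untransformed commutator is antisymmetric
  fx <- cached_fixture("h2")
  st <- initial_state(fx$system, fx$basisdef, fx$tabs,
                      guess_spec("core", "core"))
  M <- st$Fe %*% st$De %*% fx$tabs$Se - fx$tabs$Se %*% st$De %*% st$Fe
  expect_lt(max(abs(M + t(M))), 1e-12)
})

test_that("DIIS extrapolation handles trivial and degenerate histories", {
  Fe <- matrix(c(1, 2, 2, 5), 2)
  hist <- diis_push(diis_history(15), Fe, NULL, c(0.1, 0), numeric(0))
  out <- diis_extrapolate(hist)
  expect_equal(out$Fe, Fe)
  expect_equal(out$coefficients, 1)
  # two identical snapshots: degeneracy pruning returns that snapshot
  hist2 <- diis_push(hist, Fe, NULL, c(0.1, 0), numeric(0))
  out2 <- diis_extrapolate(hist2)
  expect_equal(out2$Fe, Fe)
  expect_equal(sum(out2$coefficients), 1)
})

test_that("DIIS accelerates a linearly mixing model that Roothaan oscillates on", {
  # 2x2 model: F(D) = h + g * D couples the step to the previous density
  # strongly enough that the plain fixed-point iteration cycles
  h <- matrix(c(0, 0.4, 0.4, 0.3), 2)
  g <- 2.0
  S <- diag(2)
  fock_of <- function(D) h + g * D
  occupy <- function(F) {
    es <- eigen(F, symmetric = TRUE)
    tcrossprod(es$vectors[, which.min(es$values)])
  }
  # plain Roothaan
  D <- diag(c(1, 0))
  roothaan_errs <- numeric(30)
  for (k in 1:30) {
    F <- fock_of(D)
    roothaan_errs[k] <- max(abs(F %*% D - D %*% F))
    D <- occupy(F)
  }
  expect_gt(min(roothaan_errs), 0.1) # oscillates, never approaches a fixed point
  # DIIS on the same model
  D <- diag(c(1, 0))
  hist <- diis_history(15)
  diis_err <- Inf
  for (k in 1:10) {
    F <- fock_of(D)
    e <- as.vector(F %*% D - D %*% F)
    diis_err <- max(abs(e))
    if (diis_err < 1e-10) break
    hist <- diis_push(hist, F, NULL, e, numeric(0))
    ext <- diis_extrapolate(hist)
    hist <- ext$history
    D <- occupy(ext$Fe)
  }
  expect_lt(diis_err, 1e-10)
  expect_lte(k, 10)
})

test_that("the orbital gradient matches finite differences of the energy", {
  fx <- cached_fixture("h3o+")
  tabs <- fx$tabs
  st <- initial_state(fx$system, fx$basisdef, tabs, guess_spec())
  g <- orbital_gradient(tabs, st)
  set.seed(101)
  h <- 1e-5
  gnorm <- sqrt(sum(g * g))
  for (k in 1:20) {
    v <- rnorm(length(g)); v <- v / sqrt(sum(v^2))
    fd <- (apply_rotation(tabs, st, h * v)$energy -
             apply_rotation(tabs, st, -h * v)$energy) / (2 * h)
    expect_lt(abs(sum(g * v) - fd), 1e-6 * gnorm)
  }
})

test_that("the gradient vanishes at convergence and reduces to RHF when decoupled", {
  r <- cached_run("h3o+", "SD", "diis")
  g <- orbital_gradient(r$tabs, r$state)
  expect_lt(neoscf:::rms(g), 1e-8)

  # no quantum protons: the electronic block is the conventional RHF gradient
  sys <- read_xyz("2\nclamped\nH 0 0 0\nH 0 0 0.7408481\n")
  bd <- builtin_basis("sto-3g")
  e_sh <- electronic_shells(sys, bd)
  tabs <- integral_tables(sys, e_sh, basis_layout(sys, list(), "SD"))
  Ce <- core_guess_electronic(tabs)$vectors
  st <- neoscf:::state_from_coeffs(tabs, Ce, NULL)
  g <- orbital_gradient(tabs, st)
  Fmo <- crossprod(Ce, st$Fe %*% Ce)
  expect_equal(g, as.vector(4 * Fmo[2, 1]), tolerance = 1e-12)
})

test_that("orbital rotations are unitary, invertible, and trivial at zero", {
  fx <- cached_fixture("water")
  tabs <- fx$tabs
  st <- initial_state(fx$system, fx$basisdef, tabs, guess_spec())
  n <- length(orbital_gradient(tabs, st))
  st0 <- apply_rotation(tabs, st, rep(0, n))
  expect_equal(st0$Ce, st$Ce, tolerance = 1e-14)
  expect_equal(st0$energy, st$energy, tolerance = 1e-14)
  set.seed(5)
  s <- rnorm(n, sd = 0.1)
  st1 <- apply_rotation(tabs, st, s)
  expect_lt(max(abs(crossprod(st1$Ce, tabs$Se %*% st1$Ce) -
                      diag(ncol(st1$Ce)))), 1e-10)
  st2 <- apply_rotation(tabs, st1, -s)
  expect_lt(max(abs(st2$Ce - st$Ce)), 1e-10)
  expect_lt(abs(st2$energy - st$energy), 1e-12)
})

test_that("limited-memory BFGS is exact on quadratics within dim + 2 steps", {
  set.seed(23)
  n <- 8
  A <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  x <- rnorm(n)
  gs <- gdm_state()
  h0 <- rep(1, n)
  for (it in 1:(n + 2)) {
    g <- as.vector(A %*% x)
    if (sqrt(sum(g * g)) < 1e-10) break
    d <- gdm_step(gs, g, h0)
    t_exact <- -sum(g * d) / sum(d * (A %*% d)) # exact line search
    s <- t_exact * d
    x_new <- x + s
    gs <- gdm_update(gs, s, as.vector(A %*% x_new) - g)
    x <- x_new
  }
  expect_lt(sqrt(sum((A %*% x)^2)), 1e-10)

  # the first step with empty history is preconditioned steepest descent
  g <- c(1, -2, 3)
  expect_equal(gdm_step(gdm_state(), g, c(2, 2, 2)), -g / 2)
})

test_that("GDM accepted steps never raise the energy", {
  r <- run_fixture("water", neo_config("SD", "gdm"))
  expect_equal(r$outcome, "converged")
  dE <- diff(r$trace$energy)
  expect_true(all(dE <= 1e-12))
})

test_that("Hessian-vector products are symmetric and match differentiated gradients", {
  fx <- cached_fixture("h3o+")
  tabs <- fx$tabs
  st <- initial_state(fx$system, fx$basisdef, tabs, guess_spec())
  n <- length(orbital_gradient(tabs, st))
  set.seed(77)
  u <- rnorm(n); v <- rnorm(n)
  Hu <- hessian_vector_product(tabs, st, u)
  Hv <- hessian_vector_product(tabs, st, v)
  expect_equal(sum(u * Hv), sum(v * Hu), tolerance = 1e-9)
  h <- 1e-5
  fd <- (orbital_gradient(tabs, apply_rotation(tabs, st, h * v)) -
           orbital_gradient(tabs, apply_rotation(tabs, st, -h * v))) / (2 * h)
  expect_lt(max(abs(Hv - fd)) / max(abs(fd)), 1e-5)
})

test_that("the ep coupling block of the Hessian vanishes when ep integrals are zeroed", {
  fx <- cached_fixture("h2")
  tabs <- fx$tabs
  st <- initial_state(fx$system, fx$basisdef, tabs, guess_spec())
  tabs0 <- tabs
  tabs0$Jep <- tabs$Jep * 0
  st0 <- neoscf:::state_from_coeffs(tabs0, st$Ce, st$Cp)
  blocks <- neoscf:::rotation_blocks(tabs0, st0)
  sizes <- neoscf:::block_sizes(blocks)
  # direction living purely in the nuclear block
  v <- c(rep(0, sizes[1]), rnorm(sizes[2]))
  Hv <- hessian_vector_product(tabs0, st0, v)
  expect_equal(Hv[seq_len(sizes[1])], rep(0, sizes[1]), tolerance = 1e-12)
})

test_that("the augmented-Hessian step reaches the Newton limit on SPD models", {
  set.seed(31)
  n <- 12
  A <- crossprod(matrix(rnorm(n * n), n)) + 2 * diag(n)
  g <- rnorm(n) * 1e-3
  prob <- list(g = g, hess_vec = function(x) as.vector(A %*% x),
               hdiag = diag(A), trust = 10)
  st <- trah_step(prob)
  newton <- -solve(A, g)
  expect_lt(max(abs(st$s - newton)), 1e-8)
  expect_lt(abs(st$mu), 1e-4)
  # the defining level-shifted equation holds
  resid <- (A - st$mu * diag(n)) %*% st$s + g
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("indefinite Hessians get a level shift below the spectrum and a descent step", {
  set.seed(41)
  n <- 10
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  A <- Q %*% diag(c(-1.5, -0.2, runif(n - 2, 0.5, 4))) %*% t(Q)
  g <- rnorm(n)
  prob <- list(g = g, hess_vec = function(x) as.vector(A %*% x),
               hdiag = pmax(diag(A), 0.05), trust = 0.4)
  st <- trah_step(prob)
  expect_lt(st$mu, min(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  expect_lt(sum(g * st$s), 0)
  expect_lte(st$norm, 0.4 * (1 + 1e-6))
})

test_that("Davidson matches a dense eigensolver on a small NEO instance", {
  fx <- cached_fixture("h2")
  tabs <- fx$tabs
  st <- initial_state(fx$system, fx$basisdef, tabs, guess_spec())
  g <- orbital_gradient(tabs, st)
  n <- length(g)
  expect_lte(n, 60)
  H <- sapply(seq_len(n), function(k) {
    e <- rep(0, n); e[k] <- 1
    hessian_vector_product(tabs, st, e)
  })
  H <- (H + t(H)) / 2
  for (alpha in c(1, 0.2, 5)) {
    Aug <- rbind(c(0, alpha * g), cbind(alpha * g, H))
    dense <- eigen(Aug, symmetric = TRUE)
    k <- which.min(dense$values)
    sol <- neoscf:::augmented_hessian_solve(
      g, function(x) as.vector(H %*% x),
      neoscf:::hessian_diagonal(tabs, st), alpha)
    expect_equal(sol$mu, dense$values[k], tolerance = 1e-9)
    vec <- dense$vectors[, k]
    if (abs(vec[1]) > 1e-6) { # x_tilde is well defined only off degeneracy
      ref <- vec[-1] / vec[1]
      expect_lt(max(abs(sol$x - ref)), 1e-7 * max(1, max(abs(ref))))
    }
  }
})

test_that("solvers terminate immediately when started from a converged state", {
  r <- cached_run("water", "SD", "diis")
  cfg <- neo_config("SD", "diis")
  for (runner in list(
    function() neoscf:::run_diis_like(r$tabs, r$state, cfg),
    function() neoscf:::run_gdm(r$tabs, r$state, cfg),
    function() neoscf:::run_trah(r$tabs, r$state, cfg)
  )) {
    out <- runner()
    expect_true(out$converged)
    expect_lte(nrow(out$trace), 2)
  }
})

test_that("stepwise and hybrid drivers converge to the simultaneous answer", {
  r_ref <- cached_run("water", "SD", "diis")
  for (sv in c("stepwise", "diis_gdm_hybrid")) {
    r <- run_fixture("water", neo_config("SD", sv))
    expect_equal(r$outcome, "converged")
    expect_lt(abs(r$final_energy - r_ref$final_energy), 1e-8)
  }
})
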