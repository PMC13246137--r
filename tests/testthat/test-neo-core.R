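test_that("density matrices have the right traces, blocks and idempotency", {
  D <- density_from_coeffs(diag(4), 1, 1)
  expect_equal(D, diag(c(1, 0, 0, 0)))
  expect_error(density_from_coeffs(diag(3), 4, 1), "n_occ")

  # Tr(D S) = occupation * n_occ for random S-orthonormal coefficients
  set.seed(3)
  M <- crossprod(matrix(rnorm(36), 6)) + 6 * diag(6)
  S <- M / max(M)
  X <- neoscf:::sym_inv_sqrt(S)
  C <- X %*% qr.Q(qr(matrix(rnorm(36), 6)))
  for (occ in c(1, 2)) {
    D <- density_from_coeffs(C, 2, occ)
    expect_equal(sum(D * S), occ * 2, tolerance = 1e-10)
  }

  # converged closed-shell electronic density: D S D = 2 D
  r <- cached_run("h2", "SD", "diis")
  De <- r$state$De; Se <- r$tabs$Se
  expect_lt(max(abs(De %*% Se %*% De - 2 * De)), 1e-10)
})

test_that("clamped-proton limit reproduces an independent RHF oracle", {
  # H2 with both protons classical at 1.4 bohr, minimal basis
  d <- 1.4 * 0.52917721092
  sys <- read_xyz(sprintf("2\nclamped h2\nH 0 0 0\nH 0 0 %.10f\n", d))
  bd <- builtin_basis("sto-3g")
  e_sh <- electronic_shells(sys, bd)
  st <- overlap_kinetic(e_sh, 1)
  V <- point_charge_matrix(e_sh, sys$classical$Z,
                           as.matrix(sys$classical[, c("x", "y", "z")]), -1)
  G <- coulomb_tensor(e_sh)
  ora <- oracle_rhf(st$S, st$T + V, G, n_occ = 1, e_nn = 1 / 1.4)
  # same quantities through the package's Fock/energy machinery
  tabs <- integral_tables(sys, e_sh, basis_layout(sys, list(), "SD"))
  De <- ora$D
  Fe <- build_electronic_fock(tabs, De, list())
  rep <- total_energy(tabs, De, list(), "SD")
  expect_equal(rep$total, ora$energy, tolerance = 1e-8)
  # decoupling: with no proton densities the Fock matrix is conventional RHF
  expect_lt(max(abs(Fe - ora$F)), 1e-8)
})

test_that("electron-proton coupling enters both Fock matrices with attraction sign", {
  fx <- cached_fixture("h2")
  tabs <- fx$tabs
  st <- neoscf:::state_from_coeffs(
    tabs, core_guess_electronic(tabs)$vectors, core_guess_nuclear(tabs))
  # adding a proton density lowers the electronic Fock diagonal near the
  # proton center (attractive mean field)
  Fe0 <- build_electronic_fock(tabs, st$De, list())
  Fe1 <- build_electronic_fock(tabs, st$De, st$Dp_list)
  expect_true(all(diag(Fe1) < diag(Fe0)))
  # and the converged ep energy component is negative
  r <- cached_run("h2", "SD", "diis")
  expect_lt(r$state$report$coulomb_ep, 0)
})

test_that("representation guards reject mismatched layouts", {
  fx <- cached_fixture("h2")
  tabs_sd <- fx$tabs
  hp_layout <- basis_layout(fx$system, fx$protonic_shells, "HP")
  tabs_hp <- neoscf:::retarget_tables(tabs_sd, hp_layout)
  st <- neoscf:::state_from_coeffs(
    tabs_hp, core_guess_electronic(tabs_hp)$vectors,
    core_guess_nuclear(tabs_hp))
  expect_error(build_nuclear_fock_sd(tabs_hp, st$De, Reduce(`+`, st$Dp_list)),
               "SD layout")
  expect_error(build_nuclear_fock_hp(tabs_sd, st$De, st$Dp_list, 1),
               "HP or HPstar")
})

test_that("HP* Fock differs from HP exactly by the self Coulomb-exchange term", {
  fx <- cached_fixture("water")
  hp_layout <- basis_layout(fx$system, fx$protonic_shells, "HP")
  tabs <- neoscf:::retarget_tables(fx$tabs, hp_layout)
  st <- neoscf:::state_from_coeffs(
    tabs, core_guess_electronic(tabs)$vectors, core_guess_nuclear(tabs))
  for (i in 1:2) {
    Fhp <- build_nuclear_fock_hp(tabs, st$De, st$Dp_list, i,
                                 include_self = FALSE)
    Fhps <- build_nuclear_fock_hp(tabs, st$De, st$Dp_list, i,
                                  include_self = TRUE)
    r <- hp_layout$ranges[[i]]
    self_JK <- neoscf:::contract_J(tabs$Jpp, st$Dp_list[[i]]) -
      neoscf:::contract_J(tabs$Kpp, st$Dp_list[[i]])
    expect_equal(Fhps - Fhp, self_JK[r, r], tolerance = 1e-12)
  }
})

test_that("energy components sum to the total on every fixture", {
  for (nm in c("h2", "water", "h3o+")) {
    r <- cached_run(nm, "SD", "diis")
    comps <- unclass(r$state$report)
    total <- comps$total
    parts <- unlist(comps[setdiff(names(comps), c("total", "representation"))])
    expect_equal(sum(parts), total, tolerance = 1e-10, label = nm)
  }
})

test_that("single-proton SD and HP bookkeeping agree exactly, and converge together", {
  opw <- one_proton_water()
  r_sd <- scf_drive(opw$system, opw$basisdef, opw$protonic_shells,
                    neo_config("SD", "diis"), tabs = opw$tabs)
  r_hp <- scf_drive(opw$system, opw$basisdef, opw$protonic_shells,
                    neo_config("HP", "diis"), tabs = opw$tabs)
  expect_equal(r_sd$outcome, "converged")
  expect_equal(r_hp$outcome, "converged")
  expect_lt(abs(r_sd$final_energy - r_hp$final_energy), 1e-10)
  # identical state evaluated under both bookkeeping conventions
  st <- r_sd$state
  e_sd <- total_energy(r_sd$tabs, st$De, st$Dp_list, "SD")$total
  e_hp <- total_energy(r_sd$tabs, st$De, st$Dp_list, "HP")$total
  expect_identical(e_sd == e_sd, TRUE)
  expect_lt(abs(e_sd - e_hp), 1e-12)
})

test_that("quantizing protons raises the energy above the clamped-proton RHF", {
  # conventional RHF at the same geometry (protons as classical nuclei)
  clamped_energy <- function(fx_name) {
    sys_q <- fixture(fx_name)$system
    cl <- rbind(
      sys_q$classical,
      data.frame(element = "H", Z = 1,
                 x = sys_q$proton_centers[, 1],
                 y = sys_q$proton_centers[, 2],
                 z = sys_q$proton_centers[, 3]))
    sys_c <- neo_system(cl, protons = NULL, charge = sys_q$charge)
    bd <- builtin_basis("sto-3g")
    e_sh <- electronic_shells(sys_c, bd)
    st <- overlap_kinetic(e_sh, 1)
    V <- point_charge_matrix(e_sh, sys_c$classical$Z,
                             as.matrix(sys_c$classical[, c("x", "y", "z")]),
                             -1)
    G <- coulomb_tensor(e_sh)
    rr <- as.matrix(dist(as.matrix(sys_c$classical[, c("x", "y", "z")])))
    zz <- outer(sys_c$classical$Z, sys_c$classical$Z)
    e_nn <- sum(zz[upper.tri(rr)] / rr[upper.tri(rr)])
    oracle_rhf(st$S, st$T + V, G, n_occ = sys_c$n_electrons / 2,
               e_nn = e_nn)$energy
  }
  for (nm in c("h2", "h3o+")) {
    r <- cached_run(nm, "SD", "diis")
    expect_gt(r$final_energy, clamped_energy(nm))
  }
})

test_that("inter-proton exchange is vastly smaller than electronic exchange", {
  r <- cached_run("acetylene", "SD", "diis")
  st <- r$state
  ratio <- proton_exchange_ratio(r$tabs, st$De, st$Dp_list)
  expect_gte(ratio, 8)
  # a single proton has no inter-proton exchange at all
  opw <- one_proton_water()
  r1 <- scf_drive(opw$system, opw$basisdef, opw$protonic_shells,
                  neo_config("SD", "diis"), tabs = opw$tabs)
  expect_identical(proton_exchange_ratio(r1$tabs, r1$state$De,
                                         r1$state$Dp_list), Inf)
})

test_that("variational floor: converged energy is below random trial states", {
  r <- cached_run("water", "SD", "diis")
  fx <- cached_fixture("water")
  set.seed(19)
  st <- r$state
  n <- length(orbital_gradient(r$tabs, st))
  for (k in 1:5) {
    s <- rnorm(n, sd = 0.05)
    trial <- apply_rotation(r$tabs, st, s)
    expect_gt(trial$energy, r$final_energy - 1e-12)
  }
})

test_that("energy reports serialize to JSON with fixed keys", {
  r <- cached_run("h2", "SD", "diis")
  js <- jsonlite::fromJSON(energy_report_json(r$state$report))
  expect_true(all(c("kinetic_e", "kinetic_p", "coulomb_ep", "exchange_ee",
                    "classical_repulsion", "total") %in% names(js)))
  expect_equal(js$total, r$final_energy, tolerance = 1e-12)
})
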