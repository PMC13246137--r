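# Shared fixtures: integral tables and converged reference runs are expensive
# (tensor builds dominate), so they are cached per test session.

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fx_cache[[name]])) {
    fx <- fixture(name)
    layout <- basis_layout(fx$system, fx$protonic_shells, "SD")
    fx$tabs <- integral_tables(fx$system,
                               electronic_shells(fx$system, fx$basisdef),
                               layout)
    .fx_cache[[name]] <- fx
  }
  .fx_cache[[name]]
}

run_fixture <- function(name, config) {
  fx <- cached_fixture(name)
  scf_drive(fx$system, fx$basisdef, fx$protonic_shells, config, tabs = fx$tabs)
}

.run_cache <- new.env(parent = emptyenv())

# converged run, cached by fixture/representation/solver (SAD guesses,
# default thresholds)
cached_run <- function(name, representation = "SD", solver = "diis", ...) {
  key <- paste(name, representation, solver, sep = "/")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_fixture(
      name, neo_config(representation, solver, ...))
  }
  .run_cache[[key]]
}

# a one-quantum-proton water system (the second hydrogen stays classical)
one_proton_water <- function() {
  if (is.null(.fx_cache[["opw"]])) {
    txt <- paste("3", "water, one quantum H",
                 "O 0 0 0", "H 0.9572 0 0 Q", "H -0.2399872 0.9266272 0",
                 sep = "\n")
    sys <- read_xyz(txt, charge = 0)
    bd <- builtin_basis("sto-3g")
    psh <- list(make_even_tempered_protonic(sys$proton_centers[1, ]))
    layout <- basis_layout(sys, psh, "SD")
    tabs <- integral_tables(sys, electronic_shells(sys, bd), layout)
    .fx_cache[["opw"]] <- list(system = sys, basisdef = bd,
                               protonic_shells = psh, tabs = tabs)
  }
  .fx_cache[["opw"]]
}
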