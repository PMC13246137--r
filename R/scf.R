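#' Run configuration for a NEO-SCF calculation
#'
#' Defaults follow common practice for this kind of engine: energy-change
#' and error-norm thresholds of 1e-8, DIIS subspace capped at 15, no level
#' shifting or damping, at most 200 iterations.
#'
#' @param representation `"SD"`, `"HP"`, or `"HPstar"`.
#' @param solver one of `"roothaan"`, `"diis"`, `"gdm"`, `"trah"`,
#'   `"diis_gdm_hybrid"`, `"stepwise"`. TRAH is available for the SD
#'   representation only.
#' @param guess a [guess_spec].
#' @param thresh_energy convergence threshold on the energy change (Hartree).
#' @param thresh_error convergence threshold on the RMS error norms (both
#'   the electronic and the nuclear norm must fall below it).
#' @param max_iter iteration cap.
#' @param diis_cap DIIS subspace size.
#' @param shared_hp_layout give each HP proton the full shared nuclear basis
#'   (identical variational space as SD).
#' @param level_shift virtual-orbital level shift (Hartree; 0 disables).
#' @param damping density damping factor in `[0, 1)` (0 disables).
#' @param reference_energy optional reference for outcome classification.
#' @param seed integer seed (stochastic elements only; solvers are
#'   deterministic).
#' @return `neo_config` list.
#' @export
neo_config <- function(representation = c("SD", "HP", "HPstar"),
                       solver = c("diis", "gdm", "trah", "roothaan",
                                  "diis_gdm_hybrid", "stepwise"),
                       guess = guess_spec(),
                       thresh_energy = 1e-8, thresh_error = 1e-8,
                       max_iter = 200, diis_cap = 15,
                       shared_hp_layout = FALSE,
                       level_shift = 0, damping = 0,
                       reference_energy = NULL, seed = 1L) {
  representation <- match.arg(representation)
  solver <- match.arg(solver)
  if (thresh_energy <= 0 || thresh_error <= 0) stop("thresholds must be > 0")
  if (solver == "trah" && representation != "SD") {
    stop("the TRAH solver supports the SD representation only")
  }
  list(representation = representation, solver = solver, guess = guess,
       thresh_energy = thresh_energy, thresh_error = thresh_error,
       max_iter = max_iter, diis_cap = diis_cap,
       shared_hp_layout = shared_hp_layout, level_shift = level_shift,
       damping = damping, reference_energy = reference_energy,
       seed = as.integer(seed))
}

# swap the layout (and per-block orthogonalizers) on existing tables so the
# expensive tensors can be shared across representations
retarget_tables <- function(tabs, layout) {
  if (layout$nbf != tabs$n_p_basis ||
      !isTRUE(all.equal(n_basis_functions(layout$shells), tabs$n_p_basis))) {
    stop("layout does not match the tables' nuclear basis")
  }
  tabs$layout <- layout
  tabs$Xp_blocks <- lapply(layout$ranges, function(r) {
    sym_inv_sqrt(tabs$Sp[r, r, drop = FALSE])
  })
  tabs
}

#' One Roothaan iteration
#'
#' Diagonalizes the current electronic and nuclear Fock matrices (per-proton
#' blocks under HP/HPstar), reoccupies (maximum-overlap tracking for protons
#' against the previous occupied space), and rebuilds densities, Fock
#' matrices and the energy.
#'
#' @param tabs [integral_tables].
#' @param state current state (see [initial_state]).
#' @return Updated state.
#' @export
roothaan_step <- function(tabs, state) {
  co <- diagonalize_focks(tabs, state$Fe, state$Fp, prev_Cp = state$Cp)
  state_from_coeffs(tabs, co$Ce, co$Cp)
}

#' Initial SCF state from a guess
#'
#' @param system a [neo_system].
#' @param basisdef electronic basis definition.
#' @param tabs [integral_tables].
#' @param guess a [guess_spec].
#' @return SCF state list (`Ce`, `Cp`, densities, Focks, `energy`).
#' @export
initial_state <- function(system, basisdef, tabs, guess = guess_spec()) {
  g <- build_guess(system, basisdef, tabs, guess)
  state_from_coeffs(tabs, g$Ce, g$Cp)
}

# level shift: raise the virtual space of a Fock matrix by `shift`
apply_level_shift <- function(F, S, C, n_occ, shift) {
  if (shift == 0) return(F)
  nb <- ncol(C)
  if (nb == n_occ) return(F)
  Cv <- C[, (n_occ + 1):nb, drop = FALSE]
  F + shift * (S %*% Cv) %*% t(S %*% Cv)
}

new_trace <- function() {
  data.frame(iter = integer(), energy = numeric(), dE = numeric(),
             err_e = numeric(), err_p = numeric())
}

push_trace <- function(tr, it, E, dE, err_e, err_p) {
  rbind(tr, data.frame(iter = it, energy = E, dE = dE, err_e = err_e,
                       err_p = err_p))
}

finish_report <- function(config, trace, state, converged, tabs) {
  outcome <- if (!converged) {
    "failed"
  } else if (!is.null(config$reference_energy) &&
             state$energy > config$reference_energy + 1e-6) {
    "converged_higher_energy"
  } else {
    "converged"
  }
  structure(list(
    outcome = outcome, final_energy = state$energy,
    energy_report = state$report, trace = trace,
    iterations = nrow(trace), config = config,
    representation = config$representation, solver = config$solver,
    state = state
  ), class = "neo_convergence_report")
}

#' @export
print.neo_convergence_report <- function(x, ...) {
  cat(sprintf("<neo_convergence_report: %s/%s, %s in %d iterations, E = %.10f>\n",
              x$representation, x$solver, x$outcome, x$iterations,
              x$final_energy))
  invisible(x)
}

# ---------------------------------------------------------------------------
# solver loops (simultaneous updates of both subsystems every iteration)
# ---------------------------------------------------------------------------

run_diis_like <- function(tabs, state, config, use_diis = TRUE,
                          trace = new_trace(), stall_exit = FALSE) {
  hist <- diis_history(config$diis_cap)
  E_prev <- NA_real_
  converged <- FALSE
  err_hist <- numeric()
  while (nrow(trace) < config$max_iter) {
    errs <- state_errors(tabs, state)
    err_e <- rms(errs$e); err_p <- rms(errs$p)
    dE <- state$energy - E_prev
    trace <- push_trace(trace, nrow(trace) + 1, state$energy, dE, err_e, err_p)
    if (!is.na(dE) && abs(dE) < config$thresh_energy &&
        err_e < config$thresh_error && err_p < config$thresh_error) {
      converged <- TRUE
      break
    }
    err_tot <- sqrt(err_e^2 + err_p^2)
    err_hist <- c(err_hist, err_tot)
    if (stall_exit && length(err_hist) > 5) {
      if (err_tot > 0.99 * err_hist[length(err_hist) - 5]) {
        return(list(state = state, trace = trace, converged = FALSE,
                    stalled = TRUE))
      }
    }
    E_prev <- state$energy
    if (use_diis) {
      hist <- diis_push(hist, state$Fe, state$Fp, errs$e, errs$p)
      ext <- diis_extrapolate(hist)
      hist <- ext$history
      Fe <- ext$Fe; Fp <- ext$Fp
    } else {
      Fe <- state$Fe; Fp <- state$Fp
    }
    if (config$level_shift != 0) {
      Fe <- apply_level_shift(Fe, tabs$Se, state$Ce,
                              n_occupied_electronic(tabs), config$level_shift)
    }
    co <- diagonalize_focks(tabs, Fe, Fp, prev_Cp = state$Cp)
    new_state <- state_from_coeffs(tabs, co$Ce, co$Cp)
    if (config$damping > 0) {
      d <- config$damping
      De <- (1 - d) * new_state$De + d * state$De
      Dp <- Map(function(a, b) (1 - d) * a + d * b,
                new_state$Dp_list, state$Dp_list)
      Fe <- build_electronic_fock(tabs, De, Dp)
      # damped densities re-enter through the next Fock build only
      new_state$De <- De; new_state$Dp_list <- Dp; new_state$Fe <- Fe
    }
    state <- new_state
  }
  list(state = state, trace = trace, converged = converged, stalled = FALSE)
}

run_gdm <- function(tabs, state, config, trace = new_trace()) {
  gs <- gdm_state()
  g <- orbital_gradient(tabs, state)
  E_prev <- NA_real_
  converged <- FALSE
  while (nrow(trace) < config$max_iter) {
    errs <- state_errors(tabs, state)
    err_e <- rms(errs$e); err_p <- rms(errs$p)
    dE <- state$energy - E_prev
    trace <- push_trace(trace, nrow(trace) + 1, state$energy, dE, err_e, err_p)
    if (!is.na(dE) && abs(dE) < config$thresh_energy &&
        err_e < config$thresh_error && err_p < config$thresh_error) {
      converged <- TRUE
      break
    }
    E_prev <- state$energy
    h0 <- hessian_diagonal(tabs, state)
    d <- gdm_step(gs, g, h0)
    if (sum(g * d) >= 0) { # safeguard: reset to preconditioned steepest descent
      gs <- gdm_state()
      d <- -g / h0
    }
    ls <- gdm_line_search(tabs, state, g, d)
    if (is.null(ls)) { # no descent even at tiny steps: restart memory
      gs <- gdm_state()
      ls <- gdm_line_search(tabs, state, g, -g / h0)
      if (is.null(ls)) break
    }
    g_new <- orbital_gradient(tabs, ls$state)
    gs <- gdm_update(gs, ls$step, g_new - g)
    state <- ls$state
    g <- g_new
  }
  list(state = state, trace = trace, converged = converged)
}

run_trah <- function(tabs, state, config, trace = new_trace()) {
  trust <- 0.4
  E_prev <- NA_real_
  converged <- FALSE
  while (nrow(trace) < config$max_iter) {
    errs <- state_errors(tabs, state)
    err_e <- rms(errs$e); err_p <- rms(errs$p)
    dE <- state$energy - E_prev
    trace <- push_trace(trace, nrow(trace) + 1, state$energy, dE, err_e, err_p)
    if (!is.na(dE) && abs(dE) < config$thresh_energy &&
        err_e < config$thresh_error && err_p < config$thresh_error) {
      converged <- TRUE
      break
    }
    E_prev <- state$energy
    g <- orbital_gradient(tabs, state)
    hv <- function(x) hessian_vector_product(tabs, state, x)
    hdiag <- hessian_diagonal(tabs, state)
    accepted <- FALSE
    for (try in 1:10) {
      st <- trah_step(list(g = g, hess_vec = hv, hdiag = hdiag,
                           trust = trust))
      trial <- apply_rotation(tabs, state, st$s)
      if (trial$energy - state$energy <= 1e-12) {
        pred <- sum(g * st$s) + 0.5 * sum(st$s * hv(st$s))
        ratio <- if (pred < 0) (trial$energy - state$energy) / pred else 0
        if (ratio < 0.25) trust <- 0.7 * trust
        else if (ratio > 0.75) trust <- min(1.2 * trust, 1.0)
        state <- trial
        accepted <- TRUE
        break
      }
      trust <- trust / 2
    }
    if (!accepted) break
  }
  list(state = state, trace = trace, converged = converged)
}

# alternating full electronic / full nuclear convergence; each inner Fock
# cycle counts as one iteration
run_stepwise <- function(tabs, state, config) {
  trace <- new_trace()
  converged <- FALSE
  E_prev <- NA_real_
  inner_cap <- 50
  while (nrow(trace) < config$max_iter && !converged) {
    for (sub in c("e", "p")) {
      hist <- diis_history(config$diis_cap)
      for (k in seq_len(inner_cap)) {
        if (nrow(trace) >= config$max_iter) break
        errs <- state_errors(tabs, state)
        err_e <- rms(errs$e); err_p <- rms(errs$p)
        dE <- state$energy - E_prev
        trace <- push_trace(trace, nrow(trace) + 1, state$energy, dE,
                            err_e, err_p)
        if (!is.na(dE) && abs(dE) < config$thresh_energy &&
            err_e < config$thresh_error && err_p < config$thresh_error) {
          converged <- TRUE
          break
        }
        sub_err <- if (sub == "e") err_e else err_p
        if (sub_err < config$thresh_error && k > 1) break
        E_prev <- state$energy
        # stage-local DIIS: only the active subsystem's error enters the Gram
        if (sub == "e") {
          hist <- diis_push(hist, state$Fe, state$Fp, errs$e, numeric(0))
          ext <- diis_extrapolate(hist)
          hist <- ext$history
          es <- generalized_eigen(ext$Fe, tabs$Se, tabs$Xe)
          state <- state_from_coeffs(tabs, es$vectors, state$Cp)
        } else {
          hist <- diis_push(hist, state$Fe, state$Fp, numeric(0), errs$p)
          ext <- diis_extrapolate(hist)
          hist <- ext$history
          co <- diagonalize_focks(tabs, state$Fe, ext$Fp, prev_Cp = state$Cp)
          state <- state_from_coeffs(tabs, state$Ce, co$Cp)
        }
      }
      if (converged) break
    }
  }
  list(state = state, trace = trace, converged = converged)
}

#' Drive a simultaneous NEO-SCF optimization
#'
#' Builds (or reuses) the integral tables, forms the initial guess, and runs
#' the configured solver until the energy change and both subsystem error
#' norms fall below their thresholds. The hybrid solver runs DIIS until the
#' combined error norm stalls (less than 1% relative decrease over 5
#' iterations), then hands the state to GDM.
#'
#' @param system a [neo_system].
#' @param basisdef electronic basis definition (element -> templates).
#' @param protonic_shells per-proton shell lists, e.g. from
#'   [make_even_tempered_protonic].
#' @param config a [neo_config].
#' @param tabs optional pre-built [integral_tables] (re-targeted to the
#'   configured representation's layout).
#' @return A `neo_convergence_report`: outcome, per-iteration trace, final
#'   energy decomposition, and the converged state.
#' @export
scf_drive <- function(system, basisdef, protonic_shells, config = neo_config(),
                      tabs = NULL) {
  layout <- basis_layout(system, protonic_shells, config$representation,
                         shared_hp_layout = config$shared_hp_layout)
  if (is.null(tabs)) {
    e_sh <- electronic_shells(system, basisdef)
    tabs <- integral_tables(system, e_sh, layout)
  } else {
    tabs <- retarget_tables(tabs, layout)
  }
  state <- initial_state(system, basisdef, tabs, config$guess)
  res <- switch(config$solver,
    roothaan = run_diis_like(tabs, state, config, use_diis = FALSE),
    diis = run_diis_like(tabs, state, config, use_diis = TRUE),
    gdm = run_gdm(tabs, state, config),
    trah = run_trah(tabs, state, config),
    stepwise = run_stepwise(tabs, state, config),
    diis_gdm_hybrid = {
      r1 <- run_diis_like(tabs, state, config, use_diis = TRUE,
                          stall_exit = TRUE)
      if (r1$stalled) {
        run_gdm(tabs, r1$state, config, trace = r1$trace)
      } else {
        r1
      }
    }
  )
  rep <- finish_report(config, res$trace, res$state, res$converged, tabs)
  rep$tabs <- tabs
  rep
}
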