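# Run and sweep harness: configuration files, JSON reports, and the data
# tables behind convergence-trace figures.

#' Execute one NEO-SCF run
#'
#' Accepts either a built-in fixture name or an XYZ path plus quantum tags,
#' runs [scf_drive], optionally writes a JSON report, and logs a
#' per-iteration table to stderr.
#'
#' @param fixture_name built-in fixture name (exclusive with `xyz`).
#' @param xyz path to an XYZ file (quantum protons via `Q` tokens or
#'   `quantum_tags`).
#' @param quantum_tags passed to [read_xyz].
#' @param charge total charge for XYZ input.
#' @param config a [neo_config].
#' @param protonic even-tempered protonic parameters (see [fixture]).
#' @param electronic_basis built-in electronic basis name or basis file path.
#' @param output optional JSON report path.
#' @param tabs optional pre-built integral tables.
#' @param quiet suppress the stderr log.
#' @return `neo_convergence_report` (invisibly when `output` is given).
#' @export
neo_run <- function(fixture_name = NULL, xyz = NULL, quantum_tags = "all-H",
                    charge = 0, config = neo_config(), protonic = list(),
                    electronic_basis = "sto-3g", output = NULL, tabs = NULL,
                    quiet = FALSE) {
  if (!is.null(fixture_name)) {
    fx <- fixture(fixture_name, protonic = protonic,
                  electronic_basis = electronic_basis)
    system <- fx$system; basisdef <- fx$basisdef
    protonic_shells <- fx$protonic_shells
  } else if (!is.null(xyz)) {
    system <- read_xyz(xyz, quantum_tags = quantum_tags, charge = charge)
    basisdef <- if (file.exists(electronic_basis)) {
      read_basis(electronic_basis, kind = "electronic")
    } else {
      builtin_basis(electronic_basis)
    }
    et <- modifyList(list(n_s = 4, n_p = 3, alpha0 = 4.0, beta = 2.5),
                     protonic)
    protonic_shells <- lapply(seq_len(system$n_protons), function(i) {
      make_even_tempered_protonic(system$proton_centers[i, ], n_s = et$n_s,
                                  n_p = et$n_p, alpha0 = et$alpha0,
                                  beta = et$beta)
    })
  } else {
    stop("provide either fixture_name or xyz")
  }
  report <- scf_drive(system, basisdef, protonic_shells, config, tabs = tabs)
  if (!quiet) {
    tr <- report$trace
    for (i in seq_len(nrow(tr))) {
      message(sprintf("iter %3d  E = %18.12f  dE = %10.3e  err_e = %9.3e  err_p = %9.3e",
                      tr$iter[i], tr$energy[i], tr$dE[i], tr$err_e[i],
                      tr$err_p[i]))
    }
    message(sprintf("outcome: %s after %d iterations, E = %.12f Hartree",
                    report$outcome, report$iterations, report$final_energy))
  }
  if (!is.null(output)) {
    jsonlite::write_json(report_as_list(report), output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

# Classify sweep cells against each molecule's purported lowest energy (the
# minimum over its converged cells); more than 1e-6 Hartree above it counts
# as converged_higher_energy. Order-invariant.
classify_sweep_cells <- function(cells) {
  cells$classification <- NA_character_
  for (mol in unique(cells$molecule)) {
    sel <- cells$molecule == mol
    conv <- sel & cells$outcome_raw != "failed" & !is.na(cells$energy)
    emin <- if (any(conv)) min(cells$energy[conv]) else NA_real_
    cells$classification[sel] <- ifelse(
      !conv[sel], "failed",
      ifelse(cells$energy[sel] > emin + 1e-6, "converged_higher_energy",
             "converged"))
  }
  cells
}

# JSON-serializable view of a convergence report (config echo, trace arrays,
# outcome, final energy decomposition)
report_as_list <- function(report) {
  en <- unclass(report$energy_report)
  list(
    outcome = report$outcome,
    final_energy = report$final_energy,
    iterations = report$iterations,
    representation = report$representation,
    solver = report$solver,
    config = report$config[c("representation", "solver", "thresh_energy",
                             "thresh_error", "max_iter", "diis_cap",
                             "shared_hp_layout", "level_shift", "damping",
                             "seed")],
    guess = report$config$guess[c("electronic", "nuclear", "perturb", "seed")],
    trace = as.list(report$trace),
    energy_components = en
  )
}

#' Sweep a grid of convergence experiments
#'
#' Runs every valid cell of `fixtures x representations x solvers x guesses`
#' (the TRAH/Hartree-product combination is skipped as unsupported),
#' determines each molecule's purported lowest energy as the minimum over its
#' converged cells, and classifies every cell as `converged` (to that
#' minimum), `converged_higher_energy` (more than 1e-6 Hartree above it), or
#' `failed`. Integral tables are built once per fixture and shared across
#' cells.
#'
#' @param fixtures character vector of fixture names.
#' @param representations subset of `c("SD", "HP", "HPstar")`.
#' @param solvers subset of the [neo_config] solvers.
#' @param guesses list of `c(electronic, nuclear)` pairs, e.g.
#'   `list(c("sad", "sad"), c("core", "core"))`.
#' @param config base [neo_config] (representation/solver/guess overridden
#'   per cell).
#' @param protonic even-tempered protonic parameters.
#' @param csv optional path for the per-cell CSV table.
#' @param json optional path for the JSON tallies.
#' @return `neo_sweep_result`: data frame `cells`, list `reports`, `tallies`.
#' @export
neo_sweep <- function(fixtures, representations = c("SD", "HP"),
                      solvers = c("diis", "gdm"),
                      guesses = list(c("sad", "sad")),
                      config = neo_config(), protonic = list(),
                      csv = NULL, json = NULL) {
  cells <- list()
  reports <- list()
  for (fx_name in fixtures) {
    fx <- fixture(fx_name, protonic = protonic)
    tabs <- NULL
    for (rep in representations) {
      for (sv in solvers) {
        if (sv == "trah" && rep != "SD") next
        for (gu in guesses) {
          cfg <- config
          cfg$representation <- rep
          cfg$solver <- sv
          cfg$guess <- guess_spec(electronic = gu[1], nuclear = gu[2])
          layout <- basis_layout(fx$system, fx$protonic_shells, rep,
                                 shared_hp_layout = cfg$shared_hp_layout)
          if (is.null(tabs)) {
            e_sh <- electronic_shells(fx$system, fx$basisdef)
            tabs <- integral_tables(fx$system, e_sh, layout)
          }
          rp <- tryCatch(
            scf_drive(fx$system, fx$basisdef, fx$protonic_shells, cfg,
                      tabs = tabs),
            error = function(e) {
              structure(list(outcome = "failed", final_energy = NA_real_,
                             iterations = NA_integer_, error = conditionMessage(e),
                             representation = rep, solver = sv),
                        class = "neo_convergence_report")
            })
          rp$tabs <- NULL
          rp$state <- NULL
          key <- paste(fx_name, rep, sv, paste(gu, collapse = ","), sep = "|")
          reports[[key]] <- rp
          cells[[key]] <- data.frame(
            molecule = fx_name, representation = rep, solver = sv,
            guess_e = gu[1], guess_n = gu[2],
            outcome_raw = rp$outcome, energy = rp$final_energy,
            iterations = rp$iterations, stringsAsFactors = FALSE)
        }
      }
    }
    tabs <- NULL
  }
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  cells <- classify_sweep_cells(cells)
  tallies <- table(factor(cells$classification,
                          levels = c("converged", "converged_higher_energy",
                                     "failed")))
  out <- structure(list(cells = cells, reports = reports,
                        tallies = as.list(tallies)),
                   class = "neo_sweep_result")
  if (!is.null(csv)) utils::write.csv(cells, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(tallies = out$tallies,
                              n_cells = nrow(cells)), json,
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.neo_sweep_result <- function(x, ...) {
  cat(sprintf("<neo_sweep_result: %d cells; converged %d, higher-energy %d, failed %d>\n",
              nrow(x$cells), x$tallies$converged,
              x$tallies$converged_higher_energy, x$tallies$failed))
  invisible(x)
}

#' Convergence-trace table for plotting
#'
#' Emits `log10(E_i - E0 + floor)` per iteration for a set of runs sharing a
#' reference energy `E0` (the purported lowest solution; defaults to the
#' minimum converged final energy among the reports). Iteration axes are
#' aligned; traces shorter than the longest are padded with `NA` after
#' convergence.
#'
#' @param reports list of `neo_convergence_report`s.
#' @param e0 reference energy; default from the reports.
#' @param floor additive floor inside the log (default 1e-12).
#' @return Data frame with columns `label`, `iter`, `log10_error`.
#' @export
trace_plot_data <- function(reports, e0 = NULL, floor = 1e-12) {
  if (length(reports) == 0) stop("need at least one report")
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- vapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      paste(r$representation, r$solver, i, sep = "/")
    }, character(1))
  }
  if (is.null(e0)) {
    fin <- vapply(reports, function(r) {
      if (r$outcome == "failed") NA_real_ else r$final_energy
    }, numeric(1))
    if (all(is.na(fin))) stop("no converged report to define E0")
    e0 <- min(fin, na.rm = TRUE)
  }
  nmax <- max(vapply(reports, function(r) nrow(r$trace), numeric(1)))
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    dE <- r$trace$energy - e0
    if (any(dE < -1e-8)) {
      warning("trace '", nm, "' dips below the reference energy: ",
              "inconsistent reference E0?")
    }
    val <- log10(pmax(dE, 0) + floor)
    data.frame(label = nm, iter = seq_len(nmax),
               log10_error = c(val, rep(NA_real_, nmax - length(val))))
  }))
  rownames(out) <- NULL
  out
}
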