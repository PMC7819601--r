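#' Named simulation scenarios
#'
#' Builds the model for the standard scenarios studied with this package:
#' \describe{
#'   \item{`barrier_only`}{Triangular promoter barrier (apex 25 kBT at
#'     -150 bp), no enzymes: pure statistical positioning.}
#'   \item{`barrier_spacer`}{Barrier plus spacer enzymes at k = 0.16/s
#'     (as an effective pair attraction for the equilibrium sampler).}
#'   \item{`yeast_like`}{Barrier, spacer enzymes (k = 0.16 or 0.08/s via
#'     `enzyme_rate`), and a -2 kBT positioning well on [0, 30] bp.}
#'   \item{`pol2_exchange`}{Explicit kinetics: diffusion, spacer enzymes at
#'     k = 0.16/s, and histone exchange at r_const = 0.1/s.}
#'   \item{`intermediate`}{Weakened barrier (2 kBT) and slower enzymes
#'     (k = 0.12/s): genes of intermediate activity.}
#'   \item{`density_078`}{As `barrier_spacer` with the barrier shifted 50 bp
#'     further upstream and a 0.78 density target.}
#' }
#' The returned model carries `mu = 0`; calibrate with [calibrate_mu()]
#' (target density in the `target_density` field) or use
#' [simulate_scenario()], which performs the full chain.
#'
#' @param name Scenario name.
#' @param lattice A [lattice_spec()].
#' @param enzyme_rate Override of the scenario's enzyme rate (used by
#'   `yeast_like` for the 0.16 vs 0.08 comparison).
#' @return A list with `name`, `model` (a [kinetic_model()]),
#'   `enzyme_rate`, `sampler` (`TRUE` if the scenario is meant for the
#'   accelerated equilibrium sampler), and `target_density`.
#' @export
build_preset <- function(name, lattice = lattice_spec(), enzyme_rate = NULL) {
  presets <- list(
    barrier_only = list(height = 25, k = 0, well = 0, r_const = 12,
                        D = 0, sampler = TRUE, density = 0.88, center = -150),
    barrier_spacer = list(height = 25, k = 0.16, well = 0, r_const = 12,
                          D = 0, sampler = TRUE, density = 0.88, center = -150),
    yeast_like = list(height = 25, k = 0.16, well = -2, r_const = 12,
                      D = 0, sampler = TRUE, density = 0.88, center = -150),
    pol2_exchange = list(height = 25, k = 0.16, well = 0, r_const = 0.1,
                         D = 1, sampler = FALSE, density = 0.88, center = -150),
    intermediate = list(height = 2, k = 0.12, well = 0, r_const = 12,
                        D = 0, sampler = TRUE, density = 0.88, center = -150),
    density_078 = list(height = 25, k = 0.16, well = 0, r_const = 12,
                       D = 0, sampler = TRUE, density = 0.78, center = -200))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  if (!is.null(enzyme_rate)) p$k <- enzyme_rate
  field <- energy_field(
    lattice,
    barrier = if (p$height > 0)
      make_barrier(lattice, center_offset = p$center, height = p$height)
      else NULL,
    positioning = if (p$well < 0)
      make_positioning(lattice, depth = p$well) else NULL)
  model <- if (p$sampler) {
    # the enzyme effect enters through the renormalized pair attraction,
    # attached by simulate_scenario()/effective_pair_potential()
    kinetic_model(field, D = 0, enzyme_rate = 0, r_const = p$r_const)
  } else {
    kinetic_model(field, D = p$D, enzyme_rate = p$k, r_const = p$r_const)
  }
  list(name = name, model = model, enzyme_rate = p$k, sampler = p$sampler,
       target_density = p$density)
}

#' Run a full scenario: effective potential, density calibration, sampling
#'
#' Convenience chain used by the analysis scripts: builds the preset model,
#' obtains the enzyme-renormalized pair attraction (sampler scenarios with
#' k > 0), calibrates the chemical potential to the scenario's density
#' target, and samples.
#'
#' @param name Scenario name (see [build_preset()]).
#' @param protocol A [simulation_protocol()].
#' @param lattice A [lattice_spec()].
#' @param enzyme_rate Optional enzyme-rate override.
#' @param mu Optional precalibrated chemical potential (skips calibration).
#' @param calib_seed Seed offset for the calibration runs.
#' @return A list with `record` (the `ensemble_record`), `model`, `mu`, and
#'   `pair` (the pair potential used).
#' @export
simulate_scenario <- function(name, protocol, lattice = lattice_spec(),
                              enzyme_rate = NULL, mu = NULL,
                              calib_seed = 4242L) {
  preset <- build_preset(name, lattice, enzyme_rate)
  pair <- if (preset$sampler && preset$enzyme_rate > 0)
    effective_pair_potential(preset$enzyme_rate,
                             footprint_bp = lattice$footprint_bp)
  else pair_potential(lattice$footprint_bp)
  model <- kinetic_model(preset$model$field, pair,
                         D = preset$model$D,
                         enzyme_rate = preset$model$enzyme_rate,
                         enzyme_range_bp = preset$model$enzyme_range_bp,
                         r_const = preset$model$r_const)
  if (is.null(mu))
    mu <- calibrate_mu(model, target_density = preset$target_density,
                       seed = calib_seed)
  model <- kinetic_model(model$field, model$pair, D = model$D,
                         enzyme_rate = model$enzyme_rate,
                         enzyme_range_bp = model$enzyme_range_bp,
                         r_const = model$r_const, mu = as.numeric(mu))
  record <- run_simulation(model, protocol)
  list(record = record, model = model, mu = as.numeric(mu), pair = pair)
}
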