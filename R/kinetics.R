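#' Kinetic model of nucleosome dynamics
#'
#' Bundles all rate parameters of the stochastic model with the energy field
#' and pair potential.  Four event classes are simulated: (i) thermal 1-bp
#' diffusion hops at rate `D/step^2 * exp(-dU/2)` (detailed balance);
#' (ii) spacer-enzyme remodeling: any consecutive pair with dyad gap in
#' `[footprint + 1, enzyme_range_bp]` fires at rate `enzyme_rate`,
#' moving one of the two nucleosomes 1 bp toward the other regardless of the
#' energy landscape (this breaks detailed balance); (iii) desorption of a
#' bound nucleosome at `r_const * exp(+dV/2)`; (iv) absorption at any lattice
#' site with a fully free footprint at `r_const * exp(-dV/2)`, where
#' `dV = dU_insert + mu` includes the chemical potential `mu`.
#'
#' @param field An [energy_field()].
#' @param pair A [pair_potential()]; defaults to pure hard core at the
#'   lattice footprint.  Supplying an attraction table turns the
#'   absorption/desorption dynamics into the enzyme-renormalized sampler.
#' @param D Diffusion coefficient in bp^2/s (default 1).
#' @param step_bp Hop step size in bp (default 1).
#' @param enzyme_rate Spacer-enzyme remodeling rate k in 1/s (default 0;
#'   presets in the source system: 0.16 active, 0.12 intermediate, 0.08 less
#'   active).
#' @param enzyme_range_bp Maximum dyad-to-dyad capture distance of the spacer
#'   enzyme (default 332, i.e. linker up to 185 bp).
#' @param r_const Basal histone-exchange rate constant in 1/s (default 0 =
#'   no exchange; 0.1 for explicit Pol II-driven exchange, 12 for the
#'   accelerated equilibrium sampler).
#' @param mu Chemical potential in kBT controlling the mean density under
#'   exchange; calibrate with [calibrate_mu()].
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(field, pair = NULL, D = 1, step_bp = 1,
                          enzyme_rate = 0, enzyme_range_bp = 332L,
                          r_const = 0, mu = 0) {
  lattice <- field$lattice
  if (is.null(pair)) pair <- pair_potential(lattice$footprint_bp)
  stopifnot(inherits(field, "energy_field"), inherits(pair, "pair_potential"))
  if (D < 0 || enzyme_rate < 0 || r_const < 0)
    stop("all rates must be >= 0")
  if (step_bp != 1) stop("only step_bp = 1 is supported")
  if (enzyme_range_bp < lattice$footprint_bp)
    stop("enzyme_range_bp must be >= footprint_bp")
  structure(list(field = field, pair = pair, lattice = lattice,
                 D = D, step_bp = step_bp,
                 enzyme_rate = enzyme_rate,
                 enzyme_range_bp = as.integer(enzyme_range_bp),
                 r_const = r_const, mu = mu),
            class = "kinetic_model")
}

#' Diffusion hop rate
#'
#' `D / step^2 * exp(-dU/2)`; the symmetric splitting of the energy
#' difference between forward and backward rates satisfies detailed balance.
#' Blocked moves (`dU = Inf`) have rate 0.
#' @param dU Energy change of the hop in kBT (may be `Inf`).
#' @param D Diffusion coefficient in bp^2/s.
#' @param step_bp Step size in bp.
#' @return Rate in 1/s; vectorized over `dU`.
#' @export
diffusion_rate <- function(dU, D = 1, step_bp = 1) {
  r <- D / step_bp^2 * exp(-dU / 2)
  r[is.infinite(dU) & dU > 0] <- 0
  r
}

#' Histone absorption/desorption rates
#'
#' `r_on = r_const * exp(-dV/2)`, `r_off = r_const * exp(+dV/2)` with
#' `dV = dU + mu`.  The ratio `r_on/r_off = exp(-dV)` holds exactly, so the
#' exchange dynamics satisfies detailed balance with respect to the energy
#' plus the chemical potential.
#' @param dU Insertion energy change in kBT.
#' @param mu Chemical potential in kBT.
#' @param r_const Basal rate constant in 1/s.
#' @return A list with vectors `r_on` and `r_off`.
#' @export
exchange_rates <- function(dU, mu = 0, r_const = 0.1) {
  if (r_const < 0) stop("r_const must be >= 0")
  dV <- dU + mu
  r_on <- r_const * exp(-dV / 2)
  r_on[is.infinite(dV) & dV > 0] <- 0
  list(r_on = r_on, r_off = r_const * exp(dV / 2))
}

#' Enumerate all events and rates of a configuration (reference)
#'
#' From-scratch enumeration of every elementary event available to the
#' Gillespie dynamics, with its rate.  This is the reference implementation
#' used to validate the simulation engine's incremental bookkeeping; it is
#' O(L) per call and not meant for production simulation.
#'
#' @param config A [nucleosome_config()].
#' @param model A [kinetic_model()].
#' @return A data.frame with columns `type` (`hop_left`, `hop_right`,
#'   `enzyme`, `remove`, `insert`), `id` (1-based nucleosome or pair index,
#'   or 0-based site for inserts), and `rate` (1/s).  Zero-rate events are
#'   omitted except blocked hops, which are reported with rate 0.
#' @export
enumerate_events <- function(config, model) {
  d <- config$dyads
  n <- length(d)
  L <- model$lattice$length_bp
  fp <- model$lattice$footprint_bp
  rows <- list()
  add <- function(type, id, rate)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, id = id, rate = rate)
  for (i in seq_len(n)) {
    dUl <- delta_energy(config, list(type = "hop", index = i, dir = -1L),
                        model$field, model$pair)
    dUr <- delta_energy(config, list(type = "hop", index = i, dir = +1L),
                        model$field, model$pair)
    add("hop_left", i, diffusion_rate(dUl, model$D, model$step_bp))
    add("hop_right", i, diffusion_rate(dUr, model$D, model$step_bp))
  }
  if (model$enzyme_rate > 0 && n >= 2L) {
    g <- circular_gaps(d, L)
    for (i in seq_len(n)) {
      if (g[i] >= fp + 1L && g[i] <= model$enzyme_range_bp)
        add("enzyme", i, model$enzyme_rate)
    }
  }
  if (model$r_const > 0) {
    for (i in seq_len(n)) {
      dU_ins_rev <- -delta_energy(config, list(type = "remove", index = i),
                                  model$field, model$pair)
      add("remove", i,
          exchange_rates(dU_ins_rev, model$mu, model$r_const)$r_off)
    }
    for (s in 0:(L - 1L)) {
      dU <- delta_energy(config, list(type = "insert", dyad = s),
                         model$field, model$pair)
      if (is.finite(dU))
        add("insert", s,
            exchange_rates(dU, model$mu, model$r_const)$r_on)
    }
  }
  if (!length(rows))
    return(data.frame(type = character(), id = integer(), rate = numeric()))
  do.call(rbind, rows)
}

#' One Gillespie step (reference implementation)
#'
#' Draws an exponential waiting time at the total event rate and an event
#' with probability proportional to its rate, then applies it.  Uses R's
#' RNG; intended for small-system tests and as an oracle for the compiled
#' engine.
#' @param config A [nucleosome_config()].
#' @param model A [kinetic_model()].
#' @return `list(config, dt, event)`; if the total rate is zero, `dt = Inf`
#'   and the configuration is unchanged (absorbing state).
#' @export
gillespie_step <- function(config, model) {
  ev <- enumerate_events(config, model)
  tot <- sum(ev$rate)
  if (!is.finite(tot) || tot <= 0)
    return(list(config = config, dt = Inf, event = NULL))
  dt <- stats::rexp(1, tot)
  j <- sample.int(nrow(ev), 1L, prob = ev$rate)
  e <- ev[j, ]
  move <- switch(as.character(e$type),
    hop_left  = list(type = "hop", index = e$id, dir = -1L),
    hop_right = list(type = "hop", index = e$id, dir = +1L),
    enzyme = {
      # move one member of pair (id, id+1) toward the other, coin flip
      n <- length(config$dyads)
      i <- e$id; j2 <- if (i == n) 1L else i + 1L
      if (stats::runif(1) < 0.5) list(type = "hop", index = i, dir = +1L)
      else list(type = "hop", index = j2, dir = -1L)
    },
    remove = list(type = "remove", index = e$id),
    insert = list(type = "insert", dyad = e$id))
  list(config = apply_move(config, move), dt = dt, event = e)
}

#' Simulation protocol
#'
#' Replica count, time horizon, burn-in, sampling grid, initial placement
#' and master seed.  Samples are taken at
#' `burn_in + sample_interval * (1, 2, ...)` up to `t_end`.  The default
#' burn-in discards the first half of each trajectory.
#'
#' @param n_replicas Number of independent replicas.
#' @param t_end Simulated time per replica in seconds.
#' @param burn_in Seconds discarded at the start (default `t_end/2`).
#' @param sample_interval Seconds between recorded configurations (default 2).
#' @param initial_n Number of nucleosomes placed uniformly at random at t = 0.
#' @param seed Master integer seed; replica seeds are derived from it (one
#'   `sample.int` stream per master seed, documented in the record
#'   fingerprint).
#' @return An object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(n_replicas = 1L, t_end = 5000,
                                burn_in = NULL, sample_interval = 2,
                                initial_n = 86L, seed = 1L) {
  if (is.null(burn_in)) burn_in <- t_end / 2
  if (!(t_end > burn_in && burn_in >= 0))
    stop("need t_end > burn_in >= 0")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  structure(list(n_replicas = as.integer(n_replicas), t_end = t_end,
                 burn_in = burn_in, sample_interval = sample_interval,
                 initial_n = as.integer(initial_n), seed = as.integer(seed)),
            class = "simulation_protocol")
}

#' Random non-overlapping initial configuration
#'
#' Places `n` nucleosomes uniformly at random over all valid (hard-core
#' respecting) ring configurations, by drawing the gap composition with a
#' stars-and-bars construction and a uniform rotation offset.  Uses R's RNG.
#'
#' @param n Number of nucleosomes; must not exceed `floor(L / footprint)`.
#' @param lattice A [lattice_spec()].
#' @return A valid [nucleosome_config()].
#' @export
random_initial_configuration <- function(n, lattice) {
  n <- as.integer(n)
  L <- lattice$length_bp
  fp <- lattice$footprint_bp
  cap <- L %/% fp
  if (n < 0L) stop("n must be >= 0")
  if (n > cap)
    stop(sprintf("invalid protocol: %d nucleosomes exceed lattice capacity %d",
                 n, cap))
  if (n == 0L) return(nucleosome_config(integer(0), lattice))
  offset <- sample.int(L, 1L) - 1L
  if (n == 1L) return(nucleosome_config(offset, lattice))
  slack <- L - n * fp
  # composition of `slack` into n non-negative parts, uniform
  cuts <- sort(sample.int(slack + n - 1L, n - 1L))
  parts <- diff(c(0L, cuts, slack + n)) - 1L
  gaps <- fp + parts
  dyads <- (offset + cumsum(c(0L, gaps[-n]))) %% L
  nucleosome_config(dyads, lattice)
}

#' Run the stochastic simulation
#'
#' Simulates independent replicas of the full kinetic model with the
#' compiled Gillespie engine and records configurations on the protocol's
#' sampling grid.  Bit-for-bit reproducible for a given master seed: replica
#' seeds are drawn once from the master seed and drive both the random
#' initial placement (R RNG) and the engine (mt19937-64).
#'
#' @param model A [kinetic_model()].
#' @param protocol A [simulation_protocol()].
#' @param max_events Per-replica event budget safeguard (default 2e9).
#' @return An `ensemble_record`: list with `samples` (list of 0-based dyad
#'   vectors), `replica`, `time`, `lattice`, `model`, `protocol`,
#'   `fingerprint`.
#' @export
run_simulation <- function(model, protocol, max_events = 2e9) {
  lattice <- model$lattice
  cap <- lattice$length_bp %/% lattice$footprint_bp
  if (protocol$initial_n > cap)
    stop(sprintf("invalid protocol: initial_n %d exceeds capacity %d",
                 protocol$initial_n, cap))
  m <- floor((protocol$t_end - protocol$burn_in) / protocol$sample_interval)
  if (m < 1L) stop("protocol admits no sample times")
  sample_times <- protocol$burn_in + protocol$sample_interval * seq_len(m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(protocol$seed)
  child <- sample.int(.Machine$integer.max, protocol$n_replicas)
  att <- model$pair$attraction
  if (is.null(att)) att <- numeric(0)
  samples <- list(); replica <- integer(0); time <- numeric(0)
  for (r in seq_len(protocol$n_replicas)) {
    set.seed(child[r])
    init <- random_initial_configuration(protocol$initial_n, lattice)
    res <- cpp_gillespie(lattice$length_bp, model$field$dyad_energy,
                         model$pair$hard_core_bp, att,
                         model$D, model$enzyme_rate, model$enzyme_range_bp,
                         model$r_const, model$mu,
                         init$dyads, sample_times,
                         as.double(child[r]), max_events, FALSE)
    if (res$truncated)
      warning(sprintf("replica %d hit the event budget at t = %.1f", r, res$t))
    samples <- c(samples, res$samples)
    replica <- c(replica, rep.int(r, length(res$samples)))
    time <- c(time, sample_times[seq_along(res$samples)])
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(samples = samples, replica = replica, time = time,
                 lattice = lattice, model = model, protocol = protocol,
                 fingerprint = list(
                   engine = "incremental Gillespie, mt19937-64, inversion sampling",
                   seed_scheme = "replica seeds = sample.int(2^31-1) stream from master seed",
                   child_seeds = child)),
            class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("<ensemble_record> %d samples, %d replica(s), lattice %d bp\n",
              length(x$samples), max(x$replica), x$lattice$length_bp))
  if (length(x$samples)) {
    nn <- lengths(x$samples)
    cat(sprintf("  bound nucleosomes: mean %.1f, range [%d, %d]\n",
                mean(nn), min(nn), max(nn)))
  }
  invisible(x)
}
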