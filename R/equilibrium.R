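#' Exact nearest-neighbor gap distribution on a ring (transfer sum)
#'
#' For `N` hard rods with nearest-neighbor pair potential `u` on a periodic
#' lattice of `L` sites and a uniform field, the joint gap distribution is
#' `P(g_1..g_N) proportional to prod exp(-u(g_i))` constrained to
#' `sum g_i = L`.  The marginal of one gap is computed exactly by repeated
#' convolution of the single-gap weight.  Used as the equilibrium-side
#' prediction when fitting the enzyme-renormalized pair attraction, and as
#' an independent oracle in tests.
#'
#' @param N Number of nucleosomes (>= 2).
#' @param L Lattice length in bp.
#' @param pair A [pair_potential()].
#' @return A data.frame with columns `gap` (0..L) and `p` (probability,
#'   summing to 1; zero below the hard core).
#' @export
ring_gap_marginal <- function(N, L, pair) {
  if (N < 2L) stop("N must be >= 2")
  if (N * pair$hard_core_bp > L) stop("N rods do not fit on the ring")
  f <- exp(-pair_energy(pair, 0:L))   # weight per gap; 0 below hard core
  conv <- f
  if (N > 2L) {
    # iterated FFT convolution, truncated to gaps <= L and renormalized
    P <- 2^ceiling(log2(2L * (L + 1L)))
    Ff <- stats::fft(c(f, numeric(P - L - 1L)))
    for (i in seq_len(N - 2L)) {
      Fc <- stats::fft(c(conv, numeric(P - length(conv))))
      conv <- Re(stats::fft(Fc * Ff, inverse = TRUE)) / P
      conv <- conv[seq_len(L + 1L)]   # gaps beyond L cannot occur
      conv[conv < 0] <- 0             # FFT round-off
      supp0 <- pair$hard_core_bp * (i + 1L)   # exact support lower bound
      if (supp0 > 0L) conv[seq_len(min(supp0, L + 1L))] <- 0
      conv <- conv / max(conv)
    }
  }
  # P(g) prop. to f(g) * C_{N-1}(L - g)
  p <- f * conv[L - (0:L) + 1L]
  p[is.na(p)] <- 0
  data.frame(gap = 0:L, p = p / sum(p))
}

#' Exact interior-gap distribution of rods on a bounded segment
#'
#' For `N` hard rods on a segment of `M` admissible dyad sites with
#' nearest-neighbor pair weight `exp(-u)` on the `N - 1` interior gaps and
#' free (non-interacting) end slacks, computes the exact marginal of one
#' interior gap by convolution.  This is the equilibrium description of a
#' nucleosome array confined between promoter barriers, the geometry in
#' which spacer-enzyme condensation is visible: attraction compacts the
#' array and pushes slack into the end gaps.
#'
#' @param N Number of rods (>= 2).
#' @param M Number of admissible dyad sites on the segment.
#' @param pair A [pair_potential()].
#' @return A data.frame with columns `gap` (0..M) and `p`.
#' @export
segment_gap_marginal <- function(N, M, pair) {
  if (N < 2L) stop("N must be >= 2")
  L <- M
  f <- exp(-pair_energy(pair, 0:L))
  P <- 2^ceiling(log2(2 * (L + 1L)))
  Ff <- stats::fft(c(f, numeric(P - L - 1L)))
  conv <- if (N > 3L) {
    cc <- f
    for (i in seq_len(N - 3L)) {
      Fc <- stats::fft(c(cc, numeric(P - length(cc))))
      cc <- Re(stats::fft(Fc * Ff, inverse = TRUE)) / P
      cc <- cc[seq_len(L + 1L)]; cc[cc < 0] <- 0
      supp0 <- pair$hard_core_bp * (i + 1L)
      if (supp0 > 0L) cc[seq_len(min(supp0, L + 1L))] <- 0
      cc <- cc / max(cc)
    }
    cc
  } else if (N == 3L) f else { z <- numeric(L + 1L); z[1L] <- 1; z }
  ramp <- 0:L + 1          # end-slack multiplicity (s0 + s1 = r: r + 1 ways)
  Fc <- stats::fft(c(conv, numeric(P - length(conv))))
  Fr <- stats::fft(c(ramp, numeric(P - L - 1L)))
  Tm <- Re(stats::fft(Fc * Fr, inverse = TRUE)) / P
  Tm <- Tm[seq_len(L + 1L)]; Tm[Tm < 0] <- 0
  idx <- (M - 1L) - (0:L) + 1L
  p <- ifelse(idx >= 1L, f * Tm[pmax(idx, 1L)], 0)
  data.frame(gap = 0:L, p = p / sum(p))
}

.nucsim_cache <- new.env(parent = emptyenv())

#' Effective (enzyme-renormalized) pair attraction
#'
#' Spacer enzymes move a nucleosome pair together at an energy-independent
#' rate, which breaks detailed balance.  Their steady state can be folded
#' into an equilibrium description as an effective short-range attraction
#' between nearest neighbors.  On a uniform ring the enzyme moves merely
#' exchange linker length between adjacent gaps (no net drift), so bulk gap
#' statistics are nearly blind to them; the condensation becomes visible
#' when the array is confined by a promoter barrier, where compaction of
#' the array feeds the boundary gap.  The calibration therefore runs in
#' that geometry: (i) simulate the full diffusion + enzyme kinetics at
#' fixed nucleosome number on a reduced lattice carrying the standard
#' triangular barrier; (ii) measure the steady-state distribution of
#' interior gaps (excluding the pair spanning the barrier); (iii) fit a
#' piecewise-linear attractive well `u(g) = -depth * (1 - (g - hc)/width)`
#' on `[hc, hc + width]` whose exact bounded-segment gap marginal
#' ([segment_gap_marginal()]) best matches the kinetic measurement.  A
#' control run at `k = 0` fixes the effective segment length, absorbing the
#' softness of the triangular barrier edges.  The defining contract is
#' steady-state equivalence between the absorption/desorption sampler under
#' `u_eff` and the full kinetics, which the test suite checks directly.
#' `k = 0` returns the bare hard-core potential.
#'
#' Results are cached per parameter set within the R session.
#'
#' @param k Spacer-enzyme remodeling rate in 1/s.
#' @param D Diffusion coefficient (bp^2/s).
#' @param enzyme_range_bp Enzyme capture distance (bp); the attraction
#'   vanishes beyond it.
#' @param footprint_bp Hard core (bp).
#' @param calib_L Reduced calibration lattice length (default 2940 bp, with
#'   the default barrier: 16 rods at density 0.88 of the accessible
#'   region — a 1/5-scale copy of the production system).
#' @param t_end,n_replicas Calibration simulation length (s) and replica
#'   count; the boundary-driven compaction converges within about half the
#'   default horizon.
#' @param seed Seed for the calibration runs.
#' @return A [pair_potential()] whose `attraction` table holds the fitted
#'   well, with attributes `fit` (depth, width, residual, effective segment
#'   length) and `gap_observed` (the empirical interior-gap histogram).
#' @export
effective_pair_potential <- function(k, D = 1, enzyme_range_bp = 332L,
                                     footprint_bp = 147L,
                                     calib_L = 2940L,
                                     t_end = 3e5, n_replicas = 2L,
                                     seed = 20201L) {
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(pair_potential(footprint_bp, NULL))
  key <- paste("ueff", k, D, enzyme_range_bp, footprint_bp, calib_L,
               t_end, n_replicas, seed, sep = "_")
  if (!is.null(.nucsim_cache[[key]])) return(.nucsim_cache[[key]])

  hc <- footprint_bp
  lat <- lattice_spec(calib_L, tss_index = 500L, footprint_bp = hc)
  field <- energy_field(lat, barrier = make_barrier(lat))
  M <- accessible_length(field)
  N <- as.integer(round(0.88 * M / hc))
  apex <- (lat$tss_index - 150L) %% calib_L

  interior_gaps <- function(d) {
    g <- circular_gaps(d, calib_L)
    if (length(g) < 2L) return(integer(0))
    dd <- sort(d); nxt <- c(dd[-1L], dd[1L] + calib_L)
    spans <- (dd < apex & nxt > apex) |
             (dd < apex + calib_L & nxt > apex + calib_L)
    g[!spans]
  }
  run_kinetics <- function(rate, horizon, sd) {
    model <- kinetic_model(field, D = D, enzyme_rate = rate,
                           enzyme_range_bp = enzyme_range_bp, r_const = 0)
    proto <- simulation_protocol(n_replicas = n_replicas, t_end = horizon,
                                 burn_in = horizon / 3, sample_interval = 200,
                                 initial_n = N, seed = sd)
    rec <- run_simulation(model, proto)
    unlist(lapply(rec$samples, interior_gaps))
  }

  # control: effective segment length from the k = 0 equilibrium
  gaps0 <- run_kinetics(0, t_end / 3, seed)
  mean0 <- mean(gaps0)
  cand <- (M - 20L):(M + 60L)
  merr <- vapply(cand, function(m) {
    gm <- segment_gap_marginal(N, m, pair_potential(hc))
    abs(sum(gm$gap * gm$p) - mean0)
  }, numeric(1))
  M_eff <- cand[which.min(merr)]

  gaps <- run_kinetics(k, t_end, seed + 1L)
  obs <- tabulate(gaps + 1L, nbins = M_eff + 1L)
  obs_cdf <- cumsum(obs / sum(obs))

  wmax <- enzyme_range_bp - hc
  objective <- function(par) {
    depth <- par[1]; width <- par[2]
    if (depth < 0 || width < 5 || width > wmax) return(1e6)
    att <- -depth * pmax(0, 1 - (0:ceiling(width)) / width)
    pred <- segment_gap_marginal(N, M_eff, pair_potential(hc, att))$p
    # Cramer-von-Mises-type distance between interior-gap CDFs
    sum((cumsum(pred) - obs_cdf)^2) / length(pred)
  }
  grid <- expand.grid(depth = seq(0.5, 8, by = 0.75),
                      width = seq(20, wmax, by = 25))
  vals <- apply(grid, 1L, objective)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, objective, method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-7))
  depth <- opt$par[1]; width <- opt$par[2]
  att <- -depth * pmax(0, 1 - (0:ceiling(width)) / width)
  out <- pair_potential(hc, att)
  attr(out, "fit") <- list(depth = depth, width = width,
                           residual = opt$value, k = k, M_eff = M_eff,
                           calib_N = N)
  attr(out, "gap_observed") <- obs / sum(obs)
  .nucsim_cache[[key]] <- out
  out
}

#' Accelerated equilibrium sampling by absorption/desorption kinetics
#'
#' Runs Gillespie dynamics restricted to histone absorption and desorption
#' (no diffusion, no explicit enzymes) at a high basal rate.  Because the
#' exchange rates satisfy detailed balance with respect to the model's
#' field, pair potential and chemical potential, the sampled steady state is
#' the corresponding (grand-canonical) equilibrium ensemble; using an
#' enzyme-renormalized pair attraction reproduces the steady state of the
#' full kinetics.  The two-dimensional moves avoid the jamming that slows
#' one-dimensional diffusion.
#'
#' @param model A [kinetic_model()]; its `D` and `enzyme_rate` are ignored
#'   (forced to zero), and `r_const` defaults to 12/s if the model has none.
#' @param protocol A [simulation_protocol()].
#' @return An `ensemble_record` (see [run_simulation()]).
#' @export
sample_equilibrium <- function(model, protocol) {
  r_const <- if (model$r_const > 0) model$r_const else 12
  m2 <- kinetic_model(model$field, model$pair, D = 0,
                      enzyme_rate = 0, enzyme_range_bp = model$enzyme_range_bp,
                      r_const = r_const, mu = model$mu)
  run_simulation(m2, protocol)
}

#' Accessible lattice length
#'
#' Lattice length minus the support of the promoter barrier (sites with a
#' strictly positive barrier), i.e. the stretch of DNA effectively available
#' for nucleosome formation.  The mean density target of the model refers to
#' this accessible stretch: with the default 25-kBT triangular barrier the
#' accessible length is 14401 bp, about 98 footprints, so a density of 0.88
#' corresponds to about 86 bound nucleosomes.
#' @param field An [energy_field()].
#' @return Accessible length in bp.
#' @export
accessible_length <- function(field) {
  field$lattice$length_bp - sum(field$barrier > 0)
}

#' Mean occupied density of an ensemble
#'
#' Fraction of the accessible lattice covered by nucleosome footprints,
#' averaged over samples.
#' @param record An `ensemble_record`.
#' @param accessible Accessible length in bp (default: from the model's
#'   field via [accessible_length()]).
#' @return Mean density (dimensionless fraction).
#' @export
mean_density <- function(record,
                         accessible = accessible_length(record$model$field)) {
  mean(lengths(record$samples)) * record$lattice$footprint_bp / accessible
}

#' Grand-canonical number distribution of the bounded-segment model
#'
#' Log-weights `log P(N) + const` for `N = 0..N_max` nucleosomes on a
#' segment of `M` admissible dyad sites with uniform per-nucleosome binding
#' energy `ebar`, nearest-neighbor pair potential `pair`, and chemical
#' potential `mu`:  `P(N) proportional to exp(-(ebar + mu) N) * V_N(M)`
#' where `V_N` counts (weights) the rod placements, computed exactly by
#' convolution.  This semi-analytic model guides the chemical-potential
#' calibration; the stochastic sampler has the final word.
#'
#' @param M Admissible dyad sites.
#' @param ebar Per-nucleosome binding energy in kBT (field contribution).
#' @param pair A [pair_potential()].
#' @param mu Chemical potential in kBT.
#' @param N_max Largest nucleosome number considered (default: capacity).
#' @return A data.frame with columns `N` and `logw` (unnormalized).
#' @export
segment_number_weights <- function(M, ebar, pair, mu, N_max = NULL) {
  hc <- pair$hard_core_bp
  if (is.null(N_max)) N_max <- (M + hc) %/% hc + 1L
  L <- M
  f <- exp(-pair_energy(pair, 0:L))
  P <- 2^ceiling(log2(2 * (L + 1L)))
  Ff <- stats::fft(c(f, numeric(P - L - 1L)))
  ramp <- 0:L + 1
  Fr <- stats::fft(c(ramp, numeric(P - L - 1L)))
  logV <- numeric(N_max + 1L)         # logV[N+1] = log V_N(M)
  logV[1L] <- 0                       # N = 0
  logV[2L] <- log(M)                  # N = 1: any dyad
  cc <- { z <- numeric(L + 1L); z[1L] <- 1; z }  # C_0 = delta
  logscale <- 0
  for (N in 2:N_max) {
    # C_{N-1} = C_{N-2} * f
    Fc <- stats::fft(c(cc, numeric(P - length(cc))))
    cc <- Re(stats::fft(Fc * Ff, inverse = TRUE)) / P
    cc <- cc[seq_len(L + 1L)]
    cc[cc < 0] <- 0
    # exact support: N - 1 gaps of at least hc each; zero the FFT residue
    supp0 <- hc * (N - 1L)
    if (supp0 >= length(cc)) { logV[(N + 1L):(N_max + 1L)] <- -Inf; break }
    if (supp0 > 0L) cc[seq_len(supp0)] <- 0
    mx <- max(cc)
    if (mx <= 0) { logV[(N + 1L):(N_max + 1L)] <- -Inf; break }
    cc <- cc / mx
    logscale <- logscale + log(mx)
    Fc2 <- stats::fft(c(cc, numeric(P - length(cc))))
    W <- Re(stats::fft(Fc2 * Fr, inverse = TRUE)) / P
    v <- if (M >= 1L && M <= length(W)) max(W[M], 0) else 0
    logV[N + 1L] <- if (v > 0) logscale + log(v) else -Inf
  }
  NN <- 0:N_max
  data.frame(N = NN, logw = logV - (ebar + mu) * NN)
}

#' Calibrate the chemical potential to a target density
#'
#' Finds `mu` such that the steady-state mean density (occupied fraction of
#' the accessible lattice) of the absorption/desorption sampler matches
#' `target_density`.  A semi-analytic bounded-segment model
#' ([segment_number_weights()]) supplies the starting value and the local
#' slope `d<N>/dmu = -Var(N)`; short sampler runs then refine `mu`
#' stochastically (Newton steps against the analytic slope).  Every iterate
#' is logged.
#'
#' @param model A [kinetic_model()] (its `mu` is ignored).
#' @param target_density Target occupied fraction in (0, 1) (default 0.88).
#' @param tolerance Acceptable |density - target| (default 0.01,
#'   about one nucleosome on the 14.7-kb lattice).
#' @param t_iter,n_replicas_iter Length (s) and replica count of each
#'   refinement run.
#' @param max_iter Maximum refinement runs before failing.
#' @param seed Seed for the refinement runs.
#' @return The calibrated `mu` (numeric scalar) with attribute `trace`, a
#'   data.frame logging every (mu, density) iterate (the analytic start has
#'   `density = NA`).
#' @export
calibrate_mu <- function(model, target_density = 0.88, tolerance = 0.01,
                         t_iter = 2000, n_replicas_iter = 2L,
                         max_iter = 8L, seed = 4242L) {
  if (target_density <= 0 || target_density >= 1)
    stop("target density at boundary: need 0 < target_density < 1 ",
         "(mu diverges at the boundaries)")
  fp <- model$lattice$footprint_bp
  acc <- accessible_length(model$field)
  n_target <- target_density * acc / fp
  cap <- model$lattice$length_bp %/% fp
  if (n_target > cap) stop("target density exceeds lattice capacity")

  # semi-analytic guidance: segment model with edge allowance
  M_eff <- acc + 5L
  free <- model$field$barrier == 0
  ebar <- mean(model$field$dyad_energy[free])
  mean_var_N <- function(mu) {
    w <- segment_number_weights(M_eff, ebar, model$pair, mu)
    lw <- w$logw - max(w$logw)
    p <- exp(lw) / sum(exp(lw))
    m <- sum(p * w$N)
    c(mean = m, var = sum(p * (w$N - m)^2))
  }
  f_root <- function(mu) mean_var_N(mu)["mean"] - n_target
  lo <- -abs(ebar) - 80; hi <- abs(ebar) + 80
  mu0 <- stats::uniroot(f_root, c(lo, hi), tol = 1e-3)$root

  trace <- data.frame(mu = mu0, density = NA_real_)
  measure <- function(mu, it) {
    m <- kinetic_model(model$field, model$pair, D = 0, enzyme_rate = 0,
                       enzyme_range_bp = model$enzyme_range_bp,
                       r_const = if (model$r_const > 0) model$r_const else 12,
                       mu = mu)
    p <- simulation_protocol(n_replicas = n_replicas_iter, t_end = t_iter,
                             burn_in = t_iter / 3, sample_interval = 5,
                             initial_n = as.integer(round(n_target)),
                             seed = seed + it)
    mean_density(run_simulation(m, p), accessible = acc)
  }
  mu <- mu0
  for (it in seq_len(max_iter)) {
    d <- measure(mu, it)
    trace[nrow(trace) + 1L, ] <- c(mu, d)
    if (abs(d - target_density) <= tolerance)
      return(structure(mu, trace = trace))
    slope_N <- -mean_var_N(mu)["var"]          # d<N>/dmu
    slope_d <- slope_N * fp / acc              # d(density)/dmu
    step <- (target_density - d) / slope_d
    mu <- mu + max(min(step, 3), -3)
  }
  e <- simpleError(sprintf(
    "mu calibration did not reach |density - %.3f| <= %.3f in %d runs (last density %.4f)",
    target_density, tolerance, max_iter,
    trace$density[nrow(trace)]))
  e$trace <- trace
  stop(e)
}

#' Exhaustive enumeration of small-lattice configurations
#'
#' Enumerates every valid configuration with up to `max_n` nucleosomes on a
#' small ring and returns Boltzmann log-weights `-(U + mu * N)`.  This is the
#' exact partition-sum oracle used to validate the samplers; it refuses
#' state spaces above `limit` configurations.
#'
#' @param field An [energy_field()] on a small lattice.
#' @param pair A [pair_potential()].
#' @param mu Chemical potential in kBT (set 0 and filter on `n` for
#'   canonical use).
#' @param max_n Largest nucleosome number to enumerate (<= 3).
#' @param limit Refuse enumerations above this many states.
#' @return A data.frame with columns `n`, `key` (dyads joined by ","), and
#'   `log_weight`.
#' @export
enumerate_reference <- function(field, pair, mu = 0, max_n = 3L,
                                limit = 2e6) {
  lat <- field$lattice
  L <- lat$length_bp
  hc <- pair$hard_core_bp
  if (max_n > 3L) stop("enumeration supports at most 3 nucleosomes")
  Ed <- field$dyad_energy
  u <- function(g) pair_energy(pair, g)
  out <- list(data.frame(n = 0L, key = "", log_weight = 0))
  if (max_n >= 1L && L >= hc) {
    x <- 0:(L - 1L)
    out[[length(out) + 1L]] <-
      data.frame(n = 1L, key = as.character(x), log_weight = -(Ed[x + 1L] + mu))
  }
  if (max_n >= 2L && L >= 2L * hc) {
    # build pairs x1 < x2 with both circular gaps >= hc
    lo <- (0:(L - 2L)) + hc
    hi <- pmin(L - 1L, (0:(L - 2L)) + L - hc)
    keep <- hi >= lo
    x1 <- rep((0:(L - 2L))[keep], times = (hi - lo + 1L)[keep])
    x2 <- unlist(lapply(which(keep) - 1L, function(a) (a + hc):min(L - 1L, a + L - hc)))
    if (length(x1) > limit) stop("state space too large to enumerate")
    g1 <- x2 - x1; g2 <- L - g1
    lw <- -(Ed[x1 + 1L] + Ed[x2 + 1L] + u(g1) + u(g2) + 2 * mu)
    out[[length(out) + 1L]] <-
      data.frame(n = 2L, key = paste(x1, x2, sep = ","), log_weight = lw)
  }
  if (max_n >= 3L && L >= 3L * hc) {
    gmax <- L - 2L * hc
    gg <- expand.grid(g1 = hc:gmax, g2 = hc:gmax)
    gg <- gg[gg$g1 + gg$g2 <= L - hc, , drop = FALSE]
    if (nrow(gg) * L > limit) stop("state space too large to enumerate")
    res <- lapply(seq_len(nrow(gg)), function(i) {
      g1 <- gg$g1[i]; g2 <- gg$g2[i]; g3 <- L - g1 - g2
      x1 <- 0:(L - 1L)
      x2 <- (x1 + g1) %% L
      x3 <- (x1 + g1 + g2) %% L
      keep <- x1 < x2 & x2 < x3  # canonical sorted representative
      if (!any(keep)) return(NULL)
      x1 <- x1[keep]; x2 <- x2[keep]; x3 <- x3[keep]
      lw <- -(Ed[x1 + 1L] + Ed[x2 + 1L] + Ed[x3 + 1L] +
                u(g1) + u(g2) + u(g3) + 3 * mu)
      data.frame(n = 3L, key = paste(x1, x2, x3, sep = ","), log_weight = lw)
    })
    out <- c(out, res[!vapply(res, is.null, logical(1))])
  }
  do.call(rbind, out)
}
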