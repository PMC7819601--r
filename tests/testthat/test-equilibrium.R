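test_that("ring gap marginal matches brute-force enumeration", {
  # two hard rods on a ring: every admissible gap pair is equally likely,
  # so the designated-gap marginal is uniform on [hc, L - hc]
  L <- 441L
  gm <- ring_gap_marginal(2L, L, pair_potential(147L))
  inside <- gm$gap >= 147 & gm$gap <= L - 147
  expect_true(all(gm$p[!inside] == 0))
  expect_equal(diff(range(gm$p[inside])), 0, tolerance = 1e-12)
  expect_equal(sum(gm$p), 1)
  expect_equal(sum(gm$gap * gm$p), L / 2)  # symmetry
  # with attraction: weights follow exp(-u(g)-u(L-g)) exactly
  att <- c(-2, -1, -0.5, rep(0, 4))
  pp <- pair_potential(147L, att)
  gm2 <- ring_gap_marginal(2L, L, pp)
  g <- 147:(L - 147)
  w <- exp(-pair_energy(pp, g) - pair_energy(pp, L - g))
  expect_equal(gm2$p[gm2$gap %in% g], w / sum(w), tolerance = 1e-10)
  # three rods: mean designated gap is L/N by symmetry
  gm3 <- ring_gap_marginal(3L, 588L, pair_potential(147L))
  expect_equal(sum(gm3$gap * gm3$p), 196, tolerance = 1e-6)
})

test_that("segment placement weights match brute-force counting", {
  brute2 <- function(M, hc) sum(pmax(0, (M - 1) - (0:(M - 1) + hc) + 1))
  brute3 <- function(M, hc) {
    cnt <- 0
    for (x1 in 0:(M - 1)) {
      if (x1 + hc > M - 1) next
      for (x2 in (x1 + hc):(M - 1))
        if (x2 + hc <= M - 1) cnt <- cnt + (M - 1) - (x2 + hc) + 1
    }
    cnt
  }
  M <- 500L
  w <- segment_number_weights(M, 0, pair_potential(147L), 0, N_max = 5L)
  expect_equal(w$logw[2], log(M))
  expect_equal(w$logw[3], log(brute2(M, 147L)), tolerance = 1e-9)
  expect_equal(w$logw[4], log(brute3(M, 147L)), tolerance = 1e-9)
  # capacity: 5 rods need a 589-site span, impossible on 500 sites
  expect_equal(w$logw[6], -Inf)
})

test_that("zero enzyme rate returns the bare hard-core potential", {
  pp <- effective_pair_potential(0)
  expect_null(pp$attraction)
  expect_equal(pair_energy(pp, 146L), Inf)
  expect_equal(pair_energy(pp, 200L), 0)
})

test_that("grand-canonical sampler matches exact enumeration on a small lattice", {
  lat <- lattice_spec(441L, tss_index = 0L)
  field <- two_well_field(lat, list(list(at = 80L, depth = -12),
                                    list(at = 81L, depth = -11.5),
                                    list(at = 300L, depth = -12.3),
                                    list(at = 301L, depth = -11.8)),
                          site_energy = 5 / 147)
  ref <- enumerate_reference(field, pair_potential(147L), mu = 0, max_n = 3L)
  p_ref <- ref_probs(ref)
  m <- kinetic_model(field, D = 0, r_const = 12, mu = 0)
  p <- simulation_protocol(n_replicas = 4L, t_end = 5200, burn_in = 200,
                           sample_interval = 1, initial_n = 0L, seed = 7L)
  rec <- run_simulation(m, p)
  p_emp <- state_probs(rec, ref)
  expect_lt(tv_distance(p_emp, p_ref), 0.02)
  # number statistics agree too
  expect_equal(mean(lengths(rec$samples)), sum(p_ref * ref$n), tolerance = 0.02)
})

test_that("mu calibration hits an exactly enumerable density", {
  # small lattice, weak uniform binding: exact enumeration provides the
  # density at the calibrated mu, which must sit within tolerance of target
  lat <- lattice_spec(441L, tss_index = 0L)
  field <- energy_field(lat, site_energy = -10 / 147)
  m <- kinetic_model(field, D = 0, r_const = 12)
  mu <- calibrate_mu(m, target_density = 0.5, tolerance = 0.04,
                     t_iter = 1500, seed = 21L)
  ref <- enumerate_reference(field, pair_potential(147L), mu = as.numeric(mu),
                             max_n = 3L)
  p_ref <- ref_probs(ref)
  dens_exact <- sum(p_ref * ref$n) * 147 / 441
  expect_equal(dens_exact, 0.5, tolerance = 0.06)
  expect_true(is.data.frame(attr(mu, "trace")))
  expect_error(calibrate_mu(m, target_density = 0), "boundary")
  expect_error(calibrate_mu(m, target_density = 1), "boundary")
})

test_that("a uniform field without barrier or enzymes gives a flat profile", {
  lat <- lattice_spec(2940L, tss_index = 500L)
  field <- energy_field(lat)
  m <- kinetic_model(field, D = 0, r_const = 12, mu = 37.9)  # near 0.85 coverage
  p <- simulation_protocol(n_replicas = 2L, t_end = 4500, burn_in = 500,
                           sample_interval = 2, initial_n = 16L, seed = 61L)
  rec <- run_simulation(m, p)
  pr <- smooth_profile(density_profile(rec, window = c(-400, 1400)), 10)
  expect_equal(mean(pr$density), 1, tolerance = 0.03)
  # flat within bin-counting noise; structured profiles sit at sd 0.4-0.6
  expect_lt(stats::sd(pr$density), 0.1)
})

test_that("phase diagram scans classify per point and capture per-point errors", {
  lat <- lattice_spec(2940L, tss_index = 500L)
  proto <- simulation_protocol(n_replicas = 2L, t_end = 1200, burn_in = 400,
                               sample_interval = 2, initial_n = 16L, seed = 71L)
  # without enzymes no point can be mouse-like: statistical positioning only
  pd <- phase_diagram(depths = c(0, -2), rates = 0, lattice = lat,
                      protocol = proto)
  expect_equal(nrow(pd), 2L)
  expect_true(all(pd$label %in% c("yeast_like", "boundary")))
  # an infeasible protocol is recorded per point, not propagated
  bad <- simulation_protocol(n_replicas = 1L, t_end = 100, burn_in = 10,
                             sample_interval = 2, initial_n = 30L, seed = 72L)
  pd2 <- phase_diagram(depths = 0, rates = 0, lattice = lat, protocol = bad)
  expect_true(is.na(pd2$label))
  expect_match(pd2$note, "capacity")
})

test_that("effective attraction deepens with enzyme rate and certifies its fit", {
  pp08 <- effective_pair_potential(0.08)
  pp16 <- effective_pair_potential(0.16)
  expect_lt(attr(pp16, "fit")$residual, 1e-4)
  expect_lt(attr(pp08, "fit")$residual, 1e-4)
  # stronger remodeling means a more attractive contact region
  u16 <- pair_energy(pp16, 148:200)
  u08 <- pair_energy(pp08, 148:200)
  expect_lt(mean(u16), mean(u08))
  expect_lt(mean(u08), 0)
  # attraction vanishes beyond the enzyme capture range
  expect_equal(pair_energy(pp16, 333L), 0)
  expect_equal(pair_energy(pp08, 333L), 0)
})
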