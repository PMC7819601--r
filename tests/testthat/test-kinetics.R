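test_that("diffusion and exchange rate formulas obey their identities", {
  expect_equal(diffusion_rate(0), 1)
  expect_equal(diffusion_rate(Inf), 0)
  expect_equal(diffusion_rate(2 * log(2)), 0.5)
  ex <- exchange_rates(0, 0, 0.1)
  expect_equal(ex$r_on, 0.1); expect_equal(ex$r_off, 0.1)
  ex2 <- exchange_rates(2 * log(10), 0, 12)
  expect_equal(ex2$r_on, 1.2); expect_equal(ex2$r_off, 120)
  expect_error(exchange_rates(0, 0, -1), "r_const")
})

test_that("detailed-balance ratios hold to machine precision on random input", {
  set.seed(1)
  dU <- stats::rnorm(1000, 0, 6)
  mu <- stats::rnorm(1000, 0, 10)
  ex <- exchange_rates(dU, mu, r_const = 0.37)
  expect_equal(ex$r_on / ex$r_off, exp(-(dU + mu)), tolerance = 1e-12)
  expect_equal(ex$r_on * ex$r_off, rep(0.37^2, 1000), tolerance = 1e-12)
  expect_equal(diffusion_rate(dU) / diffusion_rate(-dU), exp(-dU),
               tolerance = 1e-12)
})

test_that("event enumeration matches the documented event set", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  # single nucleosome, diffusion only: exactly two unit-rate hops
  m <- kinetic_model(f, D = 1)
  ev <- enumerate_events(nucleosome_config(100L, lat), m)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(unique(as.character(ev$type))), c("hop_left", "hop_right"))
  expect_equal(ev$rate, c(1, 1))
  # gap exactly 147: inward hops blocked, enzyme pair ineligible
  m2 <- kinetic_model(f, D = 1, enzyme_rate = 0.16)
  ev2 <- enumerate_events(nucleosome_config(c(100L, 247L), lat), m2)
  # the 147 gap is at contact (no feasible inward move) and the 441 wrap gap
  # exceeds the capture range: no enzyme event at all
  expect_equal(sum(ev2$type == "enzyme"), 0L)
  blocked <- ev2$rate[(ev2$type == "hop_right" & ev2$id == 1) |
                      (ev2$type == "hop_left" & ev2$id == 2)]
  expect_equal(blocked, c(0, 0))
  # gap 200 within range: exactly one enzyme event at the bound rate
  ev3 <- enumerate_events(nucleosome_config(c(100L, 300L), lat), m2)
  enz <- ev3[ev3$type == "enzyme", ]
  expect_equal(nrow(enz), 1L)
  expect_equal(enz$rate, 0.16)
})

test_that("engine incremental state equals from-scratch enumeration after many events", {
  set.seed(11)
  lat <- tiny_lattice()
  site <- stats::runif(lat$length_bp, -0.4, -0.1)
  field <- energy_field(lat, site_energy = site,
                        barrier = make_barrier(lat, height = 5),
                        positioning = make_positioning(lat, depth = -1))
  pp <- pair_potential(147L, attraction = -1 * pmax(0, 1 - (0:100) / 80))
  model <- kinetic_model(field, pp, D = 1, enzyme_rate = 0.2,
                         r_const = 0.5, mu = -40)
  for (trial in 1:3) {
    init <- random_initial_configuration(2L, lat)
    res <- nucsim:::cpp_engine_rates(
      lat$length_bp, field$dyad_energy, 147L, pp$attraction,
      1, 0.2, 332L, 0.5, -40, init$dyads, 400, 1000 + trial)
    cfg <- nucleosome_config(res$final, lat)
    ev <- enumerate_events(cfg, model)
    r <- res$rates
    expect_equal(r$hop_left, ev$rate[ev$type == "hop_left"], tolerance = 1e-12)
    expect_equal(r$hop_right, ev$rate[ev$type == "hop_right"], tolerance = 1e-12)
    expect_equal(r$remove, ev$rate[ev$type == "remove"], tolerance = 1e-12)
    ins_ref <- numeric(lat$length_bp)
    ins_ref[ev$id[ev$type == "insert"] + 1L] <- ev$rate[ev$type == "insert"]
    expect_equal(r$insert, ins_ref, tolerance = 1e-12)
    enz_ref <- numeric(length(cfg$dyads))
    enz_ref[ev$id[ev$type == "enzyme"]] <- ev$rate[ev$type == "enzyme"]
    expect_equal(r$enzyme, enz_ref, tolerance = 1e-12)
  }
})

test_that("simulation runs are reproducible and respect protocol contracts", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  m <- kinetic_model(f, D = 1, r_const = 0.2, mu = 40)
  p <- simulation_protocol(n_replicas = 2L, t_end = 200, burn_in = 50,
                           sample_interval = 10, initial_n = 2L, seed = 5L)
  r1 <- run_simulation(m, p)
  r2 <- run_simulation(m, p)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$time, r2$time)
  expect_true(all(r1$time > p$burn_in & r1$time <= p$t_end))
  # every sampled configuration honors exclusion
  for (d in r1$samples)
    expect_silent(nucleosome_config(d, lat))
  expect_error(run_simulation(m, simulation_protocol(initial_n = 10L, t_end = 10,
                                                     burn_in = 1, seed = 1L)),
               "capacity")
})

test_that("a fully frozen model is an absorbing state", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  m <- kinetic_model(f, D = 0, enzyme_rate = 0, r_const = 0)
  p <- simulation_protocol(n_replicas = 1L, t_end = 100, burn_in = 10,
                           sample_interval = 10, initial_n = 3L, seed = 8L)
  rec <- run_simulation(m, p)
  expect_true(all(vapply(rec$samples, identical, logical(1), rec$samples[[1]])))
})

test_that("random initial configurations are valid and capacity-checked", {
  lat <- lattice_spec(14700L, tss_index = 0L)
  set.seed(3)
  expect_length(random_initial_configuration(0L, lat)$dyads, 0L)
  crystal <- random_initial_configuration(100L, lat)  # saturation: all gaps 147
  expect_equal(unique(circular_gaps(crystal$dyads, 14700L)), 147L)
  cfg <- random_initial_configuration(86L, lat)
  expect_true(min(circular_gaps(cfg$dyads, 14700L)) >= 147L)
  expect_error(random_initial_configuration(101L, lat), "capacity")
})

test_that("gillespie_step draws exponential times and rate-weighted events", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  # single-nucleosome system: two hops with equal unit rates, total rate 2
  m <- kinetic_model(f, D = 1)
  cfg <- nucleosome_config(100L, lat)
  set.seed(9)
  dts <- replicate(3000, gillespie_step(cfg, m)$dt)
  expect_equal(mean(dts), 0.5, tolerance = 3 * 0.5 / sqrt(3000))
  # biased field: uphill/downhill hop selection frequencies follow the rates
  pos <- numeric(lat$length_bp); pos[101:588] <- -2  # step at the dyad
  f2 <- energy_field(lat, positioning = pos - 2)
  m2 <- kinetic_model(f2, D = 1)
  cfg2 <- nucleosome_config(100L, lat)
  ev <- enumerate_events(cfg2, m2)
  pr <- ev$rate / sum(ev$rate)
  set.seed(10)
  picks <- replicate(2000, gillespie_step(cfg2, m2)$event$type)
  p_right <- mean(picks == "hop_right")
  expect_equal(p_right, pr[ev$type == "hop_right"],
               tolerance = 3 * sqrt(0.25 / 2000) + 0.02)
})

test_that("insertion/removal occupancy odds match the closed-form ratio", {
  # a 147-bp ring holds at most one nucleosome: two-state birth-death chain
  # with P(occupied)/P(empty) = sum_s exp(-(E + mu)) = L * exp(-(E + mu))
  lat <- lattice_spec(147L, tss_index = 0L)
  f <- energy_field(lat, site_energy = -2 / 147)
  mu <- 2 + log(3 * 147)   # occupied:empty odds exactly 1:3
  m <- kinetic_model(f, D = 0, r_const = 5, mu = mu)
  p <- simulation_protocol(n_replicas = 4L, t_end = 3000, burn_in = 100,
                           sample_interval = 1, initial_n = 0L, seed = 12L)
  rec <- run_simulation(m, p)
  occ <- mean(lengths(rec$samples) == 1L)
  expect_equal(occ / (1 - occ), 1 / 3, tolerance = 0.08)
})
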