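test_that("lattice and configuration invariants are enforced", {
  lat <- lattice_spec(14700L, tss_index = 2000L)
  expect_equal(lat$length_bp, 14700L)
  expect_equal(lat$footprint_bp, 147L)
  expect_error(lattice_spec(100L), "length_bp")
  expect_error(lattice_spec(500L, tss_index = 500L), "tss_index")

  sm <- tiny_lattice()
  expect_silent(nucleosome_config(c(0L, 147L, 294L), sm))
  expect_error(nucleosome_config(c(0L, 146L), sm), "exclusion")
  expect_error(nucleosome_config(c(0L, 460L), sm), "exclusion")  # wrap gap 128
  expect_error(nucleosome_config(c(10L, 10L), sm), "duplicated")
  expect_equal(circular_gaps(c(0L, 200L, 400L), 588L), c(200L, 200L, 188L))
  expect_identical(circular_gaps(5L, 588L), integer(0))
})

test_that("triangular barrier has the documented geometry", {
  lat <- lattice_spec(14700L, tss_index = 2000L)
  b <- make_barrier(lat, center_offset = -150, half_width = 150, height = 25)
  at <- function(off) b[(lat$tss_index + off) %% lat$length_bp + 1L]
  expect_equal(at(-150), 25)          # apex height for active genes
  expect_equal(at(0), 0)              # triangle edge at the TSS
  expect_equal(at(-300), 0)           # triangle edge upstream
  expect_equal(at(-75), 12.5)         # linear flank, midpoint
  expect_equal(at(-225), 12.5)        # symmetric about the apex
  expect_equal(at(500), 0)
  expect_true(all(b >= 0))
  expect_error(make_barrier(lat, height = -1), "height")
})

test_that("positioning well is a flat bounded region", {
  lat <- lattice_spec(14700L, tss_index = 2000L)
  w <- make_positioning(lat, 0, 30, -2)
  at <- function(off) w[(lat$tss_index + off) %% lat$length_bp + 1L]
  expect_equal(at(15), -2)
  expect_equal(at(0), -2)
  expect_equal(at(30), -2)
  expect_equal(at(31), 0)
  expect_equal(at(-1), 0)
  expect_true(all(make_positioning(lat, 0, 30, 0) == 0))
  expect_error(make_positioning(lat, 0, 30, 1), "depth")
  expect_error(make_positioning(lat, 30, 0, -1), "start_offset")
})

test_that("nucleosome energy sums the footprint plus dyad potentials", {
  lat <- lattice_spec(14700L, tss_index = 2000L)
  f0 <- energy_field(lat)  # uniform -42/147 per bp
  expect_equal(nucleosome_energy(5000L, f0), -42)
  fb <- energy_field(lat, barrier = make_barrier(lat))
  expect_equal(nucleosome_energy((lat$tss_index - 150L) %% 14700L, fb), -17)
  fw <- energy_field(lat, positioning = make_positioning(lat))
  expect_equal(nucleosome_energy((lat$tss_index + 15L) %% 14700L, fw), -44)
  # explicit footprint sum oracle at a wrap-around dyad
  site <- stats::runif(14700, -0.5, -0.1)
  fr <- energy_field(lat, site_energy = site)
  dy <- 3L  # footprint wraps around the origin
  idx <- ((dy - 73L):(dy + 73L)) %% 14700L + 1L
  expect_equal(nucleosome_energy(dy, fr), sum(site[idx]))
})

test_that("total energy is additive with hard-core pair terms", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  pp <- pair_potential(147L)
  expect_equal(total_energy(nucleosome_config(integer(0), lat), f, pp), 0)
  expect_equal(total_energy(nucleosome_config(100L, lat), f, pp), -42)
  expect_equal(total_energy(nucleosome_config(c(100L, 247L), lat), f, pp), -84)
  expect_error(total_energy(list(dyads = c(0L, 10L), lattice = lat), f, pp))
  # pair attraction enters once per circular pair
  ppa <- pair_potential(147L, attraction = c(-1.5, rep(0, 10)))
  expect_equal(total_energy(nucleosome_config(c(100L, 247L), lat), f, ppa),
               -84 - 1.5)  # one gap at contact (147), the wrap gap is 441
})

test_that("delta_energy agrees with total-energy differences on random moves", {
  set.seed(42)
  lat <- tiny_lattice()
  site <- stats::runif(lat$length_bp, -0.4, -0.1)
  field <- energy_field(lat, site_energy = site,
                        barrier = make_barrier(lat, height = 4),
                        positioning = make_positioning(lat, depth = -1.5))
  pp <- pair_potential(147L, attraction = -0.8 * pmax(0, 1 - (0:120) / 100))
  n_checked <- 0L
  for (i in 1:1000) {
    n <- sample(0:3, 1)
    cfg <- random_initial_configuration(n, lat)
    mv <- if (n == 0L || stats::runif(1) < 0.3) {
      list(type = "insert", dyad = sample(0:(lat$length_bp - 1L), 1))
    } else if (stats::runif(1) < 0.5) {
      list(type = "hop", index = sample(n, 1), dir = sample(c(-1L, 1L), 1))
    } else {
      list(type = "remove", index = sample(n, 1))
    }
    dU <- delta_energy(cfg, mv, field, pp)
    if (is.finite(dU)) {
      dU_global <- total_energy(apply_move(cfg, mv), field, pp) -
        total_energy(cfg, field, pp)
      expect_lt(abs(dU - dU_global), 1e-9)
      n_checked <- n_checked + 1L
    } else {
      expect_true(dU == Inf)
    }
  }
  expect_gt(n_checked, 500L)
})

test_that("hops blocked by exclusion have infinite energy cost", {
  lat <- tiny_lattice()
  f <- energy_field(lat)
  cfg <- nucleosome_config(c(100L, 247L), lat)  # gap exactly 147
  expect_equal(delta_energy(cfg, list(type = "hop", index = 1L, dir = 1L), f), Inf)
  expect_equal(delta_energy(cfg, list(type = "hop", index = 2L, dir = -1L), f), Inf)
  # both outward hops are free on a uniform field with big outer gap
  expect_equal(delta_energy(cfg, list(type = "hop", index = 1L, dir = -1L), f), 0)
  # insertion equals single-nucleosome energy when isolated
  cfg1 <- nucleosome_config(100L, lat)
  expect_equal(delta_energy(cfg1, list(type = "insert", dyad = 350L), f), -42)
})

test_that("energies are invariant under joint translation (periodic wrap)", {
  lat <- tiny_lattice()
  set.seed(7)
  site <- stats::runif(lat$length_bp, -0.5, 0)
  pp <- pair_potential(147L, attraction = c(-1, -0.5, rep(0, 5)))
  cfg0 <- c(30L, 200L, 400L)
  for (shift in c(1L, 97L, 400L)) {
    f1 <- energy_field(lat, site_energy = site)
    f2 <- energy_field(lat, site_energy = site[(seq_len(lat$length_bp) - 1L - shift) %% lat$length_bp + 1L])
    e1 <- total_energy(nucleosome_config(cfg0, lat), f1, pp)
    e2 <- total_energy(nucleosome_config((cfg0 + shift) %% lat$length_bp, lat), f2, pp)
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})
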