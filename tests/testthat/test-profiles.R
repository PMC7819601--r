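# a hand-built ensemble_record for analysis tests
fake_record <- function(samples, lattice) {
  structure(list(samples = samples,
                 replica = rep(1L, length(samples)),
                 time = seq_along(samples),
                 lattice = lattice, model = NULL, protocol = NULL,
                 fingerprint = list()),
            class = "ensemble_record")
}

# a density_profile carrying an arbitrary curve
fake_profile <- function(offset, density) {
  structure(list(offset = offset, density = density, n_samples = 1L,
                 bin = 1, window = range(offset), smoothing = NULL),
            class = "density_profile")
}

test_that("density profile counts, anchors and normalizes correctly", {
  lat <- lattice_spec(2000L, tss_index = 500L)
  rec <- fake_record(list(600L), lat)  # one dyad at TSS+100
  pr <- density_profile(rec, window = c(-200, 400), bin = 1)
  expect_equal(pr$offset[pr$density > 0], 100)
  # normalization: lattice-wide mean density is 1/2000 per bp, one count in
  # the bin over one sample gives 1 / (1/2000) = 2000
  expect_equal(max(pr$density), 2000)
  expect_error(density_profile(fake_record(list(), lat)), "empty")
  # uniform ensemble is flat at 1 within sampling error
  set.seed(2)
  lat2 <- lattice_spec(5880L, tss_index = 1000L)
  samples <- replicate(400, random_initial_configuration(20L, lat2)$dyads,
                       simplify = FALSE)
  pru <- density_profile(fake_record(samples, lat2), window = c(-500, 500))
  expect_equal(mean(pru$density), 1, tolerance = 0.05)
})

test_that("smoothing is identity-like, constant-preserving and attenuates as the kernel dictates", {
  off <- 0:999
  const <- fake_profile(off, rep(2.5, 1000))
  sm <- smooth_profile(const, bandwidth = 10)
  expect_equal(sm$density, const$density, tolerance = 1e-12)
  expect_equal(sm$raw, const$density)
  # near-zero bandwidth box kernel: identity
  x <- fake_profile(off, stats::runif(1000, 0.5, 1.5))
  sm0 <- smooth_profile(x, bandwidth = 0.4, kernel = "box")
  expect_equal(sm0$density, x$density, tolerance = 1e-12)
  # cosine attenuation equals the kernel transfer value (independent oracle:
  # direct sum over the discrete kernel weights)
  period <- 165
  wave <- fake_profile(off, 1 + 0.5 * cos(2 * pi * off / period))
  smw <- smooth_profile(wave, bandwidth = 10, kernel = "gaussian")
  k <- nucsim:::smoothing_kernel(10, "gaussian", 1)
  half <- (length(k) - 1) / 2
  transfer <- sum(k * cos(2 * pi * (-half:half) / period))
  mid <- 300:700
  amp_ratio <- (max(smw$density[mid]) - 1) / 0.5
  expect_equal(amp_ratio, transfer, tolerance = 0.01)
  # mass preservation away from edges (whole number of periods)
  per <- 300:(300 + 2 * period - 1)
  expect_equal(mean(smw$density[per]), mean(wave$density[per]), tolerance = 1e-3)
  expect_error(smooth_profile(fake_profile(0:49, rep(1, 50)), bandwidth = 100),
               "window")
})

test_that("radial distribution vanishes below the hard core and spikes for crystals", {
  lat <- lattice_spec(1470L, tss_index = 0L)
  crystal <- nucleosome_config(seq(0L, 1323L, by = 147L), lat)  # 10 rods, all gaps 147
  rec <- fake_record(replicate(5, crystal$dyads, simplify = FALSE), lat)
  rdf <- radial_distribution(rec, r_max = 500)
  expect_true(all(rdf$g[rdf$r < 147] == 0))
  expect_gt(rdf$g[147], 10)                       # contact spike
  expect_equal(rdf$g[c(200, 250)], c(0, 0))       # nothing between shells
  expect_gt(rdf$g[294], 10)                       # second shell
  expect_error(radial_distribution(fake_record(list(5L), lat)), "2 nucleosomes")
})

test_that("mean spacing uses the first downstream peaks", {
  off <- -200:1000
  dens <- rep(1, length(off))
  for (p in c(150, 315, 480, 645, 810)) dens[off == p] <- 2
  pr <- fake_profile(off, dens)
  expect_equal(mean_spacing(pr, n_peaks = 5), 165)
  # cosine of period 160 on a positive baseline: peaks exactly 160 apart
  pr2 <- fake_profile(off, 1 + 0.3 * cos(2 * pi * (off - 20) / 160))
  expect_equal(mean_spacing(pr2, n_peaks = 5), 160, tolerance = 1e-6)
  flat <- fake_profile(off, rep(1, length(off)))
  expect_error(mean_spacing(flat), "insufficient peaks")
})

test_that("profile classification follows the two-peak rule", {
  off <- -100:800
  mk <- function(h1, h2) {
    d <- rep(1, length(off))
    d <- d + h1 * exp(-(off - 150)^2 / 200) + h2 * exp(-(off - 320)^2 / 200)
    fake_profile(off, d)
  }
  expect_equal(classify_profile(mk(0.5, 0.2)), "yeast_like")
  expect_equal(classify_profile(mk(0.2, 0.5)), "mouse_like")
  expect_equal(classify_profile(mk(0.3, 0.3)), "boundary")
  expect_error(classify_profile(fake_profile(off, rep(1, length(off)))),
               "unclassifiable")
})

test_that("peak detection respects prominence and separation rules", {
  off <- 0:600
  d <- 1 + 0.5 * exp(-(off - 100)^2 / 100) + 0.012 * exp(-(off - 300)^2 / 100) +
    0.45 * exp(-(off - 160)^2 / 100)
  pk <- find_peaks(fake_profile(off, d), min_prominence_frac = 0.05,
                   min_separation = 100)
  # the 300 bump is below prominence, the 160 peak is within 100 bp of a
  # higher peak: only the 100 peak survives
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$offset, 100, tolerance = 2)
})

test_that("ordered heatmap sorts by +1 position into comparable rows", {
  lat <- lattice_spec(2940L, tss_index = 500L)
  mk <- function(p1) nucleosome_config(((p1 + 500) %% 2940) + c(0L, 200L, 400L), lat)$dyads
  set.seed(4)
  p1s <- sample(seq(10L, 300L, by = 10L))
  rec <- fake_record(lapply(p1s, mk), lat)
  hm <- ordered_heatmap(rec, n_per_row = 10L, window = c(-100, 900))
  expect_equal(dim(hm$matrix), c(3L, 1001L))
  expect_false(is.unsorted(hm$order_key))
  expect_false(is.unsorted(hm$row_key))
  expect_warning(ordered_heatmap(rec, n_per_row = 100L, window = c(-100, 900)),
                 "single row")
  # identical configurations give identical rows
  rec2 <- fake_record(replicate(20, mk(50L), simplify = FALSE), lat)
  hm2 <- ordered_heatmap(rec2, n_per_row = 10L, window = c(-100, 900))
  expect_equal(hm2$matrix[1, ], hm2$matrix[2, ])
})

test_that("+1 offsets honor the species window conventions", {
  lat <- lattice_spec(2940L, tss_index = 500L)
  d <- c(470L, 700L)   # offsets -30 and +200
  expect_equal(plus_one_offset(d, lat), 200)
  expect_equal(plus_one_offset(d, lat, yeast_window = TRUE), -30)
  expect_true(is.na(plus_one_offset(integer(0), lat)))
})

test_that("ensemble gap pooling can exclude the promoter-spanning pair", {
  lat <- lattice_spec(2940L, tss_index = 500L)
  # apex at 350; configuration with a gap spanning it
  cfg <- nucleosome_config(c(200L, 600L, 800L), lat)
  rec <- fake_record(list(cfg$dyads), lat)
  g_all <- ensemble_gaps(rec, exclude_tss_flanking = FALSE)
  g_int <- ensemble_gaps(rec, exclude_tss_flanking = TRUE)
  expect_equal(sort(g_all), c(200L, 400L, 2340L))
  expect_equal(sort(g_int), c(200L, 2340L))  # the 400 gap spans the apex
})
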