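#' TSS-anchored normalized nucleosome density profile
#'
#' Counts dyads per offset bin relative to the TSS, averaged over all
#' sampled configurations, and divides by the lattice-wide mean dyad density
#' so that the bulk (featureless) level is 1.
#'
#' @param record An `ensemble_record`.
#' @param window Offsets in bp around the TSS, `c(from, to)`
#'   (default `c(-500, 1500)`).
#' @param bin Bin width in bp (default 1).
#' @return An object of class `density_profile`: list with `offset` (bin
#'   centers), `density`, `n_samples`, `bin`, `smoothing` (NULL when raw).
#' @export
density_profile <- function(record, window = c(-500, 1500), bin = 1) {
  if (!length(record$samples)) stop("empty ensemble")
  lat <- record$lattice
  L <- lat$length_bp
  dyads <- unlist(record$samples)
  n_samples <- length(record$samples)
  total <- length(dyads)
  off <- tss_offset(lat, dyads)
  breaks <- seq(window[1], window[2] + bin, by = bin) - 0.5
  sel <- off >= breaks[1] & off < breaks[length(breaks)]
  counts <- if (any(sel)) {
    idx <- floor((off[sel] - breaks[1]) / bin) + 1L
    tabulate(idx, nbins = length(breaks) - 1L)
  } else integer(length(breaks) - 1L)
  # normalize by the lattice-wide mean dyad density (total/(n_samples*L)) per bp
  dens <- counts * L / (total * bin)
  structure(list(offset = breaks[-length(breaks)] + 0.5 + (bin - 1) / 2,
                 density = dens, n_samples = n_samples, bin = bin,
                 window = window, smoothing = NULL),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> window [%g, %g] bp, bin %g bp, %d samples%s\n",
              x$window[1], x$window[2], x$bin, x$n_samples,
              if (is.null(x$smoothing)) "" else
                sprintf(", smoothed (%s, bw %g)", x$smoothing$kernel,
                        x$smoothing$bandwidth)))
  invisible(x)
}

#' Kernel-smooth a density profile
#'
#' Linear smoothing with a named kernel.  Near the window edges the kernel
#' is truncated and renormalized, so a constant profile is reproduced
#' exactly.  The raw profile is retained in the `raw` field.
#'
#' @param profile A [density_profile()].
#' @param bandwidth Kernel scale in bp: the standard deviation for
#'   `"gaussian"` (support truncated at 4 sd), the half-width for `"box"`
#'   and `"triangular"`.  Default 10 bp.
#' @param kernel One of `"gaussian"`, `"box"`, `"triangular"`.
#' @return A `density_profile` with smoothing metadata.
#' @export
smooth_profile <- function(profile, bandwidth = 10, kernel = "gaussian") {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  w_bins <- smoothing_kernel(bandwidth, kernel, profile$bin)
  if (length(w_bins) >= length(profile$density))
    stop("bandwidth larger than the analysis window")
  half <- (length(w_bins) - 1L) %/% 2L
  x <- profile$density
  n <- length(x)
  # renormalize by the kernel mass actually inside the window
  mass <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), w_bins, sides = 2)
  mass <- as.numeric(mass)[(half + 1L):(half + n)]
  num2 <- stats::filter(c(rep(0, half), x, rep(0, half)), w_bins, sides = 2)
  num2 <- as.numeric(num2)[(half + 1L):(half + n)]
  out <- profile
  out$density <- num2 / mass
  out$smoothing <- list(kernel = kernel, bandwidth = bandwidth)
  out$raw <- profile$density
  out
}

smoothing_kernel <- function(bandwidth, kernel, bin = 1) {
  bw <- bandwidth / bin
  k <- switch(kernel,
    gaussian = {
      half <- max(1L, ceiling(4 * bw))
      stats::dnorm(-half:half, sd = bw)
    },
    box = {
      half <- max(0L, floor(bw))
      rep(1, 2L * half + 1L)
    },
    triangular = {
      half <- max(1L, floor(bw))
      pmax(0, 1 - abs(-half:half) / (half + 1))
    },
    stop("unknown kernel: ", kernel))
  k / sum(k)
}

#' Radial distribution function of dyad positions
#'
#' Normalized histogram of all circular pairwise dyad distances up to
#' `r_max`, scaled so that a homogeneous ideal (non-interacting) system
#' gives g(r) = 1.  Hard-core exclusion forces g(r) = 0 below one footprint.
#'
#' @param record An `ensemble_record`.
#' @param r_max Maximum distance in bp (default 1000).
#' @return An object of class `radial_distribution`: list with `r`
#'   (1..r_max) and `g`.
#' @export
radial_distribution <- function(record, r_max = 1000) {
  L <- record$lattice$length_bp
  counts <- numeric(r_max)
  norm <- 0
  kmax <- min(ceiling(r_max / record$lattice$footprint_bp) + 2L, 10000L)
  for (d in record$samples) {
    n <- length(d)
    if (n < 2L) next
    for (k in seq_len(min(kmax, n - 1L))) {
      dist <- (c(d[-seq_len(k)], d[seq_len(k)] + L) - d)
      dist <- dist[dist >= 1 & dist <= r_max]
      if (length(dist)) {
        tb <- tabulate(dist, nbins = r_max)
        counts <- counts + tb
      }
    }
    norm <- norm + n * (n - 1L) / L
  }
  if (norm == 0) stop("need samples with >= 2 nucleosomes")
  structure(list(r = seq_len(r_max), g = counts / norm),
            class = "radial_distribution")
}

#' Pooled nearest-neighbor dyad gaps of an ensemble
#'
#' Collects all consecutive circular dyad-to-dyad distances across samples.
#' By default the pair flanking the promoter (the gap spanning the barrier
#' apex, i.e. the nucleosome-free region) is excluded, so the statistic
#' reflects spacing within the nucleosome array.
#'
#' @param record An `ensemble_record`.
#' @param exclude_tss_flanking Drop the gap spanning the barrier apex
#'   (TSS - 150 bp) in each sample (default `TRUE`).
#' @return Integer vector of gaps in bp.
#' @export
ensemble_gaps <- function(record, exclude_tss_flanking = TRUE) {
  lat <- record$lattice
  L <- lat$length_bp
  apex <- (lat$tss_index - 150L) %% L
  out <- lapply(record$samples, function(d) {
    g <- circular_gaps(d, L)
    if (!length(g)) return(integer(0))
    if (exclude_tss_flanking) {
      dd <- sort(d)
      nxt <- c(dd[-1L], dd[1L] + L)
      spans <- (dd < apex & nxt > apex) |
               (dd < apex + L & nxt > apex + L)
      g <- g[!spans]
    }
    g
  })
  unlist(out)
}

#' Detect peaks in a density profile
#'
#' Local maxima filtered by topographic prominence and a minimum mutual
#' separation (higher peak wins; ties broken leftmost).  Operates on the
#' profile as given; smooth first for noisy input.
#'
#' @param profile A [density_profile()].
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   profile's range (default 0.05).
#' @param min_separation Minimum peak-to-peak distance in bp (default 100).
#' @param from,to Restrict to offsets in `[from, to]` (defaults: whole
#'   window).
#' @return A data.frame with columns `offset`, `height`, `prominence`,
#'   ordered by offset.
#' @export
find_peaks <- function(profile, min_prominence_frac = 0.05,
                       min_separation = 100, from = -Inf, to = Inf) {
  x <- profile$density
  off <- profile$offset
  sel <- off >= from & off <= to
  x <- x[sel]; off <- off[sel]
  n <- length(x)
  if (n < 3L) return(data.frame(offset = numeric(0), height = numeric(0),
                                prominence = numeric(0)))
  # strict local maxima; for plateaus keep the leftmost point
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand)) return(data.frame(offset = numeric(0),
                                       height = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(i - 1L)])
              else min(left)
    right <- x[(i + 1L):n]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
              else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  rng <- diff(range(x))
  keep <- prom >= min_prominence_frac * max(rng, .Machine$double.eps)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(data.frame(offset = numeric(0),
                                       height = numeric(0),
                                       prominence = numeric(0)))
  # enforce separation: keep higher peaks first (ties: leftmost)
  ord <- order(-x[cand], off[cand])
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(off[cand[kept]] - off[cand[i]]) >= min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(offset = off[cand[kept]], height = x[cand[kept]],
             prominence = prom[kept])
}

#' Mean inter-nucleosome spacing from profile peaks
#'
#' Mean distance between the first `n_peaks` detected local maxima
#' downstream of the TSS.
#'
#' @param profile A [density_profile()] (smooth first for raw simulation
#'   output).
#' @param n_peaks Number of downstream peaks to use (default 5).
#' @param from Start of the peak search window in bp (default 0 = at TSS).
#' @param ... Passed to [find_peaks()].
#' @return Mean consecutive peak distance in bp.
#' @export
mean_spacing <- function(profile, n_peaks = 5L, from = 0, ...) {
  pk <- find_peaks(profile, from = from, ...)
  if (nrow(pk) < n_peaks)
    stop(sprintf("insufficient peaks: found %d, need %d", nrow(pk), n_peaks))
  pos <- pk$offset[seq_len(n_peaks)]
  mean(diff(pos))
}

#' Position of the +1 nucleosome in a configuration
#'
#' The first dyad downstream of the TSS.  With `yeast_window = TRUE` the
#' search starts at -50 bp (the +1 nucleosome sits closer to the TSS in
#' yeast); otherwise at 0.
#' @param dyads Integer dyad vector (0-based).
#' @param lattice A [lattice_spec()].
#' @param yeast_window Use the [-50, ...] search convention.
#' @return Offset of the +1 dyad in bp, or `NA` if none exists downstream.
#' @export
plus_one_offset <- function(dyads, lattice, yeast_window = FALSE) {
  off <- tss_offset(lattice, dyads)
  lo <- if (yeast_window) -50 else 0
  cand <- off[off >= lo]
  if (!length(cand)) return(NA_real_)
  min(cand)
}

#' Heatmap of configurations ordered by +1 nucleosome position
#'
#' Sorts configurations by the position of their +1 nucleosome, groups them
#' into consecutive blocks of `n_per_row`, and computes each block's local
#' density profile (same normalization constant for all rows, so rows are
#' directly comparable).
#'
#' @param record An `ensemble_record`.
#' @param n_per_row Configurations averaged per row (default 1000).
#' @param window Offset window in bp.
#' @param yeast_window Passed to [plus_one_offset()].
#' @return A list with `matrix` (rows x offsets), `offsets`, `row_key`
#'   (mean +1 position per row), and `order_key` (per-configuration +1
#'   position in row order).
#' @export
ordered_heatmap <- function(record, n_per_row = 1000L,
                            window = c(-500, 1500), yeast_window = FALSE) {
  lat <- record$lattice
  key <- vapply(record$samples, plus_one_offset, numeric(1),
                lattice = lat, yeast_window = yeast_window)
  ok <- !is.na(key)
  samples <- record$samples[ok]
  key <- key[ok]
  S <- length(samples)
  if (S < n_per_row) {
    warning("fewer configurations than n_per_row; returning a single row")
    n_per_row <- S
  }
  ord <- order(key)
  samples <- samples[ord]; key <- key[ord]
  n_rows <- S %/% n_per_row
  offs <- window[1]:window[2]
  total_dyads <- length(unlist(record$samples))
  mean_dens <- total_dyads / (length(record$samples) * lat$length_bp)
  mat <- matrix(0, nrow = n_rows, ncol = length(offs))
  row_key <- numeric(n_rows)
  for (r in seq_len(n_rows)) {
    idx <- ((r - 1L) * n_per_row + 1L):(r * n_per_row)
    d <- unlist(samples[idx])
    o <- tss_offset(lat, d)
    sel <- o >= window[1] & o <= window[2]
    counts <- tabulate(o[sel] - window[1] + 1L, nbins = length(offs))
    mat[r, ] <- counts / (n_per_row * mean_dens)
    row_key[r] <- mean(key[idx])
  }
  list(matrix = mat, offsets = offs, row_key = row_key, order_key = key)
}

#' Classify a density profile as yeast-like or mouse-like
#'
#' Compares the heights of the first two detected peaks downstream of the
#' TSS: profiles whose second peak is higher than the first (gradually
#' increasing peaks, ill-positioned +1 nucleosome) are `mouse_like`;
#' decreasing peaks are `yeast_like`; equal heights within `tol` (relative)
#' are `boundary`.
#'
#' @param profile A [density_profile()].
#' @param tol Relative height tolerance for the boundary call (default 0.02).
#' @param ... Passed to [find_peaks()].
#' @return One of `"yeast_like"`, `"mouse_like"`, `"boundary"`.
#' @export
classify_profile <- function(profile, tol = 0.02, ...) {
  pk <- find_peaks(profile, from = 0, ...)
  if (nrow(pk) < 2L)
    stop("unclassifiable profile: fewer than 2 downstream peaks")
  h1 <- pk$height[1]; h2 <- pk$height[2]
  if (abs(h2 - h1) <= tol * h1) "boundary"
  else if (h2 > h1) "mouse_like"
  else "yeast_like"
}

#' Phase diagram over positioning depth and enzyme rate
#'
#' Runs one equilibrium-sampler simulation per grid point (promoter barrier
#' plus a positioning well of the given depth and the enzyme-renormalized
#' attraction for the given rate) and classifies the resulting profile.
#' Per-point failures are recorded, not propagated.
#'
#' @param depths Positioning-well depths in kBT (<= 0).
#' @param rates Spacer-enzyme rates in 1/s.
#' @param lattice A [lattice_spec()].
#' @param target_density Density target for `mu` calibration.
#' @param protocol A [simulation_protocol()] used at every grid point.
#' @param smooth_bw Smoothing bandwidth before classification (bp).
#' @param mu Optional precalibrated `mu` values, a matrix
#'   `[depth x rate]`; calibrated per point when `NULL`.
#' @return A data.frame with columns `depth`, `rate`, `label` (classifier
#'   output or `NA` with the error in `note`).
#' @export
phase_diagram <- function(depths, rates, lattice = lattice_spec(),
                          target_density = 0.88,
                          protocol = simulation_protocol(n_replicas = 2L,
                                                         t_end = 2000,
                                                         initial_n = 80L,
                                                         seed = 7L),
                          smooth_bw = 10, mu = NULL) {
  grid <- expand.grid(depth = depths, rate = rates)
  grid$label <- NA_character_
  grid$note <- ""
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      field <- energy_field(lattice, barrier = make_barrier(lattice),
                            positioning = if (grid$depth[i] < 0)
                              make_positioning(lattice, depth = grid$depth[i])
                            else NULL)
      pp <- effective_pair_potential(grid$rate[i],
                                     footprint_bp = lattice$footprint_bp)
      model <- kinetic_model(field, pp, r_const = 12)
      muv <- if (is.null(mu)) calibrate_mu(model, target_density)
             else mu[match(grid$depth[i], depths), match(grid$rate[i], rates)]
      model <- kinetic_model(field, pp, r_const = 12, mu = as.numeric(muv))
      rec <- sample_equilibrium(model, protocol)
      prof <- smooth_profile(density_profile(rec), bandwidth = smooth_bw)
      classify_profile(prof)
    }, error = function(e) structure(NA_character_, note = conditionMessage(e)))
    grid$label[i] <- as.character(res)
    if (!is.null(attr(res, "note"))) grid$note[i] <- attr(res, "note")
  }
  grid
}
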