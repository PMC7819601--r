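# Shared builders for small test systems.

# small uniform lattice + field
tiny_lattice <- function(L = 588L, tss = 100L) lattice_spec(L, tss_index = tss)

tiny_field <- function(lattice, ...) energy_field(lattice, ...)

# field with two sharp wells (used by exactness tests: the stationary
# distribution concentrates on a handful of states, so total-variation
# comparisons against exact enumeration are statistically identifiable)
two_well_field <- function(lattice, wells, site_energy = 0) {
  pos <- numeric(lattice$length_bp)
  for (w in wells) pos[w$at + 1L] <- w$depth
  energy_field(lattice, site_energy = site_energy, positioning = pos)
}

# empirical state distribution of an ensemble, keyed like enumerate_reference
state_probs <- function(record, ref) {
  key <- vapply(record$samples, paste, "", collapse = ",")
  emp <- table(key) / length(key)
  p <- stats::setNames(rep(0, nrow(ref)), ref$key)
  p[names(emp)] <- as.numeric(emp)
  p
}

ref_probs <- function(ref) {
  w <- exp(ref$log_weight - max(ref$log_weight))
  w / sum(w)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# sampling-noise floor of a profile comparison: mean absolute difference
# between the smoothed profiles of two disjoint replica halves
profile_split_noise <- function(record, window = c(-300, 800), bandwidth = 10) {
  half <- record$replica <= stats::median(unique(record$replica))
  sub <- function(keep) {
    r <- record
    r$samples <- r$samples[keep]
    r$replica <- r$replica[keep]
    r$time <- r$time[keep]
    smooth_profile(density_profile(r), bandwidth = bandwidth)
  }
  p1 <- sub(half); p2 <- sub(!half)
  sel <- p1$offset >= window[1] & p1$offset <= window[2]
  mean(abs(p1$density[sel] - p2$density[sel]))
}

# offset of the most prominent downstream peak (robust to marginal
# contact bumps at the barrier edge)
dominant_peak <- function(profile, from = 0) {
  pk <- find_peaks(profile, from = from)
  pk$offset[which.max(pk$prominence)]
}
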