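#' Dinucleotide-periodicity affinity model parameters
#'
#' Nucleosome-favoring sequences present flexible AA/TT/TA/AT steps where
#' the minor groove faces the histone core, roughly every helical repeat
#' (10.1 bp), with stiff GC steps in counter-phase.  The model scores a
#' candidate dyad by summing a cosine of that period over every dinucleotide
#' in the footprint: in-phase classes lower the energy at crests, the
#' anti-phase class raises it.  All coefficients are explicit configuration;
#' the defaults follow the usual periodic-dinucleotide parameterization with
#' amplitudes on a scale that leaves per-footprint energies within a few kBT
#' of the mean.
#'
#' @param period_bp Helical repeat in bp (default 10.1).
#' @param amp_ww Amplitude (kBT per dinucleotide weight) of the in-phase
#'   {AA, TT, TA, AT} classes (default 0.02).
#' @param amp_gc Amplitude of the anti-phase {GC} class (default 0.02).
#' @param footprint_bp Footprint in bp (default 147).
#' @param mean_energy Mean per-nucleosome binding energy the profile is
#'   shifted to, in kBT (default -42).  Set `NA` to keep the raw
#'   (zero-centered) score.
#' @return A list of class `affinity_params`.
#' @export
affinity_params <- function(period_bp = 10.1, amp_ww = 0.02, amp_gc = 0.02,
                            footprint_bp = 147L, mean_energy = -42) {
  structure(list(period_bp = period_bp, amp_ww = amp_ww, amp_gc = amp_gc,
                 footprint_bp = as.integer(footprint_bp),
                 mean_energy = mean_energy),
            class = "affinity_params")
}

#' Score a DNA sequence for nucleosome affinity
#'
#' Computes a per-position (dyad-evaluated) binding-energy profile from the
#' phasing of dinucleotides, deterministic and strand-symmetric: the profile
#' of the reverse complement is the reversed profile.  Positions whose
#' footprint would run off the sequence (the first and last 73 bp) are
#' filled with the nearest interior value so the profile has the same length
#' as the sequence.  `N` bases contribute zero to every dinucleotide term.
#'
#' @param sequence A DNA string over A, C, G, T, N (case-insensitive), at
#'   least one footprint long.
#' @param params An [affinity_params()].
#' @param sequence_id Label stored in the result.
#' @return An object of class `affinity_profile`: list with `energies`
#'   (kBT, length = nchar(sequence)), `sequence_id`, `params`, `tss`
#'   (defaults to the sequence midpoint; used by
#'   [mean_affinity_metaprofile()]).
#' @export
score_sequence <- function(sequence, params = affinity_params(),
                           sequence_id = "seq") {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  fp <- params$footprint_bp
  if (n < fp) stop("sequence shorter than one footprint")
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("invalid characters in sequence (only A, C, G, T, N allowed)")
  di <- paste0(chars[-n], chars[-1L])
  ww <- as.numeric(di %in% c("AA", "TT", "TA", "AT"))
  gc <- as.numeric(di == "GC")
  half <- (fp - 1L) %/% 2L
  # energy at dyad x: sum over dinucleotide centers c = i + 0.5 with
  # |c - x| <= half - 0.5 of  -amp_ww*cos(2 pi (c-x)/p) + amp_gc*cos(...)
  delta <- seq(-(half - 0.5), half - 0.5, by = 1)
  kern <- cos(2 * pi * delta / params$period_bp)
  # dyad at 1-based position x1 sees the dinucleotides starting at
  # x1 - half .. x1 + half - 1 (centers at offsets -(half-0.5)..(half-0.5))
  core <- (half + 1L):(n - half)   # 1-based dyads with full footprint
  energy_core <- vapply(core, function(x1) {
    i <- (x1 - half):(x1 + half - 1L)  # dinucleotide starts, 1-based
    sum((-params$amp_ww * ww[i] + params$amp_gc * gc[i]) * kern)
  }, numeric(1))
  energies <- c(rep(energy_core[1L], half), energy_core,
                rep(energy_core[length(energy_core)], half))
  if (!is.na(params$mean_energy))
    energies <- energies - mean(energies) + params$mean_energy
  structure(list(energies = energies, sequence_id = sequence_id,
                 params = params, tss = n %/% 2L),
            class = "affinity_profile")
}

#' Average affinity metaprofile across TSS-aligned sequences
#'
#' Position-wise arithmetic mean of several affinity profiles aligned at
#' their TSS.
#'
#' @param profiles A list of [score_sequence()] results.
#' @param window Offsets in bp relative to each profile's `tss`,
#'   `c(from, to)`; must lie inside every profile.
#' @return A data.frame with columns `offset` and `energy_kBT`.
#' @export
mean_affinity_metaprofile <- function(profiles, window = c(-500, 500)) {
  if (!length(profiles)) stop("empty profile collection")
  offs <- window[1]:window[2]
  rows <- vapply(profiles, function(p) {
    idx <- p$tss + offs + 1L
    if (min(idx) < 1L || max(idx) > length(p$energies))
      stop("window outside profile ", p$sequence_id)
    p$energies[idx]
  }, numeric(length(offs)))
  data.frame(offset = offs, energy_kBT = rowMeans(rows))
}
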