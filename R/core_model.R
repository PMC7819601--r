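#' Lattice specification
#'
#' Defines the one-dimensional DNA lattice on which nucleosomes are placed.
#' Each lattice site is one base pair.  The lattice is periodic (a ring), which
#' removes end effects; all coordinates are 0-based indices in
#' `[0, length_bp)`.  A nucleosome is a hard rod whose coordinate is its dyad
#' (footprint center); the footprint covers `[dyad - 73, dyad + 73]` for the
#' default 147-bp footprint.
#'
#' @param length_bp Lattice length in base pairs (default 14700).
#' @param periodic Must be `TRUE`; only periodic lattices are supported.
#' @param tss_index 0-based coordinate of the transcription start site, the
#'   anchor for all positional potentials and profiles.
#' @param footprint_bp Nucleosome footprint in bp (default 147, odd).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(length_bp = 14700L, periodic = TRUE,
                         tss_index = 2000L, footprint_bp = 147L) {
  length_bp <- as.integer(length_bp)
  tss_index <- as.integer(tss_index)
  footprint_bp <- as.integer(footprint_bp)
  if (!isTRUE(periodic))
    stop("only periodic lattices are supported")
  if (length_bp < footprint_bp)
    stop("length_bp must be >= footprint_bp")
  if (footprint_bp < 1L || footprint_bp %% 2L == 0L)
    stop("footprint_bp must be a positive odd integer")
  if (tss_index < 0L || tss_index >= length_bp)
    stop("tss_index must lie in [0, length_bp)")
  structure(list(length_bp = length_bp, periodic = TRUE,
                 tss_index = tss_index, footprint_bp = footprint_bp),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d bp periodic ring, TSS at %d, footprint %d bp\n",
              x$length_bp, x$tss_index, x$footprint_bp))
  invisible(x)
}

#' Signed circular offset of lattice positions relative to the TSS
#'
#' Maps each position to its offset from the TSS in `(-L/2, L/2]`.
#' @param lattice A [lattice_spec()].
#' @param positions 0-based positions (default: the whole lattice).
#' @return Integer offsets in bp.
#' @export
tss_offset <- function(lattice, positions = seq_len(lattice$length_bp) - 1L) {
  L <- lattice$length_bp
  d <- (positions - lattice$tss_index) %% L
  ifelse(d > L / 2, d - L, d)
}

#' Nucleosome configuration
#'
#' A set of dyad positions on the lattice.  Validity requires strictly
#' increasing dyads in `[0, L)` and every circular dyad-to-dyad gap at least
#' one footprint (hard-core exclusion).
#'
#' @param dyads Integer vector of 0-based dyad positions (sorted or not).
#' @param lattice A [lattice_spec()].
#' @return An object of class `nucleosome_config`.
#' @export
nucleosome_config <- function(dyads, lattice) {
  dyads <- sort(as.integer(dyads))
  if (anyDuplicated(dyads))
    stop("duplicated dyad positions")
  if (length(dyads) && (min(dyads) < 0L || max(dyads) >= lattice$length_bp))
    stop("dyads must lie in [0, length_bp)")
  g <- circular_gaps(dyads, lattice$length_bp)
  if (length(g) && min(g) < lattice$footprint_bp)
    stop(sprintf("exclusion violated: minimum gap %d < footprint %d",
                 min(g), lattice$footprint_bp))
  structure(list(dyads = dyads, lattice = lattice),
            class = "nucleosome_config")
}

#' Circular dyad-to-dyad gaps
#'
#' For `n >= 2` sorted dyads on a ring of length `L`, returns the `n`
#' consecutive gaps (the i-th gap is `dyads[i+1] - dyads[i]`, the last wraps
#' around).  For `n < 2` returns an empty vector: a lone nucleosome has no
#' neighbor pair.
#' @param dyads Sorted integer dyads.
#' @param L Lattice length.
#' @return Integer gaps summing to `L` (for `n >= 2`).
#' @export
circular_gaps <- function(dyads, L) {
  n <- length(dyads)
  if (n < 2L) return(integer(0))
  c(diff(dyads), L - dyads[n] + dyads[1L])
}

#' Triangular promoter barrier potential
#'
#' A dyad-evaluated repulsive potential representing the competition of
#' transcription factors, the preinitiation complex and Pol II with histones
#' at the promoter.  The barrier is a symmetric triangle centered at
#' `tss + center_offset`: it equals `height` at the center and decreases
#' linearly to zero at `center +/- half_width`.  With the defaults the support
#' is `[-300, 0]` bp relative to the TSS and the apex sits at -150 bp.  The
#' finite, dyad-evaluated penalty lets nucleosomes occupy the promoter with
#' small but nonzero probability.
#'
#' @param lattice A [lattice_spec()].
#' @param center_offset Apex position in bp relative to the TSS (default -150).
#' @param half_width Half-width of the triangle in bp (default 150).
#' @param height Apex height in kBT (default 25; use 2 for genes of
#'   intermediate activity).
#' @return Numeric vector of length `length_bp`, >= 0 everywhere.
#' @export
make_barrier <- function(lattice, center_offset = -150, half_width = 150,
                         height = 25) {
  if (height < 0) stop("barrier height must be >= 0")
  if (half_width <= 0) stop("half_width must be > 0")
  d <- tss_offset(lattice)
  height * pmax(0, 1 - abs(d - center_offset) / half_width)
}

#' Flat positioning well downstream of the TSS
#'
#' A dyad-evaluated attractive well standing in for positioning enzymes
#' (INO80-like) that align the +1 nucleosome toward the TSS.  The well has
#' constant value `depth` (<= 0) on `[tss + start_offset, tss + end_offset]`
#' and is zero elsewhere.
#'
#' @param lattice A [lattice_spec()].
#' @param start_offset,end_offset Well extent in bp relative to the TSS
#'   (defaults 0 and 30); `start_offset < end_offset`.
#' @param depth Well depth in kBT, non-positive (default -2).
#' @return Numeric vector of length `length_bp`, <= 0 everywhere.
#' @export
make_positioning <- function(lattice, start_offset = 0, end_offset = 30,
                             depth = -2) {
  if (depth > 0) stop("positioning depth must be <= 0")
  if (start_offset >= end_offset) stop("start_offset must be < end_offset")
  d <- tss_offset(lattice)
  ifelse(d >= start_offset & d <= end_offset, depth, 0)
}

#' Energy field: per-bp binding energies and dyad-evaluated potentials
#'
#' Collects the three energy terms of the model: a per-site nucleosome
#' binding energy `V_s` (summed over the 147-bp footprint when a nucleosome
#' binds), a promoter barrier, and a positioning well (both evaluated at the
#' dyad only).  The default uniform `site_energy = -42/147` kBT per bp gives
#' the standard -42 kBT binding free energy per nucleosome.
#'
#' @param lattice A [lattice_spec()].
#' @param site_energy Scalar (uniform) or length-`length_bp` vector of per-bp
#'   binding energies in kBT.
#' @param barrier Dyad-evaluated barrier array (e.g. [make_barrier()]) or
#'   `NULL` for none.  Must be >= 0 everywhere.
#' @param positioning Dyad-evaluated positioning array
#'   (e.g. [make_positioning()]) or `NULL`.  Must be <= 0 everywhere.
#' @return An object of class `energy_field` with precomputed per-dyad total
#'   binding energies.
#' @export
energy_field <- function(lattice, site_energy = -42 / 147,
                         barrier = NULL, positioning = NULL) {
  L <- lattice$length_bp
  if (length(site_energy) == 1L) site_energy <- rep(as.numeric(site_energy), L)
  if (length(site_energy) != L)
    stop("site_energy must be scalar or have length_bp entries")
  if (is.null(barrier)) barrier <- numeric(L)
  if (is.null(positioning)) positioning <- numeric(L)
  if (length(barrier) != L || length(positioning) != L)
    stop("barrier/positioning must have length_bp entries")
  if (any(barrier < 0)) stop("barrier must be >= 0 everywhere")
  if (any(positioning > 0)) stop("positioning must be <= 0 everywhere")
  fp <- lattice$footprint_bp
  half <- (fp - 1L) %/% 2L
  # circular rolling footprint sum of site energies, centered at each dyad
  ext <- c(site_energy[(L - half + 1L):L], site_energy, site_energy[1L:half])
  cs <- c(0, cumsum(ext))
  foot <- cs[(1L:L) + fp] - cs[1L:L]
  structure(list(lattice = lattice, site_energy = site_energy,
                 barrier = barrier, positioning = positioning,
                 dyad_energy = foot + barrier + positioning),
            class = "energy_field")
}

#' Binding energy of a single nucleosome at a dyad
#'
#' Sum of the per-bp site energies over the footprint centered at the dyad
#' (with periodic wrap) plus the barrier and positioning potentials evaluated
#' at the dyad.
#' @param dyad 0-based dyad position(s); vectorized.
#' @param field An [energy_field()].
#' @return Energy in kBT.
#' @export
nucleosome_energy <- function(dyad, field) {
  L <- field$lattice$length_bp
  if (any(dyad < 0L | dyad >= L)) stop("dyad outside lattice")
  field$dyad_energy[as.integer(dyad) + 1L]
}

#' Nearest-neighbor pair potential
#'
#' Hard-core exclusion below `hard_core_bp` (infinite energy for dyad gaps
#' shorter than one footprint) plus an optional tabulated attraction
#' `u_eff(gap)` for gaps at and beyond contact, used by the accelerated
#' equilibrium sampler to fold in the effect of spacer enzymes.
#'
#' @param hard_core_bp Exclusion distance in bp (default 147).
#' @param attraction `NULL` (pure hard core) or a numeric vector giving the
#'   pair energy in kBT at gaps `hard_core_bp, hard_core_bp + 1, ...`; gaps
#'   beyond the table have zero energy.
#' @return An object of class `pair_potential`.
#' @export
pair_potential <- function(hard_core_bp = 147L, attraction = NULL) {
  hard_core_bp <- as.integer(hard_core_bp)
  if (hard_core_bp < 1L) stop("hard_core_bp must be positive")
  if (!is.null(attraction)) {
    attraction <- as.numeric(attraction)
    if (any(!is.finite(attraction))) stop("attraction table must be finite")
  }
  structure(list(hard_core_bp = hard_core_bp, attraction = attraction),
            class = "pair_potential")
}

#' Pair energy at given dyad gaps
#'
#' @param pair A [pair_potential()].
#' @param gap Integer dyad-to-dyad distances; vectorized.
#' @return Energies in kBT; `Inf` below the hard core, 0 beyond the table.
#' @export
pair_energy <- function(pair, gap) {
  gap <- as.integer(gap)
  out <- numeric(length(gap))
  out[gap < pair$hard_core_bp] <- Inf
  if (!is.null(pair$attraction)) {
    idx <- gap - pair$hard_core_bp + 1L
    sel <- idx >= 1L & idx <= length(pair$attraction)
    out[sel] <- pair$attraction[idx[sel]]
  }
  out
}

#' Total energy of a configuration
#'
#' Sum of single-nucleosome binding energies plus nearest-neighbor pair
#' energies over all consecutive circular pairs (a lone nucleosome has no
#' pair term; two nucleosomes on the ring interact across both gaps).
#' @param config A [nucleosome_config()].
#' @param field An [energy_field()].
#' @param pair A [pair_potential()] (default: pure hard core at the lattice
#'   footprint).
#' @return Total energy in kBT (finite for any valid configuration).
#' @export
total_energy <- function(config, field,
                         pair = pair_potential(config$lattice$footprint_bp)) {
  d <- config$dyads
  if (!length(d)) return(0)
  e <- sum(nucleosome_energy(d, field))
  g <- circular_gaps(sort(d), config$lattice$length_bp)
  if (length(g)) e <- e + sum(pair_energy(pair, g))
  if (!is.finite(e))
    stop("contract violation: configuration violates hard-core exclusion")
  e
}

#' Energy change of an elementary move
#'
#' Computes `total_energy(after) - total_energy(before)` from the affected
#' terms only.  Moves are 1-bp hops of an existing nucleosome, insertion of a
#' new nucleosome at a dyad, or removal of an existing nucleosome.  Returns
#' `Inf` when the move would violate hard-core exclusion.
#'
#' @param config A [nucleosome_config()].
#' @param move A list: `list(type = "hop", index = i, dir = +1 or -1)`,
#'   `list(type = "insert", dyad = s)`, or `list(type = "remove", index = i)`.
#'   `index` is the 1-based rank of the nucleosome in dyad order.
#' @param field An [energy_field()].
#' @param pair A [pair_potential()].
#' @return Energy difference in kBT, possibly `Inf`.
#' @export
delta_energy <- function(config, move, field,
                         pair = pair_potential(config$lattice$footprint_bp)) {
  d <- config$dyads
  L <- config$lattice$length_bp
  n <- length(d)
  u <- function(g) pair_energy(pair, g)
  E <- function(x) nucleosome_energy(x %% L, field)
  switch(move$type,
    hop = {
      i <- move$index
      if (i < 1L || i > n) stop("hop references a missing nucleosome")
      x <- d[i]
      xn <- (x + move$dir) %% L
      if (n == 1L) return(E(xn) - E(x))
      prev <- d[if (i == 1L) n else i - 1L]
      nxt  <- d[if (i == n) 1L else i + 1L]
      dl <- (x - prev) %% L
      dr <- (nxt - x) %% L
      if (move$dir > 0) {
        if (dr - 1L < pair$hard_core_bp) return(Inf)
        E(xn) - E(x) + u(dl + 1L) + u(dr - 1L) - u(dl) - u(dr)
      } else {
        if (dl - 1L < pair$hard_core_bp) return(Inf)
        E(xn) - E(x) + u(dl - 1L) + u(dr + 1L) - u(dl) - u(dr)
      }
    },
    insert = {
      s <- move$dyad %% L
      if (n == 0L) return(E(s))
      if (s %in% d) return(Inf)
      prev <- if (any(d < s)) max(d[d < s]) else max(d)
      nxt  <- if (any(d > s)) min(d[d > s]) else min(d)
      dl <- (s - prev) %% L
      dr <- (nxt - s) %% L
      if (dl < pair$hard_core_bp || dr < pair$hard_core_bp) return(Inf)
      if (n == 1L) return(E(s) + u(dl) + u(dr))
      E(s) + u(dl) + u(dr) - u(dl + dr)
    },
    remove = {
      i <- move$index
      if (i < 1L || i > n) stop("remove references a missing nucleosome")
      x <- d[i]
      if (n == 1L) return(-E(x))
      prev <- d[if (i == 1L) n else i - 1L]
      nxt  <- d[if (i == n) 1L else i + 1L]
      dl <- (x - prev) %% L
      dr <- (nxt - x) %% L
      if (n == 2L) return(-(E(x) + u(dl) + u(dr)))
      -(E(x) + u(dl) + u(dr) - u(dl + dr))
    },
    stop("unknown move type: ", move$type)
  )
}

#' Apply an elementary move to a configuration
#'
#' Companion to [delta_energy()]: returns the configuration after the move
#' (used by reference implementations and tests; the simulation engine keeps
#' its own incremental state).
#' @inheritParams delta_energy
#' @return A valid [nucleosome_config()].
#' @export
apply_move <- function(config, move) {
  d <- config$dyads
  L <- config$lattice$length_bp
  d2 <- switch(move$type,
    hop = { d[move$index] <- (d[move$index] + move$dir) %% L; d },
    insert = c(d, move$dyad %% L),
    remove = d[-move$index],
    stop("unknown move type: ", move$type))
  nucleosome_config(d2, config$lattice)
}
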