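#' Read a model/protocol configuration file
#'
#' Flat YAML configuration describing the lattice, potentials, kinetic
#' parameters and simulation protocol.  All fields are validated together
#' and every violation is reported; unknown keys are rejected.  Omitted
#' fields take the package defaults (lattice 14700 bp, footprint 147 bp,
#' D = 1 bp^2/s, step 1 bp), which are echoed into the returned objects.
#'
#' Recognized top-level keys: `preset` (a scenario name, see
#' [build_preset()]), `lattice` (`length_bp`, `tss_index`, `footprint_bp`),
#' `site_energy` (uniform per-bp energy) or `affinity_table` (TSV with
#' columns `position`, `energy_kBT`), `barrier` (`center`, `half_width`,
#' `height`), `positioning` (`start`, `end`, `depth`), `kinetics` (`D`,
#' `enzyme_rate`, `enzyme_range`, `r_const`, `mu`), and `protocol`
#' (`n_replicas`, `t_end`, `burn_in`, `sample_interval`, `initial_n`,
#' `seed`).
#'
#' @param path Path to a YAML file.
#' @return A list with `model` ([kinetic_model()]), `protocol`
#'   ([simulation_protocol()] or NULL), `preset` (name or NULL), and `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  known <- c("preset", "lattice", "site_energy", "affinity_table", "barrier",
             "positioning", "kinetics", "protocol")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) errs <- c(errs, paste("unknown keys:", paste(bad, collapse = ", ")))
  check_keys <- function(block, name, allowed) {
    if (!is.null(block) && length(setdiff(names(block), allowed)))
      errs <<- c(errs, sprintf("unknown keys in %s: %s", name,
                               paste(setdiff(names(block), allowed), collapse = ", ")))
  }
  check_keys(cfg$lattice, "lattice", c("length_bp", "tss_index", "footprint_bp"))
  check_keys(cfg$barrier, "barrier", c("center", "half_width", "height"))
  check_keys(cfg$positioning, "positioning", c("start", "end", "depth"))
  check_keys(cfg$kinetics, "kinetics",
             c("D", "enzyme_rate", "enzyme_range", "r_const", "mu"))
  check_keys(cfg$protocol, "protocol",
             c("n_replicas", "t_end", "burn_in", "sample_interval",
               "initial_n", "seed"))
  num_ok <- function(x, nm, min = -Inf) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || x < min))
      errs <<- c(errs, sprintf("%s must be a number >= %g", nm, min))
  }
  k <- cfg$kinetics
  num_ok(k$D, "kinetics.D", 0); num_ok(k$enzyme_rate, "kinetics.enzyme_rate", 0)
  num_ok(k$r_const, "kinetics.r_const", 0)
  num_ok(k$enzyme_range, "kinetics.enzyme_range", 1)
  if (!is.null(cfg$barrier)) num_ok(cfg$barrier$height, "barrier.height", 0)
  if (!is.null(cfg$positioning) && !is.null(cfg$positioning$depth) &&
      cfg$positioning$depth > 0)
    errs <- c(errs, "positioning.depth must be <= 0")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  lat_args <- cfg$lattice %||% list()
  lattice <- lattice_spec(
    length_bp = lat_args$length_bp %||% 14700L,
    tss_index = lat_args$tss_index %||% 2000L,
    footprint_bp = lat_args$footprint_bp %||% 147L)

  if (!is.null(cfg$preset)) {
    preset <- build_preset(cfg$preset, lattice)
    model <- preset$model
  } else {
    site <- if (!is.null(cfg$affinity_table)) {
      tab <- utils::read.delim(cfg$affinity_table)
      if (!all(c("position", "energy_kBT") %in% names(tab)))
        stop("affinity_table needs columns position, energy_kBT")
      e <- numeric(lattice$length_bp)
      e[tab$position + 1L] <- tab$energy_kBT
      e
    } else cfg$site_energy %||% (-42 / 147)
    barrier <- if (!is.null(cfg$barrier))
      make_barrier(lattice, cfg$barrier$center %||% -150,
                   cfg$barrier$half_width %||% 150,
                   cfg$barrier$height %||% 25) else NULL
    positioning <- if (!is.null(cfg$positioning))
      make_positioning(lattice, cfg$positioning$start %||% 0,
                       cfg$positioning$end %||% 30,
                       cfg$positioning$depth %||% -2) else NULL
    field <- energy_field(lattice, site, barrier, positioning)
    model <- kinetic_model(field,
                           D = k$D %||% 1,
                           enzyme_rate = k$enzyme_rate %||% 0,
                           enzyme_range_bp = k$enzyme_range %||% 332L,
                           r_const = k$r_const %||% 0,
                           mu = k$mu %||% 0)
  }
  protocol <- if (!is.null(cfg$protocol)) {
    p <- cfg$protocol
    simulation_protocol(n_replicas = p$n_replicas %||% 1L,
                        t_end = p$t_end %||% 5000,
                        burn_in = p$burn_in,
                        sample_interval = p$sample_interval %||% 2,
                        initial_n = p$initial_n %||% 86L,
                        seed = p$seed %||% 1L)
  } else NULL
  list(model = model, protocol = protocol, preset = cfg$preset, raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read DNA sequences from a FASTA file
#'
#' @param path Path to a (multi-record, possibly lowercase) FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write / read an ensemble as TSV
#'
#' Columns `replica`, `time`, `dyads` (comma-joined 0-based positions); the
#' lattice geometry is stored in `#`-prefixed header lines so that
#' `read_ensemble_tsv(write_ensemble_tsv(x))` restores the samples exactly.
#' @param record An `ensemble_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lat <- record$lattice
  writeLines(sprintf("# nucsim ensemble: length_bp=%d tss_index=%d footprint_bp=%d",
                     lat$length_bp, lat$tss_index, lat$footprint_bp), con)
  writeLines("replica\ttime\tdyads", con)
  dy <- vapply(record$samples, function(d) paste(d, collapse = ","), character(1))
  writeLines(sprintf("%d\t%g\t%s", record$replica, record$time, dy), con)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# nucsim ensemble"))
    stop("parse error at line 1: missing ensemble header")
  m <- regmatches(lines[1],
                  regexec("length_bp=(\\d+) tss_index=(\\d+) footprint_bp=(\\d+)",
                          lines[1]))[[1]]
  if (length(m) != 4L) stop("parse error at line 1: malformed geometry")
  lattice <- lattice_spec(as.integer(m[2]), tss_index = as.integer(m[3]),
                          footprint_bp = as.integer(m[4]))
  if (length(lines) < 2L || lines[2] != "replica\ttime\tdyads")
    stop("parse error at line 2: missing column header")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  badlen <- which(lengths(parts) != 3L)
  if (length(badlen))
    stop("parse error at line ", badlen[1] + 2L, ": expected 3 fields")
  samples <- lapply(parts, function(p) {
    if (p[3] == "") integer(0) else as.integer(strsplit(p[3], ",")[[1]])
  })
  structure(list(samples = samples,
                 replica = as.integer(vapply(parts, `[`, "", 1L)),
                 time = as.numeric(vapply(parts, `[`, "", 2L)),
                 lattice = lattice, model = NULL, protocol = NULL,
                 fingerprint = list(source = path)),
            class = "ensemble_record")
}

#' Write a density profile, RDF, or pair-attraction table as TSV
#'
#' @param x A `density_profile`, `radial_distribution`, or
#'   [pair_potential()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  df <- if (inherits(x, "density_profile")) {
    data.frame(offset = x$offset, density = x$density)
  } else if (inherits(x, "radial_distribution")) {
    data.frame(distance_bp = x$r, g = x$g)
  } else if (inherits(x, "pair_potential")) {
    att <- x$attraction %||% numeric(0)
    data.frame(gap_bp = x$hard_core_bp + seq_along(att) - 1L,
               energy_kBT = att)
  } else if (is.data.frame(x)) x
  else stop("unsupported object for write_tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment table (TSV)
#'
#' Expects columns `gene_id`, `molecule_id`, `start`, `end`.
#' @param path Input path.
#' @return A data.frame.
#' @export
read_fragments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "molecule_id", "start", "end")
  if (!all(req %in% names(df)))
    stop("fragment table needs columns: ", paste(req, collapse = ", "))
  df
}

#' Write a run manifest
#'
#' Records every parameter and seed of a simulation run as YAML, sufficient
#' to reproduce it bit for bit.
#' @param record An `ensemble_record` from [run_simulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(record, path) {
  m <- record$model
  manifest <- list(
    package = "nucsim",
    version = as.character(utils::packageVersion("nucsim")),
    lattice = record$lattice[c("length_bp", "tss_index", "footprint_bp")],
    kinetics = list(D = m$D, enzyme_rate = m$enzyme_rate,
                    enzyme_range_bp = m$enzyme_range_bp,
                    r_const = m$r_const, mu = m$mu,
                    attraction = as.numeric(m$pair$attraction %||% numeric(0))),
    protocol = unclass(record$protocol),
    fingerprint = record$fingerprint[c("engine", "seed_scheme")],
    child_seeds = as.integer(record$fingerprint$child_seeds))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
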