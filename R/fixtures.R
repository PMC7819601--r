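#' Generate a DNA sequence with controlled dinucleotide phasing
#'
#' Random uniform background with an in-phase dinucleotide of the given
#' class planted every `period` bp with probability `strength`.  Strength 0
#' yields an i.i.d. uniform sequence.  Seed-deterministic.
#'
#' @param length Sequence length in bp (>= 147).
#' @param period Planting period in bp (default 10).
#' @param class Dinucleotide planted (default "AA").
#' @param strength Planting probability per period position in [0, 1].
#' @param seed Integer seed.
#' @return A character scalar DNA sequence.
#' @export
generate_sequence <- function(length, period = 10L, class = "AA",
                              strength = 0, seed = 1L) {
  if (length < 147L) stop("sequence length must be >= 147")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  if (strength > 0) {
    starts <- seq(1L, length - 1L, by = period)
    plant <- starts[stats::runif(length(starts)) < strength]
    ch <- strsplit(class, "")[[1L]]
    s[plant] <- ch[1L]
    s[plant + 1L] <- ch[2L]
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  paste(s, collapse = "")
}

#' Generate a synthetic single-molecule fragment cohort
#'
#' Emulates single-molecule nucleosome-array data with known ground truth:
#' each molecule carries a nucleosome array whose +1 dyad is drawn from a
#' normal distribution (per-gene mean, common sd), with downstream
#' nucleosomes spaced by `repeat_length`, per-nucleosome dropout, fragment
#' lengths jittered within the mononucleosome range, and optional
#' out-of-range contaminant fragments.  Seed-deterministic.
#'
#' @param n_genes Number of genes.
#' @param molecules_per_gene Molecules (cells) per gene.
#' @param plus_one_mean Mean +1 dyad position in bp (scalar, or one per
#'   gene).
#' @param plus_one_sd True per-gene standard deviation of the +1 position.
#' @param repeat_length Nucleosome repeat length in bp (default 165).
#' @param downstream_count Nucleosomes per array (default 6).
#' @param missing_rate Per-nucleosome dropout probability in [0, 1].
#' @param length_jitter If `TRUE`, fragment lengths are uniform in
#'   140..180; otherwise all 147.
#' @param contaminant_rate Expected number of out-of-range fragments
#'   (length < 140 or > 180) per molecule.
#' @param seed Integer seed.
#' @return A data.frame `gene_id`, `molecule_id`, `start`, `end`.
#' @export
generate_fragment_cohort <- function(n_genes = 50L, molecules_per_gene = 50L,
                                     plus_one_mean = 150, plus_one_sd = 40,
                                     repeat_length = 165L,
                                     downstream_count = 6L,
                                     missing_rate = 0, length_jitter = TRUE,
                                     contaminant_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, contaminant_rate >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  gmean <- rep_len(plus_one_mean, n_genes)
  rows <- vector("list", n_genes * molecules_per_gene)
  ri <- 0L
  for (g in seq_len(n_genes)) {
    for (m in seq_len(molecules_per_gene)) {
      p1 <- round(stats::rnorm(1, gmean[g], plus_one_sd))
      dyads <- p1 + repeat_length * (0:(downstream_count - 1L))
      keep <- stats::runif(downstream_count) >= missing_rate
      dyads <- dyads[keep]
      lens <- if (length_jitter) sample(140:180, length(dyads), replace = TRUE)
              else rep(147L, length(dyads))
      n_cont <- stats::rpois(1, contaminant_rate)
      if (n_cont > 0) {
        cpos <- sample(0:1000, n_cont, replace = TRUE)
        clen <- sample(c(60:120, 200:400), n_cont, replace = TRUE)
        dyads <- c(dyads, cpos)
        lens <- c(lens, clen)
      }
      if (!length(dyads)) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene_id = sprintf("gene_%03d", g),
        molecule_id = sprintf("mol_%03d", m),
        start = dyads - floor(lens / 2),
        end = dyads - floor(lens / 2) + lens)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}
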