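# Synthetic-data generator.  Two layers mirror the pipeline's two inputs:
# octoploid read counts at sites governed by two tetrasomic paralogous
# loci, and multi-population genotype matrices with Balding-Nichols
# controlled divergence.

#' Expected minor-allele read fraction under the two-tetrasomic-loci model
#'
#' "High chromosome number" sturgeons carry two paralogous tetrasomic sets
#' (eight similar genomic regions in total).  A site's total B-allele
#' dosage d of 8 determines the expected B read fraction
#' \deqn{p = (d/8)(1-e) + (1-d/8)e,}
#' where e is the symmetric per-read sequencing error rate.  At d = 2
#' (one paralog fixed AAAA, the other balanced-heterozygous AABB) and
#' e = 0 this gives p = 1/4, i.e. the diagnostic 3:1 major:minor ratio;
#' d = 4 (alternatively fixed paralogs, a PSV) gives the 1:1 ratio.
#'
#' @param dosage Integer(s) in 0..8: copies of allele B among the 8.
#' @param error_rate Per-read symmetric error probability in \[0, 0.5).
#' @return Expected B-allele read fraction(s).
#' @export
expected_b_fraction <- function(dosage, error_rate = 0) {
  stopifnot(all(dosage >= 0 & dosage <= 8),
            error_rate >= 0, error_rate < 0.5)
  (dosage / 8) * (1 - error_rate) + (1 - dosage / 8) * error_rate
}

#' Expected major:minor read ratio for a dosage configuration
#'
#' @inheritParams expected_b_fraction
#' @return `max(p, 1-p) / min(p, 1-p)` with p from
#'   [expected_b_fraction()]; `Inf` for monomorphic configurations at
#'   error rate 0.
#' @export
expected_major_minor_ratio <- function(dosage, error_rate = 0) {
  p <- expected_b_fraction(dosage, error_rate)
  pmax(p, 1 - p) / pmin(p, 1 - p)
}

#' Simulate read counts at octoploid sites
#'
#' Draws B-allele read counts from Binomial(depth, p) with p from
#' [expected_b_fraction()]: each site has a true total B dosage
#' d = dosage_paralog1 + dosage_paralog2 over its two tetrasomic paralog
#' sets.  The true dosage is attached for downstream evaluation of the
#' classifier.
#'
#' @param dosage_paralog1,dosage_paralog2 Integer vectors in 0..4: B copies
#'   in each tetrasomic set (recycled to a common length).
#' @param depth Positive integer read depth(s).
#' @param error_rate Symmetric per-read error probability in \[0, 0.5).
#' @param seed Integer seed; all randomness flows from it.
#' @param est_prefix Prefix for generated EST ids.
#' @return A `site_counts` data frame with an extra `true_dosage` column.
#' @export
sim_octoploid_sites <- function(dosage_paralog1, dosage_paralog2,
                                depth, error_rate = 0.01, seed = 1L,
                                est_prefix = "SIM") {
  stopifnot(all(dosage_paralog1 %in% 0:4), all(dosage_paralog2 %in% 0:4),
            all(depth >= 1), error_rate >= 0, error_rate < 0.5)
  n <- max(length(dosage_paralog1), length(dosage_paralog2), length(depth))
  d1 <- rep_len(as.integer(dosage_paralog1), n)
  d2 <- rep_len(as.integer(dosage_paralog2), n)
  dp <- rep_len(as.integer(depth), n)
  d <- d1 + d2
  p <- expected_b_fraction(d, error_rate)
  count_b <- withr::with_seed(seed, stats::rbinom(n, dp, p))
  out <- site_counts(est_id = sprintf("%s%06d", est_prefix, seq_len(n)),
                     position = 1L, allele_a = "A", allele_b = "G",
                     count_a = dp - count_b, count_b = count_b)
  out$true_dosage <- d
  out
}

#' Population simulation configuration
#'
#' Defaults emulate the sturgeon study design: five populations
#' (Volga-river, Ural-river and Azov-sea Russian sturgeon, Persian
#' sturgeon, Siberian sturgeon) of sizes 14, 14, 5, 28 and 5, genotyped at
#' 123 biallelic loci.  Divergence is per-population Balding-Nichols drift
#' F from a shared ancestral pool; the defaults give two nearly
#' indistinguishable river populations, a slightly drifted sea population,
#' and two well-separated outgroups.
#'
#' @param n_pops Number of populations (>= 2).
#' @param pop_sizes Integer vector of individuals per population.
#' @param n_loci Number of biallelic loci.
#' @param divergence Per-population drift parameter F in (0, 1); scalar
#'   recycled, or 0 for exact copies of the ancestral frequency.
#' @param ancestral_freq_range Interval within (0, 1) for the uniform
#'   ancestral allele frequency.
#' @param missing_rate Probability a genotype call is missing.
#' @param pop_labels Optional population labels.
#' @return A `pop_sim_config` list.
#' @export
pop_sim_config <- function(n_pops = 5L,
                           pop_sizes = c(14L, 14L, 5L, 28L, 5L),
                           n_loci = 123L,
                           divergence = c(0.02, 0.02, 0.05, 0.15, 0.30),
                           ancestral_freq_range = c(0.1, 0.9),
                           missing_rate = 0,
                           pop_labels = NULL) {
  n_pops <- as.integer(n_pops)
  if (n_pops < 2L) stop("need at least 2 populations")
  if (length(pop_sizes) != n_pops)
    stop("length(pop_sizes) must equal n_pops")
  if (any(pop_sizes < 1L)) stop("population sizes must be positive")
  divergence <- rep_len(divergence, n_pops)
  if (any(divergence < 0 | divergence >= 1))
    stop("divergence F must lie in [0, 1)")
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] > ancestral_freq_range[2])
    stop("ancestral_freq_range must be an interval within (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_pops))
  structure(list(n_pops = n_pops, pop_sizes = as.integer(pop_sizes),
                 n_loci = as.integer(n_loci), divergence = divergence,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate,
                 pop_labels = as.character(pop_labels)),
            class = "pop_sim_config")
}

#' Simulate per-population allele frequencies (Balding-Nichols model)
#'
#' Each locus draws an ancestral B frequency p0 uniformly on
#' `ancestral_freq_range`; population k's frequency is then
#' Beta(p0 (1-F_k)/F_k, (1-p0)(1-F_k)/F_k), so that population k has
#' expected Wright F_ST of F_k against the ancestral pool.  F = 0
#' populations copy p0 exactly (no division by zero).
#'
#' @param config A [pop_sim_config()].
#' @param seed Integer seed.
#' @return A `pop_freqs` object (see [allele_frequencies()]) with `n_obs`
#'   set to `Inf` (parametric frequencies, not sample estimates).
#' @export
sim_population_frequencies <- function(config = pop_sim_config(),
                                       seed = 1L) {
  stopifnot(inherits(config, "pop_sim_config"))
  withr::with_seed(seed, {
    p0 <- stats::runif(config$n_loci, config$ancestral_freq_range[1],
                       config$ancestral_freq_range[2])
    freq <- matrix(NA_real_, config$n_pops, config$n_loci)
    for (k in seq_len(config$n_pops)) {
      f <- config$divergence[k]
      freq[k, ] <- if (f == 0) p0 else
        stats::rbeta(config$n_loci,
                     p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
    pop_freqs(freq,
              n_obs = matrix(Inf, config$n_pops, config$n_loci),
              pops = config$pop_labels,
              loci = sprintf("L%03d", seq_len(config$n_loci)))
  })
}

#' Simulate a genotype matrix from population allele frequencies
#'
#' Hardy-Weinberg sampling of functionally diploid calls: each genotype is
#' Binomial(2, freq); missing entries are injected independently at
#' `missing_rate`.
#'
#' @param freqs A `pop_freqs` object (rows = populations).
#' @param pop_sizes Integer vector, individuals per population.
#' @param missing_rate Probability of a missing call.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
sim_genotypes <- function(freqs, pop_sizes, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(freqs, "pop_freqs"),
            length(pop_sizes) == length(freqs$pops))
  n_loci <- length(freqs$loci)
  withr::with_seed(seed, {
    rows <- list(); inds <- character(); pops <- character()
    for (k in seq_along(freqs$pops)) {
      nk <- pop_sizes[k]
      g <- matrix(stats::rbinom(nk * n_loci, 2L,
                                rep(freqs$freq[k, ], each = nk)),
                  nrow = nk)
      rows[[k]] <- g
      inds <- c(inds, sprintf("%s_%02d", freqs$pops[k], seq_len(nk)))
      pops <- c(pops, rep(freqs$pops[k], nk))
    }
    calls <- do.call(rbind, rows)
    if (missing_rate > 0) {
      drop <- stats::runif(length(calls)) < missing_rate
      calls[drop] <- NA_integer_
    }
    genotype_matrix(calls, inds, pops, freqs$loci)
  })
}

#' One-call study-scale simulation
#'
#' Convenience wrapper: frequencies then genotypes under one seed, at the
#' study defaults of [pop_sim_config()].
#'
#' @param config A [pop_sim_config()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
sim_study_matrix <- function(config = pop_sim_config(), seed = 1L) {
  freqs <- sim_population_frequencies(config, seed = seed)
  sim_genotypes(freqs, config$pop_sizes, config$missing_rate,
                seed = seed + 1L)
}
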