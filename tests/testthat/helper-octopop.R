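# Shared fixture builders; everything is generated in code.

# Small handmade genotype matrix: 2 populations x 2 individuals, 1 locus,
# calls spanning the whole alphabet {0, 1, 2, NA}.
toy_matrix_1locus <- function() {
  genotype_matrix(matrix(c(0L, 1L, 2L, NA_integer_), ncol = 1),
                  paste0("ind", 1:4), rep(c("popA", "popB"), each = 2),
                  "L1")
}

# Two populations fixed for alternative alleles at every locus.
fixed_alt_matrix <- function(n_per_pop = 10L, n_loci = 5L) {
  genotype_matrix(rbind(matrix(0L, n_per_pop, n_loci),
                        matrix(2L, n_per_pop, n_loci)),
                  sprintf("i%02d", seq_len(2 * n_per_pop)),
                  rep(c("popA", "popB"), each = n_per_pop),
                  sprintf("L%02d", seq_len(n_loci)))
}

# Random valid genotype matrix for round-trip property tests.
random_matrix <- function(seed, n_pops = 3L, max_ind = 6L, max_loci = 8L,
                          missing_rate = 0.1) {
  withr::with_seed(seed, {
    sizes <- sample.int(max_ind, n_pops, replace = TRUE)
    n <- sum(sizes); L <- sample.int(max_loci, 1)
    calls <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE), n, L)
    calls[stats::runif(n * L) < missing_rate] <- NA_integer_
    genotype_matrix(calls, sprintf("s%03d", seq_len(n)),
                    rep(paste0("pop", seq_len(n_pops)), sizes),
                    sprintf("loc%02d", seq_len(L)))
  })
}

# Parametric frequencies with planted structure: `n_div` divergent loci
# with population-specific frequencies, the rest identical across pops.
planted_freqs <- function(n_pops = 4L, n_div = 10L, n_bg = 113L,
                          seed = 99L) {
  withr::with_seed(seed, {
    L <- n_div + n_bg
    p0 <- stats::runif(n_bg, 0.2, 0.8)
    freq <- matrix(rep(c(stats::runif(n_div, 0, 1), p0), each = n_pops),
                   n_pops, L)
    # divergent (high-F) loci: near-fixed in one population, rare in the
    # rest, cycling over populations
    for (l in seq_len(n_div)) {
      freq[, l] <- 0.05 + stats::runif(n_pops, 0, 0.05)
      k0 <- (l - 1L) %% n_pops + 1L
      freq[k0, l] <- 0.9 + stats::runif(1, 0, 0.05)
    }
    freq <- pmin(pmax(freq, 0.01), 0.99)
    pop_freqs(freq, matrix(Inf, n_pops, L),
              paste0("pop", seq_len(n_pops)),
              c(sprintf("DIV%02d", seq_len(n_div)),
                sprintf("BG%03d", seq_len(n_bg))))
  })
}

# Independent binomial log-likelihood (written from the closed form, not
# via dbinom) for the dosage-classifier oracle.
oracle_dosage_loglik <- function(count_b, depth, dosage, e) {
  p <- (dosage / 8) * (1 - e) + (1 - dosage / 8) * e
  term <- function(k, p) if (k == 0) 0 else k * log(p)
  lchoose(depth, count_b) + term(count_b, p) + term(depth - count_b, 1 - p)
}
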