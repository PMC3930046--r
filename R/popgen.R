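# Population-genetic computations on the filtered panel: per-population
# allele frequencies, Latter's FST genetic distance, the Weir-Cockerham
# (1984) theta estimator, and the UPGMA population tree with locus
# bootstrap.

#' Per-population allele frequency container
#'
#' @param freq Numeric matrix, populations x loci, of B-allele
#'   frequencies in \[0, 1\] (`NA` where a population has no data).
#' @param n_obs Matrix of non-missing call counts per population and
#'   locus (`Inf` for parametric frequencies from the simulator).
#' @param pops Population labels (rows).
#' @param loci Locus ids (columns).
#' @return A `pop_freqs` object.
#' @export
pop_freqs <- function(freq, n_obs, pops, loci) {
  freq <- as.matrix(freq); n_obs <- as.matrix(n_obs)
  stopifnot(nrow(freq) == length(pops), ncol(freq) == length(loci),
            all(dim(freq) == dim(n_obs)))
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  dimnames(freq) <- dimnames(n_obs) <- list(pops, loci)
  structure(list(freq = freq, n_obs = n_obs,
                 pops = as.character(pops), loci = as.character(loci)),
            class = "pop_freqs")
}

#' Compute per-population allele frequencies from a genotype matrix
#'
#' B-allele frequency per population and locus is
#' `(number of 1-calls + 2 * number of 2-calls) / (2 * n_obs)` over the
#' non-missing calls; a population with no non-missing call at a locus
#' gets `NA`, which pairwise computations skip.
#'
#' @param mat A [genotype_matrix()].
#' @return A [pop_freqs()] object, populations in first-appearance order.
#' @export
allele_frequencies <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  pops <- unique(mat$populations)
  freq <- matrix(NA_real_, length(pops), length(mat$loci))
  nobs <- matrix(0L, length(pops), length(mat$loci))
  for (k in seq_along(pops)) {
    g <- pop_calls(mat, pops[k])
    nobs[k, ] <- colSums(!is.na(g))
    tot <- colSums(g, na.rm = TRUE)
    freq[k, ] <- ifelse(nobs[k, ] > 0, tot / (2 * nobs[k, ]), NA_real_)
  }
  pop_freqs(freq, nobs, pops, mat$loci)
}

#' Latter's FST genetic distance between two populations
#'
#' With per-locus allele frequency vectors x and y over the two alleles,
#' \deqn{D = \frac{\sum_l \sum_a (x_a - y_a)^2 / 2}
#'            {\sum_l (1 - \sum_a x_a y_a)},}
#' i.e. summed squared frequency differences over expected
#' between-population heterozygosity.  For biallelic loci the per-locus
#' numerator reduces to (p_x - p_y)^2.  Loci where either population has
#' an absent frequency are excluded from both sums.  No sample-size bias
#' correction is applied.  When both populations are identically fixed at
#' every shared locus the denominator is zero and the distance is 0 by
#' convention.
#'
#' @param freqs A [pop_freqs()] object.
#' @param pop_x,pop_y Population labels or row indices.
#' @return Distance in \[0, 1\].
#' @export
latter_fst_distance <- function(freqs, pop_x, pop_y) {
  stopifnot(inherits(freqs, "pop_freqs"))
  x <- freqs$freq[pop_x, ]; y <- freqs$freq[pop_y, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no locus with defined frequencies in both populations")
  x <- x[ok]; y <- y[ok]
  num <- sum((x - y)^2)                       # = sum_a (x_a-y_a)^2 / 2
  den <- sum(1 - (x * y + (1 - x) * (1 - y)))
  if (den == 0) return(0)
  num / den
}

#' All pairwise Latter distances
#'
#' @param freqs A [pop_freqs()] object.
#' @return Symmetric matrix with zero diagonal, labelled by population.
#' @export
latter_fst_matrix <- function(freqs) {
  stopifnot(inherits(freqs, "pop_freqs"))
  n <- length(freqs$pops)
  d <- matrix(0, n, n, dimnames = list(freqs$pops, freqs$pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- latter_fst_distance(freqs, i, j)
  }
  d
}

#' Weir-Cockerham theta (FST) from a genotype matrix
#'
#' The Weir & Cockerham (1984) variance-components estimator for
#' biallelic loci, with the heterozygosity (c) component taken from the
#' observed heterozygote proportions.  Missing calls are excluded per
#' locus; loci that are monomorphic overall, or typed in fewer than two
#' populations, have undefined theta and are excluded from the multilocus
#' ratio, which is the ratio of summed a components to summed a+b+c
#' components across the remaining loci.
#'
#' @param mat A [genotype_matrix()] with >= 2 populations.
#' @return A list with `per_locus` (named numeric vector of theta, NA
#'   where undefined) and `multilocus` (scalar).
#' @export
wc_fst <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  pops <- unique(mat$populations)
  if (length(pops) < 2L) stop("need >= 2 populations")
  L <- length(mat$loci)
  a_l <- b_l <- c_l <- rep(NA_real_, L)
  bypop <- lapply(pops, function(p) pop_calls(mat, p))
  for (l in seq_len(L)) {
    n_i <- p_i <- h_i <- numeric(0)
    for (g in bypop) {
      gl <- g[, l]; gl <- gl[!is.na(gl)]
      if (length(gl) == 0L) next
      n_i <- c(n_i, length(gl))
      p_i <- c(p_i, mean(gl) / 2)
      h_i <- c(h_i, mean(gl == 1L))
    }
    r <- length(n_i)
    if (r < 2L) next
    nbar <- mean(n_i)
    if (nbar <= 1) next
    pbar <- sum(n_i * p_i) / (r * nbar)
    if (pbar == 0 || pbar == 1) next          # monomorphic overall
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a_l[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_l[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c_l[l] <- hbar / 2
  }
  denom <- a_l + b_l + c_l
  theta <- ifelse(!is.na(denom) & denom != 0, a_l / denom, NA_real_)
  names(theta) <- mat$loci
  ok <- !is.na(denom)
  list(per_locus = theta,
       multilocus = sum(a_l[ok]) / sum(denom[ok]))
}
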