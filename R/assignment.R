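# Frequency-based population assignment and informative-locus selection:
# each individual is assigned to the population in which its multilocus
# genotype has the highest Hardy-Weinberg likelihood; leave-one-out
# accuracy, resampling-based locus ranking and minimal-panel selection
# are built on that core.

# Zero-frequency correction: a reference population that happens to be
# fixed would otherwise assign -Inf to any individual carrying the other
# allele.  p = 0 is replaced by 1/(2n+1) and p = 1 by 1 - 1/(2n+1),
# where n is the number of genotyped individuals behind the estimate.
correct_freq <- function(p, n_obs) {
  eps <- 1 / (2 * n_obs + 1)
  ifelse(p <= 0, eps, ifelse(p >= 1, 1 - eps, p))
}

#' Per-population assignment log-likelihood of one individual
#'
#' Sums, over the locus subset, the log Hardy-Weinberg genotype
#' probability of the individual's call given each population's B-allele
#' frequency p: genotype 0 has probability (1-p)^2, genotype 1 has
#' 2p(1-p), genotype 2 has p^2.  Zero and unit frequencies are corrected
#' to 1/(2n+1) (and 1 - 1/(2n+1)) before evaluation; missing genotypes
#' are skipped.  When the individual belongs to a reference population,
#' pass frequencies computed without it (the leave-one-out contract of
#' [leave_one_out_accuracy()]).
#'
#' @param genotypes Named (by locus) or positionally aligned vector of
#'   0/1/2/NA calls for one individual.
#' @param freqs A [pop_freqs()] object.
#' @param loci Locus ids (or indices) to use; must be non-empty.
#' @return Named numeric vector: log-likelihood per population.
#' @export
assignment_loglik <- function(genotypes, freqs, loci = freqs$loci) {
  stopifnot(inherits(freqs, "pop_freqs"))
  if (length(loci) == 0L) stop("locus subset must be non-empty")
  idx <- if (is.character(loci)) match(loci, freqs$loci) else as.integer(loci)
  if (anyNA(idx)) stop("unknown locus id in subset")
  g <- if (!is.null(names(genotypes))) genotypes[freqs$loci[idx]]
       else genotypes[idx]
  out <- stats::setNames(numeric(length(freqs$pops)), freqs$pops)
  for (k in seq_along(freqs$pops)) {
    p <- freqs$freq[k, idx]
    n <- freqs$n_obs[k, idx]
    ok <- !is.na(g) & !is.na(p)
    pk <- correct_freq(p[ok], n[ok])
    gk <- g[ok]
    out[k] <- sum(ifelse(gk == 0L, 2 * log(1 - pk),
                  ifelse(gk == 1L, log(2) + log(pk) + log(1 - pk),
                         2 * log(pk))))
  }
  out
}

# Frequencies with one individual removed from its own population.
loo_freqs <- function(freqs_all, mat, ind_idx) {
  pop <- mat$populations[ind_idx]
  k <- match(pop, freqs_all$pops)
  g <- mat$calls[ind_idx, ]
  f <- freqs_all$freq; n <- freqs_all$n_obs
  ok <- !is.na(g)
  n_new <- n[k, ] - ifelse(ok, 1L, 0L)
  tot <- f[k, ] * 2 * n[k, ]
  tot[ok] <- tot[ok] - g[ok]
  f[k, ] <- ifelse(n_new > 0, tot / (2 * n_new), NA_real_)
  n[k, ] <- n_new
  pop_freqs(pmin(pmax(f, 0), 1), n, freqs_all$pops, freqs_all$loci)
}

#' Leave-one-out assignment accuracy
#'
#' Assigns every individual to the population maximizing its
#' [assignment_loglik()], with its own population's frequencies
#' recomputed without it.  Ties in the maximum leave the individual
#' unassigned and count as incorrect (conservative).  Accuracy is
#' invariant to individual and locus order.
#'
#' @param mat A [genotype_matrix()]; every population needs >= 2
#'   individuals.
#' @param loci Locus ids or indices to use (default all).
#' @return An `assignment_result` list: `assignments` data frame
#'   (individual, true and assigned population, correct flag),
#'   `confusion` matrix (true x assigned, with an `<unassigned>`
#'   column), `overall_accuracy`, and `per_pop_accuracy`.
#' @export
leave_one_out_accuracy <- function(mat, loci = mat$loci) {
  stopifnot(inherits(mat, "genotype_matrix"))
  sizes <- table(mat$populations)
  if (any(sizes < 2L))
    stop("population(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  freqs_all <- allele_frequencies(mat)
  pops <- freqs_all$pops
  n <- length(mat$individuals)
  assigned <- character(n)
  for (i in seq_len(n)) {
    fl <- loo_freqs(freqs_all, mat, i)
    ll <- assignment_loglik(mat$calls[i, ], fl, loci)
    best <- max(ll)
    top <- names(ll)[ll >= best - 1e-9]
    assigned[i] <- if (length(top) == 1L) top else "<unassigned>"
  }
  truth <- mat$populations
  correct <- assigned == truth
  confusion <- table(factor(truth, levels = pops),
                     factor(assigned, levels = c(pops, "<unassigned>")))
  per_pop <- vapply(pops, function(p) mean(correct[truth == p]),
                    numeric(1))
  structure(list(
    assignments = data.frame(individual = mat$individuals,
                             true_pop = truth, assigned_pop = assigned,
                             correct = correct, stringsAsFactors = FALSE),
    confusion = confusion,
    overall_accuracy = mean(correct),
    per_pop_accuracy = per_pop),
    class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("leave-one-out assignment: overall accuracy %.3f\n",
              x$overall_accuracy))
  print(round(x$per_pop_accuracy, 3))
  invisible(x)
}

#' Rank loci by assignment power over resampled datasets
#'
#' Emulates resampling-based informative-locus selection: several
#' synthetic datasets are drawn by resampling individuals from the
#' observed per-population genotype frequencies up to stated total sizes
#' (default 100, 100, 100 and 500, allocated to populations in proportion
#' to their observed sizes, at least 2 each).  In each dataset every
#' locus is scored by its single-locus mean leave-one-out log-likelihood
#' ratio (true population versus the best other population) and loci are
#' ordered by descending score.  The consensus set is the loci appearing
#' in the top `top_k` of every dataset, ordered by mean rank.
#'
#' @param mat A [genotype_matrix()].
#' @param resample_sizes Total individuals per resampled dataset.
#' @param top_k Depth of each per-dataset list used for the consensus.
#' @param seed Integer seed.
#' @return A `locus_ranking` list: `per_dataset` (list of ordered locus
#'   id vectors), `scores` (loci x datasets matrix), `consensus`
#'   (ordered locus ids present in every per-dataset top-`top_k`).
#' @export
rank_loci <- function(mat, resample_sizes = c(100L, 100L, 100L, 500L),
                      top_k = 12L, seed = 1L) {
  stopifnot(inherits(mat, "genotype_matrix"),
            length(resample_sizes) >= 1, top_k >= 1)
  freqs_obs <- allele_frequencies(mat)
  pops <- freqs_obs$pops
  obs_sizes <- as.integer(table(factor(mat$populations, levels = pops)))
  L <- length(mat$loci)
  scores <- matrix(NA_real_, L, length(resample_sizes),
                   dimnames = list(mat$loci, NULL))
  per_dataset <- vector("list", length(resample_sizes))
  withr::with_seed(seed, {
    for (s in seq_along(resample_sizes)) {
      sizes <- pmax(2L, round(resample_sizes[s] * obs_sizes /
                                sum(obs_sizes)))
      sim <- sim_genotypes(freqs_obs, sizes, missing_rate = 0,
                           seed = sample.int(.Machine$integer.max, 1))
      scores[, s] <- locus_llr_scores(sim)
      per_dataset[[s]] <-
        mat$loci[order(-scores[, s], mat$loci)]
    }
  })
  tops <- lapply(per_dataset, utils::head, top_k)
  consensus <- Reduce(intersect, tops)
  if (length(consensus)) {
    mean_rank <- vapply(consensus, function(l)
      mean(vapply(per_dataset, function(o) match(l, o), numeric(1))),
      numeric(1))
    consensus <- consensus[order(mean_rank, consensus)]
  }
  structure(list(per_dataset = per_dataset, scores = scores,
                 consensus = consensus, top_k = top_k),
            class = "locus_ranking")
}

# Per-locus mean leave-one-out log-likelihood ratio: for each individual,
# the single-locus loglik of its true population minus the best other.
locus_llr_scores <- function(mat) {
  freqs_all <- allele_frequencies(mat)
  pops <- freqs_all$pops
  n <- length(mat$individuals); L <- length(mat$loci)
  llr <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    fl <- loo_freqs(freqs_all, mat, i)
    k_true <- match(mat$populations[i], pops)
    g <- mat$calls[i, ]
    ll <- matrix(-Inf, length(pops), L)
    for (k in seq_along(pops)) {
      p <- correct_freq(fl$freq[k, ], fl$n_obs[k, ])
      ll[k, ] <- ifelse(is.na(g) | is.na(fl$freq[k, ]), NA_real_,
                 ifelse(g == 0L, 2 * log(1 - p),
                 ifelse(g == 1L, log(2) + log(p) + log(1 - p),
                        2 * log(p))))
    }
    other <- apply(ll[-k_true, , drop = FALSE], 2, max)
    llr[i, ] <- ll[k_true, ] - other
  }
  colMeans(llr, na.rm = TRUE)
}

#' Select the smallest informative panel reaching a target accuracy
#'
#' Walks prefixes of the consensus ranking, evaluating leave-one-out
#' overall accuracy, and returns the smallest prefix meeting
#' `target_accuracy`.  When no prefix reaches the target the full
#' consensus set is returned with `reached = FALSE`.
#'
#' @param mat A [genotype_matrix()].
#' @param ranking A `locus_ranking` from [rank_loci()], or a character
#'   vector of ordered locus ids.
#' @param target_accuracy Target overall accuracy in (0, 1\].
#' @return A list: `loci` (the selected prefix), `accuracy` (achieved
#'   leave-one-out overall accuracy), `reached` (logical).
#' @export
select_min_panel <- function(mat, ranking, target_accuracy) {
  stopifnot(target_accuracy > 0, target_accuracy <= 1)
  ordered <- if (inherits(ranking, "locus_ranking")) ranking$consensus
             else as.character(ranking)
  if (length(ordered) == 0L) stop("empty ranking")
  acc <- NA_real_
  for (k in seq_along(ordered)) {
    acc <- leave_one_out_accuracy(mat, ordered[seq_len(k)])$overall_accuracy
    if (acc >= target_accuracy)
      return(list(loci = ordered[seq_len(k)], accuracy = acc,
                  reached = TRUE))
  }
  list(loci = ordered, accuracy = acc, reached = FALSE)
}
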