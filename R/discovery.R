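# SNP discovery under the two-tetrasomic-loci dosage model.
#
# An octoploid site carries 8 allele copies split over two tetrasomic
# paralog sets.  Read counts at a candidate site are modelled as
# Binomial(depth, p_d) with p_d = (d/8)(1-e) + (1-d/8)e for total B
# dosage d in 0..8.  Maximum-likelihood dosage selection over the nine
# dosages operationalizes the "allele ratio close to 3:1" rule: at high
# coverage d = 2 or 6 is exactly the 3:1 / 1:3 configuration (one paralog
# fixed, the other balanced-heterozygous), while d = 4 is the 1:1
# signature of alternatively fixed paralogs (a paralogous sequence
# variant, not a usable SNP).

DOSAGE_CLASSES <- c(`0` = "monomorphic", `1` = "other_heterozygous",
                    `2` = "candidate_snp", `3` = "other_heterozygous",
                    `4` = "psv", `5` = "other_heterozygous",
                    `6` = "candidate_snp", `7` = "other_heterozygous",
                    `8` = "monomorphic")

SITE_CLASS_LEVELS <- c("monomorphic", "candidate_snp", "psv",
                       "other_heterozygous", "low_coverage")

#' Classify candidate sites under the octoploid dosage model
#'
#' For each site with depth >= `min_coverage`, computes the binomial
#' log-likelihood of `count_b` for every total B dosage d in 0..8 (success
#' probability `(d/8)(1-e) + (1-d/8)e`), takes the maximum-likelihood
#' dosage, and maps it to a class: d 0 or 8 = `monomorphic`; d 4 = `psv`
#' (1:1 ratio, divergent paralogs); d 2 or 6 = `candidate_snp` (the 3:1
#' configuration, one fixed and one polymorphic paralog); odd d =
#' `other_heterozygous`.  Likelihood ties are broken toward
#' `other_heterozygous` (the conservative class), with the tied dosage
#' closest to 4 reported.  Sites below `min_coverage` (including zero
#' depth) are `low_coverage`.
#'
#' @param sites A `site_counts` data frame ([read_site_counts()] or
#'   [site_counts()]).
#' @param error_rate Symmetric per-read error probability in \[0, 0.5).
#' @param min_coverage Minimum read depth for classification (default 100,
#'   the panel-design threshold).
#' @return A `site_classification` data frame: the input columns plus
#'   `depth`, `mle_dosage` (NA for low-coverage sites), `site_class`, and
#'   `lik_margin` (log-likelihood of best minus runner-up dosage).  The
#'   9-column matrix of per-dosage log-likelihoods is attached as
#'   attribute `"log_likelihoods"`.
#' @export
classify_sites <- function(sites, error_rate = 0.01, min_coverage = 100L) {
  stopifnot(inherits(sites, "data.frame"),
            error_rate >= 0, error_rate < 0.5, min_coverage >= 1)
  n <- nrow(sites)
  depth <- sites$count_a + sites$count_b
  p_d <- expected_b_fraction(0:8, error_rate)
  ll <- matrix(NA_real_, n, 9L,
               dimnames = list(NULL, paste0("d", 0:8)))
  for (j in 1:9)
    ll[, j] <- stats::dbinom(sites$count_b, depth, p_d[j], log = TRUE)
  mle <- integer(n); cls <- character(n); margin <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (depth[i] < min_coverage) {
      mle[i] <- NA_integer_; cls[i] <- "low_coverage"; next
    }
    lli <- ll[i, ]
    best <- max(lli)
    ties <- which(lli >= best - 1e-12) - 1L   # dosages, 0-based
    if (length(ties) > 1L) {
      # conservative: report as other_heterozygous, dosage nearest 4
      d <- ties[which.min(abs(ties - 4L))]
      mle[i] <- d; cls[i] <- "other_heterozygous"
    } else {
      d <- ties
      mle[i] <- d; cls[i] <- DOSAGE_CLASSES[[as.character(d)]]
    }
    margin[i] <- best - max(lli[-(d + 1L)])
  }
  out <- sites
  out$depth <- depth
  out$mle_dosage <- mle
  out$site_class <- factor(cls, levels = SITE_CLASS_LEVELS)
  out$lik_margin <- margin
  class(out) <- c("site_classification", "data.frame")
  attr(out, "log_likelihoods") <- ll
  out
}

#' Select the best-scoring SNP candidates for a genotyping panel
#'
#' Keeps only `candidate_snp` sites from [classify_sites()] and ranks them
#' by descending coverage, then by descending likelihood margin (best
#' dosage against the runner-up), then by site id — a deterministic order.
#' The list is truncated to `max_panel` entries (default 384, a GoldenGate
#' panel size).
#'
#' @inheritParams classify_sites
#' @param max_panel Maximum number of panel candidates (>= 1).
#' @return A `site_classification` data frame of at most `max_panel`
#'   candidate sites in panel rank order; empty (zero rows) when no site
#'   qualifies.
#' @export
call_candidates <- function(sites, error_rate = 0.01, min_coverage = 100L,
                            max_panel = 384L) {
  stopifnot(max_panel >= 1)
  cl <- classify_sites(sites, error_rate, min_coverage)
  keep <- which(cl$site_class == "candidate_snp")
  cl <- cl[keep, , drop = FALSE]
  attr(cl, "log_likelihoods") <- NULL
  site_id <- if (nrow(cl)) paste0(cl$est_id, ".", cl$position)
             else character(0)
  ord <- order(-cl$depth, -cl$lik_margin, site_id)
  cl <- cl[ord, , drop = FALSE]
  cl <- utils::head(cl, max_panel)
  rownames(cl) <- NULL
  cl
}

#' Tally sites by coverage threshold
#'
#' For each threshold, counts sites with depth >= threshold, and how many
#' of those classify as heterozygous (candidate_snp, psv or
#' other_heterozygous, classified without a coverage gate).  Counts are
#' monotone non-increasing in the threshold.
#'
#' @inheritParams classify_sites
#' @param thresholds Non-empty integer vector of minimum depths.
#' @return A data frame with columns `threshold`, `n_total`,
#'   `n_heterozygous`.
#' @export
coverage_tally <- function(sites, thresholds, error_rate = 0.01) {
  stopifnot(length(thresholds) >= 1)
  cl <- classify_sites(sites, error_rate, min_coverage = 1L)
  het <- cl$site_class %in% c("candidate_snp", "psv", "other_heterozygous")
  data.frame(
    threshold = as.integer(thresholds),
    n_total = vapply(thresholds, function(t) sum(cl$depth >= t),
                     integer(1)),
    n_heterozygous = vapply(thresholds, function(t)
      sum(het & cl$depth >= t), integer(1)))
}
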