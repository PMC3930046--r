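# Post-genotyping locus QC: panels designed from a single discovery
# individual contain loci that turn out uninformative across the sample —
# fixed at the same allele in everyone (monomorphic) or heterozygous in
# everyone (a paralog artifact: alternatively fixed paralogous copies
# masquerading as a heterozygous genotype).  Both are excluded.

#' Drop uninformative panel loci
#'
#' A locus is dropped when its non-missing calls are all identical:
#' all 0 or all 2 = monomorphic (fixed at the same allele);
#' all 1 = heterozygous across all individuals (paralog artifact).
#' Loci with no non-missing call at all form their own `all_missing`
#' category rather than being folded into either class.  Individual order
#' and the order of retained loci are preserved.  The filter is
#' idempotent.
#'
#' @param mat A [genotype_matrix()].
#' @return A list with `matrix` (the filtered [genotype_matrix()]) and
#'   `report`, a `qc_report` list: `n_input_loci`, `n_retained`,
#'   `n_monomorphic`, `n_all_heterozygous`, `n_all_missing`, and
#'   `dropped_locus_ids` split by category.  Categories are disjoint and
#'   sum (with retained) to the input locus count.
#' @export
filter_informative_loci <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (length(mat$loci) == 0L) stop("matrix has no loci")
  category <- vapply(seq_along(mat$loci), function(j) {
    g <- mat$calls[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return("all_missing")
    u <- unique(g)
    if (length(u) > 1L) return("retained")
    if (u == 1L) "all_heterozygous" else "monomorphic"
  }, character(1))
  keep <- category == "retained"
  filtered <- genotype_matrix(mat$calls[, keep, drop = FALSE],
                              mat$individuals, mat$populations,
                              mat$loci[keep])
  report <- structure(list(
    n_input_loci = length(mat$loci),
    n_retained = sum(keep),
    n_monomorphic = sum(category == "monomorphic"),
    n_all_heterozygous = sum(category == "all_heterozygous"),
    n_all_missing = sum(category == "all_missing"),
    dropped_locus_ids = list(
      monomorphic = mat$loci[category == "monomorphic"],
      all_heterozygous = mat$loci[category == "all_heterozygous"],
      all_missing = mat$loci[category == "all_missing"])),
    class = "qc_report")
  list(matrix = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("locus QC:", x$n_input_loci, "input loci ->", x$n_retained,
      "retained\n  dropped:", x$n_monomorphic, "monomorphic,",
      x$n_all_heterozygous, "all-heterozygous,",
      x$n_all_missing, "all-missing\n")
  invisible(x)
}

#' Percentage of reads mapped, rounded half-up
#'
#' Worked-example arithmetic for read-mapping tallies: `100 * mapped /
#' total`, rounded half-up (0.5 always rounds away from zero) to
#' `decimals` places — the convention used when reporting mapping
#' fractions like "0.3% of library reads".
#'
#' @param mapped,total Non-negative counts with `mapped <= total`,
#'   `total > 0`.
#' @param decimals Number of decimal places (default 1).
#' @return The rounded percentage.
#' @export
mapping_fraction <- function(mapped, total, decimals = 1L) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(mapped < 0) || any(mapped > total))
    stop("mapped must lie in [0, total]")
  pct <- 100 * mapped / total
  scale <- 10^decimals
  floor(pct * scale + 0.5) / scale
}
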