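# UPGMA population tree and locus bootstrap.  The agglomeration is
# written out explicitly (rather than via hclust) to fix a deterministic
# lexicographic tie-break on merge pairs; tree serialization, parsing and
# clade counting are delegated to ape.

#' UPGMA tree from a population distance matrix
#'
#' Standard unweighted-pair-group agglomeration with size-weighted
#' average linkage: at each step the pair of clusters at minimal distance
#' merges at node height = distance / 2, and the merged cluster's
#' distance to any other cluster is the size-weighted mean of its parts'
#' distances.  Ties in the minimal distance are broken by the
#' lexicographically smallest (label, label) pair, where a cluster is
#' keyed by its smallest leaf label, making the output deterministic.
#' The result is rooted, binary and ultrametric.
#'
#' @param dist Symmetric numeric matrix with zero diagonal and row/column
#'   labels (e.g. from [latter_fst_matrix()]), >= 2 labels.
#' @return A `pop_tree` object: list with `phylo` (an [ape] tree with
#'   branch lengths), `heights` (named internal-node heights, named by
#'   the sorted leaf set of each clade), and `labels`.
#' @export
upgma <- function(dist) {
  dist <- as.matrix(dist)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- colnames(dist)
  if (is.null(labels)) stop("distance matrix must have labels")
  n <- length(labels)
  if (n < 2L) stop("need >= 2 labels")
  if (any(abs(dist - t(dist)) > 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix diagonal must be zero")

  # active clusters: newick fragment, height, size, key (smallest leaf)
  cl <- lapply(seq_len(n), function(i)
    list(newick = labels[i], height = 0, size = 1L, key = labels[i],
         leaves = labels[i]))
  d <- dist
  heights <- numeric(0)
  while (length(cl) > 1L) {
    m <- length(cl)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(cl[[i]]$key, cl[[j]]$key))
      better <- d[i, j] < best_d - 1e-15 ||
        (abs(d[i, j] - best_d) <= 1e-15 &&
           (is.null(best_key) ||
              key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))
      if (better) { best <- c(i, j); best_d <- d[i, j]; best_key <- key }
    }
    i <- best[1]; j <- best[2]
    if (cl[[j]]$key < cl[[i]]$key) { tmp <- i; i <- j; j <- tmp }
    h <- best_d / 2
    bi <- h - cl[[i]]$height; bj <- h - cl[[j]]$height
    merged <- list(
      newick = sprintf("(%s:%.17g,%s:%.17g)",
                       cl[[i]]$newick, bi, cl[[j]]$newick, bj),
      height = h,
      size = cl[[i]]$size + cl[[j]]$size,
      key = min(cl[[i]]$key, cl[[j]]$key),
      leaves = sort(c(cl[[i]]$leaves, cl[[j]]$leaves)))
    heights[paste(merged$leaves, collapse = "|")] <- h
    # size-weighted average linkage update
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    if (length(keep)) {
      newd[seq_along(keep), seq_along(keep)] <- d[keep, keep, drop = FALSE]
      dk <- (cl[[i]]$size * d[keep, i] + cl[[j]]$size * d[keep, j]) /
        merged$size
      newd[seq_along(keep), length(keep) + 1L] <- dk
      newd[length(keep) + 1L, seq_along(keep)] <- dk
    }
    cl <- c(cl[keep], list(merged))
    d <- newd
  }
  phy <- ape::read.tree(text = paste0(cl[[1]]$newick, ";"))
  structure(list(phylo = phy, heights = heights, labels = labels,
                 supports = NULL),
            class = "pop_tree")
}

#' @export
print.pop_tree <- function(x, ...) {
  cat("pop_tree with", length(x$labels), "populations:",
      write_newick(x), "\n")
  invisible(x)
}

#' Cophenetic distances of a population tree
#'
#' @param tree A `pop_tree`.
#' @return Symmetric matrix of leaf-to-leaf path distances.
#' @export
tree_cophenetic <- function(tree) {
  stopifnot(inherits(tree, "pop_tree"))
  ape::cophenetic.phylo(tree$phylo)
}

#' UPGMA population tree with locus bootstrap supports
#'
#' Builds the full-data tree (allele frequencies, then Latter distances,
#' then [upgma()]), then resamples loci with replacement `n_reps` times,
#' repeating the whole pipeline per replicate.  The support of each
#' internal clade of the full-data tree is the percentage of replicate
#' trees containing that clade, rounded to an integer, and is written to
#' the tree's internal node labels (the root is left blank).
#'
#' @param mat A [genotype_matrix()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the replicate locus draws flow from it.
#' @return A `pop_tree` whose `supports` element maps clades (sorted leaf
#'   sets, `|`-joined) to integer percentages, and whose `phylo` carries
#'   them as node labels.
#' @export
bootstrap_tree <- function(mat, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(mat, "genotype_matrix"), n_reps >= 1)
  freqs <- allele_frequencies(mat)
  main <- upgma(latter_fst_matrix(freqs))
  L <- length(mat$loci)
  boot <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      bmat <- genotype_matrix(mat$calls[, idx, drop = FALSE],
                              mat$individuals, mat$populations,
                              paste0("b", seq_len(L)))
      upgma(latter_fst_matrix(allele_frequencies(bmat)))$phylo
    })
  })
  counts <- ape::prop.clades(main$phylo, boot, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  supports <- as.integer(round(100 * counts / n_reps))
  phy <- main$phylo
  labs <- as.character(supports)
  root_node <- length(phy$tip.label) + 1L
  labs[root_node - length(phy$tip.label)] <- ""
  phy$node.label <- labs
  # name supports by the sorted leaf set under each internal node
  clades <- vapply(seq_len(phy$Nnode) + length(phy$tip.label),
                   function(nd) paste(sort(
                     ape::extract.clade(phy, nd)$tip.label), collapse = "|"),
                   character(1))
  sup <- stats::setNames(supports, clades)
  structure(list(phylo = phy, heights = main$heights,
                 labels = main$labels, supports = sup),
            class = "pop_tree")
}
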