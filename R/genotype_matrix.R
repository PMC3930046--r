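#' Biallelic genotype matrix with population labels
#'
#' Container for functionally diploid genotype calls at biallelic loci.
#' Octoploid sturgeons scored on a GoldenGate-style panel produce three
#' intensity clusters per locus; these are coded as diploid-like genotypes:
#' 0 (AA), 1 (AB), 2 (BB), with `NA` for missing calls.
#'
#' @param calls Integer matrix, individuals in rows and loci in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param individuals Character vector of sample ids (one per row).
#' @param populations Character vector of population labels (one per row);
#'   every label must have at least one individual.
#' @param loci Character vector of locus ids (one per column).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `individuals`, `populations`, `loci`.
#' @export
genotype_matrix <- function(calls, individuals, populations, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(individuals))
    stop("number of rows of `calls` must equal length(individuals)")
  if (nrow(calls) != length(populations))
    stop("number of rows of `calls` must equal length(populations)")
  if (ncol(calls) != length(loci))
    stop("number of columns of `calls` must equal length(loci)")
  if (anyDuplicated(individuals))
    stop("individual ids must be unique")
  if (anyDuplicated(loci))
    stop("locus ids must be unique")
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  populations <- as.character(populations)
  if (any(!nzchar(populations)) || anyNA(populations))
    stop("every individual needs a non-empty population label")
  dimnames(calls) <- list(individuals, loci)
  structure(
    list(calls = calls,
         individuals = as.character(individuals),
         populations = populations,
         loci = as.character(loci)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci;",
      length(unique(x$populations)), "populations (",
      paste(sprintf("%s=%d", names(table(x$populations)),
                    as.integer(table(x$populations))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' @export
`==.genotype_matrix` <- function(e1, e2) {
  identical(unname(e1$calls), unname(e2$calls)) &&
    identical(e1$individuals, e2$individuals) &&
    identical(e1$populations, e2$populations) &&
    identical(e1$loci, e2$loci)
}

#' Read / write a genotype matrix as CSV
#'
#' The CSV layout is one row per individual with columns `individual`,
#' `population`, then one column per locus holding 0/1/2 codes; missing
#' calls are the literal token `NA`.
#'
#' @param path File path.
#' @return `read_genotype_csv` returns a [genotype_matrix()];
#'   `write_genotype_csv` returns `path` invisibly.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual", "population")
  if (!all(need %in% names(df)))
    stop("genotype CSV must have `individual` and `population` columns")
  loci <- setdiff(names(df), need)
  if (length(loci) == 0L) stop("genotype CSV has no locus columns")
  calls <- as.matrix(df[, loci, drop = FALSE])
  genotype_matrix(calls, df$individual, df$population, loci)
}

#' @param mat A [genotype_matrix()].
#' @rdname read_genotype_csv
#' @export
write_genotype_csv <- function(mat, path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  df <- data.frame(individual = mat$individuals,
                   population = mat$populations,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mat$calls, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Rows of `mat` restricted to one population, as an integer matrix.
pop_calls <- function(mat, pop) {
  mat$calls[mat$populations == pop, , drop = FALSE]
}
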