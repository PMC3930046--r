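# Readers/writers for the external formats the pipeline touches:
# allele-count TSV, bracketed-marker tables, GenePop, Newick.

IUPAC_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Read a per-site allele read-count table
#'
#' Tab-separated table with header
#' `est_id position allele_a allele_b count_a count_b [mean_baseq]`,
#' one row per candidate site.  Positions are 1-based offsets within the
#' EST reference sequence.  Stands in for pileup-derived mismatch catalogues
#' from a transcriptome mapping.
#'
#' @param path Path to the TSV file.
#' @return A `site_counts` data frame with one row per site, columns
#'   `est_id`, `position`, `allele_a`, `allele_b`, `count_a`, `count_b`,
#'   `mean_baseq` (NA when absent from the file); input row order preserved.
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("est_id", "position", "allele_a", "allele_b",
            "count_a", "count_b")
  if (!all(need %in% names(df)))
    stop("site-count TSV must have columns: ", paste(need, collapse = ", "))
  n <- nrow(df)
  if (n == 0L) return(empty_site_counts())
  if (!"mean_baseq" %in% names(df)) df$mean_baseq <- NA_character_
  to_int <- function(col, name, min_ok) {
    suppressWarnings(v <- as.integer(df[[col]]))
    bad <- which(is.na(v) | v < min_ok)
    if (length(bad))
      stop(sprintf("invalid %s at line %d of %s", name, bad[1] + 1L, path))
    v
  }
  position <- to_int("position", "position", 1L)
  count_a <- to_int("count_a", "count_a", 0L)
  count_b <- to_int("count_b", "count_b", 0L)
  same <- which(df$allele_a == df$allele_b)
  if (length(same))
    stop(sprintf("allele_a equals allele_b at line %d of %s",
                 same[1] + 1L, path))
  out <- data.frame(est_id = df$est_id, position = position,
                    allele_a = df$allele_a, allele_b = df$allele_b,
                    count_a = count_a, count_b = count_b,
                    mean_baseq = suppressWarnings(as.numeric(df$mean_baseq)),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

empty_site_counts <- function() {
  out <- data.frame(est_id = character(), position = integer(),
                    allele_a = character(), allele_b = character(),
                    count_a = integer(), count_b = integer(),
                    mean_baseq = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Construct a site-count table in code
#'
#' @param est_id,position,allele_a,allele_b,count_a,count_b,mean_baseq
#'   Vectors recycled to a common length; see [read_site_counts()] for
#'   field meanings.
#' @return A `site_counts` data frame.
#' @export
site_counts <- function(est_id, position, allele_a = "A", allele_b = "G",
                        count_a, count_b, mean_baseq = NA_real_) {
  out <- data.frame(est_id = est_id, position = as.integer(position),
                    allele_a = allele_a, allele_b = allele_b,
                    count_a = as.integer(count_a),
                    count_b = as.integer(count_b),
                    mean_baseq = as.numeric(mean_baseq),
                    stringsAsFactors = FALSE)
  if (any(out$position < 1L)) stop("positions are 1-based (must be >= 1)")
  if (any(out$count_a < 0L) || any(out$count_b < 0L))
    stop("read counts must be non-negative")
  if (any(out$allele_a == out$allele_b))
    stop("allele_a must differ from allele_b")
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Parse a bracketed-marker table
#'
#' Each record is a line `<name>TAB<leftflank>[X/Y]<rightflank>` where
#' `name` is `<ESTaccession>.<position>` (1-based position after the final
#' period) and the square brackets enclose the two alleles of the
#' polymorphic position.  Flanks may use the full IUPAC nucleotide
#' alphabet (ACGTRYSWKMBDHVN); any positive flank length is accepted.
#'
#' @param text Character scalar (whole table) or vector of lines.
#' @return A data frame with one row per marker: `name`, `accession`,
#'   `position`, `left_flank`, `right_flank`, `allele_a`, `allele_b`.
#' @export
parse_marker_table <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("marker line ", i, ": expected <name><TAB><sequence>")
    name <- parts[1]; seq <- toupper(parts[2])
    m <- regmatches(name, regexec("^(.*)\\.([0-9]+)$", name))[[1]]
    if (length(m) != 3L)
      stop("marker line ", i, ": name must end in .<position>: ", name)
    pos <- as.integer(m[3])
    if (pos < 1L) stop("marker line ", i, ": position must be >= 1")
    bm <- regmatches(seq, regexec(
      "^([A-Z]*)\\[([A-Z])/([A-Z])\\]([A-Z]*)$", seq))[[1]]
    if (length(bm) != 5L)
      stop("marker line ", i,
           ": sequence must contain one [X/Y] bracket pair")
    left <- bm[2]; a1 <- bm[3]; a2 <- bm[4]; right <- bm[5]
    if (!nzchar(left) || !nzchar(right))
      stop("marker line ", i, ": both flanks must be non-empty")
    chars <- strsplit(paste0(left, right, a1, a2), "")[[1]]
    bad <- setdiff(chars, IUPAC_CHARS)
    if (length(bad))
      stop("marker line ", i, ": non-IUPAC character(s) ",
           paste(bad, collapse = ", "))
    if (a1 == a2) stop("marker line ", i, ": alleles must differ")
    data.frame(name = name, accession = m[2], position = pos,
               left_flank = left, right_flank = right,
               allele_a = a1, allele_b = a2, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Read the packaged sturgeon assignment-panel marker table
#'
#' Twelve published EST-derived SNP markers used for sturgeon population
#' assignment, in the bracketed-marker dialect of [parse_marker_table()].
#'
#' @return Parsed marker data frame (12 rows).
#' @export
sturgeon_panel_markers <- function() {
  path <- system.file("extdata", "sturgeon_assignment_markers.tsv",
                      package = "octopop", mustWork = TRUE)
  parse_marker_table(readLines(path))
}

#' Read and write the GenePop dialect
#'
#' Strictly biallelic GenePop files: a title line, one locus name per line
#' (or a single comma-separated line), `Pop` separators, and individual
#' lines `id , 0101 0102 ...` with two-digit allele codes.  Codes are fixed
#' to 01/02 (00 = missing): genotype 0 is `0101`, 1 is `0102`, 2 is `0202`,
#' missing is `0000`.  Any other allele code is rejected rather than
#' coerced.
#'
#' @param path File path.
#' @return `read_genepop` returns a [genotype_matrix()] whose population
#'   labels are `pop1`, `pop2`, ... in file order unless individual ids in
#'   a block share a common prefix label.  `write_genepop` returns `path`
#'   invisibly.  Round-trip `read_genepop(write_genepop(m, f))` reproduces
#'   `m`'s calls, loci and population grouping.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("GenePop file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("GenePop file must have a title, locus names, then `Pop` blocks")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  pop_starts <- which(is_pop)
  inds <- character(); pops <- character(); rows <- list()
  for (b in seq_along(pop_starts)) {
    from <- pop_starts[b] + 1L
    to <- if (b < length(pop_starts)) pop_starts[b + 1L] - 1L
          else length(lines)
    if (to < from) stop("GenePop `Pop` block ", b, " has no individuals")
    for (ln in lines[from:to]) {
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("malformed GenePop individual line: ", ln)
      id <- trimws(parts[1])
      codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(codes) != length(loci))
        stop("individual ", id, ": expected ", length(loci),
             " genotypes, found ", length(codes))
      g <- vapply(codes, genepop_decode, integer(1), USE.NAMES = FALSE)
      inds <- c(inds, id); pops <- c(pops, paste0("pop", b))
      rows[[length(rows) + 1L]] <- g
    }
  }
  calls <- do.call(rbind, rows)
  calls[calls == -1L] <- NA_integer_
  if (anyDuplicated(inds))
    inds <- make.unique(inds, sep = "_")
  genotype_matrix(calls, inds, pops, loci)
}

genepop_decode <- function(code) {
  if (!grepl("^[0-9]{4}$", code))
    stop("GenePop genotype must be 4 digits, found: ", code)
  a1 <- substr(code, 1, 2); a2 <- substr(code, 3, 4)
  ok <- c("00", "01", "02")
  if (!(a1 %in% ok) || !(a2 %in% ok))
    stop("biallelic GenePop allele codes must be 01/02 (00 missing), found: ",
         code)
  if (a1 == "00" || a2 == "00") return(-1L)
  sum(c(a1, a2) == "02")
}

#' @param mat A [genotype_matrix()].
#' @param title Title line for the file.
#' @rdname read_genepop
#' @export
write_genepop <- function(mat, path, title = "octopop genotype export") {
  stopifnot(inherits(mat, "genotype_matrix"))
  enc <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(mat$loci, con)
  for (pop in unique(mat$populations)) {
    writeLines("Pop", con)
    idx <- which(mat$populations == pop)
    for (i in idx) {
      g <- mat$calls[i, ]
      codes <- ifelse(is.na(g), "0000", enc[as.character(g)])
      writeLines(paste0(mat$individuals[i], " , ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a population tree as Newick
#'
#' Serializes a rooted ultrametric population tree (see [upgma()]) with
#' branch lengths; bootstrap supports, when present, are written as
#' internal node labels.
#'
#' @param tree A `pop_tree` object.
#' @param path Output file path, or `NULL` to return the Newick string.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "pop_tree"))
  phy <- tree$phylo
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
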