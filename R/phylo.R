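#' Uncorrected (p-) distance matrix from an alignment
#'
#' Pairwise proportion of differing sites, with no multiple-hit correction
#' and pairwise deletion of columns where either row carries a gap.
#'
#' @param aligned Named character vector of equal-length aligned rows
#'   (gaps as `-`), at least two.
#' @return A symmetric numeric matrix with zero diagonal, labelled by the
#'   input names.
#' @export
distance_matrix <- function(aligned) {
  stopifnot(length(aligned) >= 2)
  if (length(unique(nchar(aligned))) != 1) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  if (is.null(names(aligned))) names(aligned) <- paste0("seq", seq_along(aligned))
  m <- do.call(rbind, strsplit(tolower(aligned), "", fixed = TRUE))
  rownames(m) <- names(aligned)
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                     pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape). Negative branch lengths that
#' NJ can produce on non-additive matrices are clamped to zero and flagged in
#' the `clamped_edges` attribute.
#'
#' @param dm Symmetric distance matrix with labels (at least 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped_edges") <- which(neg)
  }
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Builds the point-estimate NJ tree from uncorrected distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree for each replicate, and reports for each internal edge of the point
#' tree the percentage of replicates containing the same bipartition
#' (stored as `node.label`). Reproducible for a given `seed`.
#'
#' @param aligned Named character vector of equal-length aligned rows.
#' @param n_reps Number of bootstrap replicates (100 by default; the
#'   literature-scale 500 is a flag away).
#' @param seed Integer seed for the resampling.
#' @return The point-estimate `phylo` tree with percentage supports as
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(aligned, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  point <- neighbor_joining(distance_matrix(aligned))
  chars <- do.call(rbind, strsplit(tolower(aligned), "", fixed = TRUE))
  rownames(chars) <- names(aligned)
  ncols <- ncol(chars)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncols, ncols, replace = TRUE)
    rows <- apply(chars[, idx, drop = FALSE], 1, paste, collapse = "")
    reps[[r]] <- neighbor_joining(distance_matrix(rows))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps)
  support[1] <- NA  # root of the unrooted representation carries no split
  point$node.label <- ifelse(is.na(support), "", as.character(support))
  point
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param dm Matrix from [distance_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(formatC(rownames(dm)[i], width = -10),
                       paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
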