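#' Locate 5' consensus motif hits on both strands
#'
#' Scans a genome sequence for the element 5' consensus motif (default
#' CAATCGTTSC) under IUPAC semantics with up to `motif_max_mismatch`
#' substitutions. Degenerate codes are resolved positionally (S matches C or
#' G); N in the genome never matches any motif position.
#'
#' @param genome A single DNA string (A/C/G/T/N).
#' @param params A [scan_params()] object.
#' @return A data.frame with columns `start`, `end` (1-based closed, forward
#'   strand), `strand` and `mismatches`, sorted by position then strand
#'   (`+` before `-`).
#' @export
find_motif_sites <- function(genome, params = scan_params()) {
  genome <- validate_dna(genome)
  ml <- nchar(params$motif)
  if (nchar(genome) < ml) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  subj <- Biostrings::DNAString(genome)
  fixed <- c(pattern = FALSE, subject = TRUE)
  one_strand <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = params$motif_max_mismatch,
                                  with.indels = FALSE, fixed = fixed)
    if (length(m) == 0) {
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), mismatches = integer()))
    }
    ed <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                      starting.at = BiocGenerics::start(m),
                                      with.indels = FALSE, fixed = fixed)
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               strand = strand, mismatches = as.integer(ed))
  }
  fwd <- one_strand(params$motif, "+")
  rev <- one_strand(revcomp(params$motif), "-")
  out <- rbind(fwd, rev)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest window over a logical indicator that starts and ends on a TRUE
# position, has length >= min_len and TRUE-fraction >= purity.
# Ties broken by leftmost start. Returns c(start, end) relative to the
# indicator, or NULL.
longest_rich_window <- function(ind, min_len, purity) {
  n <- length(ind)
  if (n < min_len) return(NULL)
  cs <- cumsum(ind)
  for (L in seq(n, min_len)) {
    i <- seq_len(n - L + 1L)
    cnt <- cs[i + L - 1L] - c(0, cs)[i]
    ok <- ind[i] & ind[i + L - 1L] & (cnt / L >= purity)
    if (any(ok)) {
      s <- i[which(ok)[1]]
      return(c(s, s + L - 1L))
    }
  }
  NULL
}

#' Find a 3' poly(A) tract within a search span
#'
#' Returns the longest A-rich window inside `search_span` that starts and
#' ends on an A, has length at least `polya_min_len` and A-fraction at least
#' `polya_min_purity` (genomic tails decay by mutation, so "recognizably
#' A-rich" is a purity criterion rather than a pure run). Ties are broken by
#' the leftmost window.
#'
#' @param genome A single DNA string.
#' @param search_span Integer `c(start, end)`, 1-based closed.
#' @param params A [scan_params()] object.
#' @return Integer `c(start, end)` in genome coordinates, or `NULL`.
#' @export
find_polya <- function(genome, search_span, params = scan_params()) {
  genome <- validate_dna(genome)
  s <- as.integer(search_span[1]); e <- as.integer(search_span[2])
  if (s > e) stop("inverted search span", call. = FALSE)
  sub <- subseq_chk(genome, s, e, "search span")
  ind <- strsplit(sub, "", fixed = TRUE)[[1]] == "A"
  w <- longest_rich_window(ind, params$polya_min_len, params$polya_min_purity)
  if (is.null(w)) return(NULL)
  c(w[1] + s - 1L, w[2] + s - 1L)
}

# polypyrimidine patch annotation downstream of the motif (annotation-only;
# not required for the full_length class)
find_polypyrimidine <- function(genome, motif_end, strandlen, params) {
  s <- motif_end + 1L
  e <- min(motif_end + params$polypyrimidine_window, strandlen)
  if (s > e) return(NULL)
  sub <- substr(genome, s, e)
  ind <- strsplit(sub, "", fixed = TRUE)[[1]] %in% c("C", "T")
  w <- longest_rich_window(ind, params$polypyrimidine_min_len, 0.9)
  if (is.null(w)) return(NULL)
  c(w[1] + s - 1L, w[2] + s - 1L)
}

empty_annotation_frame <- function() {
  data.frame(genome_id = character(), start = integer(), end = integer(),
             strand = character(), length = integer(),
             structural_class = character(),
             motif_start = integer(), motif_end = integer(),
             motif_mismatches = integer(),
             polyp_start = integer(), polyp_end = integer(),
             polya_start = integer(), polya_end = integer(),
             name = character(), stringsAsFactors = FALSE)
}

# scan one strand of an oriented sequence; coordinates local to that
# orientation
scan_strand <- function(genome, params, genome_id) {
  hits <- find_motif_sites_one(genome, params)
  n <- nchar(genome)
  ml <- nchar(params$motif)
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    p <- hits$start[k]
    # the full-length distance band is searched first: the ~900 bp
    # motif-to-poly(A) structure is the diagnostic one, and a chance A-rich
    # patch inside the element body must not preempt a decayed true tail
    full_lo <- max(p + params$full_length_span[1] - 1L - params$polya_window,
                   p + ml)
    full_hi <- min(p + params$full_length_span[2] - 1L, n)
    polya <- NULL
    if (full_lo <= full_hi) {
      polya <- find_polya(genome, c(full_lo, full_hi), params)
    }
    if (is.null(polya)) {
      part_lo <- max(p + params$partial_min_len - 1L - params$polya_window,
                     p + ml)
      part_hi <- min(full_lo - 1L, n)
      if (part_lo <= part_hi) {
        polya <- find_polya(genome, c(part_lo, part_hi), params)
      }
    }
    if (!is.null(polya)) {
      len <- polya[2] - p + 1L
      cls <- if (len >= params$full_length_span[1] &&
                 len <= params$full_length_span[2]) "full_length"
             else if (len >= params$partial_min_len) "partial"
             else "fragment"
    } else {
      cls <- "fragment"
    }
    if (cls == "fragment") {
      span <- c(p, p + ml - 1L)
      polya <- NULL
    } else {
      span <- c(p, polya[2])
    }
    pyr <- find_polypyrimidine(genome, p + ml - 1L, n, params)
    rows[[k]] <- data.frame(
      genome_id = genome_id, start = span[1], end = span[2], strand = "+",
      length = span[2] - span[1] + 1L, structural_class = cls,
      motif_start = p, motif_end = p + ml - 1L,
      motif_mismatches = hits$mismatches[k],
      polyp_start = if (is.null(pyr)) NA_integer_ else pyr[1],
      polyp_end = if (is.null(pyr)) NA_integer_ else pyr[2],
      polya_start = if (is.null(polya)) NA_integer_ else polya[1],
      polya_end = if (is.null(polya)) NA_integer_ else polya[2],
      name = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_annotation_frame())
  do.call(rbind, rows)
}

# forward-strand motif hits only (helper for scan_strand)
find_motif_sites_one <- function(genome, params) {
  ml <- nchar(params$motif)
  if (nchar(genome) < ml) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  subj <- Biostrings::DNAString(genome)
  fixed <- c(pattern = FALSE, subject = TRUE)
  m <- Biostrings::matchPattern(Biostrings::DNAString(params$motif), subj,
                                max.mismatch = params$motif_max_mismatch,
                                with.indels = FALSE, fixed = fixed)
  if (length(m) == 0) return(data.frame(start = integer(), mismatches = integer()))
  ed <- Biostrings::neditStartingAt(Biostrings::DNAString(params$motif), subj,
                                    starting.at = BiocGenerics::start(m),
                                    with.indels = FALSE, fixed = fixed)
  data.frame(start = BiocGenerics::start(m), mismatches = as.integer(ed))
}

#' Structure-based scan for candidate elements
#'
#' Discovers candidate Sadhu-like elements from structural features alone:
#' each 5' motif hit is paired with the longest downstream poly(A) window
#' whose implied element length is plausible. Implied lengths within
#' `full_length_span` give the `full_length` class, shorter ones (at least
#' `partial_min_len`) the `partial` class; motif hits with no compatible
#' poly(A) are reported as `fragment` annotations covering the motif only.
#' Both strands are scanned and annotations never overlap on the same strand
#' (longest wins, then leftmost).
#'
#' @param genome A single DNA string.
#' @param params A [scan_params()] object.
#' @param genome_id Label recorded in the output.
#' @return A data.frame of element annotations (1-based closed coordinates on
#'   the forward strand; feature sub-spans for the motif, polypyrimidine
#'   patch and poly(A) tract are in the same coordinates).
#' @export
scan_elements <- function(genome, params = scan_params(), genome_id = "genome") {
  genome <- validate_dna(genome)
  n <- nchar(genome)
  fwd <- scan_strand(genome, params, genome_id)
  rev <- scan_strand(revcomp(genome), params, genome_id)
  if (nrow(rev) > 0) {
    flip <- function(s, e) list(start = n - e + 1L, end = n - s + 1L)
    for (cols in list(c("start", "end"), c("motif_start", "motif_end"),
                      c("polyp_start", "polyp_end"),
                      c("polya_start", "polya_end"))) {
      f <- flip(rev[[cols[1]]], rev[[cols[2]]])
      rev[[cols[1]]] <- f$start; rev[[cols[2]]] <- f$end
    }
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0) return(out)
  # non-overlap per strand: a complete structure with a cleaner motif beats
  # a longer but weaker competitor (class, then motif fidelity, then length,
  # then leftmost) -- chance motif look-alikes paired with a distant A-rich
  # window must not displace a genuine element
  cls_rank <- match(out$structural_class,
                    c("full_length", "partial", "fragment"))
  out <- out[order(cls_rank, out$motif_mismatches, -out$length, out$start),
             , drop = FALSE]
  keep <- logical(nrow(out))
  for (st in c("+", "-")) {
    idx <- which(out$strand == st)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (!any(out$start[i] <= taken_e & out$end[i] >= taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, out$start[i]); taken_e <- c(taken_e, out$end[i])
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert scan annotations to GRanges
#'
#' @param ann Annotation data.frame from [scan_elements()].
#' @return A `GRanges` with parent `mobile_genetic_element` features and
#'   child `sequence_motif`, `polypyrimidine_tract` and `polyA_sequence`
#'   features, suitable for GFF3 export.
#' @export
annotations_to_granges <- function(ann) {
  if (nrow(ann) == 0) {
    return(GenomicRanges::GRanges())
  }
  ids <- sprintf("element%03d", seq_len(nrow(ann)))
  parent <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand,
    type = "mobile_genetic_element", ID = ids,
    Name = ifelse(is.na(ann$name), ids, ann$name),
    structural_class = ann$structural_class, Parent = NA_character_)
  kids <- list()
  add_kid <- function(type, s, e) {
    has <- !is.na(s)
    if (!any(has)) return(NULL)
    GenomicRanges::GRanges(
      seqnames = ann$genome_id[has],
      ranges = IRanges::IRanges(s[has], e[has]),
      strand = ann$strand[has], type = type,
      ID = paste0(ids[has], ".", type),
      Name = NA_character_, structural_class = NA_character_,
      Parent = ids[has])
  }
  kids <- list(add_kid("sequence_motif", ann$motif_start, ann$motif_end),
               add_kid("polypyrimidine_tract", ann$polyp_start, ann$polyp_end),
               add_kid("polyA_sequence", ann$polya_start, ann$polya_end))
  kids <- kids[!vapply(kids, is.null, logical(1))]
  do.call(c, c(list(parent), kids))
}

#' Write scan annotations to GFF3
#'
#' @param ann Annotation data.frame from [scan_elements()].
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
write_scan_gff3 <- function(ann, path) {
  gr <- annotations_to_granges(ann)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
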