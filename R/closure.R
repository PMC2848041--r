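#' Seed-and-extend local similarity search
#'
#' A self-contained local search: exact k-mer seeds from each query are
#' located in the target (both strands), clustered by alignment diagonal,
#' and each cluster is refined by a banded local alignment (match +1,
#' mismatch -2, gap open -5, gap extend -2 -- with these scores a hit only
#' extends while local identity stays high, so low-identity regions fall
#' below `min_hit_len` and drop out). Hits passing `min_identity` and
#' `min_hit_len` are merged per strand within `merge_gap`.
#'
#' @param queries Named character vector of query sequences.
#' @param genome Named character vector of target sequences.
#' @param params A [closure_params()] object.
#' @return A data.frame of hits: `seqid`, `start`, `end`, `strand`,
#'   `length`, `query`, `identity` (matches over alignment columns of the
#'   refining local alignment).
#' @export
local_search <- function(queries, genome, params = closure_params()) {
  stopifnot(length(queries) >= 1)
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  k <- params$kmer
  hits <- list()
  for (gid in names(genome)) {
    gseq <- validate_dna(genome[[gid]])
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") gseq else revcomp(gseq)
      subj <- Biostrings::DNAString(oriented)
      n <- nchar(oriented)
      for (qid in names(queries)) {
        q <- validate_dna(queries[[qid]])
        ql <- nchar(q)
        if (ql < k) next
        starts <- seq_len(ql - k + 1L)
        words <- substring(q, starts, starts + k - 1L)
        keep <- !grepl("N", words, fixed = TRUE)
        if (!any(keep)) next
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(words[keep]))
        m <- Biostrings::matchPDict(pd, subj)
        qpos <- rep(starts[keep], S4Vectors::elementNROWS(m))
        gpos <- BiocGenerics::start(unlist(m))
        if (length(gpos) == 0) next
        seeds <- data.frame(qpos = qpos, gpos = gpos,
                            diag = gpos - qpos)
        seeds <- seeds[order(seeds$diag, seeds$gpos), , drop = FALSE]
        newc <- c(TRUE, diff(seeds$diag) > 15 | diff(seeds$gpos) > 150)
        cl <- cumsum(newc)
        for (cid in unique(cl)) {
          s <- seeds[cl == cid, , drop = FALSE]
          ws <- max(1L, min(s$gpos) - min(s$qpos) - 30L)
          we <- min(n, max(s$gpos) + k - 1L + (ql - max(s$qpos) - k + 1L) + 30L)
          if (we - ws + 1L < params$min_hit_len) next
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(q),
            Biostrings::DNAString(substr(oriented, ws, we)),
            type = "local", substitutionMatrix = sm,
            gapOpening = 5, gapExtension = 2)
          cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
          if (cols == 0) next
          ident <- Biostrings::nmatch(aln) / cols
          hs <- ws + BiocGenerics::start(Biostrings::subject(aln)) - 1L
          he <- ws + BiocGenerics::end(Biostrings::subject(aln)) - 1L
          if (he - hs + 1L < params$min_hit_len) next
          if (ident < params$min_identity) next
          if (strand == "-") {
            tmp <- hs
            hs <- n - he + 1L
            he <- n - tmp + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            seqid = gid, start = hs, end = he, strand = strand,
            length = he - hs + 1L, query = qid, identity = ident,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), query = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  merge_hits(do.call(rbind, hits), params$merge_gap)
}

# merge overlapping/nearby hits on the same sequence and strand, keeping the
# best-identity query as representative
merge_hits <- function(h, merge_gap) {
  out <- list()
  for (key in unique(paste(h$seqid, h$strand))) {
    d <- h[paste(h$seqid, h$strand) == key, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur$end + merge_gap) {
        if (d$identity[i] > cur$identity) {
          cur$identity <- d$identity[i]
          cur$query <- d$query[i]
        }
        cur$end <- max(cur$end, d$end[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- d[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res$length <- res$end - res$start + 1L
  res <- res[order(res$seqid, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Iterative homology closure over a target genome
#'
#' Repeats [local_search()] with a growing query set: sequences of new hits
#' are added as queries unless they are already represented (at least
#' `novel_identity` identical over at least `novel_coverage` of their
#' length to an existing member), until a self-referencing fixed point is
#' reached -- one more iteration adds no novel member -- or
#' `max_iterations`. Hits a single direct pass would miss (reachable only
#' through intermediate relatives) are picked up transitively.
#'
#' @param seed_queries Named character vector of seed sequences.
#' @param genome Named character vector of target sequences.
#' @param params A [closure_params()] object.
#' @return A list of class `closure_result`: `hits` (final merged hit set
#'   with `iteration_found`), `members` (the closed query set, seeds
#'   included), `iterations`, `converged`.
#' @export
closure_search <- function(seed_queries, genome, params = closure_params()) {
  stopifnot(length(seed_queries) >= 1)
  if (is.null(names(seed_queries))) {
    names(seed_queries) <- paste0("seed", seq_along(seed_queries))
  }
  queries <- vapply(seed_queries, validate_dna, character(1))
  first_seen <- list()
  converged <- FALSE
  hits <- NULL
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    hits <- local_search(queries, genome, params)
    novel <- character(0)
    if (nrow(hits) > 0) {
      for (i in seq_len(nrow(hits))) {
        key <- sprintf("%s:%d-%d:%s", hits$seqid[i], hits$start[i],
                       hits$end[i], hits$strand[i])
        if (is.null(first_seen[[key]])) first_seen[[key]] <- iter
        hseq <- substr(genome[[hits$seqid[i]]], hits$start[i], hits$end[i])
        if (hits$strand[i] == "-") hseq <- revcomp(hseq)
        known <- any(vapply(c(queries, novel), function(q) {
          pi <- pairwise_identity(hseq, q)
          pi$identity >= params$novel_identity &&
            pi$aligned_len >= params$novel_coverage * nchar(hseq)
        }, logical(1)))
        if (!known) {
          novel[[sprintf("iter%d_hit%d", iter, i)]] <- hseq
        }
      }
    }
    if (length(novel) == 0) {
      converged <- TRUE
      break
    }
    queries <- c(queries, novel)
  }
  if (!converged) {
    warning("closure did not reach a fixed point within max_iterations")
  }
  if (nrow(hits) > 0) {
    hits$iteration_found <- vapply(seq_len(nrow(hits)), function(i) {
      key <- sprintf("%s:%d-%d:%s", hits$seqid[i], hits$start[i],
                     hits$end[i], hits$strand[i])
      if (is.null(first_seen[[key]])) iter else first_seen[[key]]
    }, integer(1))
  } else {
    hits$iteration_found <- integer(0)
  }
  structure(list(hits = hits, members = queries, iterations = iter,
                 converged = converged),
            class = "closure_result")
}

#' @export
print.closure_result <- function(x, ...) {
  cat(sprintf("homology closure: %d hit(s), %d member(s), %d iteration(s)%s\n",
              nrow(x$hits), length(x$members), x$iterations,
              if (x$converged) " (fixed point)" else " (NOT converged)"))
  invisible(x)
}

#' Report structurally typed, named family members from closure hits
#'
#' Retains merged hits of at least `report_min_len`, types each hit
#' structurally (5' motif / poly(A) / length via the element scanner run on
#' the oriented hit sequence), searches the surrounding genome for a target
#' site duplication, classifies each hit against the named reference set
#' and names it with a species-prefix nomenclature (e.g. `AlSadhu1-1` for
#' the first full-length member of subfamily 1).
#'
#' @param hits Hit data.frame from [closure_search()]/[local_search()].
#' @param genome Named character vector of target sequences.
#' @param references Named character vector of full-length reference
#'   elements (names in the family nomenclature).
#' @param params A [closure_params()] object.
#' @param scanp A [scan_params()] object for structural typing.
#' @param tsdp A [tsd_params()] object for TSD detection.
#' @param species_prefix Prefix for assigned names (e.g. `"Al"`).
#' @return A data.frame with one row per reported element: `name`, `seqid`,
#'   `start`, `end`, `orientation`, `length`, `tsd_len` (NA when not
#'   detected), `full_length`, `nearest_reference`, `pct_identity`.
#' @export
report_elements <- function(hits, genome, references,
                            params = closure_params(),
                            scanp = scan_params(), tsdp = tsd_params(),
                            species_prefix = "") {
  hits <- hits[hits$length >= params$report_min_len, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(name = character(), seqid = character(),
                      start = integer(), end = integer(),
                      orientation = character(), length = integer(),
                      tsd_len = integer(), full_length = logical(),
                      nearest_reference = character(),
                      pct_identity = numeric(), stringsAsFactors = FALSE))
  }
  seqs <- character(nrow(hits))
  classes <- character(nrow(hits))
  tsd_lens <- rep(NA_integer_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    hseq <- substr(genome[[hits$seqid[i]]], hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") hseq <- revcomp(hseq)
    seqs[i] <- hseq
    ann <- scan_elements(hseq, scanp, genome_id = "hit")
    ann <- ann[ann$strand == "+", , drop = FALSE]
    classes[i] <- if (nrow(ann) > 0 && any(ann$structural_class == "full_length"))
      "full_length"
    else if (nchar(hseq) >= scanp$partial_min_len) "partial"
    else "fragment"
    tsd <- tryCatch(
      find_tsd(genome[[hits$seqid[i]]], c(hits$start[i], hits$end[i]), tsdp),
      error = function(e) NULL)
    if (!is.null(tsd)) tsd_lens[i] <- tsd$length
  }
  names(seqs) <- sprintf("hit%03d", seq_len(nrow(hits)))
  asn <- classify_elements(seqs, references, structural_class = classes)
  asn <- assign_names(asn, family_prefix = paste0(species_prefix, "Sadhu"),
                      existing = names(references))
  data.frame(name = asn$assigned_name, seqid = hits$seqid,
             start = hits$start, end = hits$end,
             orientation = hits$strand, length = hits$length,
             tsd_len = tsd_lens, full_length = classes == "full_length",
             nearest_reference = asn$nearest_full_length,
             pct_identity = round(100 * asn$identity),
             stringsAsFactors = FALSE)
}
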