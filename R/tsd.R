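#' Detect the target site duplication flanking an element
#'
#' Searches the two flanks of `element_span` for the maximal-length direct
#' repeat consistent with the TPRT staggered-cut model: one copy ending
#' within `boundary_slack` bp of the element 5' boundary, the other starting
#' within `boundary_slack` bp of the 3' boundary, identical up to
#' `max_mismatch` substitutions. Ties are broken by fewer mismatches, then
#' smaller total boundary offset, then the leftmost left copy.
#'
#' The detected repeat is the *maximal* repeat: when flanking characters
#' happen to coincide it can be longer than the biologically annotated TSD
#' (which it then contains); the filled site alone cannot disambiguate.
#'
#' The searchable repeat length is capped by the available flank; an error is
#' raised only when a flank is shorter than `min_len`.
#'
#' @param genome A single DNA string containing the locus.
#' @param element_span Integer `c(start, end)` of the element, 1-based closed.
#' @param params A [tsd_params()] object.
#' @return A list of class `tsd_call` with `left_span`, `right_span`,
#'   `repeat_seq`, `length`, `mismatches`, `left_offset`, `right_offset`;
#'   or `NULL` when no qualifying repeat exists.
#' @export
find_tsd <- function(genome, element_span, params = tsd_params()) {
  genome <- validate_dna(genome)
  n <- nchar(genome)
  es <- as.integer(element_span[1]); ee <- as.integer(element_span[2])
  if (es < 1 || ee > n || es > ee) stop("element span outside genome", call. = FALSE)
  left_flank <- es - 1L
  right_flank <- n - ee
  if (left_flank < params$min_len) {
    stop(sprintf("left flank too short (%d bp) for a %d bp repeat",
                 left_flank, params$min_len), call. = FALSE)
  }
  if (right_flank < params$min_len) {
    stop(sprintf("right flank too short (%d bp) for a %d bp repeat",
                 right_flank, params$min_len), call. = FALSE)
  }
  chars <- charToRaw(genome)
  slack <- params$boundary_slack
  lmax <- min(params$max_len, left_flank + slack, right_flank + slack)
  best <- NULL
  for (L in seq(lmax, params$min_len)) {
    for (a in seq(-slack, slack)) {        # left copy end = es - 1 + a
      le <- es - 1L + a
      ls <- le - L + 1L
      if (ls < 1L || le > n) next
      for (b in seq(-slack, slack)) {      # right copy start = ee + 1 + b
        rs <- ee + 1L + b
        re <- rs + L - 1L
        if (rs < 1L || re > n) next
        if (rs <= le) next                 # copies must not overlap
        mm <- sum(chars[ls:le] != chars[rs:re])
        if (mm > params$max_mismatch) next
        key <- c(-L, mm, abs(a) + abs(b), ls)
        if (is.null(best) || compare_keys(key, best$key) < 0) {
          best <- list(key = key, ls = ls, le = le, rs = rs, re = re,
                       mm = mm, a = a, b = b)
        }
      }
    }
    if (!is.null(best)) break   # lengths searched in decreasing order
  }
  if (is.null(best)) return(NULL)
  structure(list(left_span = c(best$ls, best$le),
                 right_span = c(best$rs, best$re),
                 repeat_seq = substr(genome, best$ls, best$le),
                 length = best$le - best$ls + 1L,
                 mismatches = best$mm,
                 left_offset = best$a, right_offset = best$b),
            class = "tsd_call")
}

# lexicographic comparison of numeric tie-break keys: -1 if a < b
compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' @export
print.tsd_call <- function(x, ...) {
  cat(sprintf("TSD call: %s (%d bp, %d mismatch%s)\n  left copy  [%d, %d]\n  right copy [%d, %d]\n",
              x$repeat_seq, x$length, x$mismatches,
              if (x$mismatches == 1) "" else "es",
              x$left_span[1], x$left_span[2],
              x$right_span[1], x$right_span[2]))
  invisible(x)
}

#' Extract nicking-site contexts around a target site duplication
#'
#' Returns the three windows used for integration-site consensus building:
#' the 9-mer immediately 5' of the left TSD copy (the 5' nicking site), the
#' first 7 nt of the repeat, and the 9-mer immediately 3' of the right copy
#' (the 3' nicking site). For an element annotated on the minus strand the
#' locus is orientation-normalized first, so contexts are always reported in
#' element-forward orientation.
#'
#' @param genome A single DNA string containing the locus.
#' @param element_span Integer `c(start, end)` of the element.
#' @param tsd A `tsd_call` from [find_tsd()] (in forward-strand locus
#'   coordinates).
#' @param strand `"+"` or `"-"`: the element's strand.
#' @return A list of class `nick_context` with `five_prime_nick`,
#'   `tsd_prefix`, `three_prime_nick`.
#' @export
extract_nick_contexts <- function(genome, element_span, tsd, strand = "+") {
  genome <- validate_dna(genome)
  n <- nchar(genome)
  if (identical(strand, "-")) {
    genome <- revcomp(genome)
    flip <- function(sp) c(n - sp[2] + 1L, n - sp[1] + 1L)
    element_span <- flip(element_span)
    new_left <- flip(tsd$right_span)
    new_right <- flip(tsd$left_span)
    tsd <- list(left_span = new_left, right_span = new_right,
                repeat_seq = revcomp(tsd$repeat_seq), length = tsd$length)
  }
  ls <- tsd$left_span[1]; re <- tsd$right_span[2]
  if (ls - 1L < 9L) stop("left flank shorter than 9 bp", call. = FALSE)
  if (n - re < 9L) stop("right flank shorter than 9 bp", call. = FALSE)
  structure(list(
    five_prime_nick = substr(genome, ls - 9L, ls - 1L),
    tsd_prefix = substr(tsd$repeat_seq, 1L, min(7L, tsd$length)),
    three_prime_nick = substr(genome, re + 1L, re + 9L)),
    class = "nick_context")
}

#' Build per-position consensus profiles of integration-site windows
#'
#' Counts bases per position across a set of nicking-site contexts and
#' computes per-position information content in bits
#' (`2 + sum_b p_b log2 p_b`, with `0 log 0 = 0`; no small-sample
#' correction, matching the plain sequence-logo statistic).
#'
#' @param contexts A list of `nick_context` objects (uniform window lengths).
#' @return A list of three `consensus_profile` objects named
#'   `five_prime_nick`, `tsd_prefix`, `three_prime_nick`; each holds a 4 x L
#'   count matrix (`counts`), `n_sequences` and `bits`.
#' @export
build_site_consensus <- function(contexts) {
  stopifnot(length(contexts) >= 1)
  one <- function(field) {
    strs <- toupper(vapply(contexts, function(x) x[[field]], character(1)))
    if (length(unique(nchar(strs))) != 1) {
      stop(sprintf("mixed window lengths in '%s'", field), call. = FALSE)
    }
    counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(strs),
                                          baseOnly = TRUE)
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    p <- sweep(counts, 2, colSums(counts), "/")
    plogp <- ifelse(p > 0, p * log2(p), 0)
    structure(list(counts = counts, n_sequences = length(strs),
                   bits = 2 + colSums(plogp)),
              class = "consensus_profile")
  }
  list(five_prime_nick = one("five_prime_nick"),
       tsd_prefix = one("tsd_prefix"),
       three_prime_nick = one("three_prime_nick"))
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("Consensus profile over %d sequences (%d positions)\n",
              x$n_sequences, ncol(x$counts)))
  print(x$counts)
  cat("bits:", paste(sprintf("%.2f", x$bits), collapse = " "), "\n")
  invisible(x)
}

#' Write consensus profiles as a logo-ready TSV
#'
#' One row per window position: window name, position, A/C/G/T counts and
#' information content in bits.
#'
#' @param profiles Output of [build_site_consensus()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_consensus_tsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(nm) {
    pr <- profiles[[nm]]
    data.frame(window = nm, position = seq_len(ncol(pr$counts)),
               A = pr$counts["A", ], C = pr$counts["C", ],
               G = pr$counts["G", ], T = pr$counts["T", ],
               bits = pr$bits)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
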