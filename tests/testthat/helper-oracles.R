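# Independent brute-force oracles used to pin down the contracts of the
# fast implementations. These are deliberately naive and share no code with
# the package internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# per-window Hamming scan under IUPAC semantics, both strands; N in the
# genome matches nothing
oracle_motif_scan <- function(genome, motif, max_mismatch) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", S = "S", W = "W",
              R = "Y", Y = "R", K = "M", M = "K", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  gch <- strsplit(genome, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp_chr(motif)
    pch <- strsplit(pat, "")[[1]]
    ml <- length(pch)
    if (length(gch) < ml) next
    for (i in seq_len(length(gch) - ml + 1)) {
      mm <- 0
      for (j in seq_len(ml)) {
        g <- gch[i + j - 1]
        if (g == "N" || !(g %in% iupac_sets[[pch[j]]])) mm <- mm + 1
      }
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- data.frame(
          start = i, end = i + ml - 1, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of all poly(A) windows (A endpoints, min length,
# purity); longest wins, ties leftmost
oracle_polya <- function(seq, min_len, purity) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      L <- j - i + 1
      if (L < min_len) next
      if (ch[i] != "A" || ch[j] != "A") next
      if (sum(ch[i:j] == "A") / L < purity) next
      if (is.null(best) || L > best[2] - best[1] + 1) best <- c(i, j)
    }
  }
  best
}

# exhaustive enumeration of flanking direct repeats under the boundary-slack
# model; collects every candidate and sorts by the tie-break keys
oracle_tsd <- function(locus, element_span, min_len = 7, max_len = 18,
                       max_mismatch = 0, slack = 3) {
  ch <- strsplit(locus, "")[[1]]
  n <- length(ch)
  es <- element_span[1]; ee <- element_span[2]
  cand <- list()
  for (L in min_len:max_len) {
    for (a in -slack:slack) {
      le <- es - 1 + a; ls <- le - L + 1
      if (ls < 1 || le > n) next
      for (b in -slack:slack) {
        rs <- ee + 1 + b; re <- rs + L - 1
        if (rs < 1 || re > n || rs <= le) next
        mm <- sum(ch[ls:le] != ch[rs:re])
        if (mm > max_mismatch) next
        cand[[length(cand) + 1]] <- data.frame(
          ls = ls, le = le, rs = rs, re = re, L = L, mm = mm,
          off = abs(a) + abs(b))
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  d <- do.call(rbind, cand)
  d <- d[order(-d$L, d$mm, d$off, d$ls), , drop = FALSE]
  d[1, , drop = FALSE]
}

# ends-free global alignment score by affine-gap (Gotoh) dynamic
# programming; gap of length L costs open + L * extend
oracle_overlap_score <- function(a, b, match = 1, mismatch = -1,
                                 open = 5, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # align av[i] with bv[j]
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (av[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, ] <- 0; M[, 1] <- 0        # free leading gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  # free trailing gaps: best cell in last row or column
  max(M[n + 1, ], M[, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# plant a TSD-flanked stub into random flanks; returns locus + element span
make_tsd_locus <- function(tsd_len = 10, flank = 30, stub_len = 50) {
  tsd <- rand_dna(tsd_len)
  stub <- rand_dna(stub_len)
  locus <- paste0(rand_dna(flank), tsd, stub, tsd, rand_dna(flank))
  list(locus = locus, tsd = tsd,
       element_span = c(flank + tsd_len + 1, flank + tsd_len + stub_len))
}
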