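#' Pairwise percent identity from a free-end-gap global alignment
#'
#' Aligns two sequences globally with free terminal gaps (scoring: match +1,
#' mismatch -1, gap open -5, gap extend -1 by default) and reports identity
#' as matches over aligned residue columns (columns where either sequence has
#' a gap are excluded), i.e. an uncorrected distance complement.
#'
#' @param a,b DNA strings.
#' @param params A [classifier_params()] object.
#' @return A list with `identity` (fraction) and `aligned_len` (residue
#'   columns).
#' @export
pairwise_identity <- function(a, b, params = classifier_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  a <- validate_dna(a); b <- validate_dna(b)
  # identity is symmetric by contract; align the pair in canonical order so
  # co-optimal alignments cannot make identity(a,b) != identity(b,a)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                 mismatch = params$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sm,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nm + nmm
  list(identity = if (cols == 0) 0 else nm / cols,
       aligned_len = cols,
       score = Biostrings::score(aln))
}

#' Classify candidate elements against a full-length reference set
#'
#' Relates each candidate to the named full-length reference elements:
#' a structurally full-length candidate is a subfamily member
#' (`member_full_length`); otherwise a candidate aligning above
#' `derived_min_identity` to a *unique* best reference (best-vs-second-best
#' identity gap at least `unique_margin`) is `derived` from that element;
#' remaining candidates are attached to their best pairwise match as `like`,
#' provided at least `min_like_aligned` bp align (else `unclassified`).
#'
#' @param candidates Named character vector of candidate sequences.
#' @param structural_class Character vector parallel to `candidates`
#'   (`"full_length"`, `"partial"` or `"fragment"`); defaults to
#'   `"partial"` for all.
#' @param full_set Named character vector of full-length reference sequences
#'   (unique names).
#' @param params A [classifier_params()] object.
#' @return A data.frame with columns `element`, `relation`,
#'   `nearest_full_length`, `identity`, `aligned_len` and `subfamily` (parsed
#'   from the nearest reference name).
#' @export
classify_elements <- function(candidates,
                              full_set,
                              structural_class = NULL,
                              params = classifier_params()) {
  stopifnot(length(full_set) >= 1)
  if (anyDuplicated(names(full_set))) {
    stop("duplicate names in full-length reference set", call. = FALSE)
  }
  if (is.null(structural_class)) {
    structural_class <- rep("partial", length(candidates))
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  rows <- lapply(seq_along(candidates), function(i) {
    ids <- vapply(full_set, function(r) {
      pi <- pairwise_identity(candidates[[i]], r, params)
      c(pi$identity, pi$aligned_len)
    }, numeric(2))
    # a free-end-gap alignment of unrelated sequences degenerates to a tiny
    # perfect overlap; only references with a substantial aligned length are
    # comparable by identity
    alignable <- which(ids[2, ] >= params$min_like_aligned)
    if (length(alignable) == 0) {
      best <- which.max(ids[2, ])
      return(data.frame(element = names(candidates)[i],
                        relation = "unclassified",
                        nearest_full_length = names(full_set)[best],
                        identity = ids[1, best], aligned_len = ids[2, best],
                        subfamily = NA_character_, stringsAsFactors = FALSE))
    }
    ord <- alignable[order(-ids[1, alignable], names(full_set)[alignable])]
    best <- ord[1]
    best_id <- ids[1, best]
    best_len <- ids[2, best]
    second_id <- if (length(ord) > 1) ids[1, ord[2]] else -Inf
    unique_best <- (best_id - second_id) >= params$unique_margin ||
      length(ord) == 1
    relation <- if (structural_class[i] == "full_length") {
      "member_full_length"
    } else if (best_id > params$derived_min_identity && unique_best) {
      "derived"
    } else {
      "like"
    }
    sf <- parse_element_name(names(full_set)[best])$subfamily
    if (is.na(sf)) sf <- names(full_set)[best]
    data.frame(element = names(candidates)[i], relation = relation,
               nearest_full_length = names(full_set)[best],
               identity = best_id, aligned_len = best_len,
               subfamily = sf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate family nomenclature for classified elements
#'
#' Assigns names in the family scheme: full-length members are numbered
#' `<prefix><X>-<k>` within subfamily X in input order (continuing after any
#' numbers already used by the reference set); the k-th derivative of
#' `<prefix><X>-<n>` is `<prefix><X>-<n>d<k>`; the k-th "like" element of
#' subfamily X is `<prefix><X>L<k>`. Names are collision-free within a run.
#'
#' @param assignments Data.frame from [classify_elements()].
#' @param family_prefix Name prefix, e.g. `"Sadhu"` or `"AlSadhu"`.
#' @param existing Character vector of names already in use (typically the
#'   reference set), consulted so numbering continues rather than collides.
#' @return `assignments` with an `assigned_name` column.
#' @export
assign_names <- function(assignments, family_prefix = "Sadhu",
                         existing = character(0)) {
  if (nrow(assignments) == 0) {
    assignments$assigned_name <- character(0)
    return(assignments)
  }
  used <- existing
  next_free <- function(make) {
    k <- 1L
    while (make(k) %in% used) k <- k + 1L
    make(k)
  }
  names_out <- character(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    rel <- assignments$relation[i]
    sf <- assignments$subfamily[i]
    parses <- grepl("^[0-9]+$", sf)
    nm <- if (rel == "member_full_length") {
      if (parses) next_free(function(k) sprintf("%s%s-%d", family_prefix, sf, k))
      else next_free(function(k) sprintf("%s-%d", sf, k))
    } else if (rel == "derived") {
      parent <- assignments$nearest_full_length[i]
      next_free(function(k) sprintf("%sd%d", parent, k))
    } else if (rel == "like") {
      if (parses) next_free(function(k) sprintf("%s%sL%d", family_prefix, sf, k))
      else next_free(function(k) sprintf("%sL%d", sf, k))
    } else {
      next_free(function(k) sprintf("%s_unclassified%d", family_prefix, k))
    }
    used <- c(used, nm)
    names_out[i] <- nm
  }
  assignments$assigned_name <- names_out
  assignments
}

#' Parse an element name into its nomenclature fields
#'
#' Inverse of [assign_names()]: `"Sadhu5-1d2"` parses to subfamily 5,
#' element 1, relation `derived`, index 2; `"AlSadhu3L1"` to species prefix
#' `"Al"`, subfamily 3, relation `like`, index 1.
#'
#' @param name An element name.
#' @param family Family stem expected inside the name.
#' @return A list with `prefix`, `subfamily`, `element`, `relation`, `index`.
#' @export
parse_element_name <- function(name, family = "Sadhu") {
  re <- paste0("^([A-Za-z]*?)", family,
               "([0-9]+)(?:-([0-9]+))?(?:(d|L)([0-9]+))?$")
  m <- regmatches(name, regexec(re, name))[[1]]
  if (length(m) == 0) {
    return(list(prefix = "", subfamily = NA_character_,
                element = NA_character_, relation = NA_character_,
                index = NA_integer_))
  }
  relation <- if (m[5] == "d") "derived"
              else if (m[5] == "L") "like"
              else "member_full_length"
  list(prefix = m[2], subfamily = m[3],
       element = if (nzchar(m[4])) m[4] else NA_character_,
       relation = relation,
       index = if (nzchar(m[6])) as.integer(m[6]) else NA_integer_)
}

#' Subfamily consensus by star alignment to an anchor member
#'
#' Aligns every member to the anchor (longest member by default) with
#' free-end-gap pairwise alignments and takes the per-anchor-column plurality
#' base across members (ties resolved in A < C < G < T order; columns in
#' which no member has a base are dropped). Member insertions relative to the
#' anchor are ignored, which suits families whose divergence is dominated by
#' substitutions; a pre-aligned set can be summarized with
#' [distance_matrix()]-style tools instead.
#'
#' @param members Named character vector of member sequences.
#' @param anchor Name or index of the anchor member; default the longest.
#' @param params A [classifier_params()] object (alignment scoring).
#' @return A consensus DNA string.
#' @export
subfamily_consensus <- function(members, anchor = NULL,
                                params = classifier_params()) {
  stopifnot(length(members) >= 1)
  members <- vapply(members, validate_dna, character(1))
  if (length(members) == 1) return(unname(members[[1]]))
  if (is.null(anchor)) anchor <- which.max(nchar(members))
  anchor_seq <- members[[anchor]]
  L <- nchar(anchor_seq)
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                 mismatch = params$mismatch)
  for (m in members) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(m), Biostrings::DNAString(anchor_seq),
      type = "overlap", substitutionMatrix = sm,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    # map alignment columns to anchor positions; the overlap alignment may
    # clip anchor ends, so track the anchor offset of the aligned region
    apos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    for (j in seq_along(sub)) {
      if (sub[j] != "-") {
        apos <- apos + 1L
        if (pat[j] %in% c("A", "C", "G", "T")) {
          counts[pat[j], apos] <- counts[pat[j], apos] + 1L
        }
      }
    }
  }
  keep <- colSums(counts) > 0
  bases <- rownames(counts)[apply(counts[, keep, drop = FALSE], 2, which.max)]
  paste(bases, collapse = "")
}
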