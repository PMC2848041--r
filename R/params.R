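#' Parameters for structural element scanning
#'
#' Tunable thresholds for [scan_elements()] and its helpers. Defaults encode
#' the diagnostic structure of Sadhu-like retroposons: a 10 bp 5' consensus
#' motif (CAATCGTTSC, S = C or G), a polypyrimidine patch shortly downstream,
#' a 3' poly(A) tract, and a full-length span of roughly 900 bp.
#'
#' @param motif IUPAC pattern for the 5' consensus motif.
#' @param motif_max_mismatch Maximum substitutions tolerated in a motif hit.
#' @param polypyrimidine_min_len Minimum length (bp) of the annotated C/T-rich
#'   patch.
#' @param polypyrimidine_window Window (bp) downstream of the motif searched
#'   for the polypyrimidine patch.
#' @param polya_min_len Minimum poly(A) window length (bp).
#' @param polya_min_purity Minimum A fraction of a poly(A) window.
#' @param polya_window Slack (bp) around the expected 3' end when pairing a
#'   motif with its poly(A) tract.
#' @param full_length_span Two-element numeric, `[min, max]` total element
#'   length (bp) for the full-length class ("approximately 900 bp"
#'   operationalized as 700-1100).
#' @param partial_min_len Minimum length (bp) for the partial class.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(motif = "CAATCGTTSC",
                        motif_max_mismatch = 1L,
                        polypyrimidine_min_len = 15L,
                        polypyrimidine_window = 120L,
                        polya_min_len = 6L,
                        polya_min_purity = 0.8,
                        polya_window = 60L,
                        full_length_span = c(700L, 1100L),
                        partial_min_len = 350L) {
  motif <- toupper(motif)
  stopifnot(nchar(motif) > 0,
            motif_max_mismatch >= 0, motif_max_mismatch < nchar(motif),
            polya_min_purity > 0, polya_min_purity <= 1,
            length(full_length_span) == 2,
            full_length_span[1] < full_length_span[2],
            partial_min_len > 0)
  structure(list(motif = motif,
                 motif_max_mismatch = as.integer(motif_max_mismatch),
                 polypyrimidine_min_len = as.integer(polypyrimidine_min_len),
                 polypyrimidine_window = as.integer(polypyrimidine_window),
                 polya_min_len = as.integer(polya_min_len),
                 polya_min_purity = polya_min_purity,
                 polya_window = as.integer(polya_window),
                 full_length_span = as.integer(full_length_span),
                 partial_min_len = as.integer(partial_min_len)),
            class = "scan_params")
}

#' Parameters for target site duplication detection
#'
#' @param min_len Minimum repeat length (bp); TSDs of non-LTR elements run
#'   from 7 bp upward.
#' @param max_len Maximum repeat length (bp); 18 is the union of the 7-16 bp
#'   range seen in A. thaliana and the 8-18 bp range seen in A. lyrata.
#' @param max_mismatch Substitutions tolerated between the two copies.
#'   Default 0: sequenced clean empty sites carry a single identical copy.
#' @param boundary_slack Allowed offset (bp) of a copy edge from the element
#'   boundary, absorbing poly(A)/TSD ambiguity (many TSDs begin with
#'   adenines).
#' @return A list of class `tsd_params`.
#' @export
tsd_params <- function(min_len = 7L, max_len = 18L,
                       max_mismatch = 0L, boundary_slack = 3L) {
  stopifnot(min_len > 0, min_len <= max_len,
            max_mismatch >= 0, boundary_slack >= 0)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_mismatch = as.integer(max_mismatch),
                 boundary_slack = as.integer(boundary_slack)),
            class = "tsd_params")
}

#' Parameters for subfamily classification
#'
#' @param derived_min_identity Identity above which a candidate aligned to a
#'   unique full-length element is called "derived" (the family literature
#'   uses >75%, in places >80%; 0.75 is the default, configurable).
#' @param unique_margin Identity gap between best and second-best full-length
#'   match required to call the best match "unique".
#' @param min_like_aligned Minimum aligned length (bp) for a "like"
#'   assignment; shorter best hits are left unclassified.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(derived_min_identity = 0.75,
                              unique_margin = 0.02,
                              min_like_aligned = 50L,
                              match = 1, mismatch = -1,
                              gap_open = 5, gap_extend = 1) {
  stopifnot(derived_min_identity > 0, derived_min_identity < 1,
            unique_margin >= 0)
  structure(list(derived_min_identity = derived_min_identity,
                 unique_margin = unique_margin,
                 min_like_aligned = as.integer(min_like_aligned),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "classifier_params")
}

#' Parameters for iterative homology closure
#'
#' @param min_identity Minimum hit identity retained by [local_search()].
#' @param min_hit_len Minimum hit length (bp).
#' @param report_min_len Minimum member length (bp) reported by
#'   [report_elements()].
#' @param merge_gap Hits on the same strand closer than this (bp) are merged.
#' @param max_iterations Iteration cap for [closure_search()].
#' @param novel_identity,novel_coverage A hit is "novel" (added to the query
#'   set) unless it is at least `novel_identity` identical over at least
#'   `novel_coverage` of its length to an existing member.
#' @param kmer Seed word size for the local search.
#' @return A list of class `closure_params`.
#' @export
closure_params <- function(min_identity = 0.70, min_hit_len = 100L,
                           report_min_len = 350L, merge_gap = 50L,
                           max_iterations = 20L,
                           novel_identity = 0.95, novel_coverage = 0.90,
                           kmer = 11L) {
  stopifnot(min_identity > 0, min_hit_len > 0,
            report_min_len >= min_hit_len, merge_gap >= 0,
            max_iterations >= 1, kmer >= 4)
  structure(list(min_identity = min_identity,
                 min_hit_len = as.integer(min_hit_len),
                 report_min_len = as.integer(report_min_len),
                 merge_gap = as.integer(merge_gap),
                 max_iterations = as.integer(max_iterations),
                 novel_identity = novel_identity,
                 novel_coverage = novel_coverage,
                 kmer = as.integer(kmer)),
            class = "closure_params")
}

#' Parameters for the TPRT radiation simulator
#'
#' The defaults describe the study conditions the rest of the package is
#' tested against: ~900 bp elements starting with the CAATCGTTSC motif plus a
#' ~20 bp polypyrimidine patch and ending in a 12 bp poly(A) tract, TSD
#' lengths uniform on 7-16 bp, within-subfamily divergence of 5-20%
#' substitutions/site and between-subfamily divergence of at least 25%.
#'
#' @param seed Integer seed; all simulator randomness flows from it.
#' @param genome_len Baseline random genome length (bp).
#' @param base_composition Probabilities for A, C, G, T.
#' @param n_subfamilies Number of subfamilies to radiate.
#' @param within_subfamily_divergence Substitutions/site between a subfamily
#'   member and the subfamily ancestor.
#' @param between_subfamily_divergence Substitutions/site between subfamily
#'   ancestors and the family ancestor.
#' @param element_len Full-length element size (bp).
#' @param polya_len Length of the encoded 3' poly(A) tract (bp).
#' @param tsd_len_range Inclusive range TSD lengths are drawn from.
#' @param derivative_mode_probs Named probabilities over the derivative modes
#'   `five_prime_truncation`, `template_switch`, `early_polyA`,
#'   `internal_deletion`.
#' @param n_strains Number of strains in a radiation panel.
#' @param p_recent_insertion Per-strain carrier probability for a recent
#'   (polymorphic) insertion.
#' @param strain_divergence Per-strain branch divergence (substitutions/site)
#'   within a panel.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       genome_len = 20000L,
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_subfamilies = 3L,
                       within_subfamily_divergence = 0.05,
                       between_subfamily_divergence = 0.25,
                       element_len = 900L,
                       polya_len = 12L,
                       tsd_len_range = c(7L, 16L),
                       derivative_mode_probs = c(five_prime_truncation = 0.55,
                                                 template_switch = 0.15,
                                                 early_polyA = 0.15,
                                                 internal_deletion = 0.15),
                       n_strains = 8L,
                       p_recent_insertion = 0.5,
                       strain_divergence = 0.005) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8,
            abs(sum(derivative_mode_probs) - 1) < 1e-8,
            within_subfamily_divergence >= 0,
            between_subfamily_divergence >= 0,
            element_len >= 100,
            tsd_len_range[1] >= 1, tsd_len_range[1] <= tsd_len_range[2])
  structure(list(seed = as.integer(seed),
                 genome_len = as.integer(genome_len),
                 base_composition = base_composition,
                 n_subfamilies = as.integer(n_subfamilies),
                 within_subfamily_divergence = within_subfamily_divergence,
                 between_subfamily_divergence = between_subfamily_divergence,
                 element_len = as.integer(element_len),
                 polya_len = as.integer(polya_len),
                 tsd_len_range = as.integer(tsd_len_range),
                 derivative_mode_probs = derivative_mode_probs,
                 n_strains = as.integer(n_strains),
                 p_recent_insertion = p_recent_insertion,
                 strain_divergence = strain_divergence),
            class = "sim_params")
}
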