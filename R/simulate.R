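#' Random DNA string
#'
#' @param n Length in bp.
#' @param base_composition Probabilities for A, C, G, T.
#' @return A DNA string of length `n`.
#' @export
random_dna <- function(n, base_composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25)) {
  paste(sample(names(base_composition), n, replace = TRUE,
               prob = base_composition), collapse = "")
}

#' Apply neutral point substitutions to a sequence
#'
#' One-pass substitution model: each site mutates with probability
#' `divergence`, drawing uniformly among the three alternative bases (no
#' multiple hits within a branch). The expected proportion of differing
#' sites between the input and output is therefore exactly `divergence`.
#'
#' @param seq A DNA string.
#' @param divergence Per-site substitution probability.
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < divergence & chars %in%
                 c("A", "C", "G", "T"))
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Expected pairwise divergence between two mutated copies
#'
#' Closed form for the one-pass substitution model of [mutate_sequence()]:
#' two copies derived from a common ancestor along branches with per-site
#' substitution probabilities `p` and `q` differ at a site with probability
#' `p(1-q) + q(1-p) + (2/3)pq`.
#'
#' @param p,q Branch substitution probabilities.
#' @return Expected proportion of differing sites.
#' @export
expected_pairwise_divergence <- function(p, q = p) {
  p * (1 - q) + q * (1 - p) + (2 / 3) * p * q
}

#' Build an ancestral full-length element
#'
#' Constructs a scannable full-length element: the 5' consensus motif (with
#' the degenerate S position drawn from C/G), a ~20 bp C/T-rich
#' polypyrimidine patch, a random body, and a 3' poly(A) tract. At
#' divergence 0 the result is recovered as a single `full_length`
#' annotation by [scan_elements()].
#'
#' @param params A [sim_params()] object (element length, poly(A) length,
#'   base composition).
#' @return A DNA string of length `params$element_len`.
#' @export
make_ancestral_element <- function(params = sim_params()) {
  stopifnot(params$element_len >= 100)
  motif <- sub("S", sample(c("C", "G"), 1), "CAATCGTTSC")
  pyr_len <- 20L
  pyr <- paste(sample(c("C", "T"), pyr_len, replace = TRUE,
                      prob = c(0.5, 0.5)), collapse = "")
  body_len <- params$element_len - nchar(motif) - pyr_len - params$polya_len
  body <- random_dna(body_len, params$base_composition)
  paste0(motif, pyr, body, strrep("A", params$polya_len))
}

#' Simulate a TPRT insertion with target site duplication
#'
#' Models the staggered-cut geometry of target-primed reverse transcription:
#' the target bases `genome[position - tsd_len + 1 .. position]` are
#' duplicated around the inserted element, flanks untouched.
#'
#' @param genome A DNA string.
#' @param element The element sequence to insert.
#' @param position Insertion position: the element body is placed after this
#'   base (1-based).
#' @param tsd_len Target site duplication length (bp).
#' @return A list with `genome` (the filled sequence) and `truth`, a list
#'   recording the element span, both TSD copy spans, the duplicated string
#'   and the pre-insertion sequence.
#' @export
simulate_tprt_insertion <- function(genome, element, position, tsd_len) {
  n <- nchar(genome)
  el <- nchar(element)
  if (position < tsd_len || position >= n) {
    stop("position too close to contig edge for the requested TSD",
         call. = FALSE)
  }
  tsd <- substr(genome, position - tsd_len + 1L, position)
  filled <- paste0(substr(genome, 1L, position), element, tsd,
                   substr(genome, position + 1L, n))
  list(genome = filled,
       truth = list(element_span = c(position + 1L, position + el),
                    left_span = c(position - tsd_len + 1L, position),
                    right_span = c(position + el + 1L, position + el + tsd_len),
                    tsd = tsd, tsd_len = tsd_len,
                    pre_insertion = genome))
}

#' Derive a partial/chimeric element from a full-length parent
#'
#' Emulates the observed derivative structures: `five_prime_truncation`
#' (abortive reverse transcription leaves only the 3' portion, poly(A)
#' retained), `template_switch` (a 10-30 bp foreign block appears 5' of the
#' poly(A), as in chimeric retroposons), `early_polyA` (3'-truncated body
#' ending in a fresh poly(A), as from early polyadenylation), and
#' `internal_deletion`.
#'
#' @param parent Full-length parent sequence (at least 200 bp).
#' @param mode One of the four derivative modes.
#' @param params A [sim_params()] object.
#' @return The derivative DNA string.
#' @export
derive_element <- function(parent,
                           mode = c("five_prime_truncation", "template_switch",
                                    "early_polyA", "internal_deletion"),
                           params = sim_params()) {
  if (nchar(parent) < 200) stop("parent shorter than 200 bp", call. = FALSE)
  mode <- match.arg(mode)
  n <- nchar(parent)
  if (mode == "five_prime_truncation") {
    cut <- sample(seq(floor(0.2 * n), floor(0.6 * n)), 1)
    substr(parent, cut + 1L, n)
  } else if (mode == "template_switch") {
    body_end <- n - params$polya_len
    cut <- sample(seq(floor(0.3 * n), floor(0.7 * n)), 1)
    foreign <- random_dna(sample(10:30, 1), params$base_composition)
    paste0(substr(parent, cut + 1L, body_end), foreign,
           strrep("A", params$polya_len))
  } else if (mode == "early_polyA") {
    cut <- sample(seq(floor(0.5 * n), floor(0.8 * n)), 1)
    paste0(substr(parent, 1L, cut), strrep("A", params$polya_len))
  } else {
    del_len <- sample(seq(floor(0.1 * n), floor(0.4 * n)), 1)
    del_start <- sample(seq(30L, n - 30L - del_len), 1)
    paste0(substr(parent, 1L, del_start - 1L),
           substr(parent, del_start + del_len, n))
  }
}

#' Simulate a genome with planted full-length elements
#'
#' Plants `n_elements` copies of an ancestral element (each independently
#' mutated at `divergence` substitutions/site) into random spacer DNA via
#' [simulate_tprt_insertion()], with TSD lengths drawn from
#' `params$tsd_len_range`.
#'
#' @param params A [sim_params()] object; `params$seed` seeds the run.
#' @param n_elements Number of planted elements.
#' @param divergence Per-element divergence from the ancestor.
#' @param spacer_len Random DNA (bp) between consecutive insertion sites.
#' @return A list with `genome` (DNA string), `ancestor` (the founder
#'   element) and `truth` (data.frame: element spans, TSD copy spans, TSD
#'   string and per-element divergence, in final genome coordinates).
#' @export
simulate_element_genome <- function(params = sim_params(), n_elements = 10L,
                                    divergence = 0, spacer_len = 150L) {
  set.seed(params$seed)
  ancestor <- make_ancestral_element(params)
  base_len <- (n_elements + 1L) * spacer_len
  genome <- random_dna(base_len, params$base_composition)
  offset <- 0L
  rows <- vector("list", n_elements)
  for (i in seq_len(n_elements)) {
    el <- mutate_sequence(ancestor, divergence)
    k <- sample(seq(params$tsd_len_range[1], params$tsd_len_range[2]), 1)
    pos <- i * spacer_len + offset
    ins <- simulate_tprt_insertion(genome, el, pos, k)
    genome <- ins$genome
    rows[[i]] <- data.frame(
      element = sprintf("planted%02d", i),
      start = ins$truth$element_span[1], end = ins$truth$element_span[2],
      left_start = ins$truth$left_span[1], left_end = ins$truth$left_span[2],
      right_start = ins$truth$right_span[1],
      right_end = ins$truth$right_span[2],
      tsd = ins$truth$tsd, tsd_len = k, divergence = divergence,
      stringsAsFactors = FALSE)
    offset <- offset + nchar(el) + k
  }
  list(genome = genome, ancestor = ancestor, truth = do.call(rbind, rows))
}

#' Simulate a radiating element family
#'
#' Builds a family ancestor, `n_subfamilies` subfamily ancestors (each at
#' `between_subfamily_divergence / 2` substitutions/site from the family
#' ancestor, so subfamily pairs sit near the configured between-subfamily
#' divergence), and `members_per_subfamily` members per subfamily (each at
#' `within_subfamily_divergence / 2` from its subfamily ancestor).
#'
#' @param params A [sim_params()] object; `params$seed` seeds the run.
#' @param members_per_subfamily Members drawn per subfamily.
#' @return A list with `ancestor`, `subfamily_ancestors`, `members` (named
#'   character vector, names `S<i>m<j>`) and `truth` (data.frame mapping
#'   member to subfamily).
#' @export
simulate_family <- function(params = sim_params(), members_per_subfamily = 4L) {
  set.seed(params$seed)
  ancestor <- make_ancestral_element(params)
  sf <- lapply(seq_len(params$n_subfamilies), function(i) {
    mutate_sequence(ancestor, params$between_subfamily_divergence / 2)
  })
  members <- character(0)
  truth <- list()
  for (i in seq_len(params$n_subfamilies)) {
    for (j in seq_len(members_per_subfamily)) {
      nm <- sprintf("S%dm%d", i, j)
      members[[nm]] <- mutate_sequence(sf[[i]],
                                       params$within_subfamily_divergence / 2)
      truth[[nm]] <- data.frame(member = nm, subfamily = i,
                                stringsAsFactors = FALSE)
    }
  }
  list(ancestor = ancestor, subfamily_ancestors = sf, members = members,
       truth = do.call(rbind, truth))
}

#' Simulate a strain panel segregating ancestral and recent insertions
#'
#' Emulates the presence/absence structure of an insertion-polymorphism
#' survey: `n_ancestral` loci carry an insertion fixed in the panel
#' (inserted before strain divergence, so every strain is filled), and
#' `n_recent` loci carry a recent insertion present in the reference strain
#' and a random subset of the others (polymorphic by construction, as in a
#' panel of loci ascertained for polymorphism). Strains accumulate neutral
#' substitutions at `params$strain_divergence` per site. Strain 1
#' (`reference_strain`) plays the role of the annotated reference genome:
#' it carries every insertion, and the returned `reference` annotations
#' (element and TSD copy spans) are in its coordinates, which the
#' substitution-only model leaves stable across strains.
#'
#' @param params A [sim_params()] object; `params$seed` seeds the run.
#' @param n_ancestral,n_recent Locus counts of each age class.
#' @param flank_len Flank length (bp) on each side of an insertion site.
#' @return A list with `strains` (list of named locus-sequence vectors, one
#'   per strain), `reference` (per-locus element/TSD spans in strain-1
#'   coordinates), `presence` (logical matrix strains x loci) and `truth`
#'   (data.frame with the planted age class per locus).
#' @export
simulate_radiation <- function(params = sim_params(), n_ancestral = 4L,
                               n_recent = 3L, flank_len = 250L) {
  stopifnot(params$n_strains >= 2)
  set.seed(params$seed)
  element <- make_ancestral_element(params)
  n_loci <- n_ancestral + n_recent
  locus_names <- sprintf("locus%02d", seq_len(n_loci))
  age <- c(rep("ancestral", n_ancestral), rep("recent", n_recent))
  strains <- replicate(params$n_strains, character(0), simplify = FALSE)
  names(strains) <- sprintf("strain%02d", seq_len(params$n_strains))
  reference <- list()
  presence <- matrix(FALSE, params$n_strains, n_loci,
                     dimnames = list(names(strains), locus_names))
  for (l in seq_len(n_loci)) {
    pre <- random_dna(2L * flank_len, params$base_composition)
    pos <- flank_len
    k <- sample(seq(params$tsd_len_range[1], params$tsd_len_range[2]), 1)
    if (age[l] == "ancestral") {
      ins <- simulate_tprt_insertion(pre, element, pos, k)
      for (s in seq_len(params$n_strains)) {
        strains[[s]][[locus_names[l]]] <-
          mutate_sequence(ins$genome, params$strain_divergence)
        presence[s, l] <- TRUE
      }
      reference[[locus_names[l]]] <- ins$truth[c("element_span", "left_span",
                                                 "right_span", "tsd_len")]
    } else {
      carriers <- c(TRUE, stats::runif(params$n_strains - 1L) <
                            params$p_recent_insertion)
      while (all(carriers[-1]) || !any(carriers[-1])) {
        carriers <- c(TRUE, stats::runif(params$n_strains - 1L) <
                              params$p_recent_insertion)
      }
      for (s in seq_len(params$n_strains)) {
        strain_pre <- mutate_sequence(pre, params$strain_divergence)
        if (carriers[s]) {
          ins <- simulate_tprt_insertion(strain_pre, element, pos, k)
          strains[[s]][[locus_names[l]]] <- ins$genome
          if (s == 1L) {
            reference[[locus_names[l]]] <- ins$truth[c("element_span",
                                                       "left_span",
                                                       "right_span",
                                                       "tsd_len")]
          }
        } else {
          strains[[s]][[locus_names[l]]] <- strain_pre
        }
        presence[s, l] <- carriers[s]
      }
    }
  }
  list(strains = strains, reference = reference, presence = presence,
       truth = data.frame(locus = locus_names, age = age,
                          stringsAsFactors = FALSE))
}

#' Write a simulated radiation panel to disk
#'
#' One FASTA per strain (loci as records) plus a truth TSV.
#'
#' @param sim Output of [simulate_radiation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_radiation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$strains)) {
    write_genome_fasta(sim$strains[[s]], file.path(dir, paste0(s, ".fasta")))
  }
  truth <- sim$truth
  pres <- as.data.frame(t(sim$presence))
  truth <- cbind(truth, pres[truth$locus, , drop = FALSE])
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
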