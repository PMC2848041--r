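#' Reconstruct the pre-insertion (empty) allele of a filled locus
#'
#' Under the TPRT model a clean empty site carries a single copy of the
#' target site duplication. The reconstruction keeps the 5' flank up to and
#' including the left TSD copy, drops the element and the right copy, and
#' appends the 3' flank: its length is the locus length minus element length
#' minus TSD length.
#'
#' @param filled_locus DNA string of the filled locus.
#' @param element_span Integer `c(start, end)` of the element.
#' @param tsd A `tsd_call` (from [find_tsd()] or simulator truth) for this
#'   locus.
#' @return The reconstructed pre-insertion DNA string.
#' @export
predict_empty_site <- function(filled_locus, element_span, tsd) {
  n <- nchar(filled_locus)
  le <- tsd$left_span[2]
  re <- tsd$right_span[2]
  if (tsd$left_span[1] < 1 || re > n ||
      le > element_span[1] + 3L || tsd$right_span[1] < element_span[2] - 3L) {
    stop("TSD spans inconsistent with element span", call. = FALSE)
  }
  paste0(substr(filled_locus, 1L, le), substr(filled_locus, re + 1L, n))
}

#' Genotype an insertion locus in one strain
#'
#' Aligns the strain's locus sequence against the filled reference and the
#' reconstructed empty allele and assigns the state whose model fits within
#' `tolerance` (edit distance per reference base): `filled`, `empty_clean`,
#' `empty_other` (the locus lacks the element but is not a clean single-TSD
#' empty site, e.g. a deletion removing one flank), or `undetermined` (no
#' model aligns at all).
#'
#' @param strain_seq DNA string covering the locus in the queried strain.
#' @param filled_ref DNA string of the filled reference locus.
#' @param element_span,tsd Element annotation of `filled_ref` (see
#'   [find_tsd()]).
#' @param tolerance Maximum edit fraction for a clean model fit.
#' @param max_divergence Edit fraction above which neither model is
#'   considered aligned and the state is `undetermined`.
#' @return A list of class `site_genotype` with `state`, `edit_filled`,
#'   `edit_empty`, `reconstructed_preinsertion` and `notes`.
#' @export
genotype_site <- function(strain_seq, filled_ref, element_span, tsd,
                          tolerance = 0.02, max_divergence = 0.30) {
  empty_ref <- predict_empty_site(filled_ref, element_span, tsd)
  d_f <- utils::adist(strain_seq, filled_ref)[1, 1] / nchar(filled_ref)
  d_e <- utils::adist(strain_seq, empty_ref)[1, 1] / nchar(empty_ref)
  state <- if (min(d_f, d_e) > max_divergence) {
    "undetermined"
  } else if (d_f <= tolerance && d_f <= d_e) {
    "filled"
  } else if (d_e <= tolerance) {
    "empty_clean"
  } else if (d_e < d_f) {
    "empty_other"
  } else if (d_f <= tolerance) {
    "filled"
  } else {
    "undetermined"
  }
  notes <- sprintf("edit_filled=%.4f edit_empty=%.4f", d_f, d_e)
  structure(list(state = state, edit_filled = d_f, edit_empty = d_e,
                 reconstructed_preinsertion = empty_ref, notes = notes),
            class = "site_genotype")
}

#' @export
print.site_genotype <- function(x, ...) {
  cat(sprintf("site genotype: %s (%s)\n", x$state, x$notes))
  invisible(x)
}

#' Genotype a locus across a strain panel
#'
#' @param strain_seqs Named character vector: one locus sequence per strain.
#' @param filled_ref,element_span,tsd Reference locus annotation as in
#'   [genotype_site()].
#' @param tolerance,max_divergence Passed to [genotype_site()].
#' @return A data.frame with one row per strain (`strain`, `state`,
#'   `edit_filled`, `edit_empty`).
#' @export
genotype_panel <- function(strain_seqs, filled_ref, element_span, tsd,
                           tolerance = 0.02, max_divergence = 0.30) {
  rows <- lapply(names(strain_seqs), function(s) {
    g <- genotype_site(strain_seqs[[s]], filled_ref, element_span, tsd,
                       tolerance, max_divergence)
    data.frame(strain = s, state = g$state, edit_filled = g$edit_filled,
               edit_empty = g$edit_empty, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call insertion age classes from a presence/absence matrix
#'
#' A locus observed as a clean empty site in at least one strain and filled
#' in at least one other is a recent, still-polymorphic insertion; a locus
#' filled in every informative strain predates the sampled radiation
#' (`fixed_in_sample`). `undetermined` cells are ignored but counted in a
#' completeness note; `empty_other` cells do not support a clean TPRT
#' polymorphism call.
#'
#' @param matrix_df Data.frame with columns `strain`, `locus`, `state`
#'   (states as produced by [genotype_site()] or fixture mapping).
#' @return A data.frame with one row per locus: `locus`, `age_call`,
#'   `n_filled`, `n_empty_clean`, `n_other`, `n_undetermined`, `note`.
#' @export
call_insertion_age <- function(matrix_df) {
  stopifnot(all(c("strain", "locus", "state") %in% names(matrix_df)))
  if (length(unique(matrix_df$strain)) < 2) {
    stop("need at least 2 strains", call. = FALSE)
  }
  rows <- lapply(split(matrix_df, matrix_df$locus), function(d) {
    nf <- sum(d$state == "filled")
    ne <- sum(d$state == "empty_clean")
    no <- sum(d$state == "empty_other")
    nu <- sum(d$state == "undetermined")
    if (nf + ne + no == 0) {
      stop(sprintf("locus '%s': all cells undetermined", d$locus[1]),
           call. = FALSE)
    }
    call <- if (ne >= 1 && nf >= 1) "recent_polymorphic"
            else if (nf >= 1 && ne == 0) "fixed_in_sample"
            else NA_character_
    data.frame(locus = d$locus[1], age_call = call, n_filled = nf,
               n_empty_clean = ne, n_other = no, n_undetermined = nu,
               note = if (nu > 0) sprintf("%d strain(s) uninformative", nu)
                      else "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
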