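fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "retrokit")
  if (!nzchar(p)) stop(sprintf("packaged fixture '%s' not found", file),
                       call. = FALSE)
  p
}

#' Load the curated target-site table (A. thaliana)
#'
#' Fourteen element insertion loci with their 9 nt 5' nicking-site context,
#' target site duplication and 9 nt 3' nicking-site context, transcribed
#' verbatim (lowercase). Row `9L3` has no counterpart in the element
#' catalogue table -- the orphan ID is preserved as printed.
#'
#' @return A data.frame with columns `element`, `five_prime_nick`, `tsd`,
#'   `three_prime_nick`.
#' @export
load_target_site_table <- function() {
  d <- utils::read.delim(fixture_path("target_sites_thaliana.tsv"),
                         colClasses = "character")
  stopifnot(nrow(d) == 14)
  if (any(nchar(d$five_prime_nick) != 9) || any(nchar(d$three_prime_nick) != 9)) {
    stop("schema mismatch in column 'five_prime_nick'/'three_prime_nick': nicking contexts must be 9 nt",
         call. = FALSE)
  }
  d
}

#' Load the strain presence/absence panel for the Sadhu5 subfamily
#'
#' Twenty-four natural strains scored at four subfamily loci by three
#' assays each (internal product, 5' flank, 3' flank). Marks are preserved
#' verbatim (`X`, `X*`, `ES`, `Short`, `Long`, blank).
#'
#' @return A data.frame, one row per strain.
#' @export
load_strain_panel <- function() {
  d <- utils::read.delim(fixture_path("strain_panel_sadhu5.tsv"),
                         colClasses = "character")
  d[is.na(d)] <- ""
  stopifnot(nrow(d) == 24)
  d
}

#' Map strain-panel marks to site genotype states
#'
#' Conservative mapping of the panel's assay marks to per-strain locus
#' states: `X`/`X*` internal product present maps to `filled`, `ES` to
#' `empty_clean`, everything else (`Short`, `Long`, blank -- marks the
#' panel never defines) to `undetermined`.
#'
#' @param panel Data.frame from [load_strain_panel()].
#' @return A long data.frame with columns `strain`, `locus`, `state`,
#'   `provenance` (always `"fixture"`).
#' @export
strain_panel_states <- function(panel = load_strain_panel()) {
  loci <- c("Sadhu5-1", "Sadhu5-1d1", "Sadhu5-1d2", "Sadhu5-2")
  rows <- list()
  for (locus in loci) {
    int <- panel[[paste0(sub("-", ".", locus, fixed = TRUE), "_int")]]
    state <- ifelse(int %in% c("X", "X*"), "filled",
                    ifelse(int == "ES", "empty_clean", "undetermined"))
    rows[[locus]] <- data.frame(strain = panel$accession, locus = locus,
                                state = state, provenance = "fixture",
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the curated A. lyrata element table
#'
#' Twenty-five family members >350 bp found by iterative homology search of
#' the A. lyrata assembly: approximate scaffold coordinates, orientation,
#' length, TSD length (`ND` when not detected), full-length flag and percent
#' identity to the nearest A. thaliana reference. Lengths are kept verbatim
#' (two rows carry printed asterisks); a parsed integer `length_bp` column
#' is added.
#'
#' @return A data.frame with 25 rows.
#' @export
load_lyrata_table <- function() {
  d <- utils::read.delim(fixture_path("lyrata_elements.tsv"),
                         colClasses = "character")
  stopifnot(nrow(d) == 25)
  d$length_bp <- as.integer(gsub("\\*", "", d$length))
  d$tsd_len <- suppressWarnings(as.integer(d$tsd_bp))
  d$full_length <- d$full_length == "Yes"
  d$pct_identity <- as.numeric(d$pct_identity)
  d
}

#' Load the A. thaliana element catalogue
#'
#' The family nomenclature next to locus IDs and genome positions for the
#' 39 family-related sequences of the reference genome.
#'
#' @return A data.frame with columns `sadhu_number`, `locus_id`, `position`.
#' @export
load_thaliana_table <- function() {
  d <- utils::read.delim(fixture_path("thaliana_elements.tsv"),
                         colClasses = "character")
  stopifnot(nrow(d) == 39)
  d
}

#' Load all packaged reference tables
#'
#' @return A list with `elements` (A. thaliana catalogue), `strain_panel`,
#'   `target_sites` and `lyrata`.
#' @export
load_fixture_tables <- function() {
  list(elements = load_thaliana_table(),
       strain_panel = load_strain_panel(),
       target_sites = load_target_site_table(),
       lyrata = load_lyrata_table())
}

#' Reconstruct an insertion locus from a target-site table row
#'
#' Builds a worked-example filled locus as
#' `5' nick + TSD + stub + TSD + 3' nick`, where the stub is a synthetic
#' element body (the 5' consensus motif with S resolved to G, a run of G's,
#' and a 12 bp poly(A) tract). The G body keeps the stub from sharing
#' sequence with either flank, so the flanking direct repeat is exactly the
#' planted duplication unless the printed nick contexts themselves extend
#' it.
#'
#' @param row One row of [load_target_site_table()].
#' @param g_body_len Length of the G run inside the stub.
#' @param polya_len Length of the stub's poly(A) tract.
#' @return A list with `locus` (uppercase DNA string), `element_span`
#'   (span of the stub) and `tsd` (the printed duplication, uppercase).
#' @export
reconstruct_target_locus <- function(row, g_body_len = 40L, polya_len = 12L) {
  stub <- paste0("CAATCGTTGC", strrep("G", g_body_len),
                 strrep("A", polya_len))
  nick5 <- toupper(row$five_prime_nick)
  tsd <- toupper(row$tsd)
  nick3 <- toupper(row$three_prime_nick)
  locus <- paste0(nick5, tsd, stub, tsd, nick3)
  es <- nchar(nick5) + nchar(tsd) + 1L
  list(locus = locus,
       element_span = c(es, es + nchar(stub) - 1L),
       tsd = tsd)
}
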