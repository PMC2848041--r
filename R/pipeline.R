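#' Assemble a run configuration
#'
#' Collects all stage parameter blocks, paths and the seed into a single
#' validated list that serializes to JSON alongside the outputs for
#' provenance.
#'
#' @param fasta Input FASTA path.
#' @param out_dir Output directory.
#' @param references Optional FASTA of named full-length reference elements;
#'   when absent the run's own full-length discoveries form the reference
#'   set.
#' @param seed Integer seed.
#' @param scan,tsd,classifier Parameter objects (see [scan_params()],
#'   [tsd_params()], [classifier_params()]).
#' @param family_prefix Nomenclature prefix for newly named elements.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta, out_dir, references = NULL, seed = 1L,
                       scan = scan_params(), tsd = tsd_params(),
                       classifier = classifier_params(),
                       family_prefix = "Sadhu") {
  stopifnot(is.character(fasta), length(fasta) == 1)
  structure(list(fasta = fasta, out_dir = out_dir, references = references,
                 seed = as.integer(seed), scan = scan, tsd = tsd,
                 classifier = classifier, family_prefix = family_prefix),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()] object.
#' @param path JSON path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(fasta = raw$fasta, out_dir = raw$out_dir,
                    references = raw$references, seed = raw$seed,
                    scan = do.call(scan_params, raw$scan[setdiff(names(raw$scan), "motif_span")]),
                    tsd = do.call(tsd_params, raw$tsd),
                    classifier = do.call(classifier_params, raw$classifier),
                    family_prefix = raw$family_prefix)
  cfg
}

# single-linkage clustering of full-length elements into subfamilies by
# pairwise identity
cluster_subfamilies <- function(seqs, threshold, params) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  grp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        pi <- pairwise_identity(seqs[[i]], seqs[[j]], params)
        if (pi$identity > threshold) {
          grp[grp == grp[j]] <- grp[i]
        }
      }
    }
  }
  as.integer(factor(grp, levels = unique(grp)))
}

#' Run the annotation pipeline end to end
#'
#' Orchestrates scan, TSD detection, nicking-site consensus, classification
#' and naming, and a neighbor-joining tree of full-length elements, writing
#' a report bundle (GFF3, TSVs, newick, consensus matrix, config echo) to
#' `config$out_dir`. A stage failure aborts the run with the failing stage
#' named and removes partial outputs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the annotation tables, consensus profiles,
#'   tree and output paths.
#' @export
run_annotate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  out_path <- function(f) {
    p <- file.path(config$out_dir, f)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(outputs)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  genomes <- stage("ingest", {
    g <- read_genome_fasta(config$fasta)
    if (length(g) == 0) stop("no sequences in input FASTA")
    g
  })

  ann <- stage("scan", {
    res <- lapply(names(genomes), function(id) {
      scan_elements(genomes[[id]], config$scan, genome_id = id)
    })
    do.call(rbind, res)
  })

  tsd_rows <- stage("tsd", {
    rows <- list()
    contexts <- list()
    if (nrow(ann) > 0) {
      for (i in which(ann$structural_class == "full_length")) {
        g <- genomes[[ann$genome_id[i]]]
        span <- c(ann$start[i], ann$end[i])
        tsd <- tryCatch(find_tsd(g, span, config$tsd),
                        error = function(e) NULL)
        if (is.null(tsd)) next
        ctx <- tryCatch(
          extract_nick_contexts(g, span, tsd, strand = ann$strand[i]),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = ann$genome_id[i], start = ann$start[i],
          end = ann$end[i], strand = ann$strand[i],
          tsd = tsd$repeat_seq, tsd_len = tsd$length,
          mismatches = tsd$mismatches,
          five_prime_nick = if (is.null(ctx)) NA else ctx$five_prime_nick,
          three_prime_nick = if (is.null(ctx)) NA else ctx$three_prime_nick,
          stringsAsFactors = FALSE)
        if (!is.null(ctx) && nchar(ctx$tsd_prefix) == 7) {
          contexts[[length(contexts) + 1L]] <- ctx
        }
      }
    }
    list(table = if (length(rows)) do.call(rbind, rows) else NULL,
         contexts = contexts)
  })

  profiles <- stage("consensus", {
    if (length(tsd_rows$contexts) >= 1) {
      build_site_consensus(tsd_rows$contexts)
    } else NULL
  })

  named <- stage("classify", {
    if (nrow(ann) == 0) {
      ann$name <- character(0)
      list(ann = ann, references = character(0))
    } else {
      seqs <- vapply(seq_len(nrow(ann)), function(i) {
        s <- substr(genomes[[ann$genome_id[i]]], ann$start[i], ann$end[i])
        if (ann$strand[i] == "-") revcomp(s) else s
      }, character(1))
      names(seqs) <- sprintf("cand%03d", seq_len(nrow(ann)))
      if (!is.null(config$references)) {
        refs <- read_genome_fasta(config$references)
      } else {
        full <- which(ann$structural_class == "full_length")
        if (length(full) == 0) stop("no full-length elements and no reference set")
        grp <- cluster_subfamilies(seqs[full],
                                   config$classifier$derived_min_identity,
                                   config$classifier)
        refs <- character(0)
        for (k in seq_along(full)) {
          idx <- sum(grp[seq_len(k)] == grp[k])
          refs[[sprintf("%s%d-%d", config$family_prefix, grp[k], idx)]] <-
            seqs[[full[k]]]
        }
      }
      asn <- classify_elements(seqs, refs,
                               structural_class = ann$structural_class,
                               params = config$classifier)
      if (is.null(config$references)) {
        # the full-length candidates already carry their reference names
        full <- which(ann$structural_class == "full_length")
        asn$assigned_name <- NA_character_
        asn$assigned_name[full] <- names(refs)
        rest <- setdiff(seq_len(nrow(asn)), full)
        if (length(rest) > 0) {
          named_rest <- assign_names(asn[rest, , drop = FALSE],
                                     family_prefix = config$family_prefix,
                                     existing = names(refs))
          asn$assigned_name[rest] <- named_rest$assigned_name
        }
      } else {
        asn <- assign_names(asn, family_prefix = config$family_prefix,
                            existing = names(refs))
      }
      ann$name <- asn$assigned_name
      ann$relation <- asn$relation
      ann$nearest <- asn$nearest_full_length
      ann$identity <- asn$identity
      list(ann = ann, references = refs, seqs = seqs)
    }
  })
  ann <- named$ann

  tree <- stage("tree", {
    full <- which(ann$structural_class == "full_length")
    if (length(full) >= 3) {
      seqs <- named$seqs[full]
      names(seqs) <- ann$name[full]
      n <- length(seqs)
      dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          pi <- pairwise_identity(seqs[[i]], seqs[[j]], config$classifier)
          dm[i, j] <- dm[j, i] <- 1 - pi$identity
        }
      }
      neighbor_joining(dm)
    } else NULL
  })

  stage("report", {
    write_scan_gff3(ann, out_path("elements.gff3"))
    utils::write.table(ann, out_path("elements.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(tsd_rows$table)) {
      utils::write.table(tsd_rows$table, out_path("tsd.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(profiles)) {
      write_consensus_tsv(profiles, out_path("consensus.tsv"))
    }
    if (!is.null(tree)) {
      ape::write.tree(tree, out_path("tree.nwk"))
    }
    write_run_config(config, out_path("config.json"))
  })

  invisible(list(annotations = ann, tsd = tsd_rows$table,
                 profiles = profiles, tree = tree,
                 references = named$references, outputs = outputs))
}
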