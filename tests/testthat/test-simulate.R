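test_that("ancestral elements are structurally well-formed and seed-reproducible", {
  sp <- sim_params(seed = 701)
  set.seed(1); e1 <- make_ancestral_element(sp)
  set.seed(1); e2 <- make_ancestral_element(sp)
  expect_identical(e1, e2)
  expect_equal(nchar(e1), sp$element_len)
  expect_match(e1, "^CAATCGT")
  expect_match(e1, "AAAAAAAAAAAA$")
  # scannable as exactly one full-length annotation at divergence 0
  ann <- scan_elements(e1, scan_params(motif_max_mismatch = 0))
  expect_equal(sum(ann$structural_class == "full_length"), 1)
})

test_that("TPRT insertion duplicates the target and respects contig edges", {
  set.seed(702)
  g <- rand_dna(300)
  el <- "CCCCCCCCCCCCCCCCCCCC"
  for (k in c(7, 16)) {
    ins <- simulate_tprt_insertion(g, el, 150, k)
    expect_equal(nchar(ins$genome), 300 + 20 + k)
    expect_identical(substr(ins$genome, ins$truth$left_span[1],
                            ins$truth$left_span[2]),
                     substr(ins$genome, ins$truth$right_span[1],
                            ins$truth$right_span[2]))
    # flanks untouched
    expect_identical(substr(ins$genome, 1, 150), substr(g, 1, 150))
    det <- find_tsd(ins$genome, ins$truth$element_span)
    expect_gte(det$length, 7)
    expect_true(grepl(ins$truth$tsd, det$repeat_seq, fixed = TRUE))
  }
  expect_error(simulate_tprt_insertion(g, el, 3, 10), "contig edge")
  expect_error(simulate_tprt_insertion(g, el, 300, 10), "contig edge")
})

test_that("derivative modes produce the documented structures", {
  set.seed(703)
  sp <- sim_params(seed = 703)
  parent <- make_ancestral_element(sp)

  tr <- derive_element(parent, "five_prime_truncation", sp)
  expect_lt(nchar(tr), nchar(parent))
  # aligns to the parent 3' region at 100%
  expect_identical(substr(parent, nchar(parent) - nchar(tr) + 1,
                          nchar(parent)), tr)

  ts <- derive_element(parent, "template_switch", sp)
  expect_match(ts, "AAAAAAAAAAAA$")
  # contains a foreign block with no parent counterpart: the aligned
  # fraction of the chimera is visibly below 1
  pid <- pairwise_identity(ts, parent)
  expect_lt(pid$aligned_len, nchar(ts))

  ep <- derive_element(parent, "early_polyA", sp)
  expect_match(ep, "AAAAAAAAAAAA$")
  expect_lt(nchar(ep), nchar(parent))
  # 5' portion aligns perfectly
  expect_identical(substr(ep, 1, 50), substr(parent, 1, 50))

  dl <- derive_element(parent, "internal_deletion", sp)
  expect_lt(nchar(dl), nchar(parent))
  expect_identical(substr(dl, 1, 20), substr(parent, 1, 20))

  expect_error(derive_element("ACGT", "early_polyA"), "200")
})

test_that("classifier recovers the parent of a diverged truncation", {
  set.seed(704)
  fam <- simulate_family(sim_params(seed = 704, n_subfamilies = 3),
                         members_per_subfamily = 1)
  refs <- fam$members
  names(refs) <- c("Sadhu1-1", "Sadhu2-1", "Sadhu3-1")
  d <- mutate_sequence(derive_element(refs[["Sadhu3-1"]],
                                      "five_prime_truncation",
                                      sim_params()), 0.1)
  asn <- classify_elements(c(x = d), refs)
  expect_equal(asn$relation, "derived")
  expect_equal(asn$nearest_full_length, "Sadhu3-1")
})

test_that("realized pairwise identities track the substitution-model expectation", {
  set.seed(705)
  anc <- rand_dna(900)
  for (p in c(0.05, 0.10)) {
    pairs <- replicate(20, {
      a <- mutate_sequence(anc, p)
      b <- mutate_sequence(anc, p)
      mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    })
    expected <- expected_pairwise_divergence(p)
    expect_lt(abs(mean(pairs) - expected), 0.05)
    expect_true(all(abs(pairs - expected) < 0.05))
  }
})

test_that("radiation panels are seed-reproducible with polymorphic recent loci", {
  sp <- sim_params(seed = 706)
  r1 <- simulate_radiation(sp, n_ancestral = 2, n_recent = 2)
  r2 <- simulate_radiation(sp, n_ancestral = 2, n_recent = 2)
  expect_identical(r1$strains, r2$strains)
  expect_identical(r1$presence, r2$presence)

  # ancestral loci fixed; recent loci polymorphic by construction
  expect_true(all(r1$presence[, r1$truth$age == "ancestral"]))
  for (l in which(r1$truth$age == "recent")) {
    expect_true(r1$presence[1, l])            # reference strain carries it
    expect_true(any(!r1$presence[-1, l]))
    expect_true(any(r1$presence[-1, l]))
  }

  # p_recent_insertion = 0 is degenerate for a polymorphic panel, but a
  # panel of ancestral loci only is all-fixed downstream
  r3 <- simulate_radiation(sim_params(seed = 707), n_ancestral = 3,
                           n_recent = 0)
  states <- do.call(rbind, lapply(r3$truth$locus, function(l) {
    ref <- r3$reference[[l]]
    seqs <- vapply(r3$strains, function(s) s[[l]], character(1))
    d <- genotype_panel(seqs, r3$strains[[1]][[l]], ref$element_span,
                        list(left_span = ref$left_span,
                             right_span = ref$right_span))
    d$locus <- l
    d
  }))
  expect_true(all(call_insertion_age(states)$age_call == "fixed_in_sample"))
})

test_that("radiation output files are written and byte-stable for a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_radiation(simulate_radiation(sim_params(seed = 708, n_strains = 3),
                                     n_ancestral = 1, n_recent = 1), dir1)
  write_radiation(simulate_radiation(sim_params(seed = 708, n_strains = 3),
                                     n_ancestral = 1, n_recent = 1), dir2)
  f1 <- list.files(dir1)
  expect_true("strain01.fasta" %in% f1 && "truth.tsv" %in% f1)
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
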