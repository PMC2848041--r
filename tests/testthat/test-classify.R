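test_that("pairwise identity matches hand values and is symmetric", {
  expect_equal(pairwise_identity("ACGT", "ACGT")$identity, 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA")$identity, 0.75)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  set.seed(301)
  for (rep in 1:40) {
    a <- rand_dna(sample(10:30, 1)); b <- rand_dna(sample(10:30, 1))
    ab <- pairwise_identity(a, b); ba <- pairwise_identity(b, a)
    expect_equal(ab$identity, ba$identity)
  }
})

test_that("free-end-gap alignment score equals the Gotoh DP oracle", {
  set.seed(302)
  for (rep in 1:60) {
    a <- rand_dna(sample(8:30, 1)); b <- rand_dna(sample(8:30, 1))
    got <- pairwise_identity(a, b)$score
    want <- oracle_overlap_score(a, b)
    expect_equal(got, want)
  }
})

test_that("classification follows the derived/like rules and their boundaries", {
  set.seed(303)
  sp <- sim_params(seed = 303, n_subfamilies = 3,
                   between_subfamily_divergence = 0.4)
  fam <- simulate_family(sp, members_per_subfamily = 1)
  refs <- fam$members
  names(refs) <- c("Sadhu1-1", "Sadhu2-1", "Sadhu3-1")

  # a reference tested against the set containing itself
  self <- classify_elements(refs["Sadhu1-1"], refs,
                            structural_class = "full_length")
  expect_equal(self$relation, "member_full_length")
  expect_equal(self$identity, 1.0)

  # 5'-truncated copy at ~10% divergence -> derived of its parent
  d <- mutate_sequence(derive_element(refs[["Sadhu2-1"]],
                                      "five_prime_truncation"), 0.05)
  asn <- classify_elements(c(x = d), refs)
  expect_equal(asn$relation, "derived")
  expect_equal(asn$nearest_full_length, "Sadhu2-1")

  # a fragment far from everything -> like, attached to the arg-max identity
  # among references with a substantial aligned length
  far <- mutate_sequence(substr(refs[["Sadhu3-1"]], 400, 800), 0.35)
  asn2 <- classify_elements(c(y = far), refs)
  expect_equal(asn2$relation, "like")
  pis <- lapply(refs, function(r) pairwise_identity(far, r))
  ids <- vapply(pis, function(p) p$identity, numeric(1))
  lens <- vapply(pis, function(p) p$aligned_len, numeric(1))
  expect_equal(asn2$nearest_full_length, names(which.max(ids[lens >= 50])))

  # identity exactly at the threshold is NOT derived (strict inequality)
  one_ref <- c(`Sadhu1-1` = "GATCCATTGCAGTCGA")  # non-repetitive 16-mer
  cand <- one_ref[[1]]
  for (p in c(3, 7, 11, 15)) {
    substr(cand, p, p) <- chartr("ACGT", "TGCA", substr(cand, p, p))
  }
  pid <- pairwise_identity(cand, one_ref[[1]])$identity
  expect_equal(pid, 0.75)
  at_threshold <- classify_elements(c(z = cand), one_ref,
                                    params = classifier_params(min_like_aligned = 10))
  expect_equal(at_threshold$relation, "like")

  # duplicate reference names error
  dup <- refs; names(dup) <- c("a", "a", "b")
  expect_error(classify_elements(c(x = d), dup), "duplicate")
})

test_that("classification is invariant to reference-set order", {
  set.seed(304)
  fam <- simulate_family(sim_params(seed = 304, n_subfamilies = 3),
                         members_per_subfamily = 2)
  refs <- fam$members
  names(refs) <- sprintf("Sadhu%d-%d", rep(1:3, each = 2), rep(1:2, 3))
  cand <- mutate_sequence(derive_element(refs[[3]], "five_prime_truncation"),
                          0.05)
  a1 <- classify_elements(c(q = cand), refs)
  a2 <- classify_elements(c(q = cand), rev(refs))
  expect_equal(a1$nearest_full_length, a2$nearest_full_length)
  expect_equal(a1$relation, a2$relation)
  expect_equal(a1$identity, a2$identity)
})

test_that("nomenclature is generated, collision-free, and parses back", {
  asn <- data.frame(
    element = c("e1", "e2", "e3", "e4"),
    relation = c("derived", "derived", "like", "member_full_length"),
    nearest_full_length = c("Sadhu5-1", "Sadhu5-1", "Sadhu3-1", "Sadhu3-1"),
    identity = c(0.9, 0.85, 0.6, 0.8), aligned_len = 500,
    subfamily = c("5", "5", "3", "3"), stringsAsFactors = FALSE)
  named <- assign_names(asn, existing = c("Sadhu5-1", "Sadhu5-1d1",
                                          "Sadhu3-1"))
  # second derivative of Sadhu5-1 (d1 exists) -> d2, then d3
  expect_equal(named$assigned_name,
               c("Sadhu5-1d2", "Sadhu5-1d3", "Sadhu3L1", "Sadhu3-2"))
  expect_false(anyDuplicated(named$assigned_name) > 0)

  p <- parse_element_name("Sadhu5-1d2")
  expect_equal(p$subfamily, "5")
  expect_equal(p$element, "1")
  expect_equal(p$relation, "derived")
  expect_equal(p$index, 2L)
  p2 <- parse_element_name("AlSadhu3L1")
  expect_equal(p2$prefix, "Al")
  expect_equal(p2$relation, "like")

  empty <- assign_names(asn[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("star-alignment consensus recovers plurality bases and ancestors", {
  expect_equal(subfamily_consensus(c(a = "ACGT")), "ACGT")
  expect_equal(subfamily_consensus(c(a = "ACGT", b = "ACGT", c = "ACTT"),
                                   anchor = 1), "ACGT")
  # ancestor recovery from 9 members at 5% divergence
  set.seed(305)
  anc <- make_ancestral_element(sim_params(seed = 305))
  members <- vapply(1:9, function(i) mutate_sequence(anc, 0.05), character(1))
  names(members) <- paste0("m", 1:9)
  cons <- subfamily_consensus(members)
  mism <- sum(strsplit(cons, "")[[1]] != strsplit(anc, "")[[1]])
  expect_lte(mism / nchar(anc), 0.02)
})
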