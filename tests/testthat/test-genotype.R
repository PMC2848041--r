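test_that("empty-site reconstruction concatenates flank + single TSD + flank", {
  ts <- load_target_site_table()
  r <- reconstruct_target_locus(ts[ts$element == "5-1", ])
  planted <- list(left_span = c(r$element_span[1] - nchar(r$tsd),
                                r$element_span[1] - 1),
                  right_span = c(r$element_span[2] + 1,
                                 r$element_span[2] + nchar(r$tsd)))
  empty <- predict_empty_site(r$locus, r$element_span, planted)
  expect_equal(empty, toupper(paste0("ctgcaatat", "agtactactact", "aatgttatc")))
  expect_equal(nchar(empty),
               nchar(r$locus) - diff(r$element_span) - 1 - nchar(r$tsd))
  # inconsistent spans error
  bad <- list(left_span = c(1, 5), right_span = c(10, 14))
  expect_error(predict_empty_site(r$locus, r$element_span, bad),
               "inconsistent")
})

test_that("empty-site reconstruction exactly inverts TPRT insertion", {
  set.seed(601)
  sp <- sim_params(seed = 601)
  el <- make_ancestral_element(sp)
  for (rep in 1:50) {
    pre <- rand_dna(600)
    k <- sample(7:18, 1)
    pos <- sample(100:500, 1)
    ins <- simulate_tprt_insertion(pre, el, pos, k)
    got <- predict_empty_site(ins$genome, ins$truth$element_span,
                              list(left_span = ins$truth$left_span,
                                   right_span = ins$truth$right_span))
    expect_identical(got, pre)
  }
})

test_that("strains genotype as filled / clean empty / other / undetermined", {
  set.seed(602)
  sp <- sim_params(seed = 602)
  el <- make_ancestral_element(sp)
  pre <- rand_dna(700)
  ins <- simulate_tprt_insertion(pre, el, 350, 10)
  span <- ins$truth$element_span
  tsd <- list(left_span = ins$truth$left_span,
              right_span = ins$truth$right_span)

  carrier <- mutate_sequence(ins$genome, 0.01)
  expect_equal(genotype_site(carrier, ins$genome, span, tsd)$state, "filled")

  non_carrier <- mutate_sequence(pre, 0.01)
  expect_equal(genotype_site(non_carrier, ins$genome, span, tsd)$state,
               "empty_clean")

  # deletion removing the element plus one flank chunk (no TSD copy left)
  chopped <- paste0(substr(ins$genome, 1, 250),
                    substr(ins$genome, span[2] + 11, nchar(ins$genome)))
  expect_equal(genotype_site(chopped, ins$genome, span, tsd)$state,
               "empty_other")

  # unrelated sequence -> undetermined
  expect_equal(genotype_site(rand_dna(700), ins$genome, span, tsd)$state,
               "undetermined")

  # tolerance 0 on noise-free input: both models exact
  expect_equal(genotype_site(ins$genome, ins$genome, span, tsd,
                             tolerance = 0)$state, "filled")
  expect_equal(genotype_site(pre, ins$genome, span, tsd,
                             tolerance = 0)$state, "empty_clean")
})

test_that("genotyping is symmetric under strain relabeling", {
  rad <- simulate_radiation(sim_params(seed = 603, n_strains = 4),
                            n_ancestral = 1, n_recent = 1)
  l <- "locus02"
  ref <- rad$reference[[l]]
  seqs <- vapply(rad$strains, function(s) s[[l]], character(1))
  g1 <- genotype_panel(seqs, rad$strains[[1]][[l]], ref$element_span,
                       list(left_span = ref$left_span,
                            right_span = ref$right_span))
  perm <- c(3, 1, 4, 2)
  g2 <- genotype_panel(seqs[perm], rad$strains[[1]][[l]], ref$element_span,
                       list(left_span = ref$left_span,
                            right_span = ref$right_span))
  expect_equal(g2$state[match(g1$strain, g2$strain)], g1$state)
})

test_that("age calls separate polymorphic from fixed loci", {
  m <- data.frame(strain = rep(c("s1", "s2", "s3"), 2),
                  locus = rep(c("fixed", "poly"), each = 3),
                  state = c("filled", "filled", "filled",
                            "filled", "empty_clean", "undetermined"))
  calls <- call_insertion_age(m)
  expect_equal(calls$age_call[calls$locus == "fixed"], "fixed_in_sample")
  expect_equal(calls$age_call[calls$locus == "poly"], "recent_polymorphic")
  expect_equal(calls$n_undetermined[calls$locus == "poly"], 1)
  expect_match(calls$note[calls$locus == "poly"], "uninformative")

  expect_error(call_insertion_age(m[m$strain == "s1", ]), "at least 2")
  bad <- data.frame(strain = c("s1", "s2"), locus = "l",
                    state = "undetermined")
  expect_error(call_insertion_age(bad), "undetermined")
})

test_that("the strain-panel fixture reproduces the published genotype summary", {
  states <- strain_panel_states()
  expect_equal(nrow(states), 24 * 4)
  # two strains lack the Sadhu5-1 insertion as clean empty sites
  expect_equal(sum(states$state == "empty_clean" &
                     states$locus == "Sadhu5-1"), 2)
  ages <- call_insertion_age(states)
  expect_equal(ages$age_call[ages$locus == "Sadhu5-1"], "recent_polymorphic")
  expect_equal(ages$age_call[ages$locus == "Sadhu5-1d1"],
               "recent_polymorphic")
  expect_equal(ages$age_call[ages$locus == "Sadhu5-2"], "fixed_in_sample")
  expect_equal(ages$age_call[ages$locus == "Sadhu5-1d2"], "fixed_in_sample")
})
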