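test_that("find_tsd recovers the worked-example duplication", {
  ts <- load_target_site_table()
  r <- reconstruct_target_locus(ts[ts$element == "5-1", ])
  call <- find_tsd(r$locus, r$element_span)
  expect_s3_class(call, "tsd_call")
  expect_equal(call$repeat_seq, "AGTACTACTACT")
  expect_equal(call$mismatches, 0)
})

test_that("no qualifying repeat returns NULL; short flanks error by side", {
  locus <- paste0(strrep("G", 30), strrep("T", 50), strrep("C", 30))
  expect_null(find_tsd(locus, c(31, 80)))
  expect_error(find_tsd(paste0("AC", strrep("T", 50), strrep("G", 30)),
                        c(3, 52)), "left flank")
  expect_error(find_tsd(paste0(strrep("G", 30), strrep("T", 50), "AC"),
                        c(31, 80)), "right flank")
})

test_that("find_tsd equals the brute-force enumeration on random planted loci", {
  set.seed(201)
  for (rep in 1:120) {
    mk <- make_tsd_locus(tsd_len = sample(7:16, 1))
    got <- find_tsd(mk$locus, mk$element_span)
    want <- oracle_tsd(mk$locus, mk$element_span)
    expect_false(is.null(got))
    expect_equal(got$left_span, c(want$ls, want$le))
    expect_equal(got$right_span, c(want$rs, want$re))
    expect_equal(got$length, want$L)
    # containment of the planted duplication is the universal guarantee
    expect_true(grepl(mk$tsd, got$repeat_seq, fixed = TRUE))
  }
})

test_that("insert-then-detect recovers the planted TSD exactly when flanks cannot extend it", {
  # flanks of G/C only, TSD and stub of A/T only: no coincidental extension
  set.seed(202)
  for (k in c(7, 12, 16, 18)) {
    tsd <- paste(sample(c("A", "T"), k, replace = TRUE), collapse = "")
    flank <- function(n) paste(sample(c("G", "C"), n, replace = TRUE),
                               collapse = "")
    stub <- paste(sample(c("A", "T"), 60, replace = TRUE), collapse = "")
    locus <- paste0(flank(30), tsd, stub, tsd, flank(30))
    span <- c(31 + k, 30 + k + 60)
    got <- find_tsd(locus, span)
    # detected repeat contains the planted one; at zero boundary offset it
    # is the planted one unless the A/T stub edge coincides
    expect_true(grepl(tsd, got$repeat_seq, fixed = TRUE))
    expect_gte(got$length, k)
  }
})

test_that("nick contexts match the curated table and mirror under strand flip", {
  ts <- load_target_site_table()
  for (i in seq_len(nrow(ts))) {
    r <- reconstruct_target_locus(ts[i, ])
    call <- find_tsd(r$locus, r$element_span)
    # anchor the context windows on the printed TSD, not any extension
    planted <- list(left_span = c(r$element_span[1] - nchar(r$tsd),
                                  r$element_span[1] - 1),
                    right_span = c(r$element_span[2] + 1,
                                   r$element_span[2] + nchar(r$tsd)),
                    repeat_seq = r$tsd, length = nchar(r$tsd))
    ctx <- extract_nick_contexts(r$locus, r$element_span, planted)
    expect_equal(ctx$five_prime_nick, toupper(ts$five_prime_nick[i]))
    expect_equal(ctx$three_prime_nick, toupper(ts$three_prime_nick[i]))
    expect_equal(ctx$tsd_prefix, substr(toupper(ts$tsd[i]), 1, 7))

    # minus-strand element: mirrored windows
    n <- nchar(r$locus)
    flip <- function(sp) c(n - sp[2] + 1, n - sp[1] + 1)
    rc_tsd <- list(left_span = flip(planted$right_span),
                   right_span = flip(planted$left_span),
                   repeat_seq = revcomp(r$tsd), length = nchar(r$tsd))
    ctx2 <- extract_nick_contexts(revcomp(r$locus), flip(r$element_span),
                                  rc_tsd, strand = "-")
    expect_equal(ctx2$five_prime_nick, ctx$five_prime_nick)
    expect_equal(ctx2$three_prime_nick, ctx$three_prime_nick)
    expect_equal(ctx2$tsd_prefix, ctx$tsd_prefix)
  }
  # flank shorter than 9 nt errors
  r <- reconstruct_target_locus(ts[1, ])
  short <- substr(r$locus, 3, nchar(r$locus))
  planted <- list(left_span = c(r$element_span[1] - nchar(r$tsd) - 2,
                                r$element_span[1] - 3),
                  right_span = c(r$element_span[2] - 1,
                                 r$element_span[2] + nchar(r$tsd) - 2),
                  repeat_seq = r$tsd, length = nchar(r$tsd))
  expect_error(extract_nick_contexts(short, r$element_span - 2, planted),
               "shorter than 9")
})

test_that("consensus profiles count exactly and report bits in [0, 2]", {
  ts <- load_target_site_table()
  contexts <- lapply(seq_len(nrow(ts)), function(i) {
    structure(list(five_prime_nick = toupper(ts$five_prime_nick[i]),
                   tsd_prefix = substr(toupper(ts$tsd[i]), 1, 7),
                   three_prime_nick = toupper(ts$three_prime_nick[i])),
              class = "nick_context")
  })
  prof <- build_site_consensus(contexts)
  expect_equal(unname(colSums(prof$five_prime_nick$counts)), rep(14, 9))
  expect_equal(unname(colSums(prof$tsd_prefix$counts)), rep(14, 7))
  # first TSD base favors adenine (12 of 14 loci)
  expect_equal(unname(prof$tsd_prefix$counts["A", 1]), 12)
  # 5' nicking site favors thymine at the cut (position 9): 7 of 14
  expect_equal(unname(prof$five_prime_nick$counts["T", 9]), 7)
  expect_equal(names(which.max(prof$five_prime_nick$counts[, 9])), "T")
  expect_true(all(prof$five_prime_nick$bits >= 0 &
                  prof$five_prime_nick$bits <= 2 + 1e-12))

  # permutation invariance
  prof2 <- build_site_consensus(rev(contexts))
  expect_equal(prof2$tsd_prefix$counts, prof$tsd_prefix$counts)

  # single uniform context: 2 bits everywhere
  one <- structure(list(five_prime_nick = "AAAAAAAAA", tsd_prefix = "AAAAAAA",
                        three_prime_nick = "AAAAAAAAA"),
                   class = "nick_context")
  p1 <- build_site_consensus(list(one))
  expect_equal(unname(p1$five_prime_nick$bits), rep(2, 9))

  # mixed window lengths error
  bad <- contexts
  bad[[1]]$five_prime_nick <- "ACGT"
  expect_error(build_site_consensus(bad), "mixed")
})
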