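test_that("fusion pseudo-transcripts carry primer sites and probes in order", {
  p <- zeroNoise(21)
  tx <- as.character(makeFusionTranscript(the_panel, "AML1-ETO", NULL, p))
  pb <- probes(the_panel)
  seqs <- setNames(pb$sequence, pb$probe_id)
  pos <- vapply(c("AML1ex5", "AML1-ETO", "ETO"), function(id)
    regexpr(seqs[[id]], tx, fixed = TRUE)[1], numeric(1))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0))  # 5' partner, junction, 3' partner
  # forward primer site precedes them; reverse site (revcomp) follows
  fwd <- primers(the_panel)$gene_specific_seq[
    primers(the_panel)$name == "AML1_F"]
  rev <- primers(the_panel)$gene_specific_seq[
    primers(the_panel)$name == "ETO_R"]
  expect_lt(regexpr(fwd, tx, fixed = TRUE)[1], pos[1])
  expect_gt(regexpr(revcompChr(rev), tx, fixed = TRUE)[1], pos[3])
})

test_that("NOVEL and MLL-style transcripts omit the junction probe", {
  p <- zeroNoise(22)
  pb <- probes(the_panel)
  seqs <- setNames(pb$sequence, pb$probe_id)

  vform <- as.character(makeFusionTranscript(the_panel, "PML-RARA", "NOVEL", p))
  expect_true(grepl(seqs[["PML-L"]], vform, fixed = TRUE))
  expect_true(grepl(seqs[["RARA"]], vform, fixed = TRUE))
  expect_false(grepl(seqs[["PML-RARA-L"]], vform, fixed = TRUE))
  expect_false(grepl(seqs[["PML-RARA-S"]], vform, fixed = TRUE))

  af9 <- as.character(makeFusionTranscript(the_panel, "MLL-AF9", NULL, p))
  expect_true(grepl(seqs[["MLL"]], af9, fixed = TRUE))
  expect_true(grepl(seqs[["AF9"]], af9, fixed = TRUE))

  expect_error(makeFusionTranscript(the_panel, "NOSUCH", NULL, p),
               "unknown fusion_id")
  expect_error(makeFusionTranscript(the_panel, "PML-RARA", "bogus", p),
               "unknown variant")
})

test_that("the control transcript contains the GUS probe and honours the seed contract", {
  p1 <- zeroNoise(31); p2 <- zeroNoise(32)
  gus_seq <- probes(the_panel)$sequence[probes(the_panel)$probe_id == "GUS"]
  t1 <- as.character(makeControlTranscript(the_panel, p1))
  t1b <- as.character(makeControlTranscript(the_panel, p1))
  t2 <- as.character(makeControlTranscript(the_panel, p2))
  expect_true(grepl(gus_seq, t1, fixed = TRUE))
  expect_identical(t1, t1b)        # same seed, same spacers
  expect_false(identical(t1, t2))  # different seed, different spacers
  expect_true(grepl(gus_seq, t2, fixed = TRUE))  # same functional content

  # degenerate spacers still give a valid, assayable transcript
  p0 <- simParams(seed = 9, spacer_len = 0, noise_sigma = 0)
  t0 <- makeControlTranscript(the_panel, p0)
  expect_true("GUS" %in% simulateAssay(t0, the_panel)$bound)
})

test_that("intensity grids are seed-deterministic with exact zero-noise levels", {
  p <- zeroNoise(41)
  ly <- arrayLayout(the_panel)
  g1 <- simulateIntensityGrid(ly, c("GUS"), p, "s")
  g2 <- simulateIntensityGrid(ly, c("GUS"), p, "s")
  expect_identical(spots(g1), spots(g2))

  sp <- spots(g1)
  expect_true(all(sp$intensity[sp$content == "GUS"] == exp(p$signal_mu)))
  expect_true(all(sp$intensity[sp$content == "BIOTIN"] ==
                    exp(p$biotin_level)))
  expect_true(all(sp$intensity[!sp$content %in% c("GUS", "BIOTIN")] ==
                    exp(p$baseline_mu)))

  # nothing bound: every probe spot sits at baseline
  g0 <- simulateIntensityGrid(ly, character(0), p)
  sp0 <- spots(g0)
  expect_true(all(sp0$intensity[sp0$content != "BIOTIN"] ==
                    exp(p$baseline_mu)))

  expect_warning(simulateIntensityGrid(ly, c("NOT-A-PROBE"), p),
                 "not on the layout")
})

test_that("an AML1-ETO sample is called correctly in at least 99 of 100 noisy seeds", {
  p <- simParams(seed = 1)  # default noise
  bound <- simulateAssay(c(makeControlTranscript(the_panel, p),
                           makeFusionTranscript(the_panel, "AML1-ETO", NULL, p)),
                         the_panel)$bound
  refs <- lapply(1:4, function(i) {
    pp <- p; pp$seed <- 5000L + i
    simulateIntensityGrid(arrayLayout(the_panel), character(0), pp)
  })
  bg <- computeBackground(refs)
  hits <- 0L
  for (s in 1:100) {
    pp <- p; pp$seed <- s
    g <- simulateIntensityGrid(arrayLayout(the_panel), bound, pp, "mc")
    rep <- callGrid(g, the_panel, bg)
    calls <- fusionCalls(rep)
    ok <- qcPass(rep) && nrow(calls) == 1L &&
      calls$fusion_id == "AML1-ETO" && calls$status == "positive"
    hits <- hits + ok
  }
  expect_gte(hits, 99L)
})

test_that("cohort generation respects the requested composition and reproduces bitwise", {
  comp <- data.frame(group = c("AML", "CML"),
                     fusion_id = c("AML1-ETO", "BCR-ABL"),
                     variant_label = c("", "p210-b3a2"),
                     n = c(2L, 1L), stringsAsFactors = FALSE)
  tbl <- cohortGenotypes(comp, group_n = c(AML = 4L, CML = 2L),
                         n_qc_fail = c(AML = 1L, CML = 0L))
  expect_equal(nrow(tbl$genotypes), 6L)
  expect_equal(sum(nzchar(tbl$genotypes$fusion_id)), 3L)
  expect_equal(sum(tbl$genotypes$include_control == 0L), 1L)
  expect_equal(nrow(tbl$references), 6L)

  p <- simParams(seed = 77)
  c1 <- makeCohort(the_panel, tbl$genotypes, p)
  c2 <- makeCohort(the_panel, tbl$genotypes, p)
  expect_identical(lapply(c1$grids, spots), lapply(c2$grids, spots))
  expect_equal(length(c1$grids), 6L)

  # over-subscribed group
  expect_error(cohortGenotypes(data.frame(group = "AML",
                                          fusion_id = "AML1-ETO",
                                          variant_label = "", n = 75L),
                               group_n = c(AML = 74L)),
               "group size")
  # empty table -> empty cohort
  empty <- makeCohort(the_panel, tbl$genotypes[0, ], p)
  expect_length(empty$grids, 0L)
  # unknown fusion rejected
  badg <- tbl$genotypes; badg$fusion_id[1] <- "NOSUCH"
  expect_error(makeCohort(the_panel, badg, p), "unknown fusion")
})
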