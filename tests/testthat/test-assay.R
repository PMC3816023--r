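eto_gs <- primers(the_panel)$gene_specific_seq[
  primers(the_panel)$name == "ETO_R"]

test_that("findPrimerSites matches a brute-force Hamming scan", {
  set.seed(101)
  for (rep in 1:20) {
    seq <- randomDnaChr(150)
    gs <- primers(the_panel)$gene_specific_seq[
      sample(which(nzchar(primers(the_panel)$gene_specific_seq)), 1)]
    # plant a forward site and a reverse site
    seq <- paste0(seq, gs, randomDnaChr(20), revcompChr(gs), randomDnaChr(10))
    for (mm in 0:2) {
      fwd <- findPrimerSites(seq, gs, "forward", mm)
      expect_identical(IRanges::start(fwd), bruteStarts(seq, gs, mm))
      rev <- findPrimerSites(seq, gs, "reverse", mm)
      expect_identical(IRanges::start(rev),
                       bruteStarts(seq, revcompChr(gs), mm))
    }
  }
})

test_that("two planted reverse sites are reported in ascending order", {
  seq <- paste0(randomDnaChr(30), revcompChr(eto_gs), randomDnaChr(40),
                revcompChr(eto_gs), randomDnaChr(15))
  sites <- findPrimerSites(seq, eto_gs, "reverse", 0)
  expect_length(sites, 2L)
  expect_true(IRanges::start(sites)[1] < IRanges::start(sites)[2])
  # no site and primer-longer-than-sequence cases are empty
  expect_length(findPrimerSites(randomDnaChr(60), eto_gs, "reverse", 0), 0L)
  expect_length(findPrimerSites("ACGT", eto_gs, "forward", 0), 0L)
})

test_that("reverse transcription emits SP6-tagged cDNAs, one per site", {
  p <- zeroNoise(3)
  gus <- makeControlTranscript(the_panel, p)
  cdnas <- reverseTranscribe(gus, the_panel)
  expect_equal(nrow(cdnas), 1L)
  expect_true(startsWith(cdnas$sequence, unname(universalTags()["SP6"])))
  # the cDNA copies the transcript 5' of the primer site
  expect_equal(nchar(cdnas$sequence),
               nchar(universalTags()["SP6"]) +
                 (cdnas$site_end - cdnas$site_start + 1L) +
                 (cdnas$site_start - 1L), ignore_attr = TRUE)

  # no binding site anywhere -> nothing
  none <- Biostrings::DNAStringSet(c(empty = randomDnaChr(400)))
  expect_equal(nrow(reverseTranscribe(none, the_panel)), 0L)

  # two distinct reverse sites -> two cDNAs
  af4_gs <- primers(the_panel)$gene_specific_seq[
    primers(the_panel)$name == "AF4_R"]
  two <- Biostrings::DNAStringSet(c(
    two = paste0(randomDnaChr(25), revcompChr(eto_gs), randomDnaChr(25),
                 revcompChr(af4_gs), randomDnaChr(25))))
  expect_equal(nrow(reverseTranscribe(two, the_panel)), 2L)
})

test_that("amplification yields tagged biotinylated products spanning the junction", {
  p <- zeroNoise(5)
  tx <- makeFusionTranscript(the_panel, "AML1-ETO", NULL, p)
  sa <- simulateAssay(tx, the_panel)
  expect_equal(nrow(sa$amplicons), 1L)
  expect_true(all(sa$amplicons$biotinylated))
  junction <- probes(the_panel)$sequence[
    probes(the_panel)$probe_id == "AML1-ETO"]
  expect_true(grepl(junction, sa$amplicons$top_strand[1], fixed = TRUE))
  # tag conservation on every product
  expect_true(all(startsWith(sa$amplicons$top_strand,
                             unname(universalTags()["T7"]))))
  expect_true(all(endsWith(sa$amplicons$top_strand,
                           revcompChr(unname(universalTags()["SP6"])))))
})

test_that("a forward site 3' of the reverse site never amplifies", {
  aml1f_gs <- primers(the_panel)$gene_specific_seq[
    primers(the_panel)$name == "AML1_F"]
  # reverse (ETO_R) site upstream of the forward (AML1_F) site
  seq <- Biostrings::DNAStringSet(c(
    flipped = paste0(randomDnaChr(20), revcompChr(eto_gs), randomDnaChr(20),
                     aml1f_gs, randomDnaChr(20))))
  cdnas <- reverseTranscribe(seq, the_panel)
  expect_equal(nrow(cdnas), 1L)
  expect_equal(nrow(amplify(cdnas, seq, the_panel)), 0L)
})

test_that("no-template input produces no amplicons and no bound probes", {
  empty <- Biostrings::DNAStringSet()
  sa <- simulateAssay(empty, the_panel)
  expect_equal(nrow(sa$amplicons), 0L)
  expect_length(sa$bound, 0L)
})

test_that("hybridization is strand-symmetric and requires biotinylation", {
  b3a2 <- probes(the_panel)$sequence[
    probes(the_panel)$probe_id == "p210-b3a2"]
  t7 <- unname(universalTags()["T7"]); sp6 <- unname(universalTags()["SP6"])
  mkamp <- function(insert, biot) data.frame(
    transcript_id = "t", forward_primer = "f", reverse_primer = "r",
    top_strand = paste0(t7, insert, revcompChr(sp6)),
    insert_start = 1L, insert_end = nchar(insert), round = 2L,
    biotinylated = biot, stringsAsFactors = FALSE)

  # probe planted on the bottom strand (top strand holds its revcomp)
  amp <- mkamp(paste0("ACGT", revcompChr(b3a2), "ACGT"), TRUE)
  expect_true("p210-b3a2" %in% boundProbes(hybridize(amp, the_panel)))

  # identical product without the biotin label generates no signal
  cold <- mkamp(paste0("ACGT", revcompChr(b3a2), "ACGT"), FALSE)
  expect_length(boundProbes(hybridize(cold, the_panel)), 0L)

  # empty amplicon table -> nothing bound
  none <- amp[0, ]
  expect_length(boundProbes(hybridize(none, the_panel)), 0L)
})

test_that("a K-562-style transcript binds the b3a2 junction and its partner probes", {
  p <- zeroNoise(7)
  tx <- makeFusionTranscript(the_panel, "BCR-ABL", "p210-b3a2", p)
  bound <- simulateAssay(tx, the_panel)$bound
  expect_true(all(c("p210-b3a2", "BCR210", "ABL") %in% bound))
  expect_false(any(c("p190", "p210-b2a2", "p230", "BCR190") %in% bound))
})

test_that("the assay is deterministic and monotone in the mismatch tolerance", {
  p <- zeroNoise(11)
  tx <- c(makeControlTranscript(the_panel, p),
          makeFusionTranscript(the_panel, "TEL-AML1", "TEL-AML1ex2", p))
  a <- simulateAssay(tx, the_panel)
  b <- simulateAssay(tx, the_panel)
  expect_identical(a$amplicons, b$amplicons)
  expect_identical(a$bound, b$bound)

  # raising max_mismatch never loses sites, amplicons or bound probes
  seqchr <- as.character(tx[[2]])
  gs <- primers(the_panel)$gene_specific_seq[
    primers(the_panel)$name == "AML1_R"]
  for (mm in 0:2) {
    s0 <- IRanges::start(findPrimerSites(seqchr, gs, "reverse", mm))
    s1 <- IRanges::start(findPrimerSites(seqchr, gs, "reverse", mm + 1L))
    expect_true(all(s0 %in% s1))
  }
  for (mm in 0:1) {
    b0 <- simulateAssay(tx, the_panel, max_mismatch = mm)$bound
    b1 <- simulateAssay(tx, the_panel, max_mismatch = mm + 1L)$bound
    expect_true(all(b0 %in% b1))
  }
})
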