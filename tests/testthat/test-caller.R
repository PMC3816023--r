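test_that("replicate aggregation is an arithmetic mean per spot content", {
  g <- gridFromValues(list(A = c(90, 100, 110), B = c(100, 100, 100),
                           BIOTIN = c(10000, 10000), BLANK = c(50, 60)))
  agg <- aggregateReplicates(g)
  expect_equal(agg$mean_intensity[agg$probe_id == "A"], 100)
  expect_equal(agg$mean_intensity[agg$probe_id == "B"], 100)
  expect_equal(agg$n_replicates[agg$probe_id == "A"], 3L)
  # BIOTIN and BLANK aggregate separately; absent probes stay absent
  expect_equal(agg$mean_intensity[agg$probe_id == "BIOTIN"], 10000)
  expect_false("C" %in% agg$probe_id)
})

test_that("background is the pooled reference mean plus a multiple of the sample SD", {
  refs <- lapply(c(100, 110, 120), function(v)
    gridFromValues(list(X = rep(v, 3))))
  bg <- computeBackground(refs)
  expect_equal(bg$background[bg$probe_id == "X"], 110 + 3 * 10)
  expect_equal(bg$n_reference[bg$probe_id == "X"], 3L)

  # identical references: SD 0, background equals the common value
  same <- lapply(1:3, function(i) gridFromValues(list(X = rep(80, 3))))
  expect_equal(computeBackground(same)$background, 80)

  # averaged blank values enter each probe's pool
  withblank <- lapply(c(100, 120), function(v)
    gridFromValues(list(X = rep(v, 3), BLANK = rep(110, 3))))
  expect_equal(computeBackground(withblank)$ref_mean, mean(c(100, 110, 120, 110)))

  # a single reference value leaves the SD undefined
  expect_error(computeBackground(list(gridFromValues(list(X = 100)))),
               "fewer than 2 reference values")
})

test_that("the cutoff is a fixed fraction of this array's biotin mean", {
  g <- gridFromValues(list(A = c(1, 2, 3), BIOTIN = rep(10000, 3)))
  expect_equal(computeCutoff(g), 1500)
  g8 <- gridFromValues(list(A = c(1, 2, 3), BIOTIN = c(7000, 8000, 9000)))
  expect_equal(computeCutoff(g8), 1200)
  expect_equal(computeCutoff(g8, callerConfig(cutoff_fraction = 0.5)), 4000)
  nob <- gridFromValues(list(A = c(1, 2, 3)))
  expect_error(computeCutoff(nob), "no BIOTIN")
})

test_that("true signals require strictly exceeding both thresholds", {
  bg <- data.frame(probe_id = c("A", "B", "C"),
                   background = c(140, 140, 140),
                   ref_mean = 110, ref_sd = 10, n_reference = 3L)
  sig <- data.frame(probe_id = c("A", "B", "C"),
                    mean_intensity = c(2000, 1500, 1400),
                    n_replicates = 3L)
  # A clears both; B sits exactly at the cutoff ("higher than" is strict);
  # C clears background only
  expect_identical(flagTrueSignals(sig, bg, 1500), "A")
  # non-strict comparison admits the boundary case
  expect_setequal(flagTrueSignals(sig, bg, 1500,
                                  callerConfig(strict_inequality = FALSE)),
                  c("A", "B"))
  # a probe absent from the background table can never be true
  sig2 <- rbind(sig, data.frame(probe_id = "D", mean_intensity = 1e6,
                                n_replicates = 3L))
  expect_message(out <- flagTrueSignals(sig2, bg, 1500), "without background")
  expect_identical(out, "A")
})

test_that("flagTrueSignals agrees with the brute-force threshold oracle on random grids", {
  set.seed(202)
  ids <- probes(the_panel)$probe_id
  bg <- data.frame(probe_id = ids,
                   background = runif(length(ids), 100, 3000),
                   ref_mean = 0, ref_sd = 0, n_reference = 3L)
  for (rep in 1:10) {
    vals <- setNames(lapply(ids, function(i) runif(3, 0, 6000)), ids)
    vals$BIOTIN <- runif(3, 5000, 30000)
    vals$BLANK <- runif(3, 0, 300)
    g <- gridFromValues(vals)
    cutoff <- computeCutoff(g)
    got <- sort(flagTrueSignals(aggregateReplicates(g), bg, cutoff))
    expect_identical(got, bruteTrueSignals(g, bg, cutoff))
  }
})

test_that("raising the cutoff fraction or SD multiplier never adds true probes or calls", {
  p <- simParams(seed = 55)
  bound <- simulateAssay(c(makeControlTranscript(the_panel, p),
                           makeFusionTranscript(the_panel, "CBFB-MYH11", "A", p)),
                         the_panel)$bound
  g <- simulateIntensityGrid(arrayLayout(the_panel), bound, p, "mono")
  refs <- lapply(1:3, function(i) {
    pp <- p; pp$seed <- 900L + i
    simulateIntensityGrid(arrayLayout(the_panel), character(0), pp)
  })
  agg <- aggregateReplicates(g)
  prev_true <- NULL; prev_calls <- NULL
  for (cf in c(0.05, 0.15, 0.5, 0.9)) for (sdm in c(1, 3, 10)) {
    cfg <- callerConfig(cutoff_fraction = cf, sd_multiplier = sdm)
    bg <- computeBackground(refs, cfg)
    tr <- flagTrueSignals(agg, bg, computeCutoff(g, cfg), cfg)
    calls <- fusionCalls(callSample(tr, the_panel, cfg))
    if (!is.null(prev_true) && cf >= prev_true$cf && sdm >= prev_true$sdm) {
      expect_true(all(tr %in% prev_true$tr))
      expect_true(all(calls$fusion_id %in% prev_calls$fusion_id))
    }
    prev_true <- list(tr = tr, cf = cf, sdm = sdm); prev_calls <- calls
  }
})

test_that("callSample applies the published positivity, QC and variant-flag rules", {
  # junction + both partners + control -> positive
  r <- callSample(c("AML1-ETO", "AML1ex5", "ETO", "GUS"), the_panel)
  expect_true(qcPass(r))
  calls <- fusionCalls(r)
  expect_equal(calls$fusion_id, "AML1-ETO")
  expect_equal(calls$status, "positive")

  # partners without any junction probe -> variant flag (V-form inference)
  r <- callSample(c("PML-L", "RARA", "GUS"), the_panel)
  calls <- fusionCalls(r)
  expect_equal(calls$fusion_id, "PML-RARA")
  expect_equal(calls$status, "variant_flag")

  # BCR-ABL p210 b3a2: junction/partner pairing is hard-wired per form
  r <- callSample(c("p210-b3a2", "BCR210", "ABL", "GUS"), the_panel)
  calls <- fusionCalls(r)
  expect_equal(calls$fusion_id, "BCR-ABL")
  expect_equal(calls$variant_label, "p210-b3a2")
  expect_equal(calls$status, "positive")
  # a stray ABL partner signal alone never calls
  r <- callSample(c("ABL", "GUS"), the_panel)
  expect_equal(nrow(fusionCalls(r)), 0L)

  # MLL-style: partner pair suffices, no variant label
  r <- callSample(c("MLL", "AF9", "GUS"), the_panel)
  calls <- fusionCalls(r)
  expect_equal(calls$fusion_id, "MLL-AF9")
  expect_equal(calls$variant_label, "")
  # two MLL partner genes true -> both calls plus a warning
  expect_warning(r <- callSample(c("MLL", "AF9", "AF4", "GUS"), the_panel),
                 "multiple MLL")
  expect_setequal(fusionCalls(r)$fusion_id, c("MLL-AF9", "MLL-AF4"))

  # control-only sample is a valid negative
  r <- callSample(c("GUS"), the_panel)
  expect_true(qcPass(r))
  expect_equal(nrow(fusionCalls(r)), 0L)

  # missing internal control invalidates the sample and suppresses calls
  r <- callSample(c("AML1-ETO", "AML1ex5", "ETO"), the_panel)
  expect_false(qcPass(r))
  expect_equal(nrow(fusionCalls(r)), 0L)

  # the caller is pure: identical input, identical report
  a <- callSample(c("MLL", "AF9", "GUS"), the_panel)
  b <- callSample(c("MLL", "AF9", "GUS"), the_panel)
  expect_identical(fusionCalls(a), fusionCalls(b))
  expect_identical(trueProbes(a), trueProbes(b))
})

test_that("coexisting splice variants of one fusion yield one call per variant", {
  r <- callSample(c("TEL-AML1ex2", "TEL-AML1ex3", "TEL", "AML1ex3", "GUS"),
                  the_panel)
  calls <- fusionCalls(r)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$variant_label, c("TEL-AML1ex2", "TEL-AML1ex3"))
  expect_true(all(calls$fusion_id == "TEL-AML1"))
})
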