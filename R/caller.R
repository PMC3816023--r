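# The spot-intensity decision procedure: replicate averaging, the per-probe
# background threshold (reference mean plus a multiple of the sample SD),
# the array-wide cutoff (a fraction of the biotin control signal on the
# same array), true-signal flags, fusion call rules and internal-control QC.

#' Caller configuration
#'
#' @param cutoff_fraction fraction of the biotinylated-control mean used as
#'   the array-wide cutoff (default 0.15)
#' @param sd_multiplier multiplier of the reference SD added to the
#'   reference mean for the per-probe background (default 3)
#' @param strict_inequality require intensities strictly greater than both
#'   thresholds ("higher than"; default TRUE)
#' @return validated list of class \code{CallerConfig}
#' @export
callerConfig <- function(cutoff_fraction = 0.15, sd_multiplier = 3,
                         strict_inequality = TRUE) {
  stopifnot(cutoff_fraction > 0, cutoff_fraction < 1, sd_multiplier > 0,
            is.logical(strict_inequality))
  structure(list(cutoff_fraction = cutoff_fraction,
                 sd_multiplier = sd_multiplier,
                 strict_inequality = strict_inequality),
            class = "CallerConfig")
}

#' Average spot replicates
#'
#' Arithmetic mean intensity per spot content.  Probe ids, \code{BIOTIN} and
#' \code{BLANK} are aggregated separately; content absent from the grid is
#' absent from the output (not zero).
#'
#' @param grid an \code{\link{IntensityGrid}}
#' @return data.frame with columns \code{probe_id}, \code{mean_intensity},
#'   \code{n_replicates}
#' @export
aggregateReplicates <- function(grid) {
  stopifnot(is(grid, "IntensityGrid"))
  sp <- spots(grid)
  if (any(!nzchar(sp$content)))
    stop("integrity error: spot with empty content")
  agg <- stats::aggregate(sp$intensity, by = list(probe_id = sp$content),
                          FUN = mean)
  n <- stats::aggregate(sp$intensity, by = list(probe_id = sp$content),
                        FUN = length)
  out <- data.frame(probe_id = agg$probe_id, mean_intensity = agg$x,
                    n_replicates = as.integer(n$x),
                    stringsAsFactors = FALSE)
  out[order(out$probe_id), , drop = FALSE]
}

#' Per-probe background thresholds from reference arrays
#'
#' For each probe, pools its replicate-averaged signal from every reference
#' grid together with each grid's averaged blank-spot value, and sets the
#' background to the pooled mean plus \code{sd_multiplier} times the pooled
#' sample SD (n-1 denominator).  Reference grids are typically no-template
#' blanks and/or negative samples; the choice of reference set is the
#' caller's, and at least two pooled values per probe are required for the
#' SD to be defined.
#'
#' @param reference_grids list of \code{\link{IntensityGrid}}
#' @param config a \code{\link{callerConfig}}
#' @return data.frame with columns \code{probe_id}, \code{background},
#'   \code{ref_mean}, \code{ref_sd}, \code{n_reference}
#' @export
computeBackground <- function(reference_grids, config = callerConfig()) {
  stopifnot(inherits(config, "CallerConfig"), length(reference_grids) >= 1L)
  pools <- list()
  for (g in reference_grids) {
    agg <- aggregateReplicates(g)
    blank <- agg$mean_intensity[agg$probe_id == "BLANK"]
    pr <- agg[!agg$probe_id %in% c("BIOTIN", "BLANK"), , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      id <- pr$probe_id[i]
      pools[[id]] <- c(pools[[id]], pr$mean_intensity[i], blank)
    }
  }
  if (length(pools) == 0L)
    stop("reference grids contain no probe spots")
  out <- lapply(names(pools), function(id) {
    v <- pools[[id]]
    if (length(v) < 2L)
      stop("fewer than 2 reference values for probe ", id,
           "; the background SD is undefined")
    data.frame(probe_id = id, background = mean(v) +
                 config$sd_multiplier * stats::sd(v),
               ref_mean = mean(v), ref_sd = stats::sd(v),
               n_reference = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$probe_id), , drop = FALSE]
}

#' Array-wide cutoff from the biotin controls of the same grid
#'
#' @param grid an \code{\link{IntensityGrid}} containing \code{BIOTIN} spots
#' @param config a \code{\link{callerConfig}}
#' @return the cutoff: \code{cutoff_fraction} times the mean biotin-spot
#'   intensity of this grid
#' @export
computeCutoff <- function(grid, config = callerConfig()) {
  stopifnot(is(grid, "IntensityGrid"), inherits(config, "CallerConfig"))
  b <- spots(grid)$intensity[spots(grid)$content == "BIOTIN"]
  if (length(b) == 0L)
    stop("grid has no BIOTIN control spots; cutoff undefined")
  config$cutoff_fraction * mean(b)
}

#' Flag true-signal probes
#'
#' A probe is a true signal when its replicate-averaged intensity exceeds
#' both the per-probe background and the array-wide cutoff (strictly, under
#' the default configuration).  Probes missing from the background table can
#' never be true and are reported via \code{message()}.
#'
#' @param signals data.frame from \code{\link{aggregateReplicates}}
#' @param background_table data.frame from \code{\link{computeBackground}}
#' @param cutoff numeric cutoff from \code{\link{computeCutoff}}
#' @param config a \code{\link{callerConfig}}
#' @return character vector of true-signal probe ids
#' @export
flagTrueSignals <- function(signals, background_table, cutoff,
                            config = callerConfig()) {
  stopifnot(inherits(config, "CallerConfig"), is.numeric(cutoff))
  pr <- signals[!signals$probe_id %in% c("BIOTIN", "BLANK"), , drop = FALSE]
  bg <- background_table$background[match(pr$probe_id,
                                          background_table$probe_id)]
  missing <- is.na(bg)
  if (any(missing))
    message("probe(s) without background value, never true: ",
            paste(pr$probe_id[missing], collapse = ", "))
  gt <- if (config$strict_inequality) `>` else `>=`
  ok <- !missing & gt(pr$mean_intensity, bg) & gt(pr$mean_intensity, cutoff)
  pr$probe_id[ok]
}

# per-fusion call evaluation (internal); GUS control rule is excluded
.evaluateCalls <- function(true_probes, rules) {
  rules <- rules[rules$mode != "control", , drop = FALSE]
  calls <- list()
  addCall <- function(fusion, variant, status, evidence)
    calls[[length(calls) + 1L]] <<- data.frame(
      fusion_id = fusion, variant_label = variant, status = status,
      evidence = paste(evidence, collapse = ";"), stringsAsFactors = FALSE)

  jlist <- strsplit(rules$junction_probes, ";", fixed = TRUE)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    partners <- c(r$partner5, r$partner3)
    partners_true <- all(partners %in% true_probes)
    if (r$mode == "standard") {
      jtrue <- intersect(jlist[[i]], true_probes)
      if (length(jtrue) && partners_true)
        addCall(r$fusion_id, r$variant_label, "positive",
                c(jtrue, partners))
    } else if (r$mode == "mll") {
      if (partners_true)
        addCall(r$fusion_id, "", "positive", partners)
    }
  }

  # variant flag: every junction probe of the fusion false, but some
  # variant's full partner set true (possible novel/variant isoform);
  # MLL-style fusions have no junction probes and are never flagged.
  std <- rules[rules$mode == "standard", , drop = FALSE]
  for (fid in unique(std$fusion_id)) {
    rf <- std[std$fusion_id == fid, , drop = FALSE]
    all_junctions <- unique(unlist(strsplit(rf$junction_probes, ";",
                                            fixed = TRUE)))
    if (any(all_junctions %in% true_probes)) next
    for (i in seq_len(nrow(rf))) {
      partners <- c(rf$partner5[i], rf$partner3[i])
      if (all(partners %in% true_probes)) {
        addCall(fid, "", "variant_flag", partners)
        break
      }
    }
  }

  if (length(calls) == 0L)
    return(data.frame(fusion_id = character(0), variant_label = character(0),
                      status = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out[!duplicated(out[, c("fusion_id", "variant_label", "status")]), ,
      drop = FALSE]
}

#' Call fusions for one sample from its true-signal probes
#'
#' Applies the published decision rule: the sample is valid only when the
#' GUS internal-control probe is a true signal (QC); a standard fusion
#' variant is positive when its chimeric junction probe and both partner
#' probes are true; an MLL-style rearrangement is positive when the MLL
#' probe and the partner-gene probe are true; and a fusion whose partner
#' probes are all true with no true junction probe is flagged as a possible
#' variant isoform.  A QC-failed sample is invalid and carries no calls.
#' When partner probes of two different MLL rearrangements are true, both
#' calls are emitted with a warning.
#'
#' @param true_probes character vector of true-signal probe ids
#' @param panel a \code{\link{FusionPanel}}
#' @param config a \code{\link{callerConfig}}
#' @param sample_id identifier for the report
#' @param thresholds optional list (recorded verbatim in the report)
#' @return a \code{\link{SampleReport}}
#' @export
#' @examples
#' panel <- loadPanel()
#' callSample(c("AML1-ETO", "AML1ex5", "ETO", "GUS"), panel)
callSample <- function(true_probes, panel, config = callerConfig(),
                       sample_id = "sample", thresholds = list()) {
  stopifnot(is(panel, "FusionPanel"), inherits(config, "CallerConfig"))
  qc <- "GUS" %in% true_probes
  calls <- if (qc) .evaluateCalls(true_probes, panel@rules)
           else data.frame(fusion_id = character(0),
                           variant_label = character(0),
                           status = character(0), evidence = character(0),
                           stringsAsFactors = FALSE)
  mll_pos <- unique(calls$fusion_id[calls$status == "positive" &
                                    grepl("^MLL-", calls$fusion_id)])
  if (length(mll_pos) > 1L)
    warning("partner probes of multiple MLL rearrangements are true: ",
            paste(mll_pos, collapse = ", "))
  new("SampleReport", sampleId = as.character(sample_id), qcPass = qc,
      trueProbes = as.character(true_probes), calls = calls,
      thresholds = thresholds)
}

#' Threshold and call one intensity grid
#'
#' Convenience wrapper: averages replicates, derives the cutoff from the
#' grid's own biotin controls, flags true signals against the supplied
#' background table, and calls the sample.
#'
#' @param grid an \code{\link{IntensityGrid}}
#' @param panel a \code{\link{FusionPanel}}
#' @param background_table data.frame from \code{\link{computeBackground}}
#' @param config a \code{\link{callerConfig}}
#' @return a \code{\link{SampleReport}} whose \code{thresholds} record the
#'   cutoff and background table used
#' @export
callGrid <- function(grid, panel, background_table,
                     config = callerConfig()) {
  signals <- aggregateReplicates(grid)
  cutoff <- computeCutoff(grid, config)
  true_probes <- flagTrueSignals(signals, background_table, cutoff, config)
  callSample(true_probes, panel, config, sample_id = sampleId(grid),
             thresholds = list(cutoff = cutoff,
                               cutoff_fraction = config$cutoff_fraction,
                               sd_multiplier = config$sd_multiplier,
                               background = background_table))
}
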