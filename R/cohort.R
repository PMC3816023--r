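# Cohort aggregation: per-group translocation frequencies, splice-variant
# distributions, and concordance against reference diagnoses.

# Display row used in cohort tables.  BCR-ABL is the one fusion whose major
# forms (p190 / p210 / p230) are reported as separate rows; the form is
# derived from the variant-label prefix.
.displayFusion <- function(fusion_id, variant_label) {
  if (fusion_id == "BCR-ABL" && nzchar(variant_label)) {
    form <- sub("^(p[0-9]+).*$", "\\1", variant_label)
    return(paste(fusion_id, form))
  }
  fusion_id
}

# per-sample detection sets (fusion level and display level); a
# variant-flagged fusion counts as detected
.detections <- function(report) {
  calls <- fusionCalls(report)
  if (nrow(calls) == 0L)
    return(list(fusions = character(0), display = character(0)))
  list(fusions = unique(calls$fusion_id),
       display = unique(mapply(.displayFusion, calls$fusion_id,
                               calls$variant_label, USE.NAMES = FALSE)))
}

#' Summarize a cohort of sample reports
#'
#' Counts, per clinical group, the samples with at least one detected fusion
#' (a positive call or a variant flag), the per-fusion detection counts with
#' their percentage of the group size, the QC failures, and the
#' splice-variant distribution of every detected fusion.  Percentages are
#' carried unrounded (\code{pct}) alongside a 1-decimal round-half-up
#' presentation value (\code{pct_1dp}).
#'
#' @param reports list of \code{\link{SampleReport}}
#' @param groups named character vector mapping sample id to clinical group
#'   (\code{AML}, \code{ALL} or \code{CML})
#' @return list of class \code{CohortSummary}: \code{group_summary},
#'   \code{fusion_summary}, \code{variant_distribution} (named list of
#'   data.frames) and \code{n}
#' @export
summarizeCohort <- function(reports, groups) {
  if (length(reports) == 0L)
    return(structure(list(
      group_summary = data.frame(group = character(0), n = integer(0),
        n_positive = integer(0), pct_positive = numeric(0),
        pct_positive_1dp = numeric(0), n_qc_fail = integer(0),
        n_negative = integer(0)),
      fusion_summary = data.frame(group = character(0), fusion = character(0),
        count = integer(0), pct = numeric(0), pct_1dp = numeric(0)),
      variant_distribution = list(), n = 0L), class = "CohortSummary"))
  ids <- vapply(reports, sampleId, character(1))
  if (!all(ids %in% names(groups)))
    stop("sample(s) without group label: ",
         paste(setdiff(ids, names(groups)), collapse = ", "))
  grp <- groups[ids]
  if (!all(grp %in% c("AML", "ALL", "CML")))
    stop("unknown group(s): ",
         paste(setdiff(unique(grp), c("AML", "ALL", "CML")), collapse = ", "))

  det <- lapply(reports, .detections)
  qc <- vapply(reports, qcPass, logical(1))
  n_det <- vapply(det, function(d) length(d$fusions), integer(1))

  glev <- intersect(c("AML", "ALL", "CML"), unique(grp))
  group_summary <- do.call(rbind, lapply(glev, function(g) {
    in_g <- grp == g
    n <- sum(in_g)
    npos <- sum(in_g & n_det > 0L)
    data.frame(group = g, n = n, n_positive = npos,
               pct_positive = 100 * npos / n,
               pct_positive_1dp = .roundHalfUp(100 * npos / n, 1L),
               n_qc_fail = sum(in_g & !qc),
               n_negative = sum(in_g & qc & n_det == 0L),
               stringsAsFactors = FALSE)
  }))

  rows <- list()
  for (g in glev) {
    in_g <- which(grp == g)
    n <- length(in_g)
    disp <- unlist(lapply(det[in_g], `[[`, "display"))
    if (length(disp) == 0L) next
    cnt <- table(disp)
    rows[[g]] <- data.frame(group = g, fusion = names(cnt),
                            count = as.integer(cnt),
                            pct = 100 * as.integer(cnt) / n,
                            pct_1dp = .roundHalfUp(100 * as.integer(cnt) / n, 1L),
                            stringsAsFactors = FALSE)
  }
  fusion_summary <- if (length(rows)) do.call(rbind, rows)
    else data.frame(group = character(0), fusion = character(0),
                    count = integer(0), pct = numeric(0), pct_1dp = numeric(0))
  rownames(fusion_summary) <- NULL

  all_fusions <- unique(unlist(lapply(det, `[[`, "fusions")))
  vd <- lapply(all_fusions, function(f) variantDistribution(reports, f))
  names(vd) <- all_fusions

  structure(list(group_summary = group_summary,
                 fusion_summary = fusion_summary,
                 variant_distribution = vd,
                 n = length(reports)),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("Cohort of", x$n, "samples\n\n")
  gs <- x$group_summary
  for (i in seq_len(nrow(gs)))
    cat(sprintf(" %s: %d/%d detected (%.1f%%), %d QC-fail, %d negative\n",
                gs$group[i], gs$n_positive[i], gs$n[i],
                gs$pct_positive_1dp[i], gs$n_qc_fail[i], gs$n_negative[i]))
  cat("\nPer-fusion detections:\n")
  fs <- x$fusion_summary
  for (i in seq_len(nrow(fs)))
    cat(sprintf("  %s %-18s %3d (%.1f%%)\n", fs$group[i], fs$fusion[i],
                fs$count[i], fs$pct_1dp[i]))
  invisible(x)
}

#' Concordance with reference diagnoses
#'
#' A sample is concordant when the assay detected the fusion named by the
#' reference diagnosis (variant labels are not compared), or when the assay
#' is negative and the reference is \code{none}.  A reference of
#' \code{other_translocation} lies beyond the panel's scope and is always
#' discordant.  QC-failed samples carry no calls, so they are concordant
#' exactly when the reference is \code{none}.
#'
#' @param reports list of \code{\link{SampleReport}}
#' @param references data.frame with columns \code{sample_id}, \code{group},
#'   \code{diagnosis} (a fusion id, optionally \code{fusion:variant},
#'   \code{"other_translocation"} or \code{"none"}) and \code{method}
#' @return list with \code{fraction}, \code{n_concordant}, \code{n} and
#'   \code{discordant} (data.frame of the discordant samples)
#' @export
concordance <- function(reports, references) {
  ids <- vapply(reports, sampleId, character(1))
  miss <- setdiff(ids, references$sample_id)
  extra <- setdiff(references$sample_id, ids)
  if (length(miss) || length(extra))
    stop("sample id mismatch between reports and references; missing from ",
         "references: [", paste(miss, collapse = ", "), "], missing from ",
         "reports: [", paste(extra, collapse = ", "), "]")
  ref <- references[match(ids, references$sample_id), , drop = FALSE]
  conc <- logical(length(ids))
  rows <- list()
  for (i in seq_along(ids)) {
    d <- .detections(reports[[i]])$fusions
    dx <- ref$diagnosis[i]
    conc[i] <- if (dx == "none") length(d) == 0L
               else if (dx == "other_translocation") FALSE
               else strsplit(dx, ":", fixed = TRUE)[[1]][1] %in% d
    if (!conc[i])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], group = ref$group[i], diagnosis = dx,
        detected = paste(d, collapse = ";"), stringsAsFactors = FALSE)
  }
  discordant <- if (length(rows)) do.call(rbind, rows)
    else data.frame(sample_id = character(0), group = character(0),
                    diagnosis = character(0), detected = character(0))
  list(fraction = sum(conc) / length(conc), n_concordant = sum(conc),
       n = length(conc), discordant = discordant)
}

#' Splice-variant distribution of one fusion
#'
#' Among the samples with at least one call for the fusion, counts each
#' variant label (a variant-flagged sample is tallied under
#' \code{"variant_flag"}); the share denominator is the number of samples
#' detected for the fusion, so a sample carrying two coexisting variants
#' contributes to both numerators.
#'
#' @param reports list of \code{\link{SampleReport}}
#' @param fusion_id fusion identifier
#' @return data.frame with columns \code{variant_label}, \code{count},
#'   \code{share}, \code{share_pct}; zero rows when no sample is detected
#'   for the fusion
#' @export
variantDistribution <- function(reports, fusion_id) {
  labels <- lapply(reports, function(r) {
    calls <- fusionCalls(r)
    calls <- calls[calls$fusion_id == fusion_id, , drop = FALSE]
    if (nrow(calls) == 0L) return(NULL)
    ifelse(calls$status == "variant_flag", "variant_flag",
           ifelse(nzchar(calls$variant_label), calls$variant_label,
                  "(unlabeled)"))
  })
  labels <- labels[!vapply(labels, is.null, logical(1))]
  n_samples <- length(labels)
  if (n_samples == 0L)
    return(data.frame(variant_label = character(0), count = integer(0),
                      share = numeric(0), share_pct = numeric(0)))
  cnt <- table(unlist(labels))
  out <- data.frame(variant_label = names(cnt), count = as.integer(cnt),
                    share = as.integer(cnt) / n_samples,
                    share_pct = 100 * as.integer(cnt) / n_samples,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$count, out$variant_label), , drop = FALSE]
}
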