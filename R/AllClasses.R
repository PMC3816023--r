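#' FusionPanel: the assay panel of primers, probes, layout and call rules
#'
#' An S4 container for the multiplex RT-PCR / microarray panel: the chimeric
#' primers (universal T7/SP6 tag plus gene-specific portion), the junction,
#' partner and control oligonucleotide probes with their array positions, the
#' physical spot layout (probes in triplicate, biotin positional controls in
#' the top row and left column, blank spots), and the per-fusion call rules
#' linking junction and partner probes to primer pairs.
#'
#' Build one with \code{\link{loadPanel}}; the panel transcribed from the
#' published tables ships with the package under
#' \code{system.file("extdata", "panel", package = "FusionChip")}.
#'
#' @slot primers data.frame of chimeric and universal primers
#' @slot probes data.frame of array probes
#' @slot layout data.frame of spots (row, col, replicate, content)
#' @slot rules data.frame of per-fusion/variant call rules
#'
#' @aliases primers probes arrayLayout fusionRules fusionIds
#' @export
setClass("FusionPanel",
  representation(primers = "data.frame", probes = "data.frame",
                 layout = "data.frame", rules = "data.frame"))

.validFusionPanel <- function(object) {
  msg <- character(0)
  pr <- object@primers; pb <- object@probes
  ly <- object@layout;  ru <- object@rules

  chimeric <- pr[nzchar(pr$gene_specific_seq), , drop = FALSE]
  bad <- chimeric$direction == "forward" & chimeric$tag_seq != .T7_TAG
  if (any(bad))
    msg <- c(msg, paste0("forward primer(s) without T7 tag: ",
                         paste(chimeric$name[bad], collapse = ", ")))
  bad <- chimeric$direction == "reverse" & chimeric$tag_seq != .SP6_TAG
  if (any(bad))
    msg <- c(msg, paste0("reverse primer(s) without SP6 tag: ",
                         paste(chimeric$name[bad], collapse = ", ")))
  bad <- grepl("[^ACGT]", chimeric$gene_specific_seq)
  if (any(bad))
    msg <- c(msg, paste0("non-ACGT gene-specific sequence in: ",
                         paste(chimeric$name[bad], collapse = ", ")))

  if (anyDuplicated(pb$probe_id))
    msg <- c(msg, "duplicate probe_id in probe table")
  if (any(!nzchar(pb$sequence)) || any(grepl("[^ACGT]", pb$sequence)))
    msg <- c(msg, "probe sequences must be non-empty and ACGT only")
  if (!all(pb$role %in% c("junction", "partner", "control")))
    msg <- c(msg, "probe role must be junction, partner or control")

  # one array position group per probe, except the multi-position GUS control
  pos <- pb$array_position[pb$role != "control"]
  if (any(grepl(";", pos)))
    msg <- c(msg, "only the control probe may occupy multiple position groups")
  if (anyDuplicated(pos))
    msg <- c(msg, "duplicate array position among non-control probes")

  spotted <- unique(ly$content)
  spotted <- setdiff(spotted, c("BIOTIN", "BLANK"))
  if (!all(spotted %in% pb$probe_id))
    msg <- c(msg, paste0("layout references unknown probe(s): ",
                         paste(setdiff(spotted, pb$probe_id), collapse = ", ")))
  if (!all(pb$probe_id %in% ly$content))
    msg <- c(msg, "probe(s) missing from layout")
  # probes spotted in triplicate within each position group
  pspots <- ly[!ly$content %in% c("BIOTIN", "BLANK"), , drop = FALSE]
  cnt <- table(paste(pspots$row, pspots$col, pspots$content))
  if (any(cnt != 3L))
    msg <- c(msg, "every probe position group must hold exactly 3 replicates")
  if (!any(ly$content == "BIOTIN"))
    msg <- c(msg, "layout lacks biotin positional control spots")

  known_probe <- function(ids) all(ids %in% c(pb$probe_id, ""))
  jp <- strsplit(ru$junction_probes, ";", fixed = TRUE)
  for (i in seq_len(nrow(ru))) {
    r <- ru[i, ]
    ids <- c(jp[[i]], r$partner5, r$partner3)
    if (!known_probe(ids))
      msg <- c(msg, paste0("rule ", r$fusion_id, "/", r$variant_label,
                           " references unknown probe(s)"))
    prim <- c(r$fwd_primer, r$rev_primer)
    if (!all(prim %in% pr$name))
      msg <- c(msg, paste0("rule ", r$fusion_id, " references unknown primer(s)"))
    if (r$mode == "standard" &&
        (!any(nzchar(jp[[i]])) || !nzchar(r$partner5) || !nzchar(r$partner3)))
      msg <- c(msg, paste0("standard rule ", r$fusion_id, "/", r$variant_label,
                           " needs >=1 junction probe and a 5' and 3' partner"))
    if (r$mode == "mll" &&
        (any(nzchar(jp[[i]])) || !"MLL" %in% c(r$partner5, r$partner3)))
      msg <- c(msg, paste0("mll rule ", r$fusion_id,
                           " must have no junction probe and include MLL"))
  }
  if (sum(ru$mode == "control") != 1L)
    msg <- c(msg, "exactly one control rule (GUS) is required")

  if (length(msg)) msg else TRUE
}
setValidity("FusionPanel", .validFusionPanel)

#' @describeIn FusionPanel-class primer table
#' @export
setMethod("primers", "FusionPanel", function(x) x@primers)

#' @describeIn FusionPanel-class probe table
#' @export
setMethod("probes", "FusionPanel", function(x) x@probes)

#' @describeIn FusionPanel-class spot layout table
#' @export
setMethod("arrayLayout", "FusionPanel", function(x) x@layout)

#' @describeIn FusionPanel-class fusion call-rule table
#' @export
setMethod("fusionRules", "FusionPanel", function(x) x@rules)

#' @describeIn FusionPanel-class fusion identifiers covered by the panel
#'   (control rule excluded)
#' @export
setMethod("fusionIds", "FusionPanel", function(x)
  unique(x@rules$fusion_id[x@rules$mode != "control"]))

setMethod("show", "FusionPanel", function(object) {
  ru <- object@rules
  cat("FusionPanel with", sum(nzchar(object@primers$gene_specific_seq)),
      "chimeric primers,", nrow(object@probes), "probes (",
      sum(object@probes$role == "junction"), "junction /",
      sum(object@probes$role == "partner"), "partner /",
      sum(object@probes$role == "control"), "control ),",
      nrow(object@layout), "spots\n")
  cat(" fusions:", paste(fusionIds(object), collapse = ", "), "\n")
  cat(" rules:", sum(ru$mode == "standard"), "standard,",
      sum(ru$mode == "mll"), "MLL-style,",
      sum(ru$mode == "control"), "control\n")
})

#' IntensityGrid: per-array spot intensities
#'
#' Scanned (or simulated) spot intensities for one hybridized array, keyed by
#' spot content (a probe id, \code{BIOTIN} for the biotinylated positional
#' controls, or \code{BLANK}) and replicate index.
#'
#' @slot sampleId sample identifier
#' @slot spots data.frame with columns \code{content}, \code{replicate},
#'   \code{intensity}
#'
#' @aliases sampleId spots
#' @export
setClass("IntensityGrid",
  representation(sampleId = "character", spots = "data.frame"))

.validIntensityGrid <- function(object) {
  msg <- character(0)
  sp <- object@spots
  need <- c("content", "replicate", "intensity")
  if (!all(need %in% names(sp)))
    msg <- c(msg, paste("spots must have columns:", paste(need, collapse = ", ")))
  else {
    if (!is.numeric(sp$intensity) || any(!is.finite(sp$intensity)) ||
        any(sp$intensity < 0))
      msg <- c(msg, "intensities must be finite and non-negative")
    if (nrow(sp) == 0L)
      msg <- c(msg, "grid has no spots")
  }
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
}
setValidity("IntensityGrid", .validIntensityGrid)

#' Construct an IntensityGrid
#'
#' @param sample_id sample identifier
#' @param spots data.frame with columns \code{content}, \code{replicate},
#'   \code{intensity}
#' @return an \code{IntensityGrid}
#' @export
IntensityGrid <- function(sample_id, spots) {
  new("IntensityGrid", sampleId = as.character(sample_id),
      spots = as.data.frame(spots))
}

#' @describeIn IntensityGrid-class sample identifier
#' @export
setMethod("sampleId", "IntensityGrid", function(x) x@sampleId)

#' @describeIn IntensityGrid-class spot table
#' @export
setMethod("spots", "IntensityGrid", function(x) x@spots)

setMethod("show", "IntensityGrid", function(object) {
  sp <- object@spots
  cat("IntensityGrid for sample", object@sampleId, "with", nrow(sp), "spots (",
      sum(!sp$content %in% c("BIOTIN", "BLANK")), "probe,",
      sum(sp$content == "BIOTIN"), "biotin,",
      sum(sp$content == "BLANK"), "blank )\n")
})

#' SampleReport: per-sample QC status and fusion calls
#'
#' The outcome of the decision procedure on one array: internal-control QC
#' (the GUS probe must be a true signal), the set of true-signal probes, and
#' the fusion calls with splice-variant labels.  Calls carry status
#' \code{positive} (junction plus both partner probes true, or the MLL-style
#' partner pair) or \code{variant_flag} (partner probes true with no true
#' junction probe: a possible novel or variant isoform).
#'
#' @slot sampleId sample identifier
#' @slot qcPass logical; \code{FALSE} invalidates the sample and suppresses
#'   all calls
#' @slot trueProbes character vector of true-signal probe ids
#' @slot calls data.frame with columns \code{fusion_id}, \code{variant_label},
#'   \code{status}, \code{evidence}
#' @slot thresholds list recording the background table and cutoff used
#'
#' @aliases qcPass trueProbes fusionCalls thresholds
#' @export
setClass("SampleReport",
  representation(sampleId = "character", qcPass = "logical",
                 trueProbes = "character", calls = "data.frame",
                 thresholds = "list"))

.validSampleReport <- function(object) {
  msg <- character(0)
  if (!isTRUE(object@qcPass) && nrow(object@calls) > 0L)
    msg <- c(msg, "a QC-failed sample must carry no calls")
  need <- c("fusion_id", "variant_label", "status", "evidence")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@calls) &&
           !all(object@calls$status %in% c("positive", "variant_flag")))
    msg <- c(msg, "call status must be positive or variant_flag")
  if (length(msg)) msg else TRUE
}
setValidity("SampleReport", .validSampleReport)

#' @describeIn SampleReport-class sample identifier
#' @export
setMethod("sampleId", "SampleReport", function(x) x@sampleId)

#' @describeIn SampleReport-class internal-control QC status
#' @export
setMethod("qcPass", "SampleReport", function(x) x@qcPass)

#' @describeIn SampleReport-class true-signal probe ids
#' @export
setMethod("trueProbes", "SampleReport", function(x) x@trueProbes)

#' @describeIn SampleReport-class fusion call table
#' @export
setMethod("fusionCalls", "SampleReport", function(x) x@calls)

#' @describeIn SampleReport-class thresholds used by the caller
#' @export
setMethod("thresholds", "SampleReport", function(x) x@thresholds)

setMethod("show", "SampleReport", function(object) {
  cat("SampleReport", object@sampleId,
      if (object@qcPass) "[QC pass]" else "[QC FAIL - invalid]", "\n")
  if (!object@qcPass) return(invisible(NULL))
  if (nrow(object@calls) == 0L) {
    cat(" no fusion detected (negative)\n")
  } else {
    for (i in seq_len(nrow(object@calls))) {
      cl <- object@calls[i, ]
      cat(sprintf(" %s %s%s\n", cl$status, cl$fusion_id,
                  if (nzchar(cl$variant_label))
                    paste0(" [", cl$variant_label, "]") else ""))
    }
  }
  invisible(NULL)
})
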