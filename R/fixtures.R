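# Synthetic-data generators: pseudo-transcripts assembled from the panel's
# own primer and probe sequences (the software analogue of the constructed
# fusion-fraction plasmids), and lognormal spot-intensity grids standing in
# for scanner output.

#' Simulation parameters
#'
#' Parameters for the fixture generators.  Intensities are drawn lognormal:
#' spots of bound probes at \code{signal_mu}, unbound and blank spots at
#' \code{baseline_mu}, biotin positional controls at \code{biotin_level}
#' (all on the log scale), each with standard deviation \code{noise_sigma}.
#' Defaults put the biotin control near 30000 fluorescence units (the upper
#' half of a 16-bit scanner range), true signals near 20000 and the
#' unbound baseline near 200, so the 15 percent biotin-referenced cutoff
#' (4500) separates the two populations cleanly at the default noise level.
#'
#' @param seed integer RNG seed; every source of randomness flows from it
#' @param spacer_len length in nt of the random spacers between functional
#'   blocks of a pseudo-transcript (default 30)
#' @param signal_mu mean log-intensity of spots whose probe is bound
#' @param noise_sigma lognormal sigma shared by all spot populations
#' @param baseline_mu mean log-intensity of unbound and blank spots
#' @param biotin_level mean log-intensity of biotin control spots
#' @param dropout_rate probability that a bound spot fails and falls back to
#'   baseline (default 0)
#' @return validated list of class \code{SimulationParams}
#' @export
#' @examples
#' simParams(seed = 42, noise_sigma = 0)
simParams <- function(seed = 1L, spacer_len = 30L,
                      signal_mu = log(20000), noise_sigma = 0.25,
                      baseline_mu = log(200), biotin_level = log(30000),
                      dropout_rate = 0) {
  stopifnot(spacer_len >= 0L, signal_mu > 0, noise_sigma >= 0,
            baseline_mu > 0, biotin_level > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(seed = as.integer(seed), spacer_len = as.integer(spacer_len),
                 signal_mu = signal_mu, noise_sigma = noise_sigma,
                 baseline_mu = baseline_mu, biotin_level = biotin_level,
                 dropout_rate = dropout_rate),
            class = "SimulationParams")
}

.randomDna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all panel oligos that must not appear by chance in a spacer region
.panelOligos <- function(panel) {
  pr <- panel@primers
  gs <- pr$gene_specific_seq[nzchar(pr$gene_specific_seq)]
  unique(c(gs, vapply(gs, .revComp, character(1)),
           panel@probes$sequence,
           vapply(panel@probes$sequence, .revComp, character(1))))
}

# Count exact occurrences of each oligo in `full` beyond those present when
# the spacers are masked out with N runs.  A positive excess means a spacer
# created (or completed) a spurious site.
.spuriousSites <- function(full, masked, oligos) {
  fs <- Biostrings::DNAString(full)
  ms <- Biostrings::DNAString(masked)
  for (o in oligos) {
    if (nchar(o) > nchar(full)) next
    nf <- Biostrings::countPattern(o, fs)
    nm <- Biostrings::countPattern(o, ms)
    if (nf > nm) return(TRUE)
  }
  FALSE
}

# assemble spacer/block/spacer/.../spacer with rejection-sampled spacers
.assembleTranscript <- function(blocks, panel, params, max_tries = 50L) {
  oligos <- .panelOligos(panel)
  n_sp <- length(blocks) + 1L
  for (try in seq_len(max_tries)) {
    spacers <- vapply(seq_len(n_sp), function(i) .randomDna(params$spacer_len),
                      character(1))
    parts <- character(0)
    masked <- character(0)
    for (i in seq_along(blocks)) {
      parts  <- c(parts,  spacers[i], blocks[i])
      masked <- c(masked, strrep("N", nchar(spacers[i])), blocks[i])
    }
    full   <- paste0(paste(parts, collapse = ""),  spacers[n_sp])
    maskf  <- paste0(paste(masked, collapse = ""), strrep("N", nchar(spacers[n_sp])))
    if (!.spuriousSites(full, maskf, oligos)) return(full)
  }
  stop("could not draw spacers free of spurious primer/probe sites")
}

# resolve the rule used to build a pseudo-transcript
.pickRule <- function(panel, fusion_id, variant_label) {
  rules <- .rulesFor(panel, fusion_id)
  if (nrow(rules) == 0L) stop("unknown fusion_id: ", fusion_id)
  if (is.null(variant_label) || identical(variant_label, "") ||
      identical(variant_label, "NOVEL")) {
    rules[1L, , drop = FALSE]
  } else {
    hit <- rules[rules$variant_label == variant_label, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop("unknown variant '", variant_label, "' for fusion ", fusion_id)
    hit[1L, , drop = FALSE]
  }
}

#' Build a fusion pseudo-transcript from the panel itself
#'
#' Assembles a sense-strand transcript carrying, in order: the rule's
#' forward-primer gene-specific site, the 5' partner probe, the junction
#' probe(s) of the requested splice variant, the 3' partner probe, and the
#' reverse complement of the reverse-primer site, separated by random
#' spacers.  Spacers are rejection-sampled so they introduce no spurious
#' primer or probe site, which keeps the zero-noise end-to-end oracle exact.
#' MLL-style rules have no junction probe; \code{variant_label = "NOVEL"}
#' omits the junction probe from the first listed rule of the fusion,
#' emulating an unknown breakpoint isoform whose partner probes still
#' hybridize.
#'
#' @param panel a \code{\link{FusionPanel}}
#' @param fusion_id fusion identifier with a rule in the panel
#' @param variant_label splice-variant label, \code{NULL}/\code{""} for the
#'   fusion's first listed variant, or \code{"NOVEL"}
#' @param params \code{\link{simParams}}; the seed determines the spacers
#' @return a named \code{DNAStringSet} of length 1
#' @export
#' @examples
#' panel <- loadPanel()
#' makeFusionTranscript(panel, "AML1-ETO", params = simParams(seed = 3))
makeFusionTranscript <- function(panel, fusion_id, variant_label = NULL,
                                 params = simParams()) {
  stopifnot(is(panel, "FusionPanel"), inherits(params, "SimulationParams"))
  rule <- .pickRule(panel, fusion_id, variant_label)
  novel <- identical(variant_label, "NOVEL")
  jseqs <- character(0)
  if (!novel && rule$mode == "standard") {
    jids <- strsplit(rule$junction_probes, ";", fixed = TRUE)[[1]]
    jids <- jids[nzchar(jids)]
    jseqs <- vapply(jids, function(id) .probeSeq(panel, id), character(1))
  }
  p5 <- if (nzchar(rule$partner5)) .probeSeq(panel, rule$partner5) else NULL
  p3 <- if (nzchar(rule$partner3)) .probeSeq(panel, rule$partner3) else NULL
  fwd <- .primerByName(panel, rule$fwd_primer)$gene_specific_seq
  rev <- .primerByName(panel, rule$rev_primer)$gene_specific_seq
  core <- paste(c(p5, jseqs, p3), collapse = "")
  blocks <- c(fwd, core, .revComp(rev))
  set.seed(.deriveSeed(params$seed, sum(utf8ToInt(paste0(fusion_id,
                                                         variant_label %||% "")))))
  seqv <- .assembleTranscript(blocks, panel, params)
  label <- paste0("pseudo:", fusion_id,
                  if (!is.null(variant_label) && nzchar(variant_label))
                    paste0(":", variant_label) else "")
  out <- Biostrings::DNAStringSet(seqv)
  names(out) <- label
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the internal-control pseudo-transcript
#'
#' The beta-glucuronidase (GUS) transcript analogue: forward-primer site,
#' GUS probe, reverse-primer site, with random spacers.  GUS is amplified in
#' every sample; its probe signal is the per-sample QC gate.
#'
#' @inheritParams makeFusionTranscript
#' @return a named \code{DNAStringSet} of length 1
#' @export
makeControlTranscript <- function(panel, params = simParams()) {
  makeFusionTranscript(panel, "GUS", NULL, params)
}

#' Simulate a spot-intensity grid for one array
#'
#' Draws one intensity per layout spot: lognormal at \code{signal_mu} for
#' spots of bound probes (unless dropped out at \code{dropout_rate}),
#' \code{baseline_mu} for unbound probe and blank spots, and
#' \code{biotin_level} for the biotin positional controls.  Fully
#' deterministic under \code{params$seed}.
#'
#' @param layout layout data.frame (see \code{\link{arrayLayout}})
#' @param bound character vector of bound probe ids (e.g. from
#'   \code{\link{simulateAssay}})
#' @param params \code{\link{simParams}}
#' @param sample_id identifier stored in the grid
#' @return an \code{\link{IntensityGrid}}
#' @export
#' @examples
#' panel <- loadPanel()
#' g <- simulateIntensityGrid(arrayLayout(panel), c("GUS"),
#'                            simParams(seed = 11))
#' head(spots(g))
simulateIntensityGrid <- function(layout, bound, params = simParams(),
                                  sample_id = "sample") {
  stopifnot(inherits(params, "SimulationParams"))
  unknown <- setdiff(bound, c(layout$content, character(0)))
  if (length(unknown))
    warning("bound probe(s) not on the layout, ignored: ",
            paste(unknown, collapse = ", "))
  n <- nrow(layout)
  meanlog <- rep(params$baseline_mu, n)
  meanlog[layout$content == "BIOTIN"] <- params$biotin_level
  is_bound <- layout$content %in% setdiff(bound, unknown)
  meanlog[is_bound] <- params$signal_mu
  set.seed(params$seed)
  u <- stats::runif(n)
  z <- stats::rnorm(n)
  dropped <- is_bound & u < params$dropout_rate
  meanlog[dropped] <- params$baseline_mu
  intensity <- exp(meanlog + params$noise_sigma * z)
  IntensityGrid(sample_id,
                data.frame(content = layout$content,
                           replicate = layout$replicate,
                           intensity = intensity,
                           stringsAsFactors = FALSE))
}

# signature identifying a genotype's deterministic hybridization outcome
.genotypeKey <- function(fusions, variants, include_control) {
  paste(paste(fusions, variants, sep = "|", collapse = ";"),
        include_control, sep = "@")
}

#' Generate a synthetic cohort of intensity grids
#'
#' For every sample in the genotype table, builds the pseudo-transcript pool
#' (the internal-control transcript unless \code{include_control} is 0, plus
#' one fusion transcript per assigned (fusion, variant)), runs the in-silico
#' assay to obtain the bound probe set, and draws a per-sample intensity
#' grid under a seed derived from \code{params$seed} and the sample index.
#' The hybridization outcome of a genotype is deterministic (spacers are
#' site-free by construction), so it is computed once per distinct genotype
#' and reused; intensity noise is still drawn independently per sample.
#'
#' @param panel a \code{\link{FusionPanel}}
#' @param genotypes data.frame with columns \code{sample_id}, \code{group},
#'   \code{fusion_id}, \code{variant_label}, \code{include_control}; one row
#'   per assigned fusion, empty \code{fusion_id} for a negative sample (see
#'   \code{\link{readGenotypes}}, \code{\link{screeningCohortGenotypes}})
#' @param params \code{\link{simParams}}
#' @return list with \code{grids} (named list of \code{IntensityGrid}),
#'   \code{groups} (named character vector sample -> group) and
#'   \code{truth} (the genotype table)
#' @export
makeCohort <- function(panel, genotypes, params = simParams()) {
  stopifnot(is(panel, "FusionPanel"))
  need <- c("sample_id", "group", "fusion_id", "variant_label",
            "include_control")
  if (!all(need %in% names(genotypes)))
    stop("genotype table lacks column(s): ",
         paste(setdiff(need, names(genotypes)), collapse = ", "))
  if (nrow(genotypes) == 0L)
    return(list(grids = list(), groups = character(0), truth = genotypes))
  known <- fusionIds(panel)
  pos <- genotypes[nzchar(genotypes$fusion_id), , drop = FALSE]
  bad <- !pos$fusion_id %in% known
  if (any(bad))
    stop("genotype table assigns unknown fusion(s): ",
         paste(unique(pos$fusion_id[bad]), collapse = ", "))
  for (i in seq_len(nrow(pos))) {
    vl <- pos$variant_label[i]
    if (nzchar(vl) && vl != "NOVEL") {
      ru <- .rulesFor(panel, pos$fusion_id[i])
      if (!vl %in% ru$variant_label)
        stop("unknown variant '", vl, "' for fusion ", pos$fusion_id[i])
    }
  }

  ids <- unique(genotypes$sample_id)
  layout <- panel@layout
  cache <- new.env(parent = emptyenv())
  grids <- vector("list", length(ids))
  names(grids) <- ids
  groups <- character(length(ids)); names(groups) <- ids
  for (i in seq_along(ids)) {
    rows <- genotypes[genotypes$sample_id == ids[i], , drop = FALSE]
    groups[i] <- rows$group[1L]
    withc <- all(rows$include_control %in% c("1", 1, TRUE, "TRUE"))
    fus <- rows$fusion_id[nzchar(rows$fusion_id)]
    var <- rows$variant_label[nzchar(rows$fusion_id)]
    key <- .genotypeKey(fus, var, withc)
    if (is.null(cache[[key]])) {
      tx <- Biostrings::DNAStringSet()
      if (withc)
        tx <- c(tx, makeControlTranscript(panel, params))
      for (k in seq_along(fus))
        tx <- c(tx, makeFusionTranscript(panel, fus[k],
                                         if (nzchar(var[k])) var[k] else NULL,
                                         params))
      cache[[key]] <- if (length(tx)) simulateAssay(tx, panel)$bound
                      else character(0)
    }
    sp <- params
    sp$seed <- .deriveSeed(params$seed, i)
    grids[[i]] <- simulateIntensityGrid(layout, cache[[key]], sp,
                                        sample_id = ids[i])
  }
  list(grids = grids, groups = groups, truth = genotypes)
}
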