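# Readers and writers for the pipeline's file formats, and the end-to-end
# pipeline driver.

#' Read transcripts from a FASTA file
#'
#' Sequences are uppercased on read and must be strictly ACGT; record ids
#' are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file
#' @return a named \code{DNAStringSet}
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  up <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(up) <- names(x)
  freq <- Biostrings::alphabetFrequency(up)
  nonacgt <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T"),
                                         drop = FALSE])
  if (any(nonacgt > 0)) {
    i <- which(nonacgt > 0)[1]
    off <- regexpr("[^ACGT]", as.character(up[[i]]))
    stop("record '", names(up)[i], "' contains a non-ACGT character at ",
         "position ", off)
  }
  up
}

#' Write transcripts to FASTA
#' @param transcripts a \code{DNAStringSet} or named character vector
#' @param path output file
#' @return invisibly, the path
#' @export
writeFasta <- function(transcripts, path) {
  Biostrings::writeXStringSet(.asTranscripts(transcripts), path)
  invisible(path)
}

#' Read a spot-intensity file
#'
#' Two dialects are supported and auto-detected: a simple TSV with columns
#' \code{probe_id} (or \code{content}), \code{replicate} and
#' \code{intensity}; and a minimal GenePix-results (ATF) dialect, detected
#' by its \code{ATF} first line, from which the \code{Name} column and the
#' \code{F532 Median} column (falling back to \code{F532 Mean}) are taken
#' and all other columns ignored.  Replicate indices in the GPR dialect are
#' assigned by order of appearance per name.
#'
#' @param path intensity file
#' @param dialect \code{"auto"} (default), \code{"tsv"} or \code{"gpr"}
#' @param sample_id sample id for the grid (default: file name without
#'   extension)
#' @return an \code{\link{IntensityGrid}}
#' @export
readIntensities <- function(path, dialect = c("auto", "tsv", "gpr"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("intensity file not found: ", path)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty intensity file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("^ATF", first)) "gpr" else "tsv"

  if (dialect == "gpr") {
    lines <- readLines(path, warn = FALSE)
    if (!grepl("^ATF", lines[1]))
      stop("not an ATF/GPR file: ", path)
    counts <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    n_opt <- as.integer(counts[1])
    if (is.na(n_opt)) stop("malformed ATF header record count in ", path)
    df <- utils::read.delim(path, skip = 2L + n_opt, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"Name" %in% names(df))
      stop("GPR dialect requires a Name column (", path, ")")
    icol <- if ("F532 Median" %in% names(df)) "F532 Median"
            else if ("F532 Mean" %in% names(df)) "F532 Mean"
            else stop("GPR dialect requires an F532 Median or F532 Mean ",
                      "column (", path, ")")
    inten <- suppressWarnings(as.numeric(df[[icol]]))
    if (any(is.na(inten)))
      stop("malformed intensity value at data line ",
           which(is.na(inten))[1], " of ", path)
    rep_idx <- stats::ave(seq_along(df$Name), df$Name, FUN = seq_along)
    sp <- data.frame(content = df$Name, replicate = as.integer(rep_idx),
                     intensity = inten, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if ("probe_id" %in% names(df)) names(df)[names(df) == "probe_id"] <- "content"
    need <- c("content", "replicate", "intensity")
    if (!all(need %in% names(df)))
      stop("intensity TSV lacks column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "), " (", path, ")")
    inten <- suppressWarnings(as.numeric(df$intensity))
    if (any(is.na(inten)))
      stop("malformed intensity value at data line ",
           which(is.na(inten))[1], " of ", path)
    sp <- data.frame(content = df$content,
                     replicate = as.integer(df$replicate),
                     intensity = inten, stringsAsFactors = FALSE)
  }
  IntensityGrid(sample_id, sp)
}

#' Write a spot-intensity grid
#'
#' @param grid an \code{\link{IntensityGrid}}
#' @param path output file
#' @param format \code{"tsv"} (default) or \code{"gpr"} (minimal ATF
#'   dialect with \code{Name} and \code{F532 Median} columns)
#' @return invisibly, the path
#' @export
writeIntensities <- function(grid, path, format = c("tsv", "gpr")) {
  format <- match.arg(format)
  sp <- spots(grid)
  if (format == "tsv") {
    out <- data.frame(probe_id = sp$content, replicate = sp$replicate,
                      intensity = sp$intensity)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ATF\t1.0", "2\t4",
                 paste0("\"Type=GenePix Results 1.4\""),
                 paste0("\"ScanRegion=1\""),
                 paste("\"Block\"", "\"Column\"", "\"Name\"",
                       "\"F532 Median\"", sep = "\t")), con)
    for (i in seq_len(nrow(sp)))
      writeLines(paste(1L, i, paste0("\"", sp$content[i], "\""),
                       sp$intensity[i], sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write genotype tables
#'
#' @param path TSV with columns \code{sample_id}, \code{group},
#'   \code{fusion_id}, \code{variant_label}, \code{include_control}
#' @return data.frame of genotypes
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "fusion_id", "variant_label",
            "include_control")
  if (!all(need %in% names(df)))
    stop("genotype table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[is.na(df)] <- ""
  df
}

#' @rdname readGenotypes
#' @param genotypes data.frame of genotypes
#' @export
writeGenotypes <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference-diagnosis table
#'
#' @param path TSV with columns \code{sample_id}, \code{group},
#'   \code{diagnosis}, \code{method}
#' @return data.frame of reference diagnoses
#' @export
readReferences <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "diagnosis", "method")
  if (!all(need %in% names(df)))
    stop("reference table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname readReferences
#' @param references data.frame of reference diagnoses
#' @export
writeReferences <- function(references, path) {
  utils::write.table(references, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# flat calls table across reports
.callsTable <- function(reports) {
  rows <- lapply(reports, function(r) {
    calls <- fusionCalls(r)
    if (nrow(calls) == 0L)
      return(data.frame(sample_id = sampleId(r), fusion_id = "",
                        variant_label = "", status = if (qcPass(r))
                          "negative" else "invalid",
                        qc_pass = qcPass(r), stringsAsFactors = FALSE))
    data.frame(sample_id = sampleId(r), fusion_id = calls$fusion_id,
               variant_label = calls$variant_label, status = calls$status,
               qc_pass = qcPass(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the simulate / call / summarize pipeline
#'
#' Drives the whole workflow on a genotype table: load the panel, generate
#' the synthetic cohort, compute per-probe backgrounds from no-template
#' blank reference arrays, threshold and call every sample, and summarize,
#' optionally against reference diagnoses.  All outputs are written under
#' \code{outdir}: \code{calls.tsv}, \code{summary.json} and \code{run.log}
#' (panel size, seed, thresholds, configuration hash).
#'
#' @param genotypes data.frame or TSV path (see \code{\link{readGenotypes}})
#' @param outdir output directory, created if absent
#' @param panel_dir panel directory (default: bundled panel)
#' @param references optional data.frame or TSV path of reference diagnoses
#' @param seed integer seed for all randomness
#' @param params optional \code{\link{simParams}} (its seed is overridden by
#'   \code{seed})
#' @param config a \code{\link{callerConfig}}
#' @param n_background number of no-template reference arrays used for the
#'   background table (default 8)
#' @return invisibly, a list with \code{reports}, \code{summary},
#'   \code{concordance} (or NULL), \code{calls} and output \code{paths}
#' @export
runPipeline <- function(genotypes, outdir,
                        panel_dir = system.file("extdata", "panel",
                                                package = "FusionChip"),
                        references = NULL, seed = 1L, params = NULL,
                        config = callerConfig(), n_background = 8L) {
  panel <- loadPanel(panel_dir)
  if (is.character(genotypes)) genotypes <- readGenotypes(genotypes)
  if (is.character(references)) references <- readReferences(references)
  if (is.null(params)) params <- simParams(seed = seed)
  params$seed <- as.integer(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  cohort <- makeCohort(panel, genotypes, params)

  blank_params <- params
  ref_grids <- lapply(seq_len(n_background), function(i) {
    bp <- blank_params
    bp$seed <- .deriveSeed(params$seed, 1000000L + i)
    simulateIntensityGrid(arrayLayout(panel), character(0), bp,
                          sample_id = paste0("blank_", i))
  })
  background <- computeBackground(ref_grids, config)

  reports <- lapply(cohort$grids, function(g)
    callGrid(g, panel, background, config))
  calls <- .callsTable(reports)
  summary <- summarizeCohort(reports, cohort$groups)
  conc <- if (!is.null(references)) concordance(reports, references)
          else NULL

  calls_path <- file.path(outdir, "calls.tsv")
  utils::write.table(calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_path <- file.path(outdir, "summary.json")
  payload <- list(group_summary = summary$group_summary,
                  fusion_summary = summary$fusion_summary,
                  variant_distribution = summary$variant_distribution)
  if (!is.null(conc))
    payload$concordance <- list(fraction = conc$fraction,
                                n_concordant = conc$n_concordant,
                                n = conc$n, discordant = conc$discordant)
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg <- list(seed = seed, cutoff_fraction = config$cutoff_fraction,
              sd_multiplier = config$sd_multiplier, params = unclass(params),
              n_background = n_background)
  tf <- tempfile(); saveRDS(cfg, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  log_path <- file.path(outdir, "run.log")
  writeLines(c(
    sprintf("panel: %d probes, %d rules (%s)", nrow(probes(panel)),
            nrow(fusionRules(panel)), panel_dir),
    sprintf("seed: %d", seed),
    sprintf("cutoff_fraction: %g  sd_multiplier: %g",
            config$cutoff_fraction, config$sd_multiplier),
    sprintf("n_samples: %d  n_background: %d", length(reports),
            n_background),
    sprintf("config_hash: %s", cfg_hash)), log_path)

  invisible(list(reports = reports, summary = summary, concordance = conc,
                 calls = calls, background = background,
                 paths = list(calls = calls_path, summary = summary_path,
                              log = log_path)))
}
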