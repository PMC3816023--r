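#' Load an assay panel from its four table files
#'
#' Reads the primer, probe, layout and rule tables (tab-separated, fixed
#' headers) and assembles a validated \code{\link{FusionPanel}}.  The bundled
#' panel transcribed verbatim from the published primer and probe tables is
#' the default.
#'
#' @param dir directory holding \code{primers.tsv}, \code{probes.tsv},
#'   \code{layout.tsv} and \code{rules.tsv}
#' @param primer_table,probe_table,layout_table,rules_table individual file
#'   paths, overriding \code{dir}
#' @return a \code{\link{FusionPanel}}
#' @seealso \code{\link{validatePanel}}, \code{\link{probesForFusion}},
#'   \code{\link{writePanel}}
#' @export
#' @examples
#' panel <- loadPanel()
#' panel
loadPanel <- function(dir = system.file("extdata", "panel",
                                        package = "FusionChip"),
                      primer_table = file.path(dir, "primers.tsv"),
                      probe_table  = file.path(dir, "probes.tsv"),
                      layout_table = file.path(dir, "layout.tsv"),
                      rules_table  = file.path(dir, "rules.tsv")) {
  readTab <- function(path, cols, what) {
    if (!file.exists(path))
      stop("panel file not found: ", path)
    df <- tryCatch(
      utils::read.delim(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e) stop("format error reading ", what, " table (",
                               path, "): ", conditionMessage(e)))
    if (!all(cols %in% names(df)))
      stop("format error: ", what, " table lacks column(s): ",
           paste(setdiff(cols, names(df)), collapse = ", "))
    if (nrow(df) == 0L)
      stop("format error: ", what, " table is empty")
    df[is.na(df)] <- ""
    df
  }
  pr <- readTab(primer_table,
                c("name", "direction", "tag", "tag_seq", "gene_specific_seq",
                  "accession", "start_1based", "stated_len", "biotin"),
                "primer")
  pb <- readTab(probe_table,
                c("probe_id", "sequence", "role", "fusion_ids",
                  "variant_label", "array_position"), "probe")
  ly <- readTab(layout_table, c("row", "col", "replicate", "content"),
                "layout")
  ru <- readTab(rules_table,
                c("fusion_id", "variant_label", "mode", "junction_probes",
                  "partner5", "partner3", "fwd_primer", "rev_primer"),
                "rules")

  if (anyDuplicated(pr$name))
    stop("integrity error: duplicate primer name(s): ",
         paste(unique(pr$name[duplicated(pr$name)]), collapse = ", "))
  if (anyDuplicated(pb$probe_id))
    stop("integrity error: duplicate probe_id(s): ",
         paste(unique(pb$probe_id[duplicated(pb$probe_id)]), collapse = ", "))

  pr$start_1based <- suppressWarnings(as.integer(pr$start_1based))
  pr$stated_len   <- suppressWarnings(as.integer(pr$stated_len))
  pr$biotin       <- pr$biotin == "1"
  ly$col          <- as.integer(ly$col)
  ly$replicate    <- as.integer(ly$replicate)

  new("FusionPanel", primers = pr, probes = pb, layout = ly, rules = ru)
}

#' Write a panel back to its four table files
#'
#' Inverse of \code{\link{loadPanel}}; a written panel reloads field-by-field
#' identical.
#'
#' @param panel a \code{\link{FusionPanel}}
#' @param dir output directory (created if absent)
#' @return invisibly, the directory
#' @export
writePanel <- function(panel, dir) {
  stopifnot(is(panel, "FusionPanel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    df2 <- df
    if ("biotin" %in% names(df2)) df2$biotin <- as.integer(df2$biotin)
    utils::write.table(df2, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wr(panel@primers, "primers.tsv")
  wr(panel@probes,  "probes.tsv")
  wr(panel@layout,  "layout.tsv")
  wr(panel@rules,   "rules.tsv")
  invisible(dir)
}

#' Cross-check the panel tables against their design claims
#'
#' Reporting-only validation of the loaded panel: (a) universal-tag integrity
#' of every chimeric primer; (b) primers whose printed gene-specific sequence
#' length differs from the stated length in the composition string (the
#' printed sequence is taken as authoritative; discrepancies are surfaced,
#' never corrected); (c) probes outside the stated 20-30 nt design range;
#' (d) probe pairs where one sequence is a substring of the other, a
#' cross-call hazard.  The panel is never mutated.
#'
#' @param panel a \code{\link{FusionPanel}}
#' @return data.frame with columns \code{check}, \code{item}, \code{message};
#'   zero rows when nothing is flagged
#' @export
#' @examples
#' issues <- validatePanel(loadPanel())
#' subset(issues, check == "length_mismatch")
validatePanel <- function(panel) {
  stopifnot(is(panel, "FusionPanel"))
  out <- list()
  add <- function(check, item, message)
    out[[length(out) + 1L]] <<- data.frame(check = check, item = item,
                                           message = message,
                                           stringsAsFactors = FALSE)

  pr <- panel@primers
  chim <- pr[nzchar(pr$gene_specific_seq), , drop = FALSE]
  for (i in seq_len(nrow(chim))) {
    p <- chim[i, ]
    want <- if (p$direction == "forward") .T7_TAG else .SP6_TAG
    if (p$tag_seq != want)
      add("tag_integrity", p$name,
          sprintf("tag differs from the %s universal sequence",
                  if (p$direction == "forward") "T7" else "SP6"))
    got <- nchar(p$gene_specific_seq)
    if (!is.na(p$stated_len) && got != p$stated_len)
      add("length_mismatch", p$name,
          sprintf("printed gene-specific sequence is %d nt but stated length is %d",
                  got, p$stated_len))
  }

  pb <- panel@probes
  len <- nchar(pb$sequence)
  off <- len < 20L | len > 30L
  for (i in which(off))
    add("probe_length_range", pb$probe_id[i],
        sprintf("probe is %d nt, outside the 20-30 nt design range", len[i]))

  seqs <- pb$sequence
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i != j && grepl(seqs[i], seqs[j], fixed = TRUE))
      add("probe_substring", pb$probe_id[i],
          sprintf("sequence is a substring of probe %s", pb$probe_id[j]))
  }

  if (length(out)) do.call(rbind, out)
  else data.frame(check = character(0), item = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Junction and partner probes of one fusion
#'
#' Partitions the panel's probes for a fusion identifier into its chimeric
#' junction probes (one per splice variant) and its partner probes.  MLL
#' rearrangements have no junction probes; their partner pair alone carries
#' the call.
#'
#' @param panel a \code{\link{FusionPanel}}
#' @param fusion_id fusion identifier, e.g. \code{"PML-RARA"}
#' @return list with elements \code{junction} and \code{partner}, each a
#'   subset of the probe table
#' @export
#' @examples
#' probesForFusion(loadPanel(), "PML-RARA")
probesForFusion <- function(panel, fusion_id) {
  stopifnot(is(panel, "FusionPanel"))
  if (!fusion_id %in% c(fusionIds(panel), "GUS"))
    stop("unknown fusion_id: ", fusion_id)
  pb <- panel@probes
  member <- vapply(strsplit(pb$fusion_ids, ";", fixed = TRUE),
                   function(f) fusion_id %in% f, logical(1))
  list(junction = pb[member & pb$role == "junction", , drop = FALSE],
       partner  = pb[member & pb$role == "partner",  , drop = FALSE])
}

# rules of one fusion (internal)
.rulesFor <- function(panel, fusion_id) {
  ru <- panel@rules
  ru[ru$fusion_id == fusion_id, , drop = FALSE]
}

# single primer row by name (internal)
.primerByName <- function(panel, name) {
  pr <- panel@primers
  hit <- pr[pr$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) stop("unknown primer: ", name)
  hit
}

# probe sequence by id (internal)
.probeSeq <- function(panel, probe_id) {
  pb <- panel@probes
  hit <- pb$sequence[pb$probe_id == probe_id]
  if (length(hit) != 1L) stop("unknown probe: ", probe_id)
  hit
}
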