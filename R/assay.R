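# In-silico model of the assay chemistry: chimeric-primer reverse
# transcription, two-round universally tagged PCR, biotin labeling, and
# probe hybridization.  Matching is Hamming-only (no indels) and exact by
# default, since the panel oligos are designed as exact transcript
# substrings.  All coordinates are 1-based closed intervals on the sense
# strand of the source transcript.

#' Locate primer binding sites on a transcript
#'
#' Scans the sense strand for the gene-specific portion of a chimeric
#' primer.  Forward primers match the sequence directly; reverse primers
#' bind the sense strand as their reverse complement.  Matching tolerates up
#' to \code{max_mismatch} substitutions and no indels.
#'
#' @param seq transcript sequence (character or \code{DNAString})
#' @param primer_specific gene-specific primer portion (ACGT)
#' @param orientation \code{"forward"} or \code{"reverse"}
#' @param max_mismatch maximum Hamming distance (default 0, exact)
#' @return an \code{IRanges} of binding sites, sorted by start; empty when
#'   the primer is longer than the sequence or no site exists
#' @export
#' @examples
#' panel <- loadPanel()
#' gs <- primers(panel)$gene_specific_seq[primers(panel)$name == "ETO_R"]
#' findPrimerSites(paste0("AAAA", as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString(gs))), "TTTT"),
#'   gs, "reverse")
findPrimerSites <- function(seq, primer_specific,
                            orientation = c("forward", "reverse"),
                            max_mismatch = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(max_mismatch >= 0L, .isDnaString(primer_specific))
  subject <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  pattern <- if (orientation == "forward") primer_specific
             else .revComp(primer_specific)
  if (nchar(pattern) > length(subject)) return(IRanges::IRanges())
  m <- Biostrings::matchPattern(pattern, subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  r <- methods::as(m, "IRanges")
  r[order(IRanges::start(r))]
}

#' Reverse-transcribe transcripts with the chimeric reverse primers
#'
#' Models the first assay step: every reverse primer that finds a binding
#' site primes a cDNA that starts with the SP6 universal tag, continues with
#' the primer's gene-specific portion, and copies the transcript from the
#' binding site back to its 5' end.  One record is emitted per (transcript,
#' primer, site); transcripts with no site contribute nothing.
#'
#' @param transcripts named character vector or \code{DNAStringSet} of sense
#'   strands
#' @param panel a \code{\link{FusionPanel}} (its chimeric reverse primers are
#'   used, which always include the internal-control GUS primer)
#' @param max_mismatch Hamming tolerance for primer binding (default 0)
#' @return data.frame with columns \code{transcript_id}, \code{primer_name},
#'   \code{sequence}, \code{site_start}, \code{site_end} (1-based site of the
#'   primer on the sense strand); the cDNA covers positions
#'   \code{[1, site_start - 1]} of the transcript
#' @export
reverseTranscribe <- function(transcripts, panel, max_mismatch = 0L) {
  stopifnot(is(panel, "FusionPanel"))
  tx <- .asTranscripts(transcripts)
  pr <- panel@primers
  rev <- pr[pr$direction == "reverse" & nzchar(pr$gene_specific_seq), ,
            drop = FALSE]
  out <- vector("list", 0L)
  for (ti in seq_along(tx)) {
    s <- tx[[ti]]
    schar <- as.character(s)
    for (pi in seq_len(nrow(rev))) {
      gs <- rev$gene_specific_seq[pi]
      sites <- findPrimerSites(s, gs, "reverse", max_mismatch)
      for (k in seq_along(sites)) {
        a <- IRanges::start(sites)[k]; b <- IRanges::end(sites)[k]
        upstream <- if (a > 1L) .revComp(substr(schar, 1L, a - 1L)) else ""
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = names(tx)[ti],
          primer_name   = rev$name[pi],
          sequence      = paste0(.SP6_TAG, gs, upstream),
          site_start    = a, site_end = b,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(transcript_id = character(0), primer_name = character(0),
                  sequence = character(0), site_start = integer(0),
                  site_end = integer(0), stringsAsFactors = FALSE)
}

#' First-round PCR with chimeric forward primers
#'
#' For each cDNA, every forward-primer site lying fully 5' of the reverse
#' site yields an amplicon whose top strand is the T7 tag, the transcript
#' from the forward site through the reverse site, and the reverse
#' complement of the SP6 tag.  Products longer than \code{max_len} are
#' dropped (a PCR-efficiency proxy).  Round-1 products are unlabeled; see
#' \code{\link{relabelRound2}} for the biotinylated second round.
#'
#' @param cdnas data.frame from \code{\link{reverseTranscribe}}
#' @param transcripts the same transcripts given to
#'   \code{\link{reverseTranscribe}}
#' @param panel a \code{\link{FusionPanel}}
#' @param max_mismatch Hamming tolerance for primer binding (default 0)
#' @param max_len maximum amplicon length in nt (default 2000)
#' @return data.frame of amplicons: \code{transcript_id},
#'   \code{forward_primer}, \code{reverse_primer}, \code{top_strand},
#'   \code{insert_start}, \code{insert_end}, \code{round},
#'   \code{biotinylated}
#' @export
amplify <- function(cdnas, transcripts, panel, max_mismatch = 0L,
                    max_len = 2000L) {
  stopifnot(is(panel, "FusionPanel"))
  tx <- .asTranscripts(transcripts)
  pr <- panel@primers
  fwd <- pr[pr$direction == "forward" & nzchar(pr$gene_specific_seq), ,
            drop = FALSE]
  empty <- data.frame(transcript_id = character(0),
                      forward_primer = character(0),
                      reverse_primer = character(0),
                      top_strand = character(0),
                      insert_start = integer(0), insert_end = integer(0),
                      round = integer(0), biotinylated = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(cdnas) == 0L) return(empty)
  out <- vector("list", 0L)
  for (ci in seq_len(nrow(cdnas))) {
    cd <- cdnas[ci, ]
    s <- tx[[cd$transcript_id]]
    schar <- as.character(s)
    for (pi in seq_len(nrow(fwd))) {
      gs <- fwd$gene_specific_seq[pi]
      sites <- findPrimerSites(s, gs, "forward", max_mismatch)
      for (k in seq_along(sites)) {
        cs <- IRanges::start(sites)[k]; ce <- IRanges::end(sites)[k]
        if (ce > cd$site_start - 1L) next  # site must be fully 5' of the RT site
        top <- paste0(.T7_TAG, substr(schar, cs, cd$site_end),
                      .revComp(.SP6_TAG))
        if (nchar(top) > max_len) next
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = cd$transcript_id,
          forward_primer = fwd$name[pi],
          reverse_primer = cd$primer_name,
          top_strand = top,
          insert_start = cs, insert_end = cd$site_end,
          round = 1L, biotinylated = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Second-round PCR with the universal T7 / biotin-SP6 primer pair
#'
#' The second round re-amplifies every first-round product with the
#' universal primers only; sequences are unchanged, and the biotinylated SP6
#' primer labels every product for detection.
#'
#' @param amplicons round-1 amplicons from \code{\link{amplify}}
#' @return the same amplicons with \code{round = 2} and
#'   \code{biotinylated = TRUE}
#' @export
relabelRound2 <- function(amplicons) {
  if (nrow(amplicons)) {
    amplicons$round <- 2L
    amplicons$biotinylated <- TRUE
  }
  amplicons
}

#' Hybridize amplicons to the probe panel
#'
#' A probe is bound when its sequence, or its reverse complement, occurs in
#' the top strand of some biotinylated amplicon within \code{max_mismatch}
#' substitutions (the amplified product is double-stranded, so both probe
#' orientations can capture it).  Unlabeled round-1 products generate no
#' signal.
#'
#' @param amplicons amplicon data.frame (after \code{\link{relabelRound2}})
#' @param panel a \code{\link{FusionPanel}}
#' @param max_mismatch Hamming tolerance (default 0)
#' @return object of class \code{HybridizationResult}: list with
#'   \code{bound}, a named list (one element per bound probe) of data.frames
#'   with \code{amplicon}, \code{offset}, \code{mismatches}, \code{strand}
#' @seealso \code{\link{boundProbes}}
#' @export
hybridize <- function(amplicons, panel, max_mismatch = 0L) {
  stopifnot(is(panel, "FusionPanel"))
  pb <- panel@probes
  lab <- amplicons[amplicons$biotinylated, , drop = FALSE]
  bound <- list()
  if (nrow(lab)) {
    subjects <- lapply(lab$top_strand, Biostrings::DNAString)
    for (i in seq_len(nrow(pb))) {
      pseq <- pb$sequence[i]
      hits <- list()
      for (ai in seq_along(subjects)) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") pseq else .revComp(pseq)
          if (nchar(pat) > length(subjects[[ai]])) next
          m <- Biostrings::matchPattern(pat, subjects[[ai]],
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE)
          if (length(m)) {
            nm <- vapply(seq_along(m), function(k)
              Biostrings::neditAt(pat, subjects[[ai]],
                                  at = IRanges::start(m)[k]), integer(1))
            hits[[length(hits) + 1L]] <- data.frame(
              amplicon = ai, offset = IRanges::start(m),
              mismatches = nm, strand = strand, stringsAsFactors = FALSE)
          }
        }
      }
      if (length(hits))
        bound[[pb$probe_id[i]]] <- do.call(rbind, hits)
    }
  }
  structure(list(bound = bound, n_amplicons = nrow(lab)),
            class = "HybridizationResult")
}

#' Probe ids bound in a hybridization result
#'
#' @param hyb a \code{HybridizationResult} from \code{\link{hybridize}}
#' @return character vector of bound probe ids (possibly empty)
#' @export
boundProbes <- function(hyb) {
  stopifnot(inherits(hyb, "HybridizationResult"))
  names(hyb$bound)
}

#' @export
print.HybridizationResult <- function(x, ...) {
  cat("HybridizationResult:", length(x$bound), "probe(s) bound over",
      x$n_amplicons, "biotinylated amplicon(s)\n")
  if (length(x$bound)) cat(" ", paste(names(x$bound), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full in-silico assay on a set of transcripts
#'
#' Convenience wrapper chaining \code{\link{reverseTranscribe}},
#' \code{\link{amplify}}, \code{\link{relabelRound2}} and
#' \code{\link{hybridize}}.
#'
#' @inheritParams reverseTranscribe
#' @param max_len maximum amplicon length passed to \code{\link{amplify}}
#' @return list with \code{cdnas}, \code{amplicons} (biotinylated round-2),
#'   \code{hyb}, and \code{bound} (character vector of bound probe ids)
#' @export
#' @examples
#' panel <- loadPanel()
#' tx <- makeControlTranscript(panel, simParams(seed = 7))
#' simulateAssay(tx, panel)$bound
simulateAssay <- function(transcripts, panel, max_mismatch = 0L,
                          max_len = 2000L) {
  cdnas <- reverseTranscribe(transcripts, panel, max_mismatch)
  amp1 <- amplify(cdnas, transcripts, panel, max_mismatch, max_len)
  amp2 <- relabelRound2(amp1)
  hyb <- hybridize(amp2, panel, max_mismatch)
  list(cdnas = cdnas, amplicons = amp2, hyb = hyb,
       bound = boundProbes(hyb))
}
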