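# Internal helpers shared across modules.

# Universal phage-promoter tags carried at the 5' end of every chimeric
# primer.  Forward primers are tailed with T7, reverse primers with SP6;
# the biotinylated SP6 universal primer drives the second PCR round.
.T7_TAG  <- "TAATACGACTCACTATAGGGA"
.SP6_TAG <- "ATTTAGGTGACACTATAGA"

#' Universal primer tags
#'
#' The T7 and SP6 phage-promoter sequences used as the universal 5' tails of
#' the chimeric forward and reverse primers.
#'
#' @return Named character vector with elements \code{T7} and \code{SP6}.
#' @export
#' @examples
#' universalTags()
universalTags <- function() c(T7 = .T7_TAG, SP6 = .SP6_TAG)

# reverse complement of a plain character string
.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.isDnaString <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) >= 1L &&
    !grepl("[^ACGT]", x)
}

# coerce character vector / DNAStringSet to a named DNAStringSet
.asTranscripts <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- paste0("transcript", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  stop("transcripts must be a DNAStringSet or a named character vector")
}

# round half up at `digits` decimals (base round() is round-half-even)
.roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a per-unit RNG seed from a base seed, kept inside 32-bit range
.deriveSeed <- function(base, i) {
  as.integer((as.double(base) + as.double(i) * 7919) %% .Machine$integer.max)
}
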