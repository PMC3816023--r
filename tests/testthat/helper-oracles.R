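# Shared fixtures and independent brute-force oracles.

the_panel <- loadPanel()

# zero-noise parameters used by many deterministic checks
zeroNoise <- function(seed = 1L) simParams(seed = seed, noise_sigma = 0)

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

randomDnaChr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force Hamming window scan; returns 1-based start positions
bruteStarts <- function(seq, pattern, max_mismatch = 0L) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); m <- length(p)
  if (m > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (sum(s[i:(i + m - 1L)] != p) <= max_mismatch)
      starts <- c(starts, i)
  }
  starts
}

# brute-force re-evaluation of the two threshold comparisons
bruteTrueSignals <- function(grid, background_table, cutoff) {
  sp <- spots(grid)
  ids <- setdiff(unique(sp$content), c("BIOTIN", "BLANK"))
  out <- character(0)
  for (id in ids) {
    m <- mean(sp$intensity[sp$content == id])
    bg <- background_table$background[background_table$probe_id == id]
    if (length(bg) == 1L && m > bg && m > cutoff) out <- c(out, id)
  }
  sort(out)
}

# grid built directly from replicate values, bypassing the simulator
gridFromValues <- function(values, sample_id = "g") {
  rows <- do.call(rbind, lapply(names(values), function(id)
    data.frame(content = id, replicate = seq_along(values[[id]]),
               intensity = values[[id]], stringsAsFactors = FALSE)))
  IntensityGrid(sample_id, rows)
}

# reports synthesized straight from true-probe sets (no simulation)
reportsFromTrueSets <- function(true_sets, panel = the_panel) {
  lapply(names(true_sets), function(id)
    callSample(true_sets[[id]], panel, sample_id = id))
}
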