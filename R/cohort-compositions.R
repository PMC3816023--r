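# Constructors for synthetic cohort compositions, including the published
# 200-patient screening cohort (74 AML / 115 ALL / 11 CML).

#' Build genotype and reference tables from a cohort composition
#'
#' Expands a per-(group, fusion, variant) count table into per-sample
#' genotype rows plus matching reference diagnoses.  Per group, positives
#' come first, then \code{n_other} samples whose reference is
#' \code{other_translocation} (carried by the reference method but outside
#' the panel, so the synthetic genotype is fusion-free), then
#' \code{n_qc_fail} samples whose internal-control transcript is omitted
#' (reference \code{none}), then plain negatives up to the group size.
#'
#' A \code{variant_label} of \code{"A+B"} assigns two coexisting variants of
#' the same fusion to each sample; \code{"NOVEL"} builds a junction-free
#' transcript (reference diagnosis \code{fusion:V-form}).
#'
#' @param composition data.frame with columns \code{group},
#'   \code{fusion_id}, \code{variant_label}, \code{n}
#' @param group_n named integer vector of group sizes
#' @param n_other,n_qc_fail named integer vectors per group (default 0)
#' @return list with data.frames \code{genotypes} (\code{sample_id},
#'   \code{group}, \code{fusion_id}, \code{variant_label},
#'   \code{include_control}) and \code{references} (\code{sample_id},
#'   \code{group}, \code{diagnosis}, \code{method})
#' @export
cohortGenotypes <- function(composition, group_n,
                            n_other = NULL, n_qc_fail = NULL) {
  need <- c("group", "fusion_id", "variant_label", "n")
  if (!all(need %in% names(composition)))
    stop("composition lacks column(s): ",
         paste(setdiff(need, names(composition)), collapse = ", "))
  zero <- stats::setNames(integer(length(group_n)), names(group_n))
  if (is.null(n_other)) n_other <- zero
  if (is.null(n_qc_fail)) n_qc_fail <- zero
  methods_cycle <- c("cytogenetics", "FISH", "RT-PCR")

  geno <- list(); refs <- list()
  for (g in names(group_n)) {
    comp_g <- composition[composition$group == g, , drop = FALSE]
    n_pos <- sum(comp_g$n)
    n_oth <- if (g %in% names(n_other)) n_other[[g]] else 0L
    n_qcf <- if (g %in% names(n_qc_fail)) n_qc_fail[[g]] else 0L
    if (n_pos + n_oth + n_qcf > group_n[[g]])
      stop("composition for group ", g, " requests ",
           n_pos + n_oth + n_qcf, " samples but the group size is ",
           group_n[[g]])
    i <- 0L
    nextId <- function() {
      i <<- i + 1L
      sprintf("%s_%03d", g, i)
    }
    for (r in seq_len(nrow(comp_g))) {
      fid <- comp_g$fusion_id[r]
      variants <- strsplit(comp_g$variant_label[r], "+", fixed = TRUE)[[1]]
      if (length(variants) == 0L) variants <- ""
      for (k in seq_len(comp_g$n[r])) {
        id <- nextId()
        for (v in variants)
          geno[[length(geno) + 1L]] <- data.frame(
            sample_id = id, group = g, fusion_id = fid, variant_label = v,
            include_control = 1L, stringsAsFactors = FALSE)
        dx <- if (identical(variants, "NOVEL")) paste0(fid, ":V-form")
              else if (nzchar(variants[1])) paste0(fid, ":", variants[1])
              else fid
        refs[[length(refs) + 1L]] <- data.frame(
          sample_id = id, group = g, diagnosis = dx,
          method = methods_cycle[(i %% 3L) + 1L], stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(n_oth)) {
      id <- nextId()
      geno[[length(geno) + 1L]] <- data.frame(
        sample_id = id, group = g, fusion_id = "", variant_label = "",
        include_control = 1L, stringsAsFactors = FALSE)
      refs[[length(refs) + 1L]] <- data.frame(
        sample_id = id, group = g, diagnosis = "other_translocation",
        method = methods_cycle[(i %% 3L) + 1L], stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_qcf)) {
      id <- nextId()
      geno[[length(geno) + 1L]] <- data.frame(
        sample_id = id, group = g, fusion_id = "", variant_label = "",
        include_control = 0L, stringsAsFactors = FALSE)
      refs[[length(refs) + 1L]] <- data.frame(
        sample_id = id, group = g, diagnosis = "none",
        method = methods_cycle[(i %% 3L) + 1L], stringsAsFactors = FALSE)
    }
    while (i < group_n[[g]]) {
      id <- nextId()
      geno[[length(geno) + 1L]] <- data.frame(
        sample_id = id, group = g, fusion_id = "", variant_label = "",
        include_control = 1L, stringsAsFactors = FALSE)
      refs[[length(refs) + 1L]] <- data.frame(
        sample_id = id, group = g, diagnosis = "none",
        method = methods_cycle[(i %% 3L) + 1L], stringsAsFactors = FALSE)
    }
  }
  list(genotypes = do.call(rbind, geno), references = do.call(rbind, refs))
}

# composition of the published 200-patient screening cohort
.screeningComposition <- function() {
  rbind(
    data.frame(group = "AML",
               fusion_id = c("AML1-ETO", "PML-RARA", "PML-RARA", "PML-RARA",
                             "CBFB-MYH11", "MLL-AF9", "MLL-ENL", "MLL-ELL",
                             "MLL-AF6", "MLL-AF10"),
               variant_label = c("", "L-form", "S-form", "NOVEL", "A", "",
                                 "", "", "", "A"),
               n = c(8L, 5L, 4L, 1L, 5L, 1L, 1L, 1L, 1L, 1L),
               stringsAsFactors = FALSE),
    data.frame(group = "ALL",
               fusion_id = c("MLL-AF4", "TEL-AML1", "TEL-AML1", "TEL-AML1",
                             "E2A-PBX1", "E2A-PBX1", "BCR-ABL"),
               variant_label = c("", "TEL-AML1ex2",
                                 "TEL-AML1ex2+TEL-AML1ex3", "TEL-AML1ex3",
                                 "I", "Ia", "p190"),
               n = c(4L, 15L, 2L, 1L, 2L, 1L, 2L),
               stringsAsFactors = FALSE),
    data.frame(group = "CML",
               fusion_id = c("BCR-ABL", "BCR-ABL"),
               variant_label = c("p210-b3a2", "p210-b2a2"),
               n = c(5L, 3L),
               stringsAsFactors = FALSE))
}

#' Genotype table of the published 200-patient cohort
#'
#' The synthetic cohort matching the published screening study: 74 AML, 115
#' ALL and 11 CML samples; 28/27/8 carry panel translocations with the
#' printed per-fusion breakdown (8 AML1-ETO; 10 PML-RARA as 5 L-form, 4
#' S-form and 1 junction-free V-form; 5 CBFB-MYH11 type A; one each of the
#' MLL-AF9/ENL/ELL/AF6/AF10 rearrangements; 4 MLL-AF4; 18 TEL-AML1 of which
#' 15 ex2, 2 with coexisting ex2+ex3 and 1 ex3; 3 E2A-PBX1 as 2 (I) and 1
#' (Ia); 2 BCR-ABL p190; 8 BCR-ABL p210 as 5 b3a2 and 3 b2a2); 4 AML and 3
#' ALL samples with reference diagnoses outside the panel; and 6 AML plus 9
#' ALL QC-failure samples whose internal-control transcript is missing.
#'
#' @return data.frame of genotypes (see \code{\link{cohortGenotypes}})
#' @seealso \code{\link{screeningCohortReferences}}
#' @export
screeningCohortGenotypes <- function() {
  .screeningCohort()$genotypes
}

#' Reference diagnoses of the published 200-patient cohort
#'
#' @return data.frame of reference diagnoses matching
#'   \code{\link{screeningCohortGenotypes}}
#' @export
screeningCohortReferences <- function() {
  .screeningCohort()$references
}

.screeningCohort <- function() {
  cohortGenotypes(.screeningComposition(),
                  group_n = c(AML = 74L, ALL = 115L, CML = 11L),
                  n_other = c(AML = 4L, ALL = 3L, CML = 0L),
                  n_qc_fail = c(AML = 6L, ALL = 9L, CML = 0L))
}
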