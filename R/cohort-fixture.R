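#' Cohort contingency tables of the profiling and validation groups
#'
#' The clinical/phenotypic summary tables of the two study cohorts
#' (profiling n = 72: AP 20, CRC 20, HC 32; validation n = 120: 40 per
#' group), as structured count tables for use as oracle inputs to the
#' cohort tests: sex and smoking status per cohort (columns AP, CRC, HC),
#' adenoma histology of the AP groups across cohorts, CRC stage per cohort,
#' and the stage-by-cohort comparison table. Age is summarized as mean and
#' sd per group (raw ages are not available).
#'
#' @return named list of integer matrices (plus `age_summary`, a
#'   data.frame).
#' @export
cohort_fixture <- function() {
  grp <- c("AP", "CRC", "HC")
  list(
    sex_profiling = matrix(c(8, 10, 12,
                             12, 10, 20), 2L, 3L, byrow = TRUE,
                           dimnames = list(c("male", "female"), grp)),
    sex_validation = matrix(c(20, 23, 20,
                              20, 17, 20), 2L, 3L, byrow = TRUE,
                            dimnames = list(c("male", "female"), grp)),
    smoking_profiling = matrix(c(8, 2, 4,
                                 10, 11, 23,
                                 2, 7, 5), 3L, 3L, byrow = TRUE,
                               dimnames = list(c("yes", "no", "unknown"),
                                               grp)),
    smoking_validation = matrix(c(1, 3, 5,
                                  27, 12, 26,
                                  12, 25, 9), 3L, 3L, byrow = TRUE,
                                dimnames = list(c("yes", "no", "unknown"),
                                                grp)),
    type_ap = matrix(c(13, 11,
                       5, 28,
                       2, 0,
                       0, 1), 4L, 2L, byrow = TRUE,
                     dimnames = list(c("tubular_adenoma", "adenoma",
                                       "tubulovillous_adenoma",
                                       "papilloadenoma"),
                                     c("profiling", "validation"))),
    stage_profiling = matrix(c(8, 1, 4, 4, 3), 5L, 1L,
                             dimnames = list(c("0", "I", "II", "III", "IV"),
                                             "CRC")),
    stage_validation = matrix(c(18, 2, 4, 14, 2), 5L, 1L,
                              dimnames = list(c("0", "I", "II", "III", "IV"),
                                              "CRC")),
    stage_by_cohort = matrix(c(8, 18,
                               1, 2,
                               4, 4,
                               4, 14,
                               3, 2), 5L, 2L, byrow = TRUE,
                             dimnames = list(c("0", "I", "II", "III", "IV"),
                                             c("profiling", "validation"))),
    age_summary = data.frame(
      cohort = rep(c("profiling", "validation"), each = 3L),
      group = rep(c("AP", "CRC", "HC"), 2L),
      mean = c(63, 68, 58, 63, 63, 57),
      sd = c(8, 8, 12, 10, 10, 15)))
}
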