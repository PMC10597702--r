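# Reference tables for the oral-lesion cohort: per-group spectrum counts,
# stage-transition band changes, and the annotated band table used both by
# the simulator and by Grad-CAM band lookup.

#' Per-group spectrum counts of the clinical study
#'
#' Returns the number of Raman spectra per diagnostic group, either as
#' acquired (`"raw"`: 90 measurements per sample) or after the
#' class-balancing averaging used for analysis (`"analysis"`). The analysis
#' totals are 2127 spectra across T and N groups and 3534 across histological
#' groups. Note the raw-to-analysis counts are carried as published and are
#' not exact arithmetic consequences of the averaging factors.
#'
#' @param task one of `"t"`, `"n"`, `"grade"`.
#' @param stage `"analysis"` (default) or `"raw"`.
#' @return data frame with columns `group` and `n`.
#' @export
study_group_counts <- function(task = c("t", "n", "grade"),
                               stage = c("analysis", "raw")) {
  task <- match.arg(task); stage <- match.arg(stage)
  tabs <- list(
    raw = list(
      t = data.frame(group = c("Tis", "T1", "T2", "T3", "T4"),
                     n = c(270L, 720L, 1350L, 180L, 990L)),
      n = data.frame(group = c("N0", "N1", "N2"),
                     n = c(2520L, 630L, 360L)),
      grade = data.frame(group = c("health", "BOD", "WD", "MD", "PD"),
                         n = c(3510L, 810L, 2790L, 540L, 300L))),
    analysis = list(
      t = data.frame(group = c("Tis", "T1", "T2", "T3", "T4"),
                     n = c(270L, 300L, 432L, 180L, 945L)),
      n = data.frame(group = c("N0", "N1", "N2"),
                     n = c(1305L, 282L, 540L)),
      grade = data.frame(group = c("health", "BOD", "WD", "MD", "PD"),
                         n = c(703L, 704L, 987L, 540L, 600L))))
  tabs[[stage]][[task]]
}

#' Annotated Raman band table for oral tissue
#'
#' Band assignments with qualitative intensity codes for healthy versus
#' benign/malignant oral tissue. Codes map to fractions of the maximum peak
#' amplitude: weak (w) 0.4-0.6, mid (m) 0.6-0.8, strong (s) 0.8-1. Where one
#' code is given it applies to all tissue states; where two are given the
#' first describes healthy and the second lesional tissue.
#'
#' @return data frame with columns `raman_shift` (label), `shift_lo`,
#'   `shift_hi`, `center` (cm^-1), `code_health`, `code_lesion`,
#'   `assignment`. The table ships as a plain CSV under
#'   `system.file("extdata", "oral_band_table.csv", package = "ramanmtn")`.
#' @export
raman_band_table <- function() {
  path <- system.file("extdata", "oral_band_table.csv",
                      package = "ramanmtn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(raman_shift = "character"))
  df$center <- (df$shift_lo + df$shift_hi) / 2
  df
}

# intensity-code midpoints on the simulator amplitude scale
code_amplitude <- c(w = 0.5, m = 0.7, s = 0.9)

# Stage-transition band changes: at each transition along the progression
# chains Tis -> TI -> TII, N0 -> N1 -> N2, WD -> MD -> PD the listed bands
# rise or fall; the simulator applies them cumulatively.
stage_transitions <- function() {
  list(
    t = list(
      TI  = list(inc = c(685, 1014, 1231), dec = c(585, 799, 858, 983)),
      TII = list(inc = c(484, 1206, 1220), dec = c(767, 863))),
    n = list(
      N1 = list(inc = c(489, 1210, 1304, 1366), dec = c(815, 862, 983)),
      N2 = list(inc = c(607, 988, 1080, 1195), dec = c(756, 1151, 1260))),
    g = list(
      MD = list(inc = c(820, 889, 998, 1034), dec = c(501, 1299, 1332)),
      PD = list(inc = c(613, 1090, 1356), dec = c(534, 1034, 1146, 1255))))
}

# assignments for transition bands (for profile annotation)
transition_assignments <- function() {
  c(`685` = "DNA bases", `1014` = "Carbohydrates", `1231` = "Amide III",
    `585` = "OH out of plane bending and phosphate of HA",
    `799` = "Phosphates", `858` = "Tyrosine, collagen", `983` = "Lipids",
    `484` = "Glycogen", `1206` = "Hydroxyproline", `1220` = "Amide III",
    `767` = "Pyrimidine ring breathing mode", `863` = "Phosphatidic acid",
    `489` = "Glycogen", `1210` = "Phenylalanine",
    `1304` = "Adenine, cytosine", `1366` = "Tryptophan",
    `815` = "Tyrosine, proline, hydroxyproline", `862` = "Phosphate group",
    `607` = "Glycerol", `988` = "Proteins",
    `1080` = "Phospholipids and phosphate vibrations",
    `1195` = "Nucleic acids and phosphates", `756` = "Tryptophan",
    `1151` = "Carotenoid", `1260` = "Lipids",
    `820` = "Protein band and structural protein modes of tumors",
    `889` = "Methylene rocking", `998` = "C-O ribose",
    `1034` = "Phenylalanine of collagen", `501` = "Methoxy group",
    `1299` = "Lipid",
    `1332` = "C3-C3 stretch and C5-O5 stretch CHa in-plane bend",
    `613` = "Cholesterol ester", `1090` = "Phosphate", `1356` = "Guanine",
    `534` = "Cholesterol ester", `1146` = "Carbohydrates",
    `1255` = "Lipids")
}

#' Default simulated cohort composition
#'
#' One row per joint (T stage, N stage, grade) class with its raw spectrum
#' count. The histological marginal reproduces the study's raw counts exactly
#' (health 3510, BOD 810, WD 2790, MD 540, PD 300). Because the published
#' tumor totals by grade (3630) and by T/N stage (3510) disagree, the T/N
#' assignment within tumor spectra pairs the published T and N marginals
#' (which pair exactly on the raw counts) and rescales them to the grade-based
#' total by largest remainder.
#'
#' @return data frame with columns `t_stage`, `n_stage`, `grade`, `n`.
#' @export
default_composition <- function() {
  data.frame(
    t_stage = c("health", "BOD", "Tis", "T1", "T2", "T3", "T4", "T4",
                "T4", "T4"),
    n_stage = c("health", "BOD", "N0", "N0", "N0", "N0", "N1", "N1",
                "N2", "N2"),
    grade = c("health", "BOD", "WD", "WD", "WD", "WD", "WD", "MD",
              "MD", "PD"),
    n = c(3510L, 810L, 279L, 745L, 1396L, 186L, 184L, 468L, 72L, 300L),
    stringsAsFactors = FALSE)
}
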