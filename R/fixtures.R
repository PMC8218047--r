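#' Reader-confidence contingency counts (study fixture)
#'
#' The published lesion-based reader-confidence cross-tabulation: for each
#' question (lesion detection / lesion classification) and display condition
#' (with / without CT), the number of lesion reads falling in each cell of
#' the reference-method (F3D) high/low by zonal-method (xB) high/low table,
#' where "high" means a confident rating (+2 or -2) and "low" an equivocal
#' one (-1, 0, +1). Totals are 2052 reads per detection table (nine readers,
#' 76 scans, three VOIs).
#'
#' @return data.frame with columns `question`, `ct`, `f3d`, `xb`, `count`.
#' @export
reader_confidence_counts <- function() {
  utils::read.csv(system.file("extdata", "reader_confidence_counts.csv",
                              package = "zonespect"),
                  stringsAsFactors = FALSE)
}

#' Per-zone tissue uptake reference table (study fixture)
#'
#' Published mean absolute uptake (kBq/ml) by tissue zone with 95% CI and
#' SD; the cortical-bone to soft-tissue mean ratio is about 13.
#'
#' @return data.frame with columns `zone`, `tissue`, `mean_kbq_ml`,
#'   `ci_lo`, `ci_hi`, `sd`.
#' @export
zone_uptake_reference <- function() {
  utils::read.csv(system.file("extdata", "zone_uptake_reference.csv",
                              package = "zonespect"),
                  stringsAsFactors = FALSE)
}

#' Concordance analysis of a reader-confidence contingency table
#'
#' For every (question, CT condition) stratum of a cell-count table in the
#' format of [reader_confidence_counts()], computes the marginal H/L counts
#' of both methods, the confidence likelihood ratio
#' `R_C = (H_xB / L_xB) / (H_F3D / L_F3D)` and the Pearson chi-squared
#' (uncorrected and Yates-corrected) of the 2x2 table.
#'
#' @param counts data.frame like [reader_confidence_counts()].
#' @return data.frame with one row per stratum: `question`, `ct`, the four
#'   marginal counts, `r_c`, `chi2`, `chi2_yates`, `p_value`, `n`.
#' @export
confidence_analysis <- function(counts = reader_confidence_counts()) {
  strata <- unique(counts[, c("question", "ct")])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    s <- counts[counts$question == strata$question[i] &
                  counts$ct == strata$ct[i], ]
    tab <- matrix(0, 2, 2, dimnames = list(f3d = c("high", "low"),
                                           xb = c("high", "low")))
    for (j in seq_len(nrow(s))) tab[s$f3d[j], s$xb[j]] <- s$count[j]
    h_xb <- sum(tab[, "high"]); l_xb <- sum(tab[, "low"])
    h_f3d <- sum(tab["high", ]); l_f3d <- sum(tab["low", ])
    rc <- confidence_ratio(hl_counts(h_xb, l_xb), hl_counts(h_f3d, l_f3d))
    ch <- contingency_chi2(tab)
    data.frame(question = strata$question[i], ct = strata$ct[i],
               h_xb = h_xb, l_xb = l_xb, h_f3d = h_f3d, l_f3d = l_f3d,
               r_c = rc, chi2 = ch$statistic, chi2_yates = ch$statistic_yates,
               p_value = ch$p_value, n = sum(tab))
  })
  do.call(rbind, out)
}

#' Expected read count of the visual-assessment design
#'
#' Bookkeeping of the reading workload: each reader reads every scan in
#' every reconstruction variant and assesses each VOI once, so the grand
#' total per reader is `n_variants * n_scans * n_vois` (912 for 4 variants,
#' 76 scans, 3 VOIs).
#'
#' @param n_variants reconstruction/display variants per scan (default 4).
#' @param n_scans scans (default 76).
#' @param n_vois VOIs assessed per scan (default 3).
#' @return integer read count.
#' @export
expected_read_count <- function(n_variants = 4L, n_scans = 76L, n_vois = 3L) {
  if (any(c(n_variants, n_scans, n_vois) < 1)) stop("counts must be >= 1")
  as.integer(n_variants) * as.integer(n_scans) * as.integer(n_vois)
}
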