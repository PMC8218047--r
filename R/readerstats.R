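#' Collapse five-point confidence ratings into confident/equivocal counts
#'
#' A rating of +2 or -2 counts as a confident (H) read; -1, 0 and +1 count
#' as equivocal (L).
#'
#' @param ratings data.frame with a `rating` column in `{-2,-1,0,1,2}`,
#'   optionally `variant` and `question` columns to select on.
#' @param variant,question optional filters.
#' @return list of class `hl_counts` with integer fields `h` and `l`
#'   (`h + l` equals the number of selected rows).
#' @export
collapse_confidence <- function(ratings, variant = NULL, question = NULL) {
  r <- ratings
  if (!is.null(variant)) r <- r[r$variant == variant, , drop = FALSE]
  if (!is.null(question)) r <- r[r$question == question, , drop = FALSE]
  if (nrow(r) > 0 && !all(r$rating %in% -2:2)) {
    stop("ratings outside the five-point scale {-2,...,2}")
  }
  hl_counts(sum(abs(r$rating) == 2), sum(abs(r$rating) <= 1))
}

#' Confident/equivocal count pair
#' @param h confident count (|rating| = 2).
#' @param l equivocal count (rating in -1/0/1).
#' @return list of class `hl_counts`.
#' @export
hl_counts <- function(h, l) {
  if (h < 0 || l < 0) stop("counts must be >= 0")
  structure(list(h = as.integer(h), l = as.integer(l)), class = "hl_counts")
}

#' Confidence likelihood ratio between two methods
#'
#' `R_C = (H_a / L_a) / (H_b / L_b)`: the odds of a confident versus an
#' equivocal read under method `a`, relative to the same odds under method
#' `b`. By construction `confidence_ratio(a, b) * confidence_ratio(b, a) = 1`.
#'
#' @param hl_a,hl_b [hl_counts()] for the two methods (all four counts > 0).
#' @return scalar R_C.
#' @export
confidence_ratio <- function(hl_a, hl_b) {
  stopifnot(inherits(hl_a, "hl_counts"), inherits(hl_b, "hl_counts"))
  counts <- c(hl_a$h, hl_a$l, hl_b$h, hl_b$l)
  if (any(counts == 0)) {
    stop("degenerate confidence table: all H and L counts must be > 0")
  }
  (hl_a$h / hl_a$l) / (hl_b$h / hl_b$l)
}

#' Pearson chi-squared on a 2x2 contingency table
#'
#' Computes both the uncorrected Pearson statistic and the Yates
#' continuity-corrected one, with p-values on 1 degree of freedom.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive margins.
#' @return list with `statistic`, `p_value` (uncorrected) and
#'   `statistic_yates`, `p_value_yates`.
#' @export
contingency_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-squared is undefined")
  }
  plain <- stats::chisq.test(tab, correct = FALSE)
  yates <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(plain$statistic),
       p_value = plain$p.value,
       statistic_yates = unname(yates$statistic),
       p_value_yates = yates$p.value)
}

#' Chi-squared critical value
#'
#' Upper critical value of the chi-squared distribution, e.g. 10.83 at
#' alpha = 0.001 with 1 df.
#'
#' @param alpha upper tail probability.
#' @param df degrees of freedom.
#' @return critical value.
#' @export
chi2_critical <- function(alpha = 0.001, df = 1) {
  stats::qchisq(1 - alpha, df = df)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects ICC from the ANOVA mean squares of a complete
#' subjects x raters matrix: ICC(2,1) for single ratings and ICC(2,k) for
#' the average of the k raters, with F-based 95% confidence intervals
#' (Shrout-Fleiss; the average-measures interval is the single-measures one
#' stepped up by Spearman-Brown).
#'
#' @param x numeric matrix, subjects in rows, raters in columns (complete,
#'   >= 2 rows and >= 2 columns).
#' @param conf_level confidence level (default 0.95).
#' @return list with `icc_single`, `icc_average`, `ci_single`, `ci_average`,
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_absolute <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells: complete ratings are required")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  # Satterthwaite df for the ICC(2,1) interval (Shrout & Fleiss 1979)
  fj <- msc / mse
  num <- (k - 1) * (n - 1) *
    (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
  den <- (n - 1) * k^2 * icc1^2 * fj^2 +
    (n * (1 + (k - 1) * icc1) - k * icc1)^2
  v <- num / den
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  list(icc_single = icc1, icc_average = icck,
       ci_single = c(lo1, hi1), ci_average = sb(c(lo1, hi1)),
       msr = msr, msc = msc, mse = mse)
}

#' Majority-vote surrogate truth from per-reader calls
#'
#' Ratings above zero vote positive, below zero negative; zeros abstain.
#' A strict majority sets the label; ties (or all-abstain panels) are
#' flagged `"needs consensus"` rather than resolved silently.
#'
#' @param ratings data.frame with `lesion_id` and `rating` columns (one row
#'   per reader per lesion; pre-filter to one variant).
#' @return data.frame with `lesion_id`, `label` in
#'   `{"positive","negative","needs consensus"}`, `n_pos`, `n_neg`.
#' @export
surrogate_truth <- function(ratings) {
  if (nrow(ratings) == 0L) stop("at least one read per lesion is required")
  ids <- unique(ratings$lesion_id)
  res <- lapply(ids, function(id) {
    r <- ratings$rating[ratings$lesion_id == id]
    np <- sum(r > 0); nn <- sum(r < 0)
    label <- if (np > nn) "positive" else if (nn > np) "negative"
             else "needs consensus"
    data.frame(lesion_id = id, label = label, n_pos = np, n_neg = nn)
  })
  do.call(rbind, res)
}
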