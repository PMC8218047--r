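#' Empirical ROC curve and AUC
#'
#' Uses the "positive if score > c" orientation (higher SUV = more
#' malignant). The AUC equals the Mann-Whitney pair statistic: the fraction
#' of (positive, negative) pairs where the positive outscores the negative,
#' ties counting one half.
#'
#' @param scores numeric scores (finite).
#' @param labels logical (or 0/1) truth labels, `TRUE` = positive; both
#'   classes must be present.
#' @return object of class `roc_result`: `thresholds` (observed score
#'   values), `sensitivity`, `specificity`, `auc`, `se_hanley_mcneil`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to form an ROC curve")
  }
  # Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores))
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(c) mean(pos > c), numeric(1))
  spec <- vapply(thr, function(c) mean(neg <= c), numeric(1))
  se <- if (auc > 0 && auc < 1 && n_pos >= 2 && n_neg >= 2) {
    auc_se_hanley_mcneil(auc, n_pos, n_neg)
  } else NA_real_
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, se_hanley_mcneil = se,
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (HM SE %.4f), %d pos / %d neg\n",
              x$auc, x$se_hanley_mcneil, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden index and its associated criterion
#'
#' `J = max(sensitivity + specificity - 1)` over the observed score values,
#' with the criterion reported as "positive if score > c". Ties are broken
#' toward the smaller criterion (higher sensitivity).
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return list with `j` and `criterion`.
#' @export
youden <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j_all <- roc$sensitivity + roc$specificity - 1
  best <- which(j_all >= max(j_all) - 1e-12)[1]  # smallest criterion wins ties
  list(j = j_all[best], criterion = roc$thresholds[best])
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE^2 = [A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)] / (n+ n-)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc area under the curve, strictly between 0 and 1.
#' @param n_pos,n_neg class sizes (>= 2).
#' @return standard error.
#' @export
auc_se_hanley_mcneil <- function(auc, n_pos, n_neg) {
  if (auc <= 0 || auc >= 1) stop("`auc` must lie strictly in (0, 1)")
  if (n_pos < 2 || n_neg < 2) stop("need at least 2 observations per class")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Nonparametric test via the structural components (placement values) of
#' the two Mann-Whitney statistics computed on the same cases.
#'
#' @param scores_a,scores_b scores of the two modalities on the same cases.
#' @param labels common truth labels (`TRUE` = positive).
#' @return list with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("scores and labels differ in length")
  }
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("both classes must be present")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  se <- sqrt(max(var_delta, 0))
  z <- if (se > 0) delta / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(delta == 0)
  if (se == 0 && delta == 0) p <- 1
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = se, z = z,
       p_value = p)
}

#' Bias-corrected accelerated (BCa) bootstrap confidence interval
#'
#' Seeded BCa interval for a statistic of a vector or data.frame sample,
#' built on `boot::boot` / `boot::boot.ci` with 1000 resamples by default.
#' A statistic that is constant over all resamples yields the zero-width
#' interval at that constant.
#'
#' @param data numeric vector or data.frame of cases to resample.
#' @param statistic function of one argument (the resampled data).
#' @param n_iterations bootstrap resamples (default 1000).
#' @param conf_level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric `c(lower, upper)` with attribute `"t0"`.
#' @export
bca_bootstrap <- function(data, statistic, n_iterations = 1000L,
                          conf_level = 0.95, seed = 1L) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1")
  take <- if (is.data.frame(data)) {
    function(d, idx) statistic(d[idx, , drop = FALSE])
  } else {
    function(d, idx) statistic(d[idx])
  }
  t0 <- if (is.data.frame(data)) statistic(data) else statistic(data)
  if (!is.finite(t0)) stop("statistic is degenerate on the original sample")
  withr_seed(seed, {
    b <- boot::boot(data, take, R = n_iterations)
    if (any(!is.finite(b$t))) {
      stop("statistic is degenerate (non-finite) on some resamples")
    }
    if (stats::var(as.vector(b$t)) == 0) {
      ci <- c(b$t[1], b$t[1])
    } else {
      bc <- boot::boot.ci(b, conf = conf_level, type = "bca")
      ci <- bc$bca[4:5]
    }
    structure(ci, t0 = t0)
  })
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` for the proportion.
#' @export
binomial_exact_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n with n >= 1")
  }
  as.numeric(stats::binom.test(k, n, conf.level = level)$conf.int)
}

#' Crossing point of two lognormal densities
#'
#' Analytic intersection of `lognormal(m1, s1)` and `lognormal(m2, s2)`
#' densities: with equal sdlog the crossing is `exp((m1 + m2) / 2)`; in
#' general the quadratic in `log x` is solved and the root between the two
#' medians is returned. Used as the oracle for SUV-criterion recovery on
#' synthetic lesion populations.
#'
#' @param meanlog1,sdlog1 parameters of the first (higher) distribution.
#' @param meanlog2,sdlog2 parameters of the second distribution.
#' @return crossing point on the original scale.
#' @export
lognormal_crossing <- function(meanlog1, sdlog1, meanlog2, sdlog2) {
  if (abs(sdlog1 - sdlog2) < 1e-12) {
    return(exp((meanlog1 + meanlog2) / 2))
  }
  # equate log-densities: quadratic a u^2 + b u + c = 0 in u = log x
  a <- 1 / (2 * sdlog2^2) - 1 / (2 * sdlog1^2)
  b <- meanlog1 / sdlog1^2 - meanlog2 / sdlog2^2
  cc <- meanlog2^2 / (2 * sdlog2^2) - meanlog1^2 / (2 * sdlog1^2) +
    log(sdlog2 / sdlog1)
  roots <- Re(polyroot(c(cc, b, a)))
  lo <- min(meanlog1, meanlog2); hi <- max(meanlog1, meanlog2)
  inb <- roots[roots >= lo & roots <= hi]
  exp(if (length(inb)) inb[1] else roots[which.min(abs(roots - (lo + hi) / 2))])
}

#' Stratified SUV-threshold ROC study over a lesion table
#'
#' Applies the location/volume strata used for SUV-based classification
#' (all lesions; not-joint; joint; not-joint with volume <= 6 ml; not-joint
#' with volume > 6 ml; lesions exactly at 6 ml fall in the "<=" stratum) and
#' reports per-stratum ROC, Youden index and associated SUV criterion,
#' optionally with BCa bootstrap intervals for J and the criterion.
#'
#' @param lesions data.frame with columns `suv`, `volume_ml`, `joint` and
#'   `true_class`.
#' @param positive_classes classes counted as truly positive
#'   (default `"malignant"`).
#' @param negative_classes classes counted as negative (default benign and
#'   negative controls; other classes are excluded).
#' @param n_boot BCa resamples for the J/criterion intervals (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return named list of per-stratum results (`roc`, `j`, `criterion`,
#'   `auc`, `n_pos`, `n_neg`, and CIs when bootstrapped); strata with a
#'   single class are flagged with `skipped = TRUE`.
#' @export
threshold_study <- function(lesions,
                            positive_classes = "malignant",
                            negative_classes = c("benign", "negative"),
                            n_boot = 0L, seed = 1L) {
  need <- c("suv", "volume_ml", "joint", "true_class")
  if (!all(need %in% names(lesions))) {
    stop("lesion table needs columns: ", paste(need, collapse = ", "))
  }
  keep <- lesions$true_class %in% c(positive_classes, negative_classes)
  les <- lesions[keep, , drop = FALSE]
  les$positive <- les$true_class %in% positive_classes
  strata <- list(
    none = rep(TRUE, nrow(les)),
    not_joint = !les$joint,
    joint = les$joint,
    not_joint_le6ml = !les$joint & les$volume_ml <= 6,
    not_joint_gt6ml = !les$joint & les$volume_ml > 6
  )
  out <- list()
  for (nm in names(strata)) {
    d <- les[strata[[nm]], , drop = FALSE]
    if (length(unique(d$positive)) < 2L) {
      out[[nm]] <- list(skipped = TRUE,
                        reason = "stratum contains a single class",
                        n = nrow(d))
      next
    }
    roc <- roc_auc(d$suv, d$positive)
    yd <- youden(roc)
    res <- list(skipped = FALSE, roc = roc, auc = roc$auc,
                j = yd$j, criterion = yd$criterion,
                n_pos = roc$n_pos, n_neg = roc$n_neg)
    if (n_boot > 0) {
      res$criterion_ci <- bca_bootstrap(
        d, function(dd) youden(roc_auc(dd$suv, dd$positive))$criterion,
        n_iterations = n_boot, seed = seed)
      res$j_ci <- bca_bootstrap(
        d, function(dd) youden(roc_auc(dd$suv, dd$positive))$j,
        n_iterations = n_boot, seed = seed)
    }
    out[[nm]] <- res
  }
  out
}
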