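test_that("AUC equals the exhaustive Mann-Whitney pair count", {
  r <- roc_auc(c(5, 3, 4, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(9, 8, 2, 1), c(1, 1, 0, 0))$auc, 1.0)
  # label inversion mirrors the AUC
  set.seed(31)
  s <- rnorm(60); l <- rep(c(TRUE, FALSE), 30)
  expect_equal(roc_auc(s, l)$auc, 1 - roc_auc(s, !l)$auc, tolerance = 1e-12)
  # exhaustive pair-counting oracle with ties, up to n = 200
  for (i in 1:5) {
    sc <- sample(round(rnorm(200), 1))  # coarse scores force ties
    lb <- runif(200) < 0.4
    pos <- sc[lb]; neg <- sc[!lb]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lb)$auc, mean(pairs), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  # agreement with an independent ROC implementation
  p <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(s, l)$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
})

test_that("the Youden criterion equals an exhaustive threshold search", {
  r <- roc_auc(c(6, 10, 12, 5, 7, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  y <- youden(r)
  expect_equal(y$j, 2 / 3, tolerance = 1e-12)
  expect_equal(y$criterion, 9)
  expect_equal(youden(roc_auc(c(9, 8, 2, 1), c(1, 1, 0, 0)))$j, 1.0)
  expect_equal(youden(roc_auc(rep(c(1, 2, 3), 2),
                              rep(c(TRUE, FALSE), each = 3)))$j, 0)
  # brute-force oracle on random data
  set.seed(17)
  for (i in 1:5) {
    sc <- round(rnorm(80), 1); lb <- runif(80) < 0.5
    r2 <- roc_auc(sc, lb)
    y2 <- youden(r2)
    cand <- sort(unique(sc))
    j_br <- vapply(cand, function(c) {
      mean(sc[lb] > c) + mean(sc[!lb] <= c) - 1
    }, numeric(1))
    expect_equal(y2$j, max(j_br), tolerance = 1e-12)
    expect_equal(y2$criterion, cand[which(j_br >= max(j_br) - 1e-12)[1]])
  }
})

test_that("the Hanley-McNeil SE follows its closed form and limits", {
  a <- 0.5; np <- 40; nn <- 60
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  oracle <- sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) +
                    (nn - 1) * (q2 - a^2)) / (np * nn))
  expect_equal(auc_se_hanley_mcneil(a, np, nn), oracle, tolerance = 1e-12)
  se_seq <- vapply(c(10, 20, 40, 80, 160), function(n)
    auc_se_hanley_mcneil(0.8, n, 50), numeric(1))
  expect_true(all(diff(se_seq) < 0))
  expect_lt(auc_se_hanley_mcneil(0.999, 50, 50),
            auc_se_hanley_mcneil(0.9, 50, 50))
  expect_error(auc_se_hanley_mcneil(1, 10, 10), "strictly")
})

test_that("the DeLong test matches a brute-force placement oracle", {
  # identical scores: no difference, p = 1
  s <- c(3, 1, 4, 1, 5, 9); l <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  d0 <- delong_paired_test(s, s, l)
  expect_equal(d0$delta, 0)
  expect_equal(d0$p_value, 1)
  # tiny example against explicit V10/V01 components
  sa <- c(2.1, 3.3, 1.2, 0.5, 2.8, 0.9)
  sb <- c(1.9, 2.0, 2.2, 1.1, 0.4, 1.3)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- delong_paired_test(sa, sb, lb)
  comp <- function(sc) {
    pos <- sc[lb]; neg <- sc[!lb]
    psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  ca <- comp(sa); cb <- comp(sb)
  var_or <- (var(ca$v10) + var(cb$v10) - 2 * cov(ca$v10, cb$v10)) / 3 +
    (var(ca$v01) + var(cb$v01) - 2 * cov(ca$v01, cb$v01)) / 3
  expect_equal(res$delta, ca$auc - cb$auc, tolerance = 1e-12)
  expect_equal(res$se, sqrt(var_or), tolerance = 1e-12)
  # antisymmetry
  res_ba <- delong_paired_test(sb, sa, lb)
  expect_equal(res_ba$z, -res$z, tolerance = 1e-12)
  expect_equal(res_ba$p_value, res$p_value, tolerance = 1e-12)
  # cross-check against an independent implementation
  set.seed(9)
  n <- 120; lab <- runif(n) < 0.5
  x1 <- rnorm(n) + lab; x2 <- 0.7 * x1 + rnorm(n, sd = 0.7)
  mine <- delong_paired_test(x1, x2, lab)
  ra <- pROC::roc(lab, x1, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lab, x2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong and Hanley-McNeil SEs agree with the bootstrap", {
  set.seed(12)
  n <- 500
  lab <- runif(n) < 0.4
  x1 <- rnorm(n, mean = ifelse(lab, 1, 0))
  x2 <- 0.6 * x1 + rnorm(n, sd = 0.8)
  dl <- delong_paired_test(x1, x2, lab)
  boots <- replicate(1000, {
    i <- sample(n, replace = TRUE)
    if (length(unique(lab[i])) < 2) return(NA_real_)
    roc_auc(x1[i], lab[i])$auc - roc_auc(x2[i], lab[i])$auc
  })
  expect_lt(abs(dl$se - sd(boots, na.rm = TRUE)) / dl$se, 0.15)
  # single-modality SEs: Hanley-McNeil vs DeLong within 20%
  pa <- zonespect:::delong_placements(x1, lab)
  se_dl <- sqrt(var(pa$v10) / sum(lab) + var(pa$v01) / sum(!lab))
  se_hm <- auc_se_hanley_mcneil(pa$auc, sum(lab), sum(!lab))
  expect_lt(abs(se_hm - se_dl) / se_dl, 0.20)
})

test_that("BCa bootstrap intervals are seeded, sane and well-calibrated", {
  expect_equal(as.numeric(bca_bootstrap(rep(3.3, 20), mean, seed = 1)),
               c(3.3, 3.3))
  set.seed(44)
  x <- rnorm(80)
  ci1 <- bca_bootstrap(x, mean, seed = 5)
  ci2 <- bca_bootstrap(x, mean, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] < mean(x) && mean(x) < ci1[2])
  # coverage of the mean of n = 100 standard normals: ~95% over 400 runs
  set.seed(99)
  cover <- replicate(400, {
    z <- rnorm(100)
    ci <- bca_bootstrap(z, mean, n_iterations = 399,
                        seed = sample.int(1e6, 1))
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("exact binomial intervals are Clopper-Pearson", {
  expect_equal(binomial_exact_ci(10, 10)[2], 1)
  expect_equal(binomial_exact_ci(0, 10)[1], 0)
  ci <- binomial_exact_ci(8, 10)
  expect_equal(ci[1], qbeta(0.025, 8, 3), tolerance = 1e-9)
  expect_equal(ci[2], qbeta(0.975, 9, 2), tolerance = 1e-9)
  expect_error(binomial_exact_ci(11, 10), "<= n")
})

test_that("the stratified threshold study partitions lesions consistently", {
  les <- make_lesion_population(lesion_population_spec(400, seed = 21))
  ts <- threshold_study(les)
  n_of <- function(nm) ts[[nm]]$n_pos + ts[[nm]]$n_neg
  expect_equal(n_of("not_joint_le6ml") + n_of("not_joint_gt6ml"),
               n_of("not_joint"))
  expect_equal(n_of("not_joint") + n_of("joint"), n_of("none"))
  # "none" equals the unstratified ROC on the same kept classes
  keep <- les[les$true_class %in% c("malignant", "benign", "negative"), ]
  direct <- roc_auc(keep$suv, keep$true_class == "malignant")
  expect_equal(ts$none$auc, direct$auc, tolerance = 1e-12)
  # a single-class stratum is flagged, not dropped silently
  one_cls <- les[les$true_class == "malignant", ]
  ts2 <- threshold_study(one_cls)
  expect_true(ts2$none$skipped)
})

test_that("the SUV criterion recovers the analytic lognormal crossing", {
  spec <- lesion_population_spec(
    600, class_proportions = c(malignant = 0.5, benign = 0.5,
                               questionable = 0, negative = 0),
    suv_meanlog = c(malignant = log(14), benign = log(7),
                    questionable = log(9), negative = log(3)),
    suv_sdlog = c(malignant = 0.35, benign = 0.35,
                  questionable = 0.4, negative = 0.4),
    joint_fraction = 0, seed = 33)
  les <- make_lesion_population(spec)
  ts <- threshold_study(les, n_boot = 400, seed = 7)
  crossing <- lognormal_crossing(log(14), 0.35, log(7), 0.35)
  expect_equal(crossing, sqrt(14 * 7), tolerance = 1e-12)
  ci <- ts$none$criterion_ci
  expect_true(ci[1] <= crossing && crossing <= ci[2])
})
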