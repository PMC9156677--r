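test_that("PLS-DA separates on an oracle feature and keeps scores orthogonal", {
  set.seed(1)
  y <- factor(rep(c("A", "B"), each = 10))
  x <- cbind(oracle = ifelse(y == "B", 1, -1) + rnorm(20, sd = 1e-6),
             noise1 = rnorm(20), noise2 = rnorm(20))
  fit <- plsda_fit(x, y, n_components = 2)
  expect_equal(as.character(predict(fit, x)), as.character(y))
  expect_lt(abs(sum(fit$T[, 1] * fit$T[, 2])), 1e-8)
  expect_equal(unname(colSums(fit$W^2)), rep(1, 2), tolerance = 1e-12)
  expect_gt(fit$vip["oracle"], 1)
})

test_that("single-feature PLS-DA has the closed form", {
  y <- factor(rep(c("A", "B"), each = 5))
  x <- matrix(c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15), 10, 1,
              dimnames = list(NULL, "f"))
  fit <- plsda_fit(x, y, n_components = 1)
  expect_equal(abs(unname(fit$W[1, 1])), 1)
  centered <- x[, 1] - mean(x[, 1])
  expect_equal(unname(fit$T[, 1]), unname(fit$W[1, 1]) * centered)
  expect_equal(unname(fit$vip), 1)
})

test_that("VIP satisfies its normalization and symmetry properties", {
  set.seed(2)
  y <- factor(rep(c("A", "B"), each = 8))
  for (p_feat in c(3, 7, 12)) {
    x <- matrix(rnorm(16 * p_feat), 16, p_feat,
                dimnames = list(NULL, paste0("f", 1:p_feat)))
    x[, 1] <- x[, 1] + ifelse(y == "B", 2, 0)
    fit <- plsda_fit(x, y, n_components = 2)
    expect_equal(sum(fit$vip^2), p_feat, tolerance = 1e-9)
  }
  # identical copies of one informative feature share VIP = 1
  base <- rnorm(16) + ifelse(y == "B", 3, 0)
  copies <- matrix(base, 16, 4, dimnames = list(NULL, paste0("c", 1:4)))
  fitc <- plsda_fit(copies, y, n_components = 1)
  expect_equal(unname(fitc$vip), rep(1, 4), tolerance = 1e-9)
})

test_that("VIP matches an independent straight-line implementation", {
  set.seed(3)
  y <- factor(rep(c("A", "B"), each = 10))
  x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 2] <- x[, 2] + ifelse(y == "B", 2.5, 0)
  fit <- plsda_fit(x, y, n_components = 2)

  # independent NIPALS written from the definition
  X <- scale(x, scale = FALSE)
  yv <- ifelse(y == "B", 1, -1); yv <- yv - mean(yv)
  W <- NULL; Tm <- NULL; qv <- NULL
  Xa <- X; ya <- yv
  for (a in 1:2) {
    w <- drop(crossprod(Xa, ya)); w <- w / sqrt(sum(w^2))
    tt <- drop(Xa %*% w)
    p <- drop(crossprod(Xa, tt)) / sum(tt^2)
    q <- sum(ya * tt) / sum(tt^2)
    Xa <- Xa - tcrossprod(tt, p); ya <- ya - q * tt
    W <- cbind(W, w); Tm <- cbind(Tm, tt); qv <- c(qv, q)
  }
  ssy <- qv^2 * colSums(Tm^2)
  vip_ref <- sqrt(5 * drop(W^2 %*% ssy) / sum(ssy))
  expect_equal(unname(fit$vip), unname(vip_ref), tolerance = 1e-9)
  expect_gt(fit$vip["f2"], 1)
  expect_true(all(fit$vip[-2] < fit$vip["f2"]))
})

test_that("first latent variable agrees with an external PLS-DA", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  y <- factor(rep(c("A", "B"), each = 10))
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- x[, 1] + ifelse(y == "B", 2, 0)
  fit <- plsda_fit(x, y, n_components = 1)
  ref <- mixOmics::plsda(x, y, ncomp = 1, scale = FALSE)
  expect_gt(abs(cor(fit$T[, 1], ref$variates$X[, 1])), 0.999)
})

test_that("double cross-validation recovers separation and stays honest on noise", {
  sim <- simulate_cohort_study(
    simulation_params(n_per_cohort = 10, n_species = 30, cohort_shift = 3),
    seed = 11)
  st <- sim$study
  norm <- gaussianize(prevalence_filter(
    to_relative_abundance(st$abundance), 0.05))
  g <- cohort_labels(st)
  dcv <- double_cv_classify(norm, g, repeats = 10, seed = 1)
  expect_true(all(dcv$rates$mean_rate >= 95))

  # determinism under a fixed seed
  dcv2 <- double_cv_classify(norm, g, repeats = 10, seed = 1)
  expect_identical(dcv$rates, dcv2$rates)

  # permuted labels: chance level
  set.seed(99)
  gp <- sample(g)
  dcv0 <- double_cv_classify(norm, gp, repeats = 10, seed = 2)
  expect_true(mean(dcv0$rates$mean_rate) > 35 &&
                mean(dcv0$rates$mean_rate) < 65)
})

test_that("Mann-Whitney and Kruskal-Wallis branches behave as documented", {
  res <- group_difference_test(c(1, 2, 3, 4, 5, 6),
                               rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)   # exact enumeration of C(6,3) splits
  expect_true(res$extras$exact)

  same <- group_difference_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)

  # exact and normal-approximation branches agree closely at n = 10 + 10
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(20)
    g <- rep(c("a", "b"), each = 10)
    p_exact <- suppressWarnings(wilcox.test(v[1:10], v[11:20],
                                            exact = TRUE)$p.value)
    p_approx <- suppressWarnings(wilcox.test(v[1:10], v[11:20], exact = FALSE,
                                             correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.011)
  }

  kw <- group_difference_test(c(rnorm(5), rnorm(5) + 8, rnorm(5) + 16),
                              rep(c("a", "b", "c"), each = 5),
                              method = "kruskal-wallis")
  expect_lt(kw$p_value, 0.05)
  expect_error(group_difference_test(1:4, c("a", "a", "b", "c")),
               "exactly 2 groups")
})

test_that("fold ratios orient to the higher cohort and flag zero means", {
  fr <- fold_ratio(c(117.15, 86.80), c("EE", "SE"))
  expect_equal(round(fr$fr, 2), 1.35)
  expect_equal(fr$higher_cohort, "EE")

  expect_equal(fold_ratio(c(5, 5, 3, 3), rep(c("A", "B"), each = 2))$fr, 5 / 3)
  expect_equal(fold_ratio(c(4, 4), c("A", "B"))$fr, 1)

  zero <- fold_ratio(c(2, 2, 0, 0), rep(c("A", "B"), each = 2))
  expect_true(zero$fr_infinite)
  expect_equal(zero$fr, Inf)

  expect_equal(fold_ratio_directional(c(10, 10, 5, 5),
                                      rep(c("EE", "SE"), each = 2),
                                      "EE", "SE"), 2)
})

test_that("volcano tables rank the planted metabolite at the top", {
  sim <- simulate_cohort_study(simulation_params(n_species = 20), seed = 21)
  st <- sim$study
  v <- volcano_table(st$metabolites, cohort_labels(st),
                     numerator = "EE", denominator = "SE")
  expect_equal(v$neg_log10_p, -log10(v$p_value))
  expect_false(is.unsorted(v$p_value))
  # planted 2.81x formate should dominate the ranking over many seeds
  top3 <- vapply(1:100, function(s) {
    sim <- simulate_cohort_study(simulation_params(n_species = 20),
                                 seed = 200 + s)
    vt <- volcano_table(sim$study$metabolites, cohort_labels(sim$study),
                        numerator = "EE", denominator = "SE")
    "formate" %in% vt$metabolite[1:3]
  }, logical(1))
  expect_gte(mean(top3), 0.9)

  const <- volcano_table(
    tibble::tibble(sample_id = sprintf("m%d", 1:6),
                   flat = rep(2, 6), varies = c(1, 2, 3, 7, 8, 9)),
    rep(c("A", "B"), each = 3))
  expect_equal(const$log2_fr[const$metabolite == "flat"], 0)
  expect_equal(const$p_value[const$metabolite == "flat"], 1)
})

test_that("vip_table combines VIP, fold ratio and Mann-Whitney p", {
  sim <- simulate_cohort_study(
    simulation_params(n_per_cohort = 10, n_species = 20, cohort_shift = 2),
    seed = 31)
  st <- sim$study
  rel <- to_relative_abundance(st$abundance)
  norm <- gaussianize(rel)
  g <- cohort_labels(st)
  fit <- plsda_fit(norm, g, n_components = 2)
  vt <- vip_table(fit, rel, g)
  expect_setequal(vt$feature, fit$features)
  expect_false(is.unsorted(rev(vt$vip)))
  expect_true(all(vt$fr >= 1 | vt$fr_infinite))
  expect_true(all(vt$p_value > 0 & vt$p_value <= 1))
})
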