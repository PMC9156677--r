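#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis by NIPALS: the two classes
#' are encoded as a single centered +/-1 response, and components are
#' extracted iteratively — weight \eqn{w_a \propto X'y} normalized to unit
#' length, scores \eqn{t_a = X w_a}, x-loadings
#' \eqn{p_a = X't_a / t_a't_a}, y-loading \eqn{q_a = y't_a / t_a't_a},
#' then deflation \eqn{X \leftarrow X - t_a p_a'}. Successive score
#' vectors are mutually orthogonal. The fit is deterministic.
#'
#' Constant (after centering) features are dropped with a warning; a
#' component request above the data rank is capped with a warning.
#'
#' @param x samples-by-features data frame (with `sample_id`) or matrix;
#'   typically the output of [gaussianize()].
#' @param y class labels, exactly 2 levels.
#' @param n_components number of latent variables to extract.
#' @return object of class `sig_plsda`: weights `W`, scores `T`,
#'   x-loadings `P`, y-loadings `q` (per component), `vip` vector,
#'   centering info and class encoding.
#' @export
plsda_fit <- function(x, y, n_components = 2) {
  m <- as_feature_matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) abort("PLS-DA fitting supports exactly 2 classes.")
  if (length(y) != nrow(m)) abort("`y` must supply one label per sample.")

  keep <- apply(m, 2, function(v) max(v) - min(v) > 0)
  if (!all(keep)) {
    warn(paste0("Dropping constant feature(s): ",
                toString(head(colnames(m)[!keep], 5))))
    m <- m[, keep, drop = FALSE]
  }
  x_center <- colMeans(m)
  X <- sweep(m, 2, x_center)
  y_num <- ifelse(y == levels(y)[2], 1, -1)
  y_center <- mean(y_num)
  yc <- y_num - y_center

  a_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components > a_max) {
    warn(sprintf("n_components capped at rank bound %d.", a_max))
    n_components <- a_max
  }

  p_feat <- ncol(X)
  W <- P <- matrix(0, p_feat, 0)
  Tm <- matrix(0, nrow(X), 0)
  q <- numeric(0)
  Xa <- X
  ya <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # nothing left to extract
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W <- cbind(W, w)
    Tm <- cbind(Tm, t_a)
    P <- cbind(P, p_a)
    q <- c(q, q_a)
  }
  if (ncol(W) == 0) abort("No PLS component could be extracted.")
  dimnames(W) <- dimnames(P) <- list(colnames(X),
                                     paste0("LV", seq_len(ncol(W))))
  colnames(Tm) <- paste0("LV", seq_len(ncol(Tm)))
  rownames(Tm) <- rownames(X)

  model <- structure(
    list(W = W, T = Tm, P = P, q = q, n_components = ncol(W),
         x_center = x_center, y_center = y_center, levels = levels(y),
         y = y, features = colnames(X)),
    class = "sig_plsda"
  )
  model$vip <- vip_scores(model)
  model
}

#' @export
print.sig_plsda <- function(x, ...) {
  cat("<sig_plsda> ", x$n_components, " component(s), ",
      length(x$features), " features, classes ",
      paste(x$levels, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}} with
#' \eqn{SSY_a = q_a^2\, t_a' t_a} the response variance captured by
#' component \eqn{a} and \eqn{p} the feature count, so
#' \eqn{\sum_j VIP_j^2 = p} and VIP values above 1 flag features that
#' contribute more than an average share to the discrimination.
#'
#' @param model a fitted [plsda_fit()] model.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "sig_plsda"))
  ssy <- model$q^2 * colSums(model$T^2)
  if (sum(ssy) <= 0) abort("VIP undefined: model explains no response variance.")
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")  # ||w_a|| = 1 already
  p <- nrow(model$W)
  setNames(sqrt(p * as.vector(w2 %*% ssy) / sum(ssy)), rownames(model$W))
}

#' Project new samples into PLS score space and classify
#'
#' Scores for new data use the model rotation
#' \eqn{T_{new} = (X_{new} - \bar x) W (P'W)^{-1}}; each sample is assigned
#' the class whose training-score centroid is nearest (Euclidean, using
#' `n_components` axes).
#'
#' @param object a `sig_plsda` model.
#' @param newdata data frame or matrix with the model's features.
#' @param n_components number of components to use (default: all fitted).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.sig_plsda <- function(object, newdata, n_components = NULL, ...) {
  a <- n_components %||% object$n_components
  a <- min(a, object$n_components)
  m <- as_feature_matrix(newdata)[, object$features, drop = FALSE]
  R <- object$W %*% solve(crossprod(object$P, object$W))
  scores <- sweep(m, 2, object$x_center) %*% R[, seq_len(a), drop = FALSE]
  centroids <- vapply(object$levels, function(lv) {
    colMeans(object$T[object$y == lv, seq_len(a), drop = FALSE])
  }, numeric(a))
  centroids <- matrix(centroids, nrow = a)  # a x 2
  d2 <- vapply(1:2, function(k) {
    rowSums(sweep(scores, 2, centroids[, k])^2)
  }, numeric(nrow(scores)))
  d2 <- matrix(d2, ncol = 2)
  factor(object$levels[max.col(-d2, ties.method = "first")],
         levels = object$levels)
}

#' Double cross-validated PLS-DA classification
#'
#' Nested resampling estimate of how reliably PLS-DA separates the
#' cohorts: an outer stratified K-fold loop holds out test samples; on
#' each outer training split an inner K-fold loop picks the component
#' count (1..`max_components`) with the smallest classification error;
#' the outer test samples are then classified by nearest class centroid in
#' score space. The whole procedure is repeated with reshuffled folds and
#' per-class correct-classification rates are aggregated as mean and
#' standard deviation over repeats (in percent).
#'
#' @param x samples-by-features data frame or matrix (already normalized).
#' @param y class labels (2 levels); at least 4 samples per class.
#' @param outer_folds,inner_folds fold counts (default 5 and 5; reduced
#'   with a warning when a class is too small).
#' @param max_components largest component count the inner loop may select.
#' @param repeats number of repetitions with reshuffled folds (default 50).
#' @param seed integer seed for the fold shuffling.
#' @return object of class `sig_double_cv`: tibble `rates` (class,
#'   mean_rate, sd_rate in %), `chosen_components` counts, `repeats`.
#' @export
double_cv_classify <- function(x, y, outer_folds = 5, inner_folds = 5,
                               max_components = 5, repeats = 50,
                               seed = NULL) {
  m <- as_feature_matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) abort("Two classes required.")
  n_class <- table(y)
  if (any(n_class < 4)) abort("Need at least 4 samples per class.")
  if (outer_folds > min(n_class)) {
    warn(sprintf("outer_folds reduced to %d (smallest class).", min(n_class)))
    outer_folds <- min(n_class)
  }

  local_seed(seed, {
    per_repeat <- matrix(NA_real_, repeats, 2,
                         dimnames = list(NULL, levels(y)))
    chosen <- integer(0)
    for (r in seq_len(repeats)) {
      folds <- stratified_folds(y, outer_folds)
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (k in seq_len(outer_folds)) {
        test_idx <- which(folds == k)
        train_idx <- setdiff(seq_along(y), test_idx)
        a_best <- inner_select(m[train_idx, , drop = FALSE], y[train_idx],
                               inner_folds, max_components)
        chosen <- c(chosen, a_best)
        fit <- suppressWarnings(
          plsda_fit(m[train_idx, , drop = FALSE], y[train_idx], a_best))
        pred[test_idx] <- predict(fit, m[test_idx, , drop = FALSE])
      }
      for (lv in levels(y)) {
        idx <- y == lv
        per_repeat[r, lv] <- 100 * mean(pred[idx] == lv)
      }
    }
    structure(
      list(
        rates = tibble::tibble(
          class = levels(y),
          mean_rate = colMeans(per_repeat),
          sd_rate = apply(per_repeat, 2, sd)
        ),
        per_repeat = per_repeat,
        chosen_components = table(chosen),
        repeats = repeats
      ),
      class = "sig_double_cv"
    )
  })
}

#' @export
print.sig_double_cv <- function(x, ...) {
  cat("<sig_double_cv> per-class correct classification over ",
      x$repeats, " repeats:\n", sep = "")
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf("  %s: %.1f +/- %.1f %%\n", x$rates$class[i],
                x$rates$mean_rate[i], x$rates$sd_rate[i]))
  }
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

inner_select <- function(x, y, inner_folds, max_components) {
  k <- min(inner_folds, min(table(y)))
  a_max <- min(max_components, nrow(x) - ceiling(nrow(x) / k) - 1, ncol(x))
  a_max <- max(a_max, 1)
  folds <- stratified_folds(y, k)
  err <- numeric(a_max)
  for (fk in seq_len(k)) {
    te <- which(folds == fk)
    tr <- setdiff(seq_along(y), te)
    if (length(unique(y[tr])) < 2) next
    fit <- suppressWarnings(plsda_fit(x[tr, , drop = FALSE], y[tr], a_max))
    for (a in seq_len(min(a_max, fit$n_components))) {
      pr <- predict(fit, x[te, , drop = FALSE], n_components = a)
      err[a] <- err[a] + sum(pr != y[te])
    }
  }
  which.min(err)
}

#' Nonparametric group difference test
#'
#' Mann-Whitney U for two groups — exact two-sided when the pooled sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction — or Kruskal-Wallis
#' (chi-square approximation with tie correction) for two or more groups.
#'
#' @param values numeric vector of per-sample measurements.
#' @param groups group labels, one per value.
#' @param method `"mann-whitney"` or `"kruskal-wallis"`.
#' @return a `sig_test`.
#' @export
group_difference_test <- function(values, groups,
                                  method = c("mann-whitney",
                                             "kruskal-wallis")) {
  method <- match.arg(method)
  g <- factor(as.character(groups))
  if (any(table(g) < 1) || nlevels(g) < 2) {
    abort("Every group needs at least one observation.")
  }
  if (method == "mann-whitney") {
    if (nlevels(g) != 2) abort("Mann-Whitney requires exactly 2 groups.")
    x1 <- values[g == levels(g)[1]]
    x2 <- values[g == levels(g)[2]]
    ties <- anyDuplicated(values) > 0
    exact <- (length(values) <= 20) && !ties
    ht <- suppressWarnings(
      wilcox.test(x1, x2, exact = exact, correct = TRUE,
                  alternative = "two.sided"))
    sig_test("Mann-Whitney U", unname(ht$statistic), ht$p.value,
             extras = list(exact = exact,
                           group_n = as.list(table(g))))
  } else {
    ht <- kruskal.test(values, g)
    sig_test("Kruskal-Wallis", unname(ht$statistic), ht$p.value,
             extras = list(df = unname(ht$parameter),
                           group_n = as.list(table(g))))
  }
}

#' Fold ratio between two group means
#'
#' FR = larger group mean / smaller group mean (so FR >= 1), with the label
#' of the higher group. When the lower mean is zero the ratio is reported
#' as infinite with `fr_infinite = TRUE`. `fold_ratio_directional()` gives
#' the signed version numerator/denominator for a chosen cohort order.
#'
#' @param values numeric per-sample measurements.
#' @param groups two-level group labels.
#' @return tibble with `fr`, `higher_cohort`, `fr_infinite` and the two
#'   group means.
#' @examples
#' fold_ratio(c(117.15, 86.80), c("EE", "SE"))  # 1.35-fold, higher in EE
#' @export
fold_ratio <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) != 2) abort("fold_ratio requires exactly 2 groups.")
  mns <- tapply(values, g, mean)
  hi <- names(mns)[which.max(mns)]
  lo <- names(mns)[which.min(mns)]
  if (mns[hi] == mns[lo]) { hi <- names(mns)[1]; lo <- names(mns)[2] }
  inf <- mns[lo] == 0
  tibble::tibble(
    fr = if (inf) Inf else unname(mns[hi] / mns[lo]),
    higher_cohort = hi,
    fr_infinite = inf,
    mean_higher = unname(mns[hi]),
    mean_lower = unname(mns[lo])
  )
}

#' @rdname fold_ratio
#' @param numerator,denominator cohort labels fixing the direction.
#' @export
fold_ratio_directional <- function(values, groups, numerator, denominator) {
  g <- as.character(groups)
  m_num <- mean(values[g == numerator])
  m_den <- mean(values[g == denominator])
  if (!is.finite(m_num) || !is.finite(m_den)) {
    abort("Both cohorts must be present.")
  }
  m_num / m_den
}

#' Per-feature VIP table with fold ratios and Mann-Whitney p
#'
#' The discriminant summary behind a VIP plot: for every feature the VIP
#' score of a fitted PLS-DA model, the fold ratio of the raw group means
#' (oriented so FR >= 1), the cohort with the higher mean and the
#' two-sided Mann-Whitney p-value (unadjusted, as is conventional for a
#' fixed-size VIP panel).
#'
#' @param model a fitted `sig_plsda`.
#' @param raw data frame or matrix of the untransformed per-sample values
#'   used for fold ratios (same samples, same features).
#' @param groups two-level labels.
#' @return tibble sorted by decreasing VIP: `feature`, `vip`, `fr`,
#'   `fr_infinite`, `higher_cohort`, `p_value`.
#' @export
vip_table <- function(model, raw, groups) {
  stopifnot(inherits(model, "sig_plsda"))
  m <- as_feature_matrix(raw)
  purrr::map_dfr(model$features, function(f) {
    ratio <- fold_ratio(m[, f], groups)
    tibble::tibble(
      feature = f,
      vip = unname(model$vip[f]),
      fr = ratio$fr,
      fr_infinite = ratio$fr_infinite,
      higher_cohort = ratio$higher_cohort,
      p_value = group_difference_test(m[, f], groups)$p_value
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' Volcano table for two-cohort metabolite changes
#'
#' Per metabolite: signed log2 fold ratio of group means
#' (`numerator`/`denominator`) and the two-sided Mann-Whitney p-value with
#' its -log10. Metabolites constant across both groups get p = 1 and
#' log2 FR = 0. Rows are sorted by increasing p.
#'
#' @param metabolites data frame with `sample_id` plus metabolite columns,
#'   or a matrix.
#' @param groups two-level cohort labels.
#' @param numerator,denominator cohort labels fixing the fold direction
#'   (defaults: second and first factor level).
#' @return tibble `metabolite`, `log2_fr`, `p_value`, `neg_log10_p`.
#' @export
volcano_table <- function(metabolites, groups, numerator = NULL,
                          denominator = NULL) {
  m <- as_feature_matrix(metabolites)
  g <- factor(as.character(groups))
  if (nlevels(g) != 2) abort("Volcano table requires exactly 2 cohorts.")
  numerator <- numerator %||% levels(g)[2]
  denominator <- denominator %||% levels(g)[1]
  purrr::map_dfr(colnames(m), function(f) {
    v <- m[, f]
    if (max(v) == min(v)) {
      return(tibble::tibble(metabolite = f, log2_fr = 0, p_value = 1))
    }
    tibble::tibble(
      metabolite = f,
      log2_fr = log2(fold_ratio_directional(v, g, numerator, denominator)),
      p_value = group_difference_test(v, g)$p_value
    )
  }) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p_value)) |>
    dplyr::arrange(.data$p_value)
}
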