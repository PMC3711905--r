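# LOO-CV harness with fold-local preprocessing, balanced multi-class
# metrics, chance levels, Monte Carlo permutation testing and small
# cohort-summary statistics.

# Per-fold centered kernels. These depend on the features only (never on
# labels), so permutation tests precompute them once and reuse them across
# label permutations; this is exactly equivalent to re-running the
# embedded-preprocessing LOO loop per permutation.
.loo_fold_kernels <- function(X, center = TRUE, scale = FALSE,
                              normalize = TRUE) {
  n <- nrow(X)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- seq_len(n)[-i]
    Xtr <- X[tr, , drop = FALSE]
    xte <- X[i, ]
    if (center) {
      mu <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2, mu, "-")
      xte <- xte - mu
    }
    if (scale) {
      sd_ <- apply(Xtr, 2, stats::sd)
      sd_[!is.finite(sd_) | sd_ == 0] <- 1
      Xtr <- sweep(Xtr, 2, sd_, "/")
      xte <- xte / sd_
    }
    K <- tcrossprod(Xtr)
    s0 <- if (normalize) mean(diag(K)) else 1
    if (s0 <= 0) s0 <- 1
    folds[[i]] <- list(K = K / s0,
                       kx = matrix(Xtr %*% xte, nrow = 1) / s0,
                       kd = sum(xte^2) / s0,
                       train_idx = tr)
  }
  folds
}

.loo_from_kernels <- function(folds, labels, config) {
  n <- length(folds)
  labels <- droplevels(as.factor(labels))
  class_names <- levels(labels)
  m <- length(class_names)
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("class ", paste(names(cnt)[cnt < 2], collapse = ", "),
         " has fewer than 2 members; its only fold would leave it untrained")
  probs <- matrix(NA_real_, n, m, dimnames = list(NULL, class_names))
  for (i in seq_len(n)) {
    fd <- folds[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    post <- fit_mnp(fd$K, labels[fd$train_idx], cfg, validate = FALSE)
    pred <- predict_mnp(post, fd$kx, fd$kd)
    probs[i, ] <- pred$probabilities[1, ]
  }
  predicted <- assign_class(probs)
  cm <- confusion_matrix(labels, predicted, class_names)
  structure(list(probabilities = probs,
                 predicted = predicted,
                 true = labels,
                 confusion = cm,
                 metrics = compute_metrics(cm),
                 class_names = class_names,
                 config = config,
                 n_folds = n),
            class = "cv_result")
}

#' Leave-one-out cross-validation of the kernel classifier
#'
#' For each subject in turn: the fold preprocessor (training-mean centering,
#' optionally scaling) is fitted on the remaining subjects only, both
#' partitions are transformed, linear kernels are built on the training
#' normalisation, the multinomial probit classifier is fitted, and the
#' held-out subject's class probabilities are predicted. Per-fold sampler
#' seeds are derived from \code{config$seed} so the whole run is
#' reproducible.
#'
#' @param features a \code{feature_matrix}.
#' @param labels class labels, one per subject; every class needs at least 2
#'   members.
#' @param config an [mnp_config()].
#' @param center,scale fold-local preprocessing switches.
#' @param normalize_kernel divide each fold's kernel by its mean training
#'   self-similarity.
#' @return a \code{cv_result}: per-subject predicted probabilities and hard
#'   labels, assembled \code{confusion_matrix}, \code{metrics} and the
#'   configuration snapshot.
#' @export
loo_cross_validate <- function(features, labels, config = mnp_config(),
                               center = TRUE, scale = FALSE,
                               normalize_kernel = TRUE) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (any(!is.finite(X))) stop("features contain non-finite values")
  if (nrow(X) != length(labels)) stop("labels length must match subjects")
  folds <- .loo_fold_kernels(X, center = center, scale = scale,
                             normalize = normalize_kernel)
  .loo_from_kernels(folds, labels, config)
}

#' Confusion matrix with rows = true class, columns = predicted class
#'
#' @param true_labels,predicted_labels vectors of labels drawn from
#'   \code{class_names}.
#' @param class_names ordered class names fixing row/column order.
#' @return a \code{confusion_matrix} (integer matrix with dimnames).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_names) {
  if (length(true_labels) == 0) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  tf <- factor(as.character(true_labels), levels = class_names)
  pf <- factor(as.character(predicted_labels), levels = class_names)
  if (anyNA(tf) || anyNA(pf)) {
    bad <- unique(c(as.character(true_labels)[is.na(tf)],
                    as.character(predicted_labels)[is.na(pf)]))
    stop("unknown label: ", paste(bad, collapse = ", "))
  }
  C <- unclass(table(tf, pf))
  dimnames(C) <- list(true = class_names, predicted = class_names)
  structure(C, class = c("confusion_matrix", class(C)))
}

#' Balanced multi-class metrics from a confusion matrix
#'
#' Sensitivity of class i is its diagonal count over its row sum; predictive
#' value is the diagonal count over its column sum, defined as 0 with a
#' warning when the class is never predicted. Balanced accuracy and overall
#' predictive value (OPV) are the unweighted means of the per-class
#' sensitivities and predictive values, which makes them robust to unequal
#' class sizes.
#'
#' @param cm a \code{confusion_matrix}.
#' @return a \code{metrics_report} list: \code{sensitivity},
#'   \code{predictive_value} (named per class), \code{balanced_accuracy},
#'   \code{overall_predictive_value}, \code{chance_accuracy} (1/m) and
#'   \code{per_class_chance} (true-class proportions).
#' @export
compute_metrics <- function(cm) {
  C <- unclass(as.matrix(cm))
  if (sum(C) == 0) stop("confusion matrix has no predictions")
  m <- nrow(C)
  rs <- rowSums(C)
  cs <- colSums(C)
  sens <- ifelse(rs > 0, diag(C) / rs, NA_real_)
  pv <- numeric(m)
  never <- cs == 0
  if (any(never))
    warning("class never predicted, predictive value set to 0: ",
            paste(rownames(C)[never], collapse = ", "))
  pv[!never] <- diag(C)[!never] / cs[!never]
  names(sens) <- names(pv) <- rownames(C)
  structure(list(sensitivity = sens,
                 predictive_value = pv,
                 balanced_accuracy = mean(sens),
                 overall_predictive_value = mean(pv),
                 chance_accuracy = 1 / m,
                 per_class_chance = rs / sum(C)),
            class = "metrics_report")
}

#' Chance levels for a classifier
#'
#' The aggregate chance accuracy of uninformed guessing is 1/m (33%, 25%,
#' 20% for the three-, four- and five-class contrasts); the per-class chance
#' levels are the training-set class proportions, as used for per-class
#' sensitivity/predictive-value bars.
#'
#' @param training_labels training class labels.
#' @param m number of classes.
#' @return list with \code{chance_accuracy} and \code{per_class_chance}.
#' @export
chance_levels <- function(training_labels, m) {
  stopifnot(m >= 2)
  tab <- table(training_labels)
  list(chance_accuracy = 1 / m,
       per_class_chance = setNames(as.numeric(tab) / sum(tab), names(tab)))
}

#' Monte Carlo permutation test of a cross-validated metric
#'
#' Reruns the full LOO pipeline (fold-local preprocessing included) under
#' \code{n_perm} random label permutations and compares the observed metric
#' against the permutation distribution with the add-one estimator
#' p = (1 + #\{permuted >= observed\}) / (1 + n_perm).
#'
#' @param features a \code{feature_matrix}.
#' @param labels true class labels.
#' @param metric function mapping a \code{cv_result} to a scalar; default
#'   extracts the balanced accuracy.
#' @param n_perm number of label permutations.
#' @param seed seed for the permutation sequence.
#' @param config classifier configuration shared by all runs.
#' @param center,scale,normalize_kernel as in [loo_cross_validate()].
#' @return a \code{permutation_result}: \code{observed}, \code{permuted}
#'   (length \code{n_perm}), \code{p}, \code{n_perm}, \code{seed}.
#' @export
permutation_test <- function(features, labels, metric = NULL, n_perm = 999,
                             seed = 1L, config = mnp_config(),
                             center = TRUE, scale = FALSE,
                             normalize_kernel = TRUE) {
  stopifnot(n_perm >= 1)
  if (is.null(metric)) metric <- function(cv) cv$metrics$balanced_accuracy
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  folds <- .loo_fold_kernels(X, center = center, scale = scale,
                             normalize = normalize_kernel)
  observed <- metric(.loo_from_kernels(folds, labels, config))
  permuted <- numeric(n_perm)
  set.seed(derive_seed(seed, 0L))
  perms <- replicate(n_perm, sample(length(labels)))
  for (b in seq_len(n_perm)) {
    permuted[b] <- tryCatch(
      suppressWarnings(
        metric(.loo_from_kernels(folds, labels[perms[, b]], config))),
      error = function(e)
        stop("metric extractor failed on permutation ", b, ": ",
             conditionMessage(e)))
  }
  structure(list(observed = observed, permuted = permuted,
                 p = (1 + sum(permuted >= observed)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' Monte Carlo posterior interval for the balanced accuracy
#'
#' Per class i the accuracy is given an independent Beta(C_ii + 1,
#' n_i - C_ii + 1) posterior (uniform prior); draws are averaged over
#' classes and the central interval of the resulting balanced accuracy is
#' reported. This is a multi-class balanced generalisation of the familiar
#' Beta interval for a single accuracy and is reported descriptively, not
#' validated against any published interval construction.
#'
#' @param cm a \code{confusion_matrix}.
#' @param level central coverage (default 0.95).
#' @param n_draws Monte Carlo draws.
#' @param seed integer seed.
#' @return list with \code{lower}, \code{upper}, \code{point} (the plug-in
#'   balanced accuracy), \code{level}.
#' @export
balanced_accuracy_interval <- function(cm, level = 0.95, n_draws = 10000,
                                       seed = 1L) {
  C <- unclass(as.matrix(cm))
  rs <- rowSums(C)
  keep <- rs > 0
  set.seed(seed)
  draws <- sapply(which(keep), function(i)
    rbeta(n_draws, C[i, i] + 1, rs[i] - C[i, i] + 1))
  ba <- rowMeans(draws)
  qs <- quantile(ba, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(lower = qs[1], upper = qs[2],
       point = mean(diag(C)[keep] / rs[keep]), level = level)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Classic (uncorrected) Pearson statistic with (r-1)(c-1) degrees of
#' freedom, as used for cohort demographic contingency tables such as
#' sex-by-diagnosis counts.
#'
#' @param tab numeric r x c matrix of nonnegative counts with positive row
#'   and column margins.
#' @return list with \code{statistic}, \code{dof}, \code{p}.
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic),
       dof = unname(res$parameter),
       p = res$p.value)
}

#' Significance marker used in report output
#'
#' @param p p-value.
#' @return "*" for p < 0.01, "#" for p < 0.05, "+" for p < 0.1, "" else.
#' @export
significance_marker <- function(p) {
  if (p < 0.01) "*" else if (p < 0.05) "#" else if (p < 0.1) "+" else ""
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y)
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Leave-one-out cross-validation:", x$n_folds, "folds,",
      length(x$class_names), "classes\n")
  print(x$confusion)
  mt <- x$metrics
  cat(sprintf("balanced accuracy %.1f%% (chance %.1f%%), OPV %.1f%%\n",
              100 * mt$balanced_accuracy, 100 * mt$chance_accuracy,
              100 * mt$overall_predictive_value))
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- data.frame(sensitivity = x$sensitivity,
                   predictive_value = x$predictive_value,
                   chance = x$per_class_chance)
  print(round(df, 3))
  cat(sprintf("balanced accuracy: %.3f  OPV: %.3f  chance: %.3f\n",
              x$balanced_accuracy, x$overall_predictive_value,
              x$chance_accuracy))
  invisible(x)
}
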