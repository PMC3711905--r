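#' Configuration for the multinomial probit kernel classifier
#'
#' The classifier places independent Gaussian-process-style priors on one
#' latent function per class over the training kernel, with the observed
#' class being the argmax of the latent values plus standard normal noise.
#' Inference is auxiliary-variable Gibbs sampling; predictions average the
#' probit argmax probability over post-burn-in draws.
#'
#' @param n_samples number of post-burn-in latent draws.
#' @param n_burnin number of discarded warm-up sweeps.
#' @param seed integer seed controlling the full draw sequence.
#' @param kernel_jitter diagonal jitter added to the kernel; default
#'   \code{1e-6} times the mean kernel diagonal.
#' @param latent_prior_scale positive multiplier of the (jittered) kernel
#'   used as the latent prior covariance; fixed, not sampled.
#' @return an \code{mnp_config} list.
#' @export
mnp_config <- function(n_samples = 2000, n_burnin = 500, seed = 1L,
                       kernel_jitter = NULL, latent_prior_scale = 1) {
  stopifnot(n_samples >= 1, n_burnin >= 0, latent_prior_scale > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin),
                 seed = as.integer(seed),
                 kernel_jitter = kernel_jitter,
                 latent_prior_scale = latent_prior_scale),
            class = "mnp_config")
}

.gh_cache <- new.env(parent = emptyenv())

# Gauss-Hermite nodes rescaled for expectations under N(0, 1), cached since
# prediction is called once per cross-validation fold.
.gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    .gh_cache[[key]] <- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .gh_cache[[key]]
}

#' Fit the multinomial probit classifier on a training kernel
#'
#' Alternates (a) truncated-normal draws of auxiliary variables consistent
#' with each training label being the argmax of its latent values plus
#' standard normal noise, and (b) draws of each class's latent function from
#' its Gaussian conditional, whose prior covariance is
#' \code{latent_prior_scale * (K + jitter * I)}.
#'
#' @param K training \code{kernel_matrix} (or square numeric matrix),
#'   symmetric positive semi-definite.
#' @param labels factor of training class labels; every factor level must be
#'   present.
#' @param config an [mnp_config()].
#' @param validate check kernel symmetry/PSD (can be disabled inside tight
#'   resampling loops after validating once).
#' @return an \code{mnp_posterior}: latent draws (n x m x n_samples),
#'   training labels, class names, the jittered-kernel inverse used for
#'   prediction, and kernel metadata.
#' @export
fit_mnp <- function(K, labels, config = mnp_config(), validate = TRUE) {
  kernel_scale <- 1
  kernel_type <- "linear"
  if (inherits(K, "kernel_matrix")) {
    kernel_scale <- K$scale
    kernel_type <- K$kernel_type
    K <- K$values
  }
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("training kernel must be square")
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length must match the kernel")
  class_names <- levels(labels)
  m <- length(class_names)
  if (m < 2) stop("need at least two classes")
  cnt <- table(labels)
  if (any(cnt == 0))
    stop("class absent from training labels: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))

  jitter <- config$kernel_jitter
  if (is.null(jitter)) jitter <- 1e-6 * mean(diag(K))
  if (jitter <= 0) stop("kernel_jitter must be positive")
  Kj <- (K + t(K)) / 2 + diag(jitter, n)
  if (validate && !is_psd(Kj))
    stop("kernel is not positive semi-definite after jitter")

  s <- config$latent_prior_scale
  C <- s * Kj
  # posterior operator for f | g: mean P g, covariance C - P C
  P <- C %*% solve(C + diag(n))
  Sigma <- C - P %*% C
  Sigma <- (Sigma + t(Sigma)) / 2 + diag(1e-10 * mean(diag(C)) + 1e-300, n)
  L <- t(chol(Sigma))

  set.seed(config$seed)
  draws <- mnp_gibbs_cpp(P, L, as.integer(labels) - 1L, m,
                         config$n_samples, config$n_burnin)
  structure(list(draws = draws,
                 training_labels = labels,
                 class_names = class_names,
                 A = solve(Kj),
                 jitter = jitter,
                 latent_prior_scale = s,
                 kernel_scale = kernel_scale,
                 kernel_type = kernel_type,
                 config = config),
            class = "mnp_posterior")
}

#' Predictive class probabilities for test subjects
#'
#' For each posterior draw the test latents' conditional Gaussian is
#' combined analytically with the probit noise: conditional on a draw, the
#' effective test score for class c is normal with the conditional mean and
#' variance \code{1 + v}, and the probability that class c attains the
#' argmax is evaluated by Gauss-Hermite quadrature. Probabilities are
#' averaged over draws; rows are normalised to sum to one.
#'
#' @param post an \code{mnp_posterior}.
#' @param K_cross test-by-train \code{kernel_matrix} (or matrix) on the same
#'   scale as the training kernel.
#' @param k_test_diag self-similarity of each test subject on the training
#'   kernel scale (see [kernel_self_diag()]).
#' @param gh_nodes number of Gauss-Hermite nodes.
#' @return an \code{mnp_prediction} with a \code{probabilities} matrix
#'   (test subjects x classes, rows summing to 1).
#' @export
predict_mnp <- function(post, K_cross, k_test_diag, gh_nodes = 20) {
  Kx <- if (inherits(K_cross, "kernel_matrix")) K_cross$values else
    as.matrix(K_cross)
  n <- nrow(post$A)
  if (ncol(Kx) != n) stop("cross-kernel columns must match training subjects")
  nt <- nrow(Kx)
  if (length(k_test_diag) != nt)
    stop("k_test_diag length must match test subjects")
  m <- length(post$class_names)
  S <- dim(post$draws)[3]

  B <- Kx %*% post$A
  v <- post$latent_prior_scale *
    pmax(k_test_diag + post$jitter - rowSums(B * Kx), 0)
  # conditional means for every draw at once: draws is n x m x S
  Fmat <- matrix(post$draws, n, m * S)
  Mall <- B %*% Fmat                      # nt x (m*S), class fastest
  gh <- .gh_nodes(gh_nodes)
  z <- gh$z
  w <- gh$w

  probs <- matrix(NA_real_, nt, m, dimnames = list(NULL, post$class_names))
  for (t in seq_len(nt)) {
    M <- t(matrix(Mall[t, ], m, S))       # S x m
    sdv <- sqrt(1 + v[t])
    p <- numeric(m)
    for (cc in seq_len(m)) {
      Tj <- outer(M[, cc], sdv * z, "+")  # S x nodes
      pr <- 1
      for (oc in seq_len(m)) {
        if (oc == cc) next
        pr <- pr * pnorm((Tj - M[, oc]) / sdv)
      }
      p[cc] <- sum((t(pr) %*% rep(1 / S, S)) * w)
    }
    probs[t, ] <- p / sum(p)
  }
  structure(list(probabilities = probs, class_names = post$class_names),
            class = "mnp_prediction")
}

#' Hard class assignment from predictive probabilities
#'
#' Argmax per row; exact ties are broken toward the lowest class index with
#' a warning listing the tied rows.
#'
#' @param pred an \code{mnp_prediction} or a probability matrix.
#' @return factor of predicted class labels.
#' @export
assign_class <- function(pred) {
  probs <- if (inherits(pred, "mnp_prediction")) pred$probabilities else
    as.matrix(pred)
  cls <- colnames(probs)
  if (is.null(cls)) cls <- as.character(seq_len(ncol(probs)))
  idx <- integer(nrow(probs))
  ties <- integer(0)
  for (i in seq_len(nrow(probs))) {
    mx <- which(probs[i, ] == max(probs[i, ]))
    if (length(mx) > 1) ties <- c(ties, i)
    idx[i] <- mx[1]
  }
  if (length(ties))
    warning("tie broken toward the lowest class index for row(s) ",
            paste(ties, collapse = ", "))
  factor(cls[idx], levels = cls)
}
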