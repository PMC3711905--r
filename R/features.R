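#' Extract a masked two-channel feature matrix from a cohort
#'
#' Vectorises each subject's two tissue channels over the voxels of the
#' requested mask and concatenates them, giving one row per subject with
#' channel-1 (grey) voxels first and channel-2 (white) voxels second, each
#' block in ascending voxel linear-index order. This is exactly the input
#' the kernel classifier consumes.
#'
#' @param images list of \code{subject_image}s sharing the atlas grid.
#' @param atlas a \code{region_atlas}.
#' @param mask_name \code{"whole_brain"}, \code{"subcortical_network"} or
#'   \code{"region:<name>"}.
#' @return a \code{feature_matrix}: list with \code{values} (subjects x
#'   2*voxels), \code{subject_ids}, \code{feature_index} (data frame of
#'   \code{channel}, \code{voxel} linear index per column) and
#'   \code{mask_name}.
#' @export
extract_features <- function(images, atlas, mask_name) {
  mask <- atlas_mask(atlas, mask_name)
  vox <- which(mask)  # ascending linear indices
  n <- length(images)
  p <- length(vox)
  values <- matrix(NA_real_, n, 2L * p)
  ids <- character(n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    ch <- img$channels
    if (!identical(dim(ch[[1]]), dim(mask)) ||
        !identical(dim(ch[[2]]), dim(mask)))
      stop("image '", img$subject_id, "' does not match the atlas grid")
    values[i, ] <- c(ch[[1]][vox], ch[[2]][vox])
    ids[i] <- img$subject_id
  }
  if (any(!is.finite(values))) stop("non-finite feature values")
  rownames(values) <- ids
  structure(list(values = values,
                 subject_ids = ids,
                 feature_index = data.frame(
                   channel = rep(1:2, each = p),
                   voxel = rep(vox, 2L)),
                 mask_name = mask_name),
            class = "feature_matrix")
}

#' Build a feature matrix directly from a values matrix
#'
#' Convenience constructor used when features do not originate from images
#' (e.g. small simulated designs); the feature index is synthetic.
#'
#' @param values numeric subjects-by-features matrix.
#' @param subject_ids optional ids (default row numbers).
#' @param mask_name label carried through to kernels and reports.
#' @return a \code{feature_matrix}.
#' @export
as_feature_matrix <- function(values, subject_ids = NULL,
                              mask_name = "custom") {
  values <- as.matrix(values)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%03d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(list(values = values, subject_ids = subject_ids,
                 feature_index = data.frame(channel = 1L,
                                            voxel = seq_len(ncol(values))),
                 mask_name = mask_name),
            class = "feature_matrix")
}

#' Fit a fold-local preprocessor on training rows only
#'
#' Per-feature centering (and optional unit-variance scaling) whose
#' statistics are estimated from the training subset alone, preserving the
#' contract that no statistic crosses the train/test boundary inside the
#' cross-validation loop.
#'
#' @param train a \code{feature_matrix} of training subjects.
#' @param scale if TRUE also divide by the training SD (features with zero
#'   training SD are left unscaled).
#' @return a \code{fold_preprocessor}.
#' @export
fit_fold_preprocessor <- function(train, scale = FALSE) {
  X <- train$values
  if (nrow(X) < 1) stop("empty training matrix")
  mu <- colMeans(X)
  sd_ <- NULL
  if (scale) {
    sd_ <- apply(X, 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
  }
  structure(list(training_mean = mu, training_scale = sd_),
            class = "fold_preprocessor")
}

#' Apply a fold preprocessor to a feature matrix
#'
#' @param prep a \code{fold_preprocessor}.
#' @param fm a \code{feature_matrix} with matching columns.
#' @return the transformed \code{feature_matrix}.
#' @export
apply_preprocessor <- function(prep, fm) {
  X <- fm$values
  if (ncol(X) != length(prep$training_mean))
    stop("feature dimension mismatch between preprocessor and matrix")
  X <- sweep(X, 2, prep$training_mean, "-")
  if (!is.null(prep$training_scale))
    X <- sweep(X, 2, prep$training_scale, "/")
  fm$values <- X
  fm
}

#' Linear kernel between feature matrices
#'
#' Entry (i, j) is the inner product of row i of \code{A} with row j of
#' \code{B}. With \code{normalize = TRUE} (the default) the kernel is
#' divided by the mean self-similarity of \code{A} (or by an externally
#' supplied \code{scale}, which cross-kernels must reuse from their training
#' kernel so train and test live on the same scale).
#'
#' @param A,B \code{feature_matrix} objects with identical feature indexes
#'   (\code{B} defaults to \code{A}).
#' @param normalize divide by mean self-similarity of \code{A}.
#' @param scale optional externally fixed normalisation constant.
#' @return a \code{kernel_matrix}: list with \code{values}, \code{row_ids},
#'   \code{col_ids}, \code{scale} (the divisor used) and
#'   \code{kernel_type = "linear"}.
#' @export
linear_kernel <- function(A, B = NULL, normalize = TRUE, scale = NULL) {
  symmetric <- is.null(B)
  if (symmetric) B <- A
  if (!isTRUE(all.equal(A$feature_index, B$feature_index)))
    stop("feature_index mismatch between kernel inputs")
  K <- tcrossprod(A$values, B$values)
  if (is.null(scale))
    scale <- if (normalize) mean(rowSums(A$values^2)) else 1
  if (scale <= 0) scale <- 1
  K <- K / scale
  structure(list(values = K, row_ids = A$subject_ids, col_ids = B$subject_ids,
                 scale = scale, kernel_type = "linear",
                 symmetric = symmetric),
            class = "kernel_matrix")
}

#' Self-similarity diagonal on a reference kernel scale
#'
#' @param fm a \code{feature_matrix}.
#' @param scale normalisation constant of the training kernel.
#' @return numeric vector of scaled squared row norms.
#' @export
kernel_self_diag <- function(fm, scale = 1) {
  rowSums(fm$values^2) / scale
}

#' Check positive semi-definiteness of a symmetric kernel
#'
#' @param K \code{kernel_matrix} or numeric matrix.
#' @param tol eigenvalues above \code{-tol * trace} count as nonnegative.
#' @return TRUE/FALSE.
#' @export
is_psd <- function(K, tol = 1e-8) {
  M <- if (inherits(K, "kernel_matrix")) K$values else K
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(sum(diag(M)), .Machine$double.eps)
}
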