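#' Multi-class voxel weight maps from a fitted classifier
#'
#' For a linear kernel the dual representation can be mapped back to voxel
#' space: per class c the weight vector is w_c = X' alpha_c, where alpha_c
#' is the posterior-mean dual coefficient vector obtained by solving the
#' posterior-mean latent values against the jittered training kernel, and X
#' is the (preprocessed) training feature matrix the kernel was built from.
#' Weights are scattered back to their voxel positions per tissue channel,
#' giving one two-channel spatial map of predictive weight per class.
#'
#' @param post an \code{mnp_posterior} fitted on the linear kernel of
#'   \code{train}.
#' @param train the preprocessed training \code{feature_matrix} that the
#'   kernel was computed from.
#' @param atlas the \code{region_atlas} defining the grid.
#' @param mask_name the mask the features were extracted with.
#' @return a \code{weight_map}: per-class list of \code{grey}/\code{white}
#'   3-D volumes (zero outside the mask), plus \code{class_names},
#'   \code{mask_name} and the raw per-class weight vectors.
#' @export
compute_weight_maps <- function(post, train, atlas, mask_name) {
  if (!identical(post$kernel_type, "linear"))
    stop("weight maps are defined only for the linear kernel")
  if (!identical(train$mask_name, mask_name))
    stop("mask_name does not match the feature matrix")
  fbar <- apply(post$draws, c(1, 2), mean)       # posterior-mean latents
  alpha <- post$A %*% fbar                       # dual coefficients per class
  W <- crossprod(train$values, alpha) / post$kernel_scale
  colnames(W) <- post$class_names

  fi <- train$feature_index
  maps <- lapply(post$class_names, function(cn) {
    vols <- lapply(1:2, function(ch) {
      v <- array(0, dim = atlas$grid_dims)
      sel <- fi$channel == ch
      v[fi$voxel[sel]] <- W[sel, cn]
      v
    })
    names(vols) <- c("grey", "white")
    vols
  })
  names(maps) <- post$class_names
  structure(list(maps = maps, weights = W, class_names = post$class_names,
                 mask_name = mask_name, grid_dims = atlas$grid_dims),
            class = "weight_map")
}

#' Export weight maps as NIfTI volumes
#'
#' Writes one atlas-aligned NIfTI file per class per channel, in raw and
#' unit-norm (weights divided by the per-class Euclidean norm) variants,
#' plus a JSON sidecar recording class order, mask and normalisation.
#'
#' @param maps a \code{weight_map}.
#' @param atlas the \code{region_atlas} the maps live on.
#' @param dir output directory.
#' @return (invisibly) the sidecar path.
#' @export
export_weight_maps <- function(maps, atlas, dir) {
  if (!identical(maps$grid_dims, atlas$grid_dims))
    stop("grid mismatch between weight maps and atlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (cn in maps$class_names) {
    nrm <- sqrt(sum(maps$weights[, cn]^2))
    if (nrm == 0) nrm <- 1
    for (ch in c("grey", "white")) {
      safe <- gsub("[^A-Za-z0-9]+", "_", cn)
      f <- sprintf("weights_%s_%s.nii.gz", safe, ch)
      .write_vol(maps$maps[[cn]][[ch]], atlas$affine, file.path(dir, f))
      fu <- sprintf("weights_%s_%s_unitnorm.nii.gz", safe, ch)
      .write_vol(maps$maps[[cn]][[ch]] / nrm, atlas$affine,
                 file.path(dir, fu))
      files[[cn]][[ch]] <- list(raw = f, unit_norm = fu)
    }
  }
  sidecar <- file.path(dir, "weight_maps.json")
  jsonlite::write_json(list(class_names = maps$class_names,
                            mask_name = maps$mask_name,
                            normalization = "raw and per-class unit Euclidean norm",
                            files = files),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read back exported weight-map volumes
#'
#' @param dir directory written by [export_weight_maps()].
#' @param variant \code{"raw"} or \code{"unit_norm"}.
#' @return list per class of \code{grey}/\code{white} arrays.
#' @export
read_weight_maps <- function(dir, variant = "raw") {
  sidecar <- file.path(dir, "weight_maps.json")
  if (!file.exists(sidecar)) stop("missing sidecar '", sidecar, "'")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out <- lapply(meta$class_names, function(cn) {
    vols <- lapply(c("grey", "white"), function(ch) {
      f <- meta$files[[cn]][[ch]][[variant]]
      v <- RNifti::readNifti(file.path(dir, f))
      array(as.numeric(v), dim = dim(v))
    })
    names(vols) <- c("grey", "white")
    vols
  })
  names(out) <- meta$class_names
  out
}
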