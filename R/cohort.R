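#' Default class-by-region atrophy effect matrix
#'
#' Mean regional tissue-loss effects, in units of the per-voxel noise SD,
#' used by the default synthetic cohort. The pattern encodes the qualitative
#' disease structure the pipeline is meant to recover: PSP affects all six
#' network regions (brainstem strongest), IPD shows a brainstem-only effect
#' at half magnitude, MSA-P affects cerebellum/brainstem/putamen, MSA-C has
#' the strongest pontocerebellar involvement, and healthy controls are null.
#' Magnitudes are a modelling choice, not estimates from any patient cohort.
#'
#' @return numeric matrix, rows classes (HC, PSP, IPD, MSA-P, MSA-C),
#'   columns the six network regions.
#' @export
default_effect_matrix <- function() {
  regions <- c("cerebellum", "brainstem", "caudate", "putamen", "pallidum",
               "accumbens")
  m <- rbind(
    `HC`    = c(0,   0,   0,   0,   0,   0),
    `PSP`   = c(1.0, 3.0, 2.0, 2.0, 2.0, 1.0),
    `IPD`   = c(0,   1.5, 0,   0,   0,   0),
    `MSA-P` = c(2.5, 2.5, 0,   2.0, 0,   0),
    `MSA-C` = c(3.5, 3.0, 0,   0,   0,   0)
  )
  colnames(m) <- regions
  m
}

#' Specify a synthetic cohort design
#'
#' @param class_names ordered character vector of class names.
#' @param n_per_class integer counts per class (recycled names from
#'   \code{class_names} if unnamed).
#' @param effect_matrix numeric class-by-region matrix of mean regional
#'   signal decreases, in units of the per-voxel noise SD. Rows must be
#'   named by class; any class named \code{"HC"} must have an all-zero row.
#' @param noise_sd per-voxel SD of the (smoothed) noise field.
#' @param smoothing_fwhm full width at half maximum of the Gaussian noise
#'   smoothing kernel, in voxels; 0 disables smoothing.
#' @param subject_scale_sd SD of the subject-level multiplicative intensity
#'   factor (mean 1), a global nuisance mimicking overall volume/intensity
#'   variation.
#' @param baseline baseline voxel value before effects and noise.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a \code{cohort_design} list.
#' @export
cohort_design <- function(class_names = c("HC", "PSP", "IPD", "MSA-P", "MSA-C"),
                          n_per_class = c(HC = 19, PSP = 17, IPD = 14,
                                          `MSA-P` = 12, `MSA-C` = 7),
                          effect_matrix = default_effect_matrix(),
                          noise_sd = 1,
                          smoothing_fwhm = 2,
                          subject_scale_sd = 0.05,
                          baseline = 1,
                          seed = 1L) {
  class_names <- as.character(class_names)
  if (is.null(names(n_per_class))) names(n_per_class) <- class_names
  n_per_class <- n_per_class[class_names]
  if (any(is.na(n_per_class)) || any(n_per_class < 1))
    stop("every class needs a count of at least 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  effect_matrix <- as.matrix(effect_matrix)
  if (is.null(rownames(effect_matrix)) || is.null(colnames(effect_matrix)))
    stop("effect_matrix needs class row names and region column names")
  missing_cls <- setdiff(class_names, rownames(effect_matrix))
  if (length(missing_cls))
    stop("effect_matrix has no row for class ",
         paste(missing_cls, collapse = ", "))
  effect_matrix <- effect_matrix[class_names, , drop = FALSE]
  if ("HC" %in% class_names && any(effect_matrix["HC", ] != 0))
    stop("the HC (healthy control) effect row must be all zero")
  structure(list(class_names = class_names,
                 n_per_class = as.integer(n_per_class),
                 effect_matrix = effect_matrix,
                 noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm,
                 subject_scale_sd = subject_scale_sd,
                 baseline = baseline,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Separable zero-padded Gaussian convolution along one array axis.
.conv_axis <- function(a, band, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  out <- array(band %*% matrix(ap, nrow = dp[1]), dim = dp)
  aperm(out, order(perm))
}

#' Smooth a 3-D array with an isotropic Gaussian kernel
#'
#' Separable discrete Gaussian convolution with zero padding at the edges.
#'
#' @param x 3-D numeric array.
#' @param fwhm kernel full width at half maximum, in voxels; 0 returns
#'   \code{x} unchanged.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    n <- dim(x)[axis]
    band <- matrix(0, n, n)
    for (j in seq_len(2 * r + 1)) {
      off <- j - r - 1L
      idx <- seq_len(n)
      keep <- idx + off >= 1 & idx + off <= n
      band[cbind(idx[keep], idx[keep] + off)] <- k[j]
    }
    x <- .conv_axis(x, band, axis)
  }
  x
}

# Interior-voxel SD shrink factor of the separable smoothing, used to put
# planted effects back on the scale of the post-smoothing voxel SD.
.smooth_sd_factor <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sqrt(sum(k^2))^3
}

#' Generate a synthetic two-channel volumetric cohort
#'
#' Each subject of class c receives, in both tissue channels, a baseline
#' volume minus \code{effect_matrix[c, r] * noise_sd} inside each region r,
#' plus spatially smoothed Gaussian noise (rescaled so its interior voxel SD
#' equals \code{noise_sd}), the whole image then multiplied by a
#' subject-level factor \code{1 + N(0, subject_scale_sd)}. Noise is drawn
#' independently per channel; the regional effect is shared, emulating the
#' grey-/white-matter components of a morphometric (scalar-momentum-like)
#' feature map. The cohort is bit-reproducible from \code{design$seed}.
#'
#' @param atlas a \code{region_atlas} covering every region named in the
#'   design's effect matrix.
#' @param design a \code{cohort_design}.
#' @return list with \code{images} (list of \code{subject_image}: two
#'   channels \code{grey}, \code{white}, a \code{subject_id} and
#'   \code{class_label}), \code{labels} (data frame \code{subject_id},
#'   \code{class}) and the \code{design}.
#' @export
generate_cohort <- function(atlas, design) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(design, "cohort_design"))
  regions <- colnames(design$effect_matrix)
  unknown <- setdiff(regions, unname(atlas$region_names))
  if (length(unknown))
    stop("effect_matrix names unknown region ", paste(unknown, collapse = ", "))
  masks <- lapply(regions, function(r) atlas_mask(atlas, paste0("region:", r)))
  names(masks) <- regions
  shrink <- .smooth_sd_factor(design$smoothing_fwhm)

  set.seed(design$seed)
  images <- vector("list", sum(design$n_per_class))
  ids <- character(length(images))
  cls <- character(length(images))
  idx <- 0L
  for (ci in seq_along(design$class_names)) {
    cname <- design$class_names[ci]
    base <- array(design$baseline, dim = atlas$grid_dims)
    for (r in regions) {
      eff <- design$effect_matrix[cname, r]
      if (eff != 0) base[masks[[r]]] <- base[masks[[r]]] - eff * design$noise_sd
    }
    for (si in seq_len(design$n_per_class[ci])) {
      idx <- idx + 1L
      subject_scale <- 1 + rnorm(1, 0, design$subject_scale_sd)
      chans <- lapply(c("grey", "white"), function(ch) {
        noise <- array(rnorm(prod(atlas$grid_dims)), dim = atlas$grid_dims)
        noise <- gaussian_smooth_3d(noise, design$smoothing_fwhm) / shrink
        subject_scale * (base + design$noise_sd * noise)
      })
      names(chans) <- c("grey", "white")
      ids[idx] <- sprintf("sub-%03d", idx)
      cls[idx] <- cname
      images[[idx]] <- structure(list(channels = chans,
                                      subject_id = ids[idx],
                                      class_label = cname),
                                 class = "subject_image")
    }
  }
  list(images = images,
       labels = data.frame(subject_id = ids, class = cls,
                           stringsAsFactors = FALSE),
       design = design)
}
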