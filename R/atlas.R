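#' Build a spherical-region label atlas
#'
#' Constructs an integer-labelled 3-D volume in which each named region is a
#' voxelised sphere. The six subcortical motor-network regions (bilateral
#' cerebellum, brainstem, caudate, putamen, pallidum, accumbens) are
#' represented as disjoint spheres on a small grid; an optional brain sphere
#' supplies a \code{cortex_background} compartment so that a whole-brain mask
#' (all nonzero labels) strictly contains the network mask.
#'
#' Voxel indices are 1-based in R; the affine maps the centre of voxel
#' (1,1,1) to the world origin with isotropic \code{voxel_size} mm spacing.
#'
#' @param grid_dims integer vector of length 3, volume dimensions in voxels.
#' @param regions data frame with columns \code{name}, \code{cx}, \code{cy},
#'   \code{cz} (sphere centres, voxels) and \code{radius} (voxels).
#' @param brain_radius optional radius (voxels) of a brain sphere centred on
#'   the grid; voxels inside it but in no named region are labelled
#'   \code{cortex_background}.
#' @param voxel_size isotropic voxel edge length in mm (metadata only).
#' @return a \code{region_atlas}: list with \code{labels} (3-D integer
#'   array), \code{region_names} (label -> name), \code{grid_dims},
#'   \code{affine}.
#' @examples
#' at <- build_atlas(c(16, 16, 16),
#'   data.frame(name = "brainstem", cx = 8, cy = 8, cz = 8, radius = 3))
#' table(at$labels)
#' @export
build_atlas <- function(grid_dims, regions, brain_radius = NULL,
                        voxel_size = 2) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1))
  regions <- as.data.frame(regions)
  need <- c("name", "cx", "cy", "cz", "radius")
  if (!all(need %in% names(regions)))
    stop("'regions' must have columns ", paste(need, collapse = ", "))
  if (any(regions$radius <= 0)) stop("region radii must be positive")
  if (anyDuplicated(regions$name)) stop("duplicated region names")

  labels <- array(0L, dim = grid_dims)
  sq <- function(n, c) (seq_len(n) - c)^2
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    if (r$cx - r$radius < 1 || r$cx + r$radius > grid_dims[1] ||
        r$cy - r$radius < 1 || r$cy + r$radius > grid_dims[2] ||
        r$cz - r$radius < 1 || r$cz + r$radius > grid_dims[3])
      stop("region '", r$name, "' extends outside the grid")
    d2 <- outer(outer(sq(grid_dims[1], r$cx), sq(grid_dims[2], r$cy), "+"),
                sq(grid_dims[3], r$cz), "+")
    inside <- d2 <= r$radius^2
    clash <- inside & labels != 0L
    if (any(clash)) {
      other <- regions$name[unique(labels[clash])]
      stop("regions '", r$name, "' and '", other[1], "' overlap")
    }
    labels[inside] <- k
  }
  region_names <- setNames(as.character(regions$name),
                           as.character(seq_len(nrow(regions))))
  if (!is.null(brain_radius)) {
    ctr <- (grid_dims + 1) / 2
    d2 <- outer(outer(sq(grid_dims[1], ctr[1]), sq(grid_dims[2], ctr[2]), "+"),
                sq(grid_dims[3], ctr[3]), "+")
    bg <- d2 <= brain_radius^2 & labels == 0L
    lab_bg <- nrow(regions) + 1L
    labels[bg] <- lab_bg
    region_names[as.character(lab_bg)] <- "cortex_background"
  }
  if (any(tabulate(labels[labels > 0L], nbins = length(region_names)) == 0L))
    stop("atlas contains an empty region")
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * 0  # voxel (1,1,1) centre at the origin
  structure(list(labels = labels, region_names = region_names,
                 grid_dims = grid_dims, affine = affine,
                 voxel_size = voxel_size),
            class = "region_atlas")
}

# Reference sphere layout for the six network regions, as fractions of the
# grid so the same geometry scales to smaller test grids.
.atlas_layout <- data.frame(
  name  = c("cerebellum", "brainstem", "caudate", "putamen", "pallidum",
            "accumbens"),
  fx    = c(10, 24, 16, 16, 16, 16) / 32,
  fy    = c(16, 16, 10, 24, 16, 16) / 32,
  fz    = c(16, 16, 16, 16, 10, 24) / 32,
  frad  = c(5, 4, 3, 3, 3, 2) / 32
)

#' Default six-region atlas
#'
#' The default synthetic anatomy: six disjoint spheres standing in for the
#' bilateral subcortical motor-network regions, surrounded by a spherical
#' \code{cortex_background} compartment. Region placement and relative sizes
#' are fixed fractions of the grid, so smaller grids give geometrically
#' similar (coarser) atlases.
#'
#' @param grid_dims volume dimensions in voxels (default 32 cubed).
#' @inheritParams build_atlas
#' @return a \code{region_atlas}.
#' @export
default_atlas <- function(grid_dims = c(32, 32, 32), voxel_size = 2) {
  grid_dims <- as.integer(grid_dims)
  sc <- mean(grid_dims)
  regions <- data.frame(
    name = .atlas_layout$name,
    cx = round(.atlas_layout$fx * grid_dims[1]),
    cy = round(.atlas_layout$fy * grid_dims[2]),
    cz = round(.atlas_layout$fz * grid_dims[3]),
    radius = pmax(1, round(.atlas_layout$frad * sc))
  )
  build_atlas(grid_dims, regions, brain_radius = round(15 / 32 * sc),
              voxel_size = voxel_size)
}

#' Names of the network regions in an atlas
#'
#' @param atlas a \code{region_atlas}.
#' @return character vector of region names excluding
#'   \code{cortex_background}.
#' @export
network_regions <- function(atlas) {
  setdiff(unname(atlas$region_names), "cortex_background")
}

#' Logical voxel mask for a named mask
#'
#' @param atlas a \code{region_atlas}.
#' @param mask_name \code{"whole_brain"} (all labelled voxels),
#'   \code{"subcortical_network"} (union of the six network regions) or
#'   \code{"region:<name>"} for a single region.
#' @return logical 3-D array.
#' @export
atlas_mask <- function(atlas, mask_name) {
  stopifnot(inherits(atlas, "region_atlas"))
  name_to_label <- setNames(as.integer(names(atlas$region_names)),
                            unname(atlas$region_names))
  if (identical(mask_name, "whole_brain")) {
    m <- atlas$labels > 0L
  } else if (identical(mask_name, "subcortical_network")) {
    m <- array(atlas$labels %in% name_to_label[network_regions(atlas)],
               dim = atlas$grid_dims)
  } else if (startsWith(mask_name, "region:")) {
    rn <- sub("^region:", "", mask_name)
    if (!rn %in% names(name_to_label))
      stop("unknown region '", rn, "'")
    m <- atlas$labels == name_to_label[[rn]]
  } else {
    stop("unknown mask '", mask_name, "'")
  }
  if (!any(m)) stop("mask '", mask_name, "' is empty")
  m
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas:", paste(x$grid_dims, collapse = " x "), "voxels\n")
  cnt <- tabulate(x$labels[x$labels > 0L], nbins = length(x$region_names))
  for (i in seq_along(x$region_names))
    cat(sprintf("  %2s %-18s %5d voxels\n", names(x$region_names)[i],
                x$region_names[i], cnt[i]))
  invisible(x)
}
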