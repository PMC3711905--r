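# NIfTI round-trip of cohorts and atlases. Volumes are stored as
# double-precision NIfTI-1 so read(write(x)) is exact; the atlas is int16.

.write_vol <- function(vol, affine, file, datatype = "double") {
  im <- RNifti::asNifti(vol)
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, file, datatype = datatype)
  invisible(file)
}

#' Write a cohort (and its atlas) to a directory
#'
#' Writes one NIfTI file per subject per channel, the atlas labels as NIfTI,
#' the label table as CSV and a JSON manifest recording files, seed and the
#' full design, enough to reproduce or reload the cohort.
#'
#' @param cohort as returned by [generate_cohort()].
#' @param atlas the \code{region_atlas} the cohort was generated on.
#' @param dir output directory (created if needed).
#' @return (invisibly) the manifest path.
#' @export
write_cohort <- function(cohort, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (img in cohort$images) {
    for (ch in names(img$channels)) {
      f <- sprintf("%s_%s.nii.gz", img$subject_id, ch)
      .write_vol(img$channels[[ch]], atlas$affine, file.path(dir, f))
      files[[img$subject_id]][[ch]] <- f
    }
  }
  .write_vol(atlas$labels, atlas$affine, file.path(dir, "atlas.nii.gz"),
             datatype = "int16")
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  design <- cohort$design
  manifest <- list(
    files = files,
    atlas_file = "atlas.nii.gz",
    labels_file = "labels.csv",
    region_names = as.list(atlas$region_names),
    grid_dims = atlas$grid_dims,
    voxel_size = atlas$voxel_size,
    seed = design$seed,
    design = list(class_names = design$class_names,
                  n_per_class = design$n_per_class,
                  effect_matrix = list(rows = rownames(design$effect_matrix),
                                       cols = colnames(design$effect_matrix),
                                       values = design$effect_matrix),
                  noise_sd = design$noise_sd,
                  smoothing_fwhm = design$smoothing_fwhm,
                  subject_scale_sd = design$subject_scale_sd,
                  baseline = design$baseline)
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing \code{manifest.json}.
#' @return list with \code{images}, \code{labels}, \code{design} (as in
#'   [generate_cohort()]) and the reloaded \code{atlas}.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest file '", mf, "'")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c(manifest$atlas_file, manifest$labels_file,
            unlist(manifest$files, use.names = FALSE))
  for (f in need)
    if (!file.exists(file.path(dir, f))) stop("missing file '", f, "'")

  atlas_img <- RNifti::readNifti(file.path(dir, manifest$atlas_file))
  labels_arr <- array(as.integer(atlas_img), dim = dim(atlas_img))
  grid_dims <- as.integer(manifest$grid_dims)
  affine <- structure(RNifti::xform(atlas_img), imagedim = NULL, code = NULL)
  atlas <- structure(list(labels = labels_arr,
                          region_names = unlist(manifest$region_names),
                          grid_dims = grid_dims,
                          affine = matrix(as.numeric(affine), 4, 4),
                          voxel_size = manifest$voxel_size),
                     class = "region_atlas")

  label_tab <- read.csv(file.path(dir, manifest$labels_file),
                        stringsAsFactors = FALSE)
  images <- vector("list", nrow(label_tab))
  for (i in seq_len(nrow(label_tab))) {
    sid <- label_tab$subject_id[i]
    chans <- lapply(manifest$files[[sid]], function(f) {
      v <- RNifti::readNifti(file.path(dir, f))
      if (!identical(as.integer(dim(v)), grid_dims))
        stop("grid mismatch between image '", f, "' and atlas")
      array(as.numeric(v), dim = grid_dims)
    })
    images[[i]] <- structure(list(channels = chans, subject_id = sid,
                                  class_label = label_tab$class[i]),
                             class = "subject_image")
  }
  dm <- manifest$design
  em <- matrix(as.numeric(dm$effect_matrix$values),
               nrow = length(dm$effect_matrix$rows),
               dimnames = list(dm$effect_matrix$rows, dm$effect_matrix$cols))
  design <- cohort_design(class_names = dm$class_names,
                          n_per_class = setNames(dm$n_per_class,
                                                 dm$class_names),
                          effect_matrix = em,
                          noise_sd = dm$noise_sd,
                          smoothing_fwhm = dm$smoothing_fwhm,
                          subject_scale_sd = dm$subject_scale_sd,
                          baseline = dm$baseline,
                          seed = manifest$seed)
  list(images = images, labels = label_tab, design = design, atlas = atlas)
}
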