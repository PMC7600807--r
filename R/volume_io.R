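# Cohort manifests, mask application, and the subject-by-voxel matrix that
# all downstream statistics operate on.

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `group` (`control` /
#' `patient`), `age_years`, `sex` (`F` / `M`) and `volume_path`.  Relative
#' volume paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A validated `data.frame` of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("Manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rel <- !is.na(df$volume_path) & !grepl("^(/|[A-Za-z]:)", df$volume_path)
  df$volume_path[rel] <- file.path(dirname(path), df$volume_path[rel])
  as_cohort_manifest(df)
}

#' Validate a data frame as a cohort manifest
#'
#' @param df Data frame with columns `subject_id`, `group`, `age_years`,
#'   `sex` and (optionally) `volume_path`.
#' @return The data frame, classed `cohort_manifest`.
#' @export
as_cohort_manifest <- function(df) {
  required <- c("subject_id", "group", "age_years", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("Manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("Manifest subject_id values must be unique")
  }
  if (!all(df$group %in% c("control", "patient"))) {
    stop("Manifest group must be 'control' or 'patient'")
  }
  if (!all(df$sex %in% c("F", "M"))) {
    stop("Manifest sex must be 'F' or 'M'")
  }
  if (!is.numeric(df$age_years) || anyNA(df$age_years)) {
    stop("Manifest age_years must be numeric and complete")
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest CSV
#'
#' @param manifest A `cohort_manifest` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a masked subject-by-voxel stack
#'
#' Internal constructor shared by [load_cohort()] and the simulator: applies
#' a binary mask to a list of equally shaped 3D volumes.  In-mask voxels are
#' ordered by lexicographic (column-major array) scan order, so the ordering
#' is deterministic for a given mask.
#'
#' @param volumes Named list of 3D arrays, one per subject, in manifest order.
#' @param mask Logical/binary 3D array of the same shape.
#' @param manifest The corresponding `cohort_manifest`.
#' @param affine Optional 4x4 affine carried along for outputs.
#' @return A `masked_stack`: list with `data` (subjects x voxels matrix),
#'   `voxel_index` (voxels x 3 integer matrix of 0-based grid coordinates),
#'   `grid_shape`, `subject_order`, `manifest`, `affine`.
#' @export
masked_stack <- function(volumes, mask, manifest, affine = diag(4)) {
  mask <- mask != 0
  grid_shape <- dim(mask)
  if (sum(mask) == 0L) stop("Mask is empty: no in-mask voxels")
  if (length(volumes) != nrow(manifest)) {
    stop("Number of volumes (", length(volumes), ") does not match manifest rows (",
         nrow(manifest), ")")
  }
  idx <- which(mask)
  coords <- arrayInd(idx, grid_shape) - 1L   # 0-based template-grid coordinates
  data <- matrix(NA_real_, nrow = length(volumes), ncol = length(idx))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v), grid_shape)) {
      stop("Volume for subject '", manifest$subject_id[i],
           "' has grid ", paste(dim(v), collapse = "x"),
           " but the mask grid is ", paste(grid_shape, collapse = "x"))
    }
    data[i, ] <- v[idx]
  }
  rownames(data) <- manifest$subject_id
  structure(list(data = data, voxel_index = coords, grid_shape = grid_shape,
                 subject_order = manifest$subject_id, manifest = manifest,
                 affine = affine),
            class = "masked_stack")
}

#' Load a cohort of registered volumes under a thalamus mask
#'
#' Reads every subject volume named in the manifest, checks that each shares
#' the mask's grid and affine (absolute tolerance 1e-4; volumes must be
#' pre-registered, no resampling is performed), and assembles the in-mask
#' intensity matrix.
#'
#' @param manifest_path Path to the manifest CSV (or a `cohort_manifest`).
#' @param mask_path Path to the binary mask NIfTI.
#' @return A `masked_stack`.
#' @export
load_cohort <- function(manifest_path, mask_path) {
  manifest <- if (inherits(manifest_path, "cohort_manifest")) manifest_path
              else read_manifest(manifest_path)
  mask_img <- read_nifti(mask_path)
  mask <- mask_img$data != 0
  if (sum(mask) == 0L) stop("Mask is empty: ", mask_path)

  volumes <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_nifti(manifest$volume_path[i])
    if (!identical(dim(img$data), dim(mask))) {
      stop("Geometry mismatch for subject '", manifest$subject_id[i],
           "': volume grid ", paste(dim(img$data), collapse = "x"),
           " vs mask grid ", paste(dim(mask), collapse = "x"))
    }
    if (max(abs(img$affine - mask_img$affine)) > 1e-4) {
      stop("Affine mismatch for subject '", manifest$subject_id[i],
           "' exceeds tolerance 1e-4; volumes must be registered to the mask grid")
    }
    volumes[[i]] <- img$data
  }
  masked_stack(volumes, mask, manifest, affine = mask_img$affine)
}

#' Write a binary region mask as NIfTI
#'
#' @param region Logical/binary 3D array, or a logical vector over the
#'   in-mask voxels of `reference` (a `masked_stack`), which is then
#'   scattered back onto the 3D grid.
#' @param reference A `masked_stack` or a list with `grid_shape` and `affine`
#'   supplying the output geometry.
#' @param out_path Output `.nii` / `.nii.gz` path.
#' @return `out_path`, invisibly.
#' @export
write_region_mask <- function(region, reference, out_path) {
  if (is.null(dim(region))) {
    region <- region_to_volume(region, reference)
  }
  if (!identical(dim(region), reference$grid_shape)) {
    stop("Region grid ", paste(dim(region), collapse = "x"),
         " does not match reference grid ",
         paste(reference$grid_shape, collapse = "x"))
  }
  affine <- if (!is.null(reference$affine)) reference$affine else diag(4)
  write_nifti(array(as.integer(region != 0), dim = dim(region)),
              out_path, affine = affine, datatype = "uint8")
  invisible(out_path)
}

#' Scatter an in-mask voxel vector back to a 3D volume
#'
#' @param values Vector over in-mask voxels (logical or numeric), in the
#'   stack's voxel order.
#' @param stack The `masked_stack` defining the voxel index and grid.
#' @param fill Background value for out-of-mask voxels.
#' @return A 3D array of the stack's grid shape.
#' @export
region_to_volume <- function(values, stack, fill = 0) {
  if (length(values) != nrow(stack$voxel_index)) {
    stop("Vector length ", length(values), " does not match the ",
         nrow(stack$voxel_index), " in-mask voxels")
  }
  vol <- array(fill, dim = stack$grid_shape)
  lin <- 1L + stack$voxel_index %*% c(1L, stack$grid_shape[1],
                                      stack$grid_shape[1] * stack$grid_shape[2])
  vol[as.vector(lin)] <- as.numeric(values)
  vol
}

#' @export
print.masked_stack <- function(x, ...) {
  cat("<masked_stack> ", nrow(x$data), " subjects x ", ncol(x$data),
      " in-mask voxels on a ", paste(x$grid_shape, collapse = "x"),
      " grid\n", sep = "")
  tab <- table(x$manifest$group)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
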