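# File interchange: 6-component tensor NIfTI volumes, ASCII PLY meshes,
# per-vertex label TSVs, cohort CSVs and cutpoint JSON sidecars. All
# formats are plain open formats so that pipeline runs can be resumed
# from any stage's outputs.

#' Write a tensor volume as a 6-component NIfTI file
#'
#' Components are stored as the 4th dimension in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) with the voxel-to-world affine in the
#' sform. The cortical mask is written alongside as `<stem>_mask.nii.gz`.
#'
#' @param vol A `tensor_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_tensor_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "tensor_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mimg <- RNifti::asNifti(array(as.numeric(vol$mask), dim(vol$mask)))
  mimg <- RNifti::`sform<-`(mimg, structure(vol$affine, code = 2L))
  RNifti::writeNifti(mimg, mask_path)
  invisible(path)
}

#' Read a 6-component tensor NIfTI file
#'
#' @param path Tensor NIfTI path; the mask is read from
#'   `<stem>_mask.nii.gz` when present, otherwise voxels with nonzero
#'   off-diagonal structure are treated as cortical.
#' @return A `tensor_volume`.
#' @export
read_tensor_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L) {
    stop("expected a 4-D NIfTI with 6 tensor components", call. = FALSE)
  }
  affine <- structure(RNifti::xform(img), code = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  if (file.exists(mask_path)) {
    mask <- array(as.numeric(RNifti::readNifti(mask_path)) > 0.5,
                  dim(arr)[1:3])
  } else {
    off <- abs(arr[, , , 2]) + abs(arr[, , , 4]) + abs(arr[, , , 5])
    mask <- array(off > 0, dim(arr)[1:3])
  }
  structure(list(data = arr, affine = affine, mask = mask,
                 voxel_mm = sqrt(sum(affine[1:3, 1]^2)), n_clamped = 0L),
            class = "tensor_volume")
}

write_ply_one <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(vertices, 1, function(v) {
    paste(format(v, trim = TRUE, digits = 10), collapse = " ")
  }), con)
  if (nrow(faces) > 0L) {
    writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
               con)
  }
  invisible(path)
}

read_ply_one <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  start <- which(lines == "end_header") + 1L
  verts <- do.call(rbind, lapply(lines[start:(start + nv - 1L)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    faces <- do.call(rbind, lapply(
      lines[(start + nv):(start + nv + nf - 1L)], function(l) {
        as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:4] + 1L
      }))
  }
  list(vertices = verts, faces = faces)
}

#' Write a surface model as white/pial PLY meshes and a label TSV
#'
#' @param surfaces A `surface_model`.
#' @param stem Output path stem; writes `<stem>_white.ply`,
#'   `<stem>_pial.ply` and `<stem>_labels.tsv` (vertex_index, region,
#'   hemisphere).
#' @return The three paths, invisibly.
#' @export
write_surface_model <- function(surfaces, stem) {
  stopifnot(inherits(surfaces, "surface_model"))
  pw <- paste0(stem, "_white.ply")
  pp <- paste0(stem, "_pial.ply")
  pl <- paste0(stem, "_labels.tsv")
  write_ply_one(surfaces$white, surfaces$faces, pw)
  write_ply_one(surfaces$pial, surfaces$faces, pp)
  utils::write.table(surfaces$labels, pl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(white = pw, pial = pp, labels = pl))
}

#' Read a surface model from PLY meshes and a label TSV
#'
#' @param white,pial PLY mesh paths (index-matched vertices).
#' @param labels TSV path with columns vertex_index, region, hemisphere.
#' @return A `surface_model` (without phantom geometry metadata).
#' @export
read_surface_model <- function(white, pial, labels) {
  w <- read_ply_one(white)
  p <- read_ply_one(pial)
  if (nrow(w$vertices) != nrow(p$vertices)) {
    stop("white and pial meshes must have equal vertex counts", call. = FALSE)
  }
  lab <- utils::read.delim(labels, stringsAsFactors = FALSE)
  check_region_names(unique(lab$region), "label table")
  structure(list(white = w$vertices, pial = p$vertices, faces = w$faces,
                 labels = lab, geometry = NULL),
            class = "surface_model")
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cutpoint as JSON
#'
#' Records the biomarker, threshold, polarity, per-group bandwidths and
#' sample sizes (the density grid is omitted for compactness).
#'
#' @param cutpoint A `cutpoint` object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_cutpoint_json <- function(cutpoint, path) {
  stopifnot(inherits(cutpoint, "cutpoint"))
  jsonlite::write_json(list(biomarker = cutpoint$biomarker,
                            threshold = cutpoint$threshold,
                            polarity = cutpoint$polarity,
                            n_cu = cutpoint$n_cu, n_ad = cutpoint$n_ad,
                            bw_cu = cutpoint$bw_cu, bw_ad = cutpoint$bw_ad),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
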