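#' 4D BOLD run container
#'
#' Bundles one subject's 4D BOLD time series with its repetition time, brain
#' mask and voxel size.  All analysis functions in the package consume and
#' return this class.
#'
#' @param data numeric 4D array, dimensions x,y,z,t (arbitrary units).
#' @param tr_seconds repetition time in seconds.
#' @param mask logical 3D array marking in-brain voxels; defaults to all TRUE.
#' @param voxel_mm numeric length-3 voxel size in mm; default 3 mm isotropic.
#'
#' @return An object of class \code{bold_run}: a list with elements
#'   \code{data}, \code{tr_seconds}, \code{mask}, \code{voxel_mm}.
#' @export
bold_run <- function(data, tr_seconds, mask = NULL, voxel_mm = c(3, 3, 3)) {
  .assert(is.array(data) && length(dim(data)) == 4L, "data must be a 4D array")
  .assert(dim(data)[4] >= 60L, "a BOLD run needs at least 60 volumes")
  .assert(all(is.finite(data)), "data contains non-finite values")
  .assert(is.numeric(tr_seconds) && tr_seconds > 0, "tr_seconds must be positive")
  .assert(length(voxel_mm) == 3L && all(voxel_mm > 0), "voxel_mm must be 3 positive numbers")
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  .assert(is.logical(mask) && all(dim(mask) == dim(data)[1:3]), "mask must match the spatial grid")
  .assert(any(mask), "mask is empty")
  structure(list(data = data, tr_seconds = tr_seconds, mask = mask,
                 voxel_mm = as.numeric(voxel_mm)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes, TR %.3g s, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

n_volumes <- function(run) dim(run$data)[4]

# In-mask data as a t x v matrix (voxels in column-major mask order).
run_matrix <- function(run) {
  v <- which(run$mask)
  d <- dim(run$data)
  m <- matrix(run$data, prod(d[1:3]), d[4])[v, , drop = FALSE]
  t(m)
}

# Rebuild a bold_run from a t x v in-mask matrix, zero outside the mask.
matrix_to_run <- function(mat, template) {
  d <- dim(template$data)
  flat <- matrix(0, prod(d[1:3]), d[4])
  flat[which(template$mask), ] <- t(mat)
  # preserve out-of-mask voxels untouched
  out <- which(!template$mask)
  if (length(out)) flat[out, ] <- matrix(template$data, prod(d[1:3]), d[4])[out, ]
  bold_run(array(flat, d), template$tr_seconds, template$mask, template$voxel_mm)
}

# mm coordinate of the centre of voxel (i,j,k), 1-based: (ijk - 1) * voxel_mm.
ijk_to_mm <- function(ijk, voxel_mm) {
  sweep(ijk - 1, 2, voxel_mm, `*`)
}

#' Read / write BOLD runs as NIfTI
#'
#' @param path file path of a NIfTI volume (\code{.nii} or \code{.nii.gz}).
#' @param run a \code{\link{bold_run}}.
#' @param sidecar logical; also write \code{<path>.json} with tr and mask info.
#' @return \code{read_bold_nifti} returns a \code{bold_run};
#'   \code{write_bold_nifti} returns \code{path} invisibly.
#' @export
write_bold_nifti <- function(run, path, sidecar = TRUE) {
  img <- RNifti::asNifti(run$data, pixdim = c(run$voxel_mm, run$tr_seconds))
  RNifti::writeNifti(img, path)
  if (sidecar) {
    jsonlite::write_json(list(tr_seconds = run$tr_seconds, voxel_mm = run$voxel_mm),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param tr_seconds repetition time; if \code{NULL}, taken from the NIfTI
#'   header (4th pixdim) or the JSON sidecar.
#' @param mask optional logical 3D array; default: voxels with non-zero
#'   temporal standard deviation.
#' @export
read_bold_nifti <- function(path, tr_seconds = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  if (is.null(tr_seconds)) {
    side <- paste0(path, ".json")
    tr_seconds <- if (file.exists(side)) jsonlite::read_json(side)$tr_seconds
                  else if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  if (is.null(mask)) {
    d <- dim(arr)
    sds <- apply(matrix(arr, prod(d[1:3]), d[4]), 1, stats::sd)
    mask <- array(sds > 0, d[1:3])
  }
  bold_run(arr, tr_seconds, mask, voxel_mm = pd[1:3])
}
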