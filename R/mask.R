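#' Voxelized left-ventricular myocardium mask
#'
#' Container for a binary 3D myocardium mask on a regular grid. World
#' coordinates follow the voxel-center convention: the center of voxel
#' `(i, j, k)` (1-based array indices) sits at
#' `origin + (c(i, j, k) - 1) * spacing` in right-handed millimetre
#' coordinates, i.e. `origin` is the world position of the center of the
#' first voxel.
#'
#' @param grid Logical (or coercible) 3D array; `TRUE`/nonzero = myocardium.
#' @param spacing Numeric length-3 vector of voxel spacings in mm (all > 0).
#' @param origin Numeric length-3 world position (mm) of the first voxel
#'   center.
#' @return An object of class `myocardium_mask`: a list with elements
#'   `grid`, `spacing`, `origin`.
#' @seealso [read_myocardium_mask()], [voxel_volume_ml()], [assign_voxels()]
#' @export
myocardium_mask <- function(grid, spacing, origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm/voxel)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)")
  }
  storage.mode(grid) <- "logical"
  grid[is.na(grid)] <- FALSE
  structure(
    list(grid = grid, spacing = spacing, origin = origin),
    class = "myocardium_mask"
  )
}

#' @export
print.myocardium_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat("Myocardium mask:", paste(d, collapse = " x "), "voxels,",
      "spacing", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  foreground:", sum(x$grid), "voxels =",
      format(total_volume_ml(x), digits = 5), "ml\n")
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param mask A [myocardium_mask()].
#' @return Volume of one voxel in ml (product of spacings / 1000).
#' @export
voxel_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "myocardium_mask"))
  prod(mask$spacing) / 1000
}

#' Total foreground (LV myocardium) volume in millilitres
#'
#' @param mask A [myocardium_mask()].
#' @return Foreground volume in ml.
#' @export
total_volume_ml <- function(mask) {
  sum(mask$grid) * voxel_volume_ml(mask)
}

# World-mm centers of the given linear voxel indices (defaults: all
# foreground voxels), as an n x 3 matrix.
voxel_centers <- function(mask, idx = which(mask$grid)) {
  ijk <- arrayInd(idx, dim(mask$grid))
  sweep(sweep(ijk - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Read a myocardium mask from a NIfTI file
#'
#' Any nonzero voxel is treated as myocardium. The voxel-to-world transform
#' must be axis-aligned with positive scales (a diagonal direction matrix);
#' oblique or flipped orientations are rejected rather than silently
#' reinterpreted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [myocardium_mask()].
#' @export
read_myocardium_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  xf <- RNifti::xform(img)
  dir <- xf[1:3, 1:3]
  offdiag <- dir
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(dir))))) {
    stop("NIfTI orientation is not axis-aligned; resample before use")
  }
  if (any(diag(dir) <= 0)) {
    stop("NIfTI orientation has negative axis scales; resample before use")
  }
  myocardium_mask(array(img != 0, dim = dim(img)),
                  spacing = diag(dir), origin = xf[1:3, 4])
}

#' Write a myocardium mask (or any label volume) to NIfTI
#'
#' @param mask A [myocardium_mask()], or a 3D array together with `spacing`
#'   and `origin`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param data Optional 3D array to write on the mask's grid (e.g. a
#'   territory label volume); defaults to the binary mask itself.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path, data = NULL) {
  stopifnot(inherits(mask, "myocardium_mask"))
  arr <- if (is.null(data)) mask$grid + 0L else data
  if (!identical(dim(arr), dim(mask$grid))) {
    stop("`data` must match the mask grid dimensions")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing  # before the sform, which scales by it
  xf <- diag(c(mask$spacing, 1))
  xf[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
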