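#' 3D volume with voxel spacing
#'
#' A `vol3d` is a plain 3D array carrying its voxel spacing (mm per axis) as
#' an attribute. World coordinates follow a centred RAS convention: voxel
#' index `i` (0-based) on an axis of length `n` with spacing `s` sits at
#' `(i - (n - 1) / 2) * s` mm, so the grid is symmetric about the origin and
#' the `+x` direction is the anatomical right.
#'
#' @param data numeric or integer 3D array.
#' @param spacing numeric length-3, mm per axis.
#' @return a `vol3d` object.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("vol3d requires a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  attr(data, "spacing") <- spacing
  class(data) <- c("vol3d", class(data))
  data
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(vspacing(x), 4), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume
#' @param x array or `vol3d`.
#' @param default spacing assumed when `x` carries none.
#' @return numeric length-3 (mm).
#' @export
vspacing <- function(x, default = c(1, 1, 1)) {
  s <- attr(x, "spacing")
  if (is.null(s)) as.numeric(default) else s
}

# strip vol3d class so base array semantics apply
as_arr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' World-coordinate axes of a grid
#'
#' @param dim integer length-3 grid shape.
#' @param spacing mm per axis.
#' @return list of three numeric vectors (x, y, z voxel-centre positions, mm).
#' @export
coord_axes <- function(dim, spacing) {
  lapply(1:3, function(a) (seq_len(dim[a]) - 1 - (dim[a] - 1) / 2) * spacing[a])
}

#' @rdname coord_axes
#' @details `coord_arrays` returns the three full grid-shaped coordinate
#'   arrays instead of the axis vectors.
#' @export
coord_arrays <- function(dim, spacing) {
  ax <- coord_axes(dim, spacing)
  list(
    x = array(rep(ax[[1]], times = dim[2] * dim[3]), dim),
    y = array(rep(rep(ax[[2]], each = dim[1]), times = dim[3]), dim),
    z = array(rep(ax[[3]], each = dim[1] * dim[2]), dim)
  )
}

#' Index-to-world affine of a grid
#'
#' 4x4 matrix sending 0-based voxel indices to centred world mm coordinates.
#' @inheritParams coord_axes
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(dim, spacing) {
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- -(dim - 1) / 2 * spacing
  A
}

# integer shift of a 3D array along one axis; pad by edge replication or value
shift_axis <- function(a, k, axis, pad = c("replicate", "zero"), fill = 0) {
  pad <- match.arg(pad)
  if (k == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) - k
  if (pad == "replicate") idx <- pmin(pmax(idx, 1L), n) else idx[idx < 1 | idx > n] <- NA
  a <- as_arr(a)
  out <- switch(axis,
                a[idx, , , drop = FALSE],
                a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  if (pad == "zero") out[is.na(out)] <- fill
  dim(out) <- d
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Shift-and-add separable convolution with edge replication; the kernel is
#' truncated at 3 sigma and renormalised, so constant images are preserved.
#'
#' @param a 3D array.
#' @param sigma_vox standard deviation per axis in voxels (scalar or length 3).
#' @return smoothed array of the same shape.
#' @export
gauss_smooth3d <- function(a, sigma_vox) {
  sp <- attr(a, "spacing")
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  out <- as_arr(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(out))
    for (t in -r:r) acc <- acc + w[t + r + 1] * shift_axis(out, t, axis)
    out <- acc
  }
  if (!is.null(sp)) out <- vol3d(out, sp)
  out
}

#' Dice overlap coefficient
#' @param a,b logical arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' Euclidean distance to a voxel set
#'
#' Exact distance (mm) from every voxel centre to the nearest voxel centre of
#' `mask`, honouring anisotropic spacing.
#'
#' @param mask logical 3D array (the sites).
#' @param spacing mm per axis; defaults to the mask's own spacing.
#' @return numeric array of distances (`Inf` when `mask` is empty).
#' @export
distance_to <- function(mask, spacing = vspacing(mask)) {
  d <- dim(mask)
  out <- cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing))
  dim(out) <- d
  sqrt(out)
}

#' Morphological operators built on the distance transform
#'
#' Ball-structuring-element dilation, erosion and closing of binary masks,
#' with the radius in mm.
#'
#' @param mask logical 3D array.
#' @param r_mm structuring ball radius (mm).
#' @param spacing mm per axis.
#' @return logical array.
#' @export
dilate_mask <- function(mask, r_mm, spacing = vspacing(mask)) {
  if (!any(mask)) return(mask)
  distance_to(mask, spacing) <= r_mm + 1e-9
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, r_mm, spacing = vspacing(mask)) {
  !dilate_mask(!mask, r_mm, spacing)
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, r_mm, spacing = vspacing(mask)) {
  erode_mask(dilate_mask(mask, r_mm, spacing), r_mm, spacing)
}

#' Connected components of a binary mask
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  out <- cpp_components(as.logical(mask), as.integer(d), as.integer(connectivity))
  dim(out) <- d
  out
}

#' Largest connected component
#' @inheritParams label_components
#' @return logical array retaining only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

#' Fill interior holes of a binary mask
#'
#' Background components (6-connected) not touching the volume border are
#' absorbed into the mask.
#' @param mask logical 3D array.
#' @return logical array.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 6)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

# block-mean downsampling by an integer factor (trailing partial blocks drop)
downsample_block <- function(a, factor) {
  if (factor == 1L) return(as_arr(a))
  d <- dim(a)
  nd <- d %/% factor
  a <- as_arr(a)[seq_len(nd[1] * factor), seq_len(nd[2] * factor), seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  dim(out) <- nd
  out
}

#' Resample a volume through an affine world map
#'
#' @param vol `vol3d` (or array with `spacing`) to resample.
#' @param affine 4x4 matrix mapping the volume's world coordinates to the
#'   output grid's world coordinates.
#' @param out_dim,out_spacing output grid geometry; default the input's.
#' @param background value for samples falling outside the input grid.
#' @param nearest use nearest-neighbour (for label volumes) instead of
#'   trilinear interpolation.
#' @return resampled `vol3d` on the output grid.
#' @export
resample_affine <- function(vol, affine, out_dim = dim(vol),
                            out_spacing = vspacing(vol), background = 0,
                            nearest = FALSE) {
  Win <- grid_affine(dim(vol), vspacing(vol))
  Wout <- grid_affine(out_dim, out_spacing)
  # output index -> output world -> input world -> input index
  M <- solve(Win) %*% solve(affine) %*% Wout
  out <- cpp_resample_affine(as.numeric(vol), as.integer(dim(vol)), M,
                             as.integer(out_dim), background, nearest)
  dim(out) <- out_dim
  vol3d(out, out_spacing)
}

#' NIfTI-1 input/output
#'
#' Volumes are written with their voxel spacing in the header (gzipped
#' NIfTI-1); reading restores a `vol3d`.
#'
#' @param vol `vol3d` to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a `vol3d`; `write_volume_nifti`
#'   returns `path` invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(as_arr(vol))
  RNifti::pixdim(img) <- vspacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(array(as.numeric(img), dim(img)[1:3]), RNifti::pixdim(img)[1:3])
}
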