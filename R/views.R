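#' Extract a segmentation-masked local 3D view
#'
#' Cuts a cubic window of `view_size` voxels per side centered on the voxel
#' containing `center_xyz_nm`, and masks the intensity by the segmentation
#' of the object at the center: voxels belonging to other segments (or the
#' background) are set to the fill value, so surrounding context cannot
#' leak into the encoder input. The cube is cubic in voxel index space;
#' its physical extent follows the (possibly anisotropic) voxel size.
#' Out-of-bounds regions are padded with the fill value and mask `FALSE`.
#'
#' Intensities are centered by subtracting the volume-wide mean
#' (`normalize = TRUE`), so the fill value 0 coincides with the mean
#' intensity of the dataset.
#'
#' @param volume A [segmented_volume()].
#' @param center_xyz_nm Numeric length-3 center position in nm.
#' @param segment_id Expected segment at the center voxel (error on
#'   mismatch).
#' @param view_size Cube side in voxels (odd; default 129).
#' @param fill Fill value for masked-out and padded voxels.
#' @param normalize Subtract the volume intensity mean inside the mask.
#' @return A `segclr_view`: list with `intensity` and `mask` arrays of dim
#'   `(view_size)^3`, `center_xyz_nm`, `segment_id`, `view_size`.
#' @export
extract_view <- function(volume, center_xyz_nm, segment_id, view_size = 129,
                         fill = 0, normalize = TRUE) {
  stopifnot(inherits(volume, "segclr_volume"), view_size %% 2 == 1)
  shape <- dim(volume$intensity)
  vox <- floor(center_xyz_nm / volume$voxel_size_nm) + 1
  if (any(vox < 1) || any(vox > shape)) stop("center outside volume")
  if (volume$segmentation[vox[1], vox[2], vox[3]] != segment_id) {
    stop(sprintf("segmentation at center voxel is %d, not %d",
                 volume$segmentation[vox[1], vox[2], vox[3]], segment_id))
  }
  h <- (view_size - 1) / 2
  lo <- vox - h
  hi <- vox + h
  src_lo <- pmax(lo, 1)
  src_hi <- pmin(hi, shape)
  dst_lo <- src_lo - lo + 1
  dst_hi <- dst_lo + (src_hi - src_lo)

  intensity <- array(fill, dim = rep(view_size, 3))
  mask <- array(FALSE, dim = rep(view_size, 3))
  sx <- src_lo[1]:src_hi[1]; sy <- src_lo[2]:src_hi[2]; sz <- src_lo[3]:src_hi[3]
  dx <- dst_lo[1]:dst_hi[1]; dy <- dst_lo[2]:dst_hi[2]; dz <- dst_lo[3]:dst_hi[3]
  seg_win <- volume$segmentation[sx, sy, sz, drop = FALSE]
  int_win <- volume$intensity[sx, sy, sz, drop = FALSE]
  m <- seg_win == segment_id
  if (normalize) int_win <- int_win - volume$intensity_mean
  int_win[!m] <- fill
  intensity[dx, dy, dz] <- int_win
  mask[dx, dy, dz] <- m

  structure(list(intensity = intensity, mask = mask,
                 center_xyz_nm = as.numeric(center_xyz_nm),
                 segment_id = segment_id, view_size = view_size,
                 fill = fill),
            class = "segclr_view")
}

#' @export
print.segclr_view <- function(x, ...) {
  cat(sprintf("<segclr_view> %d^3 @ segment %d, mask fraction %.3f\n",
              x$view_size, x$segment_id, mean(x$mask)))
  invisible(x)
}

# the 24 proper axis-aligned rotations as (axis permutation, flips) pairs
proper_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    perm_sign <- ifelse(identical(p, c(1, 2, 3)) || identical(p, c(2, 3, 1)) ||
                          identical(p, c(3, 1, 2)), 1, -1)
    for (f1 in c(1, -1)) for (f2 in c(1, -1)) for (f3 in c(1, -1)) {
      if (perm_sign * f1 * f2 * f3 == 1) {
        out[[length(out) + 1]] <- list(perm = p, flip = c(f1, f2, f3) < 0)
      }
    }
  }
  out
}

apply_orientation <- function(a, perm, flip) {
  a <- aperm(a, perm)
  idx <- lapply(seq_len(3), function(k)
    if (flip[k]) rev(seq_len(dim(a)[k])) else seq_len(dim(a)[k]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Apply training augmentations to a view
#'
#' Contrastive mode applies independent per-axis reflections (probability
#' 0.5 each) and a photometric jitter: an affine brightness/contrast
#' change of the masked-in intensities (default +/-10% contrast, +/-0.1
#' brightness). The mask itself is never altered by photometric jitter,
#' and masked-out voxels keep the fill value. Supervised mode applies
#' reflections plus a random axis-aligned 90-degree rotation (one of the
#' 24 proper orientations) and no photometric jitter. Mode `none` is the
#' identity.
#'
#' @param view A `segclr_view`.
#' @param mode One of "contrastive", "supervised", "none".
#' @param brightness,contrast Photometric jitter half-ranges.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return An augmented `segclr_view`.
#' @export
augment_view <- function(view, mode = c("contrastive", "supervised", "none"),
                         brightness = 0.1, contrast = 0.1, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(view)
  if (!is.null(seed)) set.seed(seed)
  intensity <- view$intensity
  mask <- view$mask
  flips <- runif(3) < 0.5
  if (any(flips)) {
    intensity <- apply_orientation(intensity, c(1, 2, 3), flips)
    mask <- apply_orientation(mask, c(1, 2, 3), flips)
  }
  if (mode == "supervised") {
    rots <- proper_rotations()
    r <- rots[[sample.int(length(rots), 1)]]
    intensity <- apply_orientation(intensity, r$perm, r$flip)
    mask <- apply_orientation(mask, r$perm, r$flip)
  }
  if (mode == "contrastive") {
    a <- 1 + runif(1, -contrast, contrast)
    b <- runif(1, -brightness, brightness)
    intensity[mask] <- a * intensity[mask] + b
  }
  view$intensity <- intensity
  view$mask <- mask
  view
}

# Stack a list of views into a (vs, vs, vs, 1, n) batch array.
views_to_batch <- function(views) {
  vs <- views[[1]]$view_size
  x <- array(0, dim = c(vs, vs, vs, 1, length(views)))
  for (i in seq_along(views)) x[, , , 1, i] <- views[[i]]$intensity
  x
}
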