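#' Volumetric augmentation policy
#'
#' The positive-pair augmentation pipeline for contrastive pretraining on
#' cubic subtomograms: a random resized crop applied with probability
#' `p_crop` (crop volume fraction drawn from `crop_scale_range`, resampled
#' back to the input side), followed by a random affine applied with
#' probability `p_affine` (rotation about the z axis, in-plane x/y
#' translation by at most `trans_frac_max` of the side, isotropic scaling
#' within `1 +/- scale_frac_max`). Defaults are the pipeline's published
#' operating point: both gates at 50%, crop scale 0.5-1, rotation -45..45
#' degrees, translation and scale deviations at most 0.1.
#'
#' Deliberately absent: photometric jitter (meaningless for density maps),
#' Gaussian blur / gamma / elastic / bias-field (too destructive at these
#' volume sizes), and CTF/MTF corruption (an upstream reconstruction
#' artefact, not an augmentation).
#'
#' @param p_crop,p_affine Gate probabilities in `[0, 1]`, sampled
#'   independently per view.
#' @param crop_scale_range Crop scale interval, a subset of (0, 1].
#' @param crop_scale_mode `"volume"` (scale is the retained volume fraction,
#'   crop side = `side * scale^(1/3)`, the 3-d analogue of area-fraction
#'   cropping) or `"side"` (scale is the side fraction).
#' @param rot_range_deg Rotation interval in degrees, subset of (-180, 180).
#' @param trans_frac_max Max |translation| as a fraction of the side, in
#'   `[0, 0.5)`.
#' @param scale_frac_max Max scale deviation from 1, in `[0, 1)`.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(p_crop = 0.5, crop_scale_range = c(0.5, 1),
                           crop_scale_mode = c("volume", "side"),
                           p_affine = 0.5, rot_range_deg = c(-45, 45),
                           trans_frac_max = 0.1, scale_frac_max = 0.1) {
  crop_scale_mode <- match.arg(crop_scale_mode)
  stopifnot(p_crop >= 0, p_crop <= 1, p_affine >= 0, p_affine <= 1,
            length(crop_scale_range) == 2, crop_scale_range[1] > 0,
            crop_scale_range[2] <= 1, diff(crop_scale_range) >= 0,
            length(rot_range_deg) == 2, all(abs(rot_range_deg) < 180),
            diff(rot_range_deg) >= 0,
            trans_frac_max >= 0, trans_frac_max < 0.5,
            scale_frac_max >= 0, scale_frac_max < 1)
  structure(list(p_crop = p_crop, crop_scale_range = crop_scale_range,
                 crop_scale_mode = crop_scale_mode, p_affine = p_affine,
                 rot_range_deg = rot_range_deg,
                 trans_frac_max = trans_frac_max,
                 scale_frac_max = scale_frac_max),
            class = "augment_policy")
}

#' Sample augmentation parameters
#'
#' Draws `n` independent parameter sets from a policy (gates, crop scale,
#' rotation angle, translations, scale factor) from the ambient RNG stream.
#' The stochastic augmentation operations consume draws from this sampler,
#' so its distribution is the single source of truth for the pipeline's
#' parameter ranges.
#'
#' @param policy An [augment_policy()].
#' @param n Number of draws.
#' @return A tibble with one row per draw.
#' @export
sample_augment_params <- function(policy, n = 1) {
  stopifnot(inherits(policy, "augment_policy"))
  tibble::tibble(
    apply_crop = runif(n) < policy$p_crop,
    crop_scale = runif(n, policy$crop_scale_range[1], policy$crop_scale_range[2]),
    apply_affine = runif(n) < policy$p_affine,
    angle = runif(n, policy$rot_range_deg[1], policy$rot_range_deg[2]),
    tx_frac = runif(n, -policy$trans_frac_max, policy$trans_frac_max),
    ty_frac = runif(n, -policy$trans_frac_max, policy$trans_frac_max),
    scale = runif(n, 1 - policy$scale_frac_max, 1 + policy$scale_frac_max)
  )
}

crop_side_for <- function(side, scale, mode) {
  cs <- if (mode == "volume") round(side * scale^(1 / 3)) else round(side * scale)
  as.integer(min(cs, side))
}

# Extract the cubic block at 0-based corner `lo` with side `cs` and resample
# it back to `side` with align-corners trilinear interpolation (exact
# identity when cs == side and lo == 0).
crop_and_resize <- function(vol, lo, cs) {
  side <- dim(vol)[1]
  if (cs == side && all(lo == 0)) return(vol)
  sc <- if (side > 1) (cs - 1) / (side - 1) else 1
  resample_affine(vol, diag(sc, 3), as.numeric(lo), dim(vol))
}

#' Random resized crop of a cubic volume
#'
#' Extracts a random cubic sub-block whose scale is drawn from
#' `scale_range` at a random in-bounds position and trilinearly resamples it
#' back to the input side. At scale 1 the output equals the input exactly.
#'
#' @param vol Cubic volume of side >= 8.
#' @param scale_range Crop scale interval (see [augment_policy()]).
#' @param mode Interpretation of scale: `"volume"` fraction or `"side"`
#'   fraction.
#' @return Cropped-and-resized volume, same shape as the input.
#' @export
random_resized_crop <- function(vol, scale_range = c(0.5, 1),
                                mode = c("volume", "side")) {
  check_volume(vol, cubic = TRUE)
  mode <- match.arg(mode)
  side <- dim(vol)[1]
  stopifnot(side >= 8)
  if (crop_side_for(side, scale_range[1], mode) < 4) {
    abort("crop scale lower bound yields a crop side below 4 voxels")
  }
  scale <- runif(1, scale_range[1], scale_range[2])
  cs <- crop_side_for(side, scale, mode)
  lo <- sample.int(side - cs + 1L, 3, replace = TRUE) - 1L
  crop_and_resize(vol, lo, cs)
}

#' Deterministic z-axis affine transform of a volume
#'
#' Applies, in one trilinear resampling pass, isotropic scaling by `scale`,
#' rotation by `angle` degrees about the z axis, then translation by
#' `translation` voxels in (x, y) - the fixed composition order of the
#' augmentation pipeline. Out-of-bounds voxels are zero-filled. Grid-aligned
#' transforms (identity, multiples of 90 degrees about the centre, integer
#' translations) are exact.
#'
#' @param vol Cubic volume.
#' @param angle Rotation angle in degrees about z.
#' @param translation Length-2 (x, y) translation in voxels.
#' @param scale Isotropic scale factor (> 0).
#' @return Transformed volume, same shape.
#' @export
affine_transform <- function(vol, angle = 0, translation = c(0, 0), scale = 1) {
  check_volume(vol, cubic = TRUE)
  stopifnot(scale > 0, length(translation) == 2)
  side <- dim(vol)[1]
  ctr <- (side - 1) / 2  # 0-based grid centre
  t3 <- c(translation, 0)
  # output voxel p maps back to source A p + b with A = Rz(-angle)/scale
  A <- rotation_z(-angle) / scale
  b <- rep(ctr, 3) - A %*% (rep(ctr, 3) + t3)
  resample_affine(vol, A, as.numeric(b), dim(vol))
}

#' Random affine augmentation
#'
#' Draws rotation, translation and scale from the policy ranges and applies
#' them via [affine_transform()].
#'
#' @param vol Cubic volume.
#' @param policy An [augment_policy()].
#' @return Transformed volume.
#' @export
random_affine <- function(vol, policy = augment_policy()) {
  check_volume(vol, cubic = TRUE)
  side <- dim(vol)[1]
  p <- sample_augment_params(policy, 1)
  affine_transform(vol, angle = p$angle,
                   translation = c(p$tx_frac, p$ty_frac) * side,
                   scale = p$scale)
}

#' Manufacture a positive pair of augmented views
#'
#' Two independent draws of the stochastic pipeline (crop gate, then affine
#' gate) from one source volume, each z-score normalized - the query and key
#' views consumed by contrastive pretraining. Labels are never consulted.
#'
#' @param vol Cubic volume.
#' @param policy An [augment_policy()].
#' @return A list with elements `x_q`, `x_k` (augmented, normalized volumes)
#'   and `info`, a 2-row tibble recording which gates fired per view.
#' @export
make_pair <- function(vol, policy = augment_policy()) {
  check_volume(vol, cubic = TRUE)
  side <- dim(vol)[1]
  one_view <- function() {
    p <- sample_augment_params(policy, 1)
    v <- vol
    if (p$apply_crop) {
      cs <- crop_side_for(side, p$crop_scale, policy$crop_scale_mode)
      if (cs < 4) abort("crop scale lower bound yields a crop side below 4 voxels")
      lo <- sample.int(side - cs + 1L, 3, replace = TRUE) - 1L
      v <- crop_and_resize(v, lo, cs)
    }
    if (p$apply_affine) {
      v <- affine_transform(v, angle = p$angle,
                            translation = c(p$tx_frac, p$ty_frac) * side,
                            scale = p$scale)
    }
    list(v = normalize_volume(v), info = p[, c("apply_crop", "apply_affine")])
  }
  q <- one_view()
  k <- one_view()
  list(x_q = q$v, x_k = k$v,
       info = dplyr::bind_rows(query = q$info, key = k$info, .id = "view"))
}
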