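#' Parametric macromolecule structure classes
#'
#' Each class is a rigid density motif built from (a) concentric Gaussian
#' radial shells - a class-specific rotation-invariant radial mass profile,
#' the way macromolecules differ in size and compactness - and (b) a set of
#' smaller anisotropic Gaussian blobs with fixed relative geometry that make
#' the motif pose-sensitive. Geometry is a deterministic function of the
#' class index, so class `k` denotes the same structure in every dataset.
#' Coordinates and widths are fractions of the volume side, so a class
#' renders at any resolution; the 3-sigma envelope stays within 0.36 of the
#' side, leaving at least a two-voxel margin for sides >= 16.
#'
#' @param n_classes Number of distinct classes.
#' @return A list of `structure_class` objects with fields `class_id`,
#'   `shells` (k x 3 matrix: fractional radius, width, amplitude),
#'   `centers` (k x 3 fractional blob offsets), `sigmas` (k x 3 fractional
#'   widths) and `amps` (blob amplitudes).
#' @examples
#' cls <- structure_classes(3)
#' vol <- render_structure(cls[[1]], side = 24)
#' @export
structure_classes <- function(n_classes) {
  stopifnot(n_classes >= 1)
  phi <- (sqrt(5) - 1) / 2  # golden-ratio spacing spreads class signatures
  lapply(seq_len(n_classes) - 1L, function(id) {
    local_seed(20011L + 7L * id, {
      # radial profile: a central core plus an outer shell, radii/widths/
      # amplitudes class-specific
      # radial profile from a fixed bank of mutually near-orthogonal slots
      # (a central core plus three well-separated ring radii): the class
      # activates the slot subset encoded by the nonzero 4-bit code of its
      # index, so two radial profiles share energy only where their codes
      # overlap - a structural guarantee of pairwise decorrelation.
      # Per-slot amplitudes are energy-balanced (rings scale as 1/r) and
      # modulated per class.
      code <- (id %% 15L) + 1L
      on <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0)
      slot_r <- c(0, 0.12, 0.18, 0.24)
      slot_w <- c(0.02 + 0.015 * ((id * sqrt(3)) %% 1), 0.024, 0.024, 0.024)
      mod <- 0.75 + 0.5 * ((id * sqrt(c(2, 5, 7, 11))) %% 1)
      # equalize the L2 mass of every active slot: squared-density integrals
      # are pi^1.5 sigma^3 for the core and ~4 pi r^2 w sqrt(pi) for a ring
      e_slot <- c(pi^1.5 * slot_w[1]^3, 4 * pi * slot_r[-1]^2 * slot_w[-1] * sqrt(pi))
      slot_a <- mod * sqrt(e_slot[2] / e_slot)
      shells <- cbind(slot_r[on], slot_w[on], slot_a[on])
      colnames(shells) <- c("r", "w", "a")
      # anisotropic decorations
      k <- 4L + id %% 3L
      dirs <- matrix(rnorm(3 * k), ncol = 3)
      dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
      centers <- dirs * runif(k, 0.07, 0.17)
      sigmas <- matrix(runif(3 * k, 0.03, 0.045), ncol = 3)
      amps <- runif(k, 0.55, 0.8)
      # recentre the decorations on their integrated-mass centroid so the
      # motif centroid sits at the volume centre (shells contribute zero)
      mass <- amps * apply(sigmas, 1, prod)
      centers <- sweep(centers, 2, colSums(centers * mass) / sum(mass))
      r <- max(sqrt(rowSums(centers^2)))
      if (r > 0.18) centers <- centers * (0.18 / r)
      structure(
        list(class_id = id, shells = shells, centers = centers,
             sigmas = sigmas, amps = amps),
        class = "structure_class"
      )
    })
  })
}

# Fractional extent of the motif envelope: max over shells (radius + 3w) and
# blobs (centre offset + 3 sigma); invariant under rotation.
motif_extent <- function(cls) {
  max(max(cls$shells[, "r"] + 3 * cls$shells[, "w"]),
      max(sqrt(rowSums(cls$centers^2)) + 3 * apply(cls$sigmas, 1, max)))
}

voxel_grids <- function(side) {
  g <- seq_len(side)
  gx <- array(g, c(side, side, side))
  list(x = gx, y = aperm(gx, c(2, 1, 3)), z = aperm(gx, c(3, 2, 1)))
}

# Evaluate the motif density on the voxel grid: radial shells centred at
# `origin` (voxel coords) plus rotated anisotropic Gaussians at `centers`.
# sigmas_vox: k x 3 voxel widths in the motif frame; rot applies to blobs
# (shells are rotation-invariant by construction).
render_motif <- function(side, origin, shells_vox, centers, sigmas_vox, amps,
                         rot) {
  g <- voxel_grids(side)
  vol <- array(0, c(side, side, side))
  dist <- sqrt((g$x - origin[1])^2 + (g$y - origin[2])^2 +
                 (g$z - origin[3])^2)
  for (i in seq_len(nrow(shells_vox))) {
    vol <- vol + shells_vox[i, "a"] *
      exp(-0.5 * ((dist - shells_vox[i, "r"]) / shells_vox[i, "w"])^2)
  }
  for (i in seq_len(nrow(centers))) {
    # precision matrix of the rotated component: R diag(1/sig^2) R'
    p <- rot %*% diag(1 / sigmas_vox[i, ]^2, 3) %*% t(rot)
    dx <- g$x - centers[i, 1]
    dy <- g$y - centers[i, 2]
    dz <- g$z - centers[i, 3]
    q <- p[1, 1] * dx * dx + p[2, 2] * dy * dy + p[3, 3] * dz * dz +
      2 * (p[1, 2] * dx * dy + p[1, 3] * dx * dz + p[2, 3] * dy * dz)
    vol <- vol + amps[i] * exp(-0.5 * q)
  }
  vol
}

#' Render a posed structure into a cubic volume
#'
#' Places the class motif at the grid centre under a rigid pose (proper
#' rotation plus translation). With `rotation = NULL` a uniform random
#' rotation and a translation keeping the motif centroid inside the central
#' third of the volume are drawn from the ambient RNG stream; poses whose
#' 3-sigma envelope would leave the in-bounds margin are resampled (bounded
#' retries). An explicitly supplied out-of-bounds pose is an error.
#'
#' @param cls A `structure_class`.
#' @param side Volume side length in voxels (>= 8).
#' @param rotation Optional 3x3 proper rotation matrix.
#' @param translation Optional length-3 translation in voxels; the motif
#'   centroid must stay within the central third of the volume. Random poses
#'   draw a small jitter (up to 1% of the side, emulating residual
#'   particle-picking offset) rather than the full central-third excursion.
#' @param margin In-bounds margin in voxels (default 2).
#' @param max_tries Pose resampling budget when the pose is random.
#' @return A non-negative `side^3` density array.
#' @export
render_structure <- function(cls, side, rotation = NULL, translation = NULL,
                             margin = 2, max_tries = 25L) {
  stopifnot(inherits(cls, "structure_class"), side >= 8)
  ctr <- (side + 1) / 2
  explicit <- !is.null(rotation) || !is.null(translation)
  if (!is.null(rotation)) {
    if (!all(dim(rotation) == c(3, 3)) ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
        det(rotation) < 0) {
      abort("`rotation` must be a proper 3-d rotation matrix")
    }
  }
  ext <- motif_extent(cls) * side  # rotation-invariant envelope radius
  lim <- side / 6  # central third of the volume, about the centre
  half_avail <- (side - 1) / 2 - margin
  t_max <- min(lim, 0.01 * side, half_avail - ext)
  if (is.null(translation) && t_max < 0) {
    abort(sprintf("class %d motif (envelope %.1f voxels) cannot fit side %d with margin %g",
                  cls$class_id, ext, side, margin))
  }
  for (try in seq_len(max_tries)) {
    rot <- rotation %||% random_rotation()
    tr <- translation %||% runif(3, -t_max, t_max)
    if (any(abs(tr) > lim + 1e-9)) {
      abort("`translation` must keep the motif centroid inside the central third")
    }
    ok <- all(ctr + tr - ext >= 1 + margin) && all(ctr + tr + ext <= side - margin)
    if (ok) {
      centers <- t(rot %*% t(cls$centers * side)) +
        matrix(ctr + tr, nrow(cls$centers), 3, byrow = TRUE)
      shells <- cls$shells * side
      return(render_motif(side, ctr + tr, shells, centers,
                          cls$sigmas * side, cls$amps, rot))
    }
    if (explicit) abort("posed motif exceeds the volume bounds")
  }
  abort(sprintf("no in-bounds pose found for class %d after %d tries",
                cls$class_id, max_tries))
}

#' Superimpose random neighbouring structures
#'
#' Adds `n` motifs of random class and pose with centroids placed outside the
#' central third of the volume, emulating the crowded neighbourhood around a
#' target particle. Additions are purely additive, so the target density is
#' unchanged wherever neighbours do not overlap; overlap with the target is
#' allowed (that crowding is the point).
#'
#' @param vol Target volume (cubic array).
#' @param classes List of `structure_class` objects to draw neighbours from.
#' @param n Number of neighbours (>= 0).
#' @return The volume with neighbours added.
#' @export
add_neighbors <- function(vol, classes, n) {
  check_volume(vol, cubic = TRUE)
  stopifnot(n >= 0)
  if (n == 0) return(vol)
  side <- dim(vol)[1]
  lim <- side / 6
  for (i in seq_len(n)) {
    cls <- classes[[sample.int(length(classes), 1)]]
    rot <- random_rotation()
    # centroid anywhere in the margin-respecting box but outside the
    # central third; neighbours may clip the boundary (their tails truncate)
    repeat {
      pos <- runif(3, 3, side - 2)
      if (any(abs(pos - (side + 1) / 2) > lim)) break
    }
    centers <- t(rot %*% t(cls$centers * side)) +
      matrix(pos, nrow(cls$centers), 3, byrow = TRUE)
    vol <- vol + render_motif(side, pos, cls$shells * side, centers,
                              cls$sigmas * side, cls$amps, rot)
  }
  vol
}

#' Apply the tomographic missing wedge in Fourier space
#'
#' Zeroes every 3D Fourier coefficient whose frequency vector lies inside the
#' double wedge of half-angle `wedge_half_angle` about the beam (z) axis,
#' i.e. where `atan2(|kx|, |kz|) < w`, emulating the unsampled region left by
#' a limited tilt series about the y axis (half-angle 30 degrees corresponds
#' to the conventional +/-60 degree tilt range). The mask is symmetric under
#' k -> -k, so the filtered volume is real up to round-off; the real part is
#' returned.
#'
#' Note the discrete geometry: the kx = 0, kz != 0 plane (the never-tilted
#' beam axis) lies inside the wedge for every positive half-angle, so the
#' zeroed set shrinks to that plane, not to the empty set, as the angle
#' approaches zero.
#'
#' @param vol Cubic volume.
#' @param wedge_half_angle Missing-wedge half-angle in degrees, in (0, 90).
#' @return Filtered volume, same shape.
#' @export
apply_missing_wedge <- function(vol, wedge_half_angle = 30) {
  check_volume(vol, cubic = TRUE)
  stopifnot(wedge_half_angle > 0, wedge_half_angle < 90)
  n <- dim(vol)[1]
  f <- seq_len(n) - 1L
  f <- ifelse(f > n / 2, f - n, f)  # signed integer frequencies
  kx <- array(f, c(n, n, n))
  kz <- aperm(kx, c(3, 2, 1))
  mask <- missing_wedge_mask(kx, kz, wedge_half_angle)
  sp <- fft(vol)
  sp[mask] <- 0
  out <- fft(sp, inverse = TRUE) / length(sp)
  if (max(Mod(Im(out))) > 1e-6 * max(1e-12, max(Mod(out)))) {
    warn("missing-wedge filter left a non-negligible imaginary part")
  }
  array(Re(out), dim(vol))
}

# TRUE where the (kx, kz) direction lies strictly inside the double wedge.
missing_wedge_mask <- function(kx, kz, wedge_half_angle) {
  ang <- atan2(abs(kx), abs(kz))
  ang < wedge_half_angle * pi / 180 & !(kx == 0 & kz == 0)
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' SNR is defined as Var(signal) / Var(noise), the usual cryo-ET convention;
#' zero-mean Gaussian noise with variance `var(vol)/snr` is added. `snr = Inf`
#' returns the input unchanged (the noiseless dataset).
#'
#' @param vol Volume.
#' @param snr Positive real or `Inf`.
#' @return Noisy volume.
#' @export
add_noise_at_snr <- function(vol, snr) {
  check_volume(vol)
  stopifnot(snr > 0)
  if (is.infinite(snr)) return(vol)
  v <- var(as.vector(vol))
  if (v == 0) abort("SNR is undefined for a zero-variance signal")
  vol + array(rnorm(length(vol), sd = sqrt(v / snr)), dim(vol))
}

#' Simulation configuration
#'
#' Defaults reproduce the shape of the simulated study datasets: 10 classes,
#' 500 subtomograms per class at side 32, SNR one of Inf / 0.05 / 0.03,
#' a 30-degree missing wedge, several (2-6) neighbouring macromolecules, and
#' a 60:20:20 train/validation/test split.
#'
#' @param side_length Voxels per side (>= 8).
#' @param n_classes Number of structure classes.
#' @param per_class Volumes per class.
#' @param n_neighbors_range Integer interval the per-volume neighbour count
#'   is drawn from (uniformly).
#' @param snr Signal-to-noise ratio (positive or Inf).
#' @param wedge_half_angle Missing-wedge half-angle in degrees.
#' @param split_ratio Length-3 positive weights for train/val/test.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   this configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(side_length = 32, n_classes = 10, per_class = 500,
                       n_neighbors_range = c(2L, 6L), snr = Inf,
                       wedge_half_angle = 30, split_ratio = c(3, 1, 1),
                       seed = 1L) {
  stopifnot(side_length >= 8, n_classes >= 1, per_class >= 1,
            snr > 0, wedge_half_angle > 0, wedge_half_angle < 90,
            length(n_neighbors_range) == 2, n_neighbors_range[1] >= 0,
            n_neighbors_range[2] >= n_neighbors_range[1],
            length(split_ratio) == 3, all(split_ratio > 0))
  structure(list(side_length = as.integer(side_length),
                 n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 n_neighbors_range = as.integer(n_neighbors_range),
                 snr = snr, wedge_half_angle = wedge_half_angle,
                 split_ratio = split_ratio / sum(split_ratio),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Contiguous per-class partition sizes: val and test floor, train absorbs the
# remainder, so every class reaches the training split even at per_class = 1.
split_counts <- function(n, ratio) {
  n_val <- floor(n * ratio[2])
  n_test <- floor(n * ratio[3])
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Generate a labelled synthetic subtomogram dataset
#'
#' For each volume: render the target class motif under a random pose, add a
#' random number of neighbouring motifs, apply the missing-wedge filter, and
#' add Gaussian noise at the configured SNR. Volumes are written as MRC
#' (mode 2, float32), one file per subtomogram, alongside `manifest.csv`.
#' Split assignment is a seeded shuffle within each class followed by a
#' contiguous partition, so classes are balanced in every split. The whole
#' dataset is bit-reproducible from the configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return The dataset manifest, a tibble with columns `id`, `path`
#'   (absolute), `class_id`, `split`, invisibly.
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))
  classes <- structure_classes(cfg$n_classes)
  n_total <- cfg$n_classes * cfg$per_class
  ids <- sprintf("vol_%05d", seq_len(n_total))
  class_id <- rep(seq_len(cfg$n_classes) - 1L, each = cfg$per_class)
  local_seed(cfg$seed, {
    split <- unlist(lapply(seq_len(cfg$n_classes), function(ci) {
      cnt <- split_counts(cfg$per_class, cfg$split_ratio)
      s <- rep(c("train", "val", "test"), times = cnt)
      s[order(sample.int(cfg$per_class))]
    }), use.names = FALSE)
    paths <- file.path(normalizePath(dir), paste0(ids, ".mrc"))
    for (i in seq_len(n_total)) {
      vol <- render_structure(classes[[class_id[i] + 1L]], cfg$side_length)
      n_nb <- sample(seq(cfg$n_neighbors_range[1], cfg$n_neighbors_range[2]), 1)
      vol <- add_neighbors(vol, classes, n_nb)
      vol <- apply_missing_wedge(vol, cfg$wedge_half_angle)
      vol <- add_noise_at_snr(vol, cfg$snr)
      write_volume(vol, paths[i])
    }
    man <- tibble::tibble(id = ids, path = paths, class_id = class_id,
                          split = split)
    write_manifest(man, file.path(dir, "manifest.csv"))
    invisible(man)
  })
}
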