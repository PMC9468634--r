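test_that("rendering is deterministic and places the canonical motif at the centre", {
  cls <- structure_classes(3)
  v1 <- render_structure(cls[[1]], side = 16, rotation = diag(3),
                         translation = c(0, 0, 0))
  v2 <- render_structure(cls[[1]], side = 16, rotation = diag(3),
                         translation = c(0, 0, 0))
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0))
  expect_equal(dim(v1), c(16, 16, 16))
  # density-weighted centroid sits at the grid centre
  g <- seq_len(16)
  w <- sum(v1)
  cent <- c(sum(apply(v1, 1, sum) * g), sum(apply(v1, 2, sum) * g),
            sum(apply(v1, 3, sum) * g)) / w
  # exact up to edge truncation of the Gaussian tails
  expect_lt(max(abs(cent - (16 + 1) / 2)), 0.05)
  # seeded random poses reproduce bit-identically
  set.seed(5); a <- render_structure(cls[[2]], 16)
  set.seed(5); b <- render_structure(cls[[2]], 16)
  expect_identical(a, b)
})

test_that("a 90-degree z rotation equals the axis permutation of the identity render", {
  cls <- structure_classes(4)
  r90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  for (i in c(1, 4)) {
    vid <- render_structure(cls[[i]], 16, rotation = diag(3), translation = c(0, 0, 0))
    vrot <- render_structure(cls[[i]], 16, rotation = r90, translation = c(0, 0, 0))
    # oracle: out[i,j,k] = in[j, S+1-i, k]
    expected <- aperm(vid[, 16:1, ], c(2, 1, 3))
    expect_equal(vrot, expected, tolerance = 1e-10)
  }
})

test_that("invalid poses are rejected", {
  cls <- structure_classes(1)
  expect_error(render_structure(cls[[1]], 16, rotation = diag(2)), "rotation")
  expect_error(render_structure(cls[[1]], 16, rotation = diag(3) * 2), "rotation")
  expect_error(
    render_structure(cls[[1]], 16, rotation = diag(3), translation = c(10, 0, 0)),
    "central third")
})

test_that("distinct classes decorrelate below 0.9 cross-correlation", {
  cls <- structure_classes(10)
  vols <- lapply(cls, function(c)
    render_structure(c, 32, rotation = diag(3), translation = c(0, 0, 0)))
  ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  worst <- 0
  for (i in 1:9) for (j in (i + 1):10) worst <- max(worst, ncc(vols[[i]], vols[[j]]))
  expect_lt(worst, 0.9)
})

test_that("neighbours only add density and are reproducible", {
  cls <- structure_classes(3)
  set.seed(2)
  v <- render_structure(cls[[1]], 16)
  expect_identical(add_neighbors(v, cls, 0), v)
  set.seed(7); n1 <- add_neighbors(v, cls, 3)
  set.seed(7); n2 <- add_neighbors(v, cls, 3)
  expect_identical(n1, n2)
  expect_gt(sum(n1), sum(v))
  expect_true(all(n1 - v >= -1e-12))
})

test_that("missing wedge zeroes exactly the enumerated in-wedge coefficients", {
  n <- 16
  delta <- array(0, c(n, n, n)); delta[1, 1, 1] <- 1
  out <- apply_missing_wedge(delta, 30)
  sp <- fft(out)
  # independent enumeration of integer frequency vectors inside the wedge
  f <- 0:(n - 1); f <- ifelse(f > n / 2, f - n, f)
  inside <- 0
  mask <- array(FALSE, c(n, n, n))
  for (ix in 1:n) for (iz in 1:n) {
    kx <- f[ix]; kz <- f[iz]
    if (atan2(abs(kx), abs(kz)) < 30 * pi / 180 && !(kx == 0 && kz == 0)) {
      mask[ix, , iz] <- TRUE
      inside <- inside + n
    }
  }
  expect_gt(inside, 0)
  expect_lt(max(Mod(sp[mask])), 1e-10)
  # delta spectrum is flat, so everything outside the wedge survives
  expect_gt(min(Mod(sp[!mask])), 0.5)
})

test_that("missing wedge preserves realness, shape and errors on non-cubic input", {
  set.seed(3)
  v <- array(rnorm(16^3), c(16, 16, 16))
  out <- apply_missing_wedge(v, 30)
  expect_equal(dim(out), dim(v))
  expect_true(is.numeric(out))
  sp_in <- fft(v); sp_out <- fft(out)
  f <- 0:15; f <- ifelse(f > 8, f - 16, f)
  kx <- array(f, c(16, 16, 16)); kz <- aperm(kx, c(3, 2, 1))
  mask <- cryocssl:::missing_wedge_mask(kx, kz, 30)
  # untouched coefficients are preserved, masked ones vanish
  expect_lt(max(Mod(sp_out[!mask] - sp_in[!mask])) / max(Mod(sp_in)), 1e-10)
  expect_lt(max(Mod(sp_out[mask])) / max(Mod(sp_in)), 1e-10)
  expect_error(apply_missing_wedge(array(0, c(8, 8, 4)), 30), "cubic")
  expect_error(apply_missing_wedge(v, 0))
  expect_error(apply_missing_wedge(v, 90))
})

test_that("the small-angle wedge limit shrinks to the untiltable axis plane", {
  set.seed(4)
  n <- 16
  # a volume constant along z has no spectral energy off the kz = 0 plane,
  # hence no energy on the kx = 0, kz != 0 line: tiny wedges leave it intact
  slice <- matrix(rnorm(n^2), n, n)
  vz <- array(rep(slice, n), c(n, n, n))
  out <- apply_missing_wedge(vz, 0.5)
  expect_equal(out, vz, tolerance = 1e-12)
  # the zeroed set shrinks monotonically with the angle
  count_zeroed <- function(w) {
    f <- 0:(n - 1); f <- ifelse(f > n / 2, f - n, f)
    kx <- array(f, c(n, n, n)); kz <- aperm(kx, c(3, 2, 1))
    sum(atan2(abs(kx), abs(kz)) < w * pi / 180 & !(kx == 0 & kz == 0))
  }
  expect_true(all(diff(sapply(c(0.5, 10, 30, 60), count_zeroed)) > 0))
  expect_equal(count_zeroed(0.5), n * n - n)  # just the kx=0, kz!=0 plane
})

test_that("noise injection hits the configured signal-to-noise ratio", {
  set.seed(8)
  v <- array(rnorm(32^3), c(32, 32, 32))  # unit-variance signal
  expect_identical(add_noise_at_snr(v, Inf), v)
  noisy <- add_noise_at_snr(v, 0.05)
  expect_equal(var(as.vector(noisy - v)), 20, tolerance = 0.1 * 20)
  noisy1 <- add_noise_at_snr(v, 1)
  snr_hat <- var(as.vector(v)) / var(as.vector(noisy1 - v))
  expect_gt(snr_hat, 0.9); expect_lt(snr_hat, 1.1)
  expect_error(add_noise_at_snr(array(1, c(4, 4, 4)), 1), "zero-variance")
})

test_that("split arithmetic matches the study dataset shapes", {
  cnt <- cryocssl:::split_counts(500, c(0.6, 0.2, 0.2))
  expect_equal(unname(cnt), c(300, 100, 100))     # x10 classes: 3000/1000/1000
  cnt2 <- cryocssl:::split_counts(400, c(3, 1, 1) / 5)
  expect_equal(unname(cnt2), c(240, 80, 80))      # x7 classes: 1680/560/560
  cnt3 <- cryocssl:::split_counts(1, c(0.6, 0.2, 0.2))
  expect_equal(unname(cnt3), c(1, 0, 0))          # degenerate: train wins
})

test_that("generated datasets are balanced, well-formed and bit-reproducible", {
  man <- micro_manifest()
  expect_equal(nrow(man), 12)
  tab <- table(man$class_id, man$split)
  expect_true(all(tab[, "train"] == 4))
  expect_true(all(tab[, "val"] == 1))
  expect_true(all(tab[, "test"] == 1))
  expect_false(anyDuplicated(man$id) > 0)
  # regenerating under the same config reproduces every byte
  cfg <- sim_config(side_length = 12, n_classes = 2, per_class = 6, snr = Inf,
                    n_neighbors_range = c(0, 1), wedge_half_angle = 30,
                    split_ratio = c(4, 1, 1), seed = 21)
  dir2 <- file.path(tempdir(), "cryocssl-regen")
  man2 <- generate_dataset(cfg, dir2)
  expect_equal(man2$class_id, man$class_id)
  expect_equal(man2$split, man$split)
  for (i in c(1, 5, 12)) {
    expect_identical(readBin(man$path[i], "raw", file.size(man$path[i])),
                     readBin(man2$path[i], "raw", file.size(man2$path[i])))
  }
})
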