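#' Read a subtomogram volume from an MRC file
#'
#' Supports the standard 1024-byte-header MRC format, mode 2 (float32),
#' little-endian, as written by [write_volume()] and by mainstream cryo-EM
#' software. The volume is returned as a numeric 3-d array with the x index
#' fastest, matching R's column-major layout. Non-cubic volumes are read
#' as-is; model-facing validation happens later.
#'
#' @param path Path to an `.mrc` file.
#' @return A numeric 3-d array.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such volume file: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 4, size = 4, endian = "little")
  if (length(hdr) < 4) abort(sprintf("'%s': truncated MRC header", path))
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e4)) {
    abort(sprintf("'%s': corrupt MRC header (dims %d x %d x %d)", path, nx, ny, nz))
  }
  if (mode != 2L) {
    abort(sprintf("'%s': unsupported MRC mode %d (only mode 2, float32)", path, mode))
  }
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  dat <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(dat) < n) {
    abort(sprintf("'%s': truncated MRC data (expected %d voxels, got %d)",
                  path, n, length(dat)))
  }
  array(dat, c(nx, ny, nz))
}

#' Write a volume as MRC (mode 2, float32)
#'
#' @param vol Numeric 3-d array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  check_volume(vol)
  check_finite(vol)
  d <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2 = float32
  wi(c(0, 0, 0))                          # nxstart
  wi(d)                                   # mx my mz
  wf(d)                                   # cell dimensions (1 A / voxel)
  wf(c(90, 90, 90))                       # cell angles
  wi(c(1, 2, 3))                          # axis order
  wf(c(min(vol), max(vol), mean(vol)))    # dmin dmax dmean
  wi(1)                                   # ispg: volume
  wi(0)                                   # nsymbt
  writeBin(raw(25 * 4), con)              # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.vector(vol)))                  # rms
  wi(0)                                   # nlabl
  writeBin(raw(200 * 4), con)             # labels
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

#' Per-volume z-score normalization
#'
#' Maps a volume to zero mean and unit variance (constant volumes map to
#' all-zeros). Applied to every volume before both pretraining and
#' fine-tuning so that intensity scales are comparable across SNR settings.
#'
#' @param vol Numeric 3-d array with finite values.
#' @return Normalized volume.
#' @export
normalize_volume <- function(vol) {
  check_volume(vol)
  check_finite(vol)
  s <- sd(as.vector(vol))
  if (s == 0) return(array(0, dim(vol)))
  (vol - mean(vol)) / s
}

check_manifest <- function(man) {
  need <- c("id", "path", "class_id", "split")
  if (!is.data.frame(man) || !all(need %in% names(man))) {
    abort("a manifest needs columns id, path, class_id, split")
  }
  if (anyDuplicated(man$id)) abort("manifest ids must be unique")
  if (!all(man$split %in% c("train", "val", "test"))) {
    abort("manifest split must be one of train/val/test")
  }
  if ("labelled" %in% names(man) &&
      any(man$labelled & man$split != "train", na.rm = TRUE)) {
    abort("labelled flags are only allowed on training records")
  }
  invisible(man)
}

#' Write / read a dataset manifest CSV
#'
#' Columns `id, path, class_id, split` plus an optional `labelled` flag on
#' training records. Paths are stored relative to the CSV location and
#' resolved back to absolute paths on read. Writing asserts that no val/test
#' record carries a labelled flag (no label leakage across splits).
#'
#' @param man Manifest tibble.
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest tibble with absolute paths;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(man, path) {
  check_manifest(man)
  out <- man
  base <- paste0(normalizePath(dirname(path)), "/")
  p <- normalizePath(out$path, mustWork = FALSE)
  hit <- startsWith(p, base)
  p[hit] <- substring(p[hit], nchar(base) + 1L)
  out$path <- p
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  base <- normalizePath(dirname(path))
  abs <- !grepl("^/", man$path)
  man$path[abs] <- file.path(base, man$path[abs])
  man$class_id <- as.integer(man$class_id)
  check_manifest(man)
  man
}

#' Flag a stratified labelled subset of the training split
#'
#' Marks exactly `round(fraction * n_train)` training records as labelled,
#' sampled per class proportionally (largest-remainder apportionment across
#' classes, deterministic under `seed`). Validation and test records are
#' never flagged. This is the label-fraction mask of the semi-supervised
#' protocol (25/50/75/100% of the training set).
#'
#' @param man Dataset manifest.
#' @param fraction Labelled fraction in (0, 1].
#' @param seed Integer seed for the per-class sampling.
#' @return The manifest with a logical `labelled` column.
#' @export
subsample_labels <- function(man, fraction, seed = 1L) {
  check_manifest(man)
  stopifnot(fraction > 0, fraction <= 1)
  tr <- which(man$split == "train")
  n_target <- round(fraction * length(tr))
  cls <- sort(unique(man$class_id[tr]))
  per_cls <- vapply(cls, function(ci) sum(man$class_id[tr] == ci), integer(1))
  base <- floor(fraction * per_cls)
  rem <- n_target - sum(base)
  if (rem > 0) {
    # largest fractional remainder first; ties broken by class id
    ord <- order(-(fraction * per_cls - base), cls)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(fraction * per_cls - base, cls)
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1L
  }
  if (any(base < 1)) {
    abort(sprintf("fraction %.3f leaves class %d with no labelled record",
                  fraction, cls[which(base < 1)[1]]))
  }
  man$labelled <- FALSE
  local_seed(seed, {
    for (j in seq_along(cls)) {
      pool <- tr[man$class_id[tr] == cls[j]]
      man$labelled[pool[sample.int(length(pool), base[j])]] <- TRUE
    }
  })
  man
}
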