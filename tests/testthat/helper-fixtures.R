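# Shared fixtures, generated once per test run and cached in tempdir().

fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(name, cfg) {
  if (!is.null(fixture_env[[name]])) return(fixture_env[[name]])
  dir <- file.path(tempdir(), paste0("cryocssl-fix-", name))
  if (!file.exists(file.path(dir, "manifest.csv"))) generate_dataset(cfg, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  fixture_env[[name]] <- man
  man
}

# 12 volumes at 12^3, 2 classes: the cheapest trainable dataset
micro_manifest <- function() {
  fixture_dataset("micro", sim_config(
    side_length = 12, n_classes = 2, per_class = 6, snr = Inf,
    n_neighbors_range = c(0, 1), wedge_half_angle = 30,
    split_ratio = c(4, 1, 1), seed = 21))
}

# the desk-scale study conditions: 3 classes x 50 volumes at 16^3, SNR 0.5,
# moderate crowding
tiny_manifest <- function() {
  fixture_dataset("tiny", sim_config(
    side_length = 16, n_classes = 3, per_class = 50, snr = 0.5,
    n_neighbors_range = c(1, 3), seed = 11))
}

# noiseless, neighbour-free counterpart of the desk-scale set
clean_manifest <- function() {
  fixture_dataset("clean", sim_config(
    side_length = 16, n_classes = 3, per_class = 50, snr = Inf,
    n_neighbors_range = c(0, 0), seed = 11))
}

micro_encoder <- function(n_classes = 2) {
  encoder_config(in_side = 12, n_classes = n_classes, base_filters = 4,
                 n_stages = 1, fc_width = 16, embed_dim = 8,
                 stem_pool = TRUE, use_concat = FALSE)
}

tiny_encoder <- function(n_classes = 3) {
  encoder_config(in_side = 16, n_classes = n_classes, tiny_mode = TRUE)
}

desk_pretrain_control <- function(epochs = 20) {
  pretrain_control(queue_size = 32, batch_size = 16, epochs = epochs,
                   lr = 1e-4, momentum = 0.9)
}

desk_finetune_control <- function(epochs = 15) {
  finetune_control(lr = 2e-3, epochs = epochs)
}

load_split_vols <- function(man, split) {
  rows <- man[man$split == split, ]
  list(vols = lapply(rows$path, function(p) normalize_volume(read_volume(p))),
       labels = rows$class_id)
}

# nearest-centroid classifier on raw (normalized) voxels
centroid_accuracy <- function(man) {
  tr <- load_split_vols(man, "train")
  te <- load_split_vols(man, "test")
  Xtr <- t(vapply(tr$vols, as.vector, numeric(length(tr$vols[[1]]))))
  Xte <- t(vapply(te$vols, as.vector, numeric(length(te$vols[[1]]))))
  cls <- sort(unique(tr$labels))
  cents <- vapply(cls, function(c) colMeans(Xtr[tr$labels == c, , drop = FALSE]),
                  numeric(ncol(Xtr)))
  pred <- cls[apply(Xte, 1, function(v) which.min(colSums((cents - v)^2)))]
  100 * mean(pred == te$labels)
}

random_unit_rows <- function(n, l) {
  m <- matrix(rnorm(n * l), n, l)
  m / sqrt(rowSums(m^2))
}
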