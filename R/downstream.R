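#' Fine-tuning hyperparameters
#'
#' Defaults are the published fine-tuning settings: SGD with cosine decay,
#' learning rate 5e-4, weight decay 1e-4, batch size 16, 50 epochs, best
#' validation-accuracy checkpoint kept. `sgd_momentum` (0.9) is the
#' package's choice; the schedule applies to the learning rate only.
#'
#' @param lr Initial learning rate.
#' @param weight_decay L2 weight decay.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (0 is a no-op returning initial weights).
#' @param sgd_momentum Classical momentum coefficient.
#' @param schedule `"cosine"` or `"constant"`.
#' @return A `finetune_control` list.
#' @export
finetune_control <- function(lr = 5e-4, weight_decay = 1e-4, batch_size = 16,
                             epochs = 50, sgd_momentum = 0.9,
                             schedule = c("cosine", "constant")) {
  schedule <- match.arg(schedule)
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0,
            sgd_momentum >= 0, sgd_momentum < 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), sgd_momentum = sgd_momentum,
                 schedule = schedule),
            class = "finetune_control")
}

load_labelled <- function(manifest, split, labelled_only = FALSE) {
  check_manifest(manifest)
  keep <- manifest$split == split
  if (labelled_only) {
    if (!"labelled" %in% names(manifest)) {
      keep_lab <- keep          # no mask: the full training set is labelled
    } else {
      keep_lab <- keep & manifest$labelled
    }
    keep <- keep_lab
  }
  idx <- which(keep)
  list(vols = lapply(manifest$path[idx],
                     function(p) normalize_volume(read_volume(p))),
       labels = manifest$class_id[idx], ids = manifest$id[idx])
}

batch_forward_probs <- function(model, vols, chunk = 32L) {
  n <- length(vols)
  out <- vector("list", ceiling(n / chunk))
  for (i in seq_along(out)) {
    take <- ((i - 1) * chunk + 1):min(i * chunk, n)
    x <- stack_volumes(vols[take])
    out[[i]] <- encoder_forward(model, x, head = "class")$probs
  }
  do.call(rbind, out)
}

accuracy_pct <- function(probs, labels) {
  pred <- max.col(probs, ties.method = "first") - 1L
  100 * mean(pred == labels)
}

#' Fine-tune a classifier on the labelled subset
#'
#' Supervised cross-entropy training of the full encoder (no frozen layers)
#' starting from contrastive-pretrained or random initial weights, with SGD
#' and a cosine learning-rate schedule. Validation accuracy is evaluated
#' after every epoch and the parameters of the best epoch are returned
#' (ties resolved to the earliest epoch). With `epochs = 0` the initial
#' weights are returned unchanged.
#'
#' @param pretrained A `cssl_pretrain` object, a checkpoint from
#'   [load_weights()], or `NULL` for random initialization.
#' @param manifest Dataset manifest; training records flagged by
#'   [subsample_labels()] are used (all of them if no `labelled` column).
#' @param encoder An [encoder_config()]; required when `pretrained` is
#'   `NULL`, otherwise it must match the checkpoint fingerprint.
#' @param control A [finetune_control()].
#' @param seed Integer seed (initialization and batch order).
#' @return A `cssl_classifier`: the best-epoch model, provenance, and a
#'   per-epoch history tibble (`epoch`, `lr`, `train_loss`, `val_acc`).
#' @export
finetune <- function(pretrained = NULL, manifest, encoder = NULL,
                     control = finetune_control(), seed = 1L) {
  stopifnot(inherits(control, "finetune_control"))
  if (!is.null(pretrained)) {
    cfg <- pretrained$config
    if (!is.null(encoder) &&
        !identical(encoder$fingerprint, cfg$fingerprint)) {
      abort("`encoder` does not match the pretrained checkpoint fingerprint")
    }
    init_params <- pretrained$weights
    provenance <- pretrained$provenance %||% "cssl_pretrained"
    method <- pretrained$method %||% "pretrained"
  } else {
    if (is.null(encoder)) abort("`encoder` is required for random initialization")
    cfg <- encoder
    init_params <- NULL
    provenance <- "random_init"
    method <- "random_init"
  }
  tr <- load_labelled(manifest, "train", labelled_only = TRUE)
  if (length(tr$vols) == 0) abort("no labelled training records")
  train_classes <- sort(unique(manifest$class_id[manifest$split == "train"]))
  missing_cls <- setdiff(train_classes, unique(tr$labels))
  if (length(missing_cls) > 0) {
    abort(sprintf("labelled subset misses class(es): %s",
                  paste(missing_cls, collapse = ", ")))
  }
  if (max(tr$labels) >= cfg$n_classes) {
    abort("manifest contains a class index outside the model head")
  }
  va <- load_labelled(manifest, "val")
  local_seed(seed, {
    model <- build_encoder(cfg)
    if (!is.null(init_params)) model$params <- init_params
    model$provenance <- provenance
    if (control$epochs == 0) {
      return(structure(list(model = model, provenance = provenance,
                            method = method, best_epoch = 0L, seed = seed,
                            history = tibble::tibble(epoch = integer(),
                                                     lr = numeric(),
                                                     train_loss = numeric(),
                                                     val_acc = numeric())),
                       class = "cssl_classifier"))
    }
    opt <- sgd_init(model$params)
    n <- length(tr$vols)
    B <- min(control$batch_size, n)
    best <- list(acc = -Inf, epoch = 0L, params = model$params)
    hist <- vector("list", control$epochs)
    for (epoch in seq_len(control$epochs)) {
      lr <- if (control$schedule == "cosine") {
        cosine_lr(control$lr, epoch, control$epochs)
      } else control$lr
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = B)) {
        take <- ord[start:min(start + B - 1, n)]
        x <- stack_volumes(tr$vols[take])
        y <- tr$labels[take]
        fw <- encoder_forward(model, x, head = "class", keep_cache = TRUE)
        nb <- length(take)
        onehot <- matrix(0, nb, cfg$n_classes)
        onehot[cbind(seq_len(nb), y + 1L)] <- 1
        losses <- c(losses, -mean(log(pmax(
          fw$probs[cbind(seq_len(nb), y + 1L)], 1e-12))))
        g <- (fw$probs - onehot) / nb
        bw <- encoder_backward(model, fw$cache, g_logits = g)
        st <- sgd_step(model$params, bw$grads, opt, lr,
                       control$sgd_momentum, control$weight_decay)
        model$params <- st$params
        opt <- st$state
      }
      val_acc <- if (length(va$vols) > 0) {
        accuracy_pct(batch_forward_probs(model, va$vols), va$labels)
      } else NA_real_
      if (!is.na(val_acc) && val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, params = model$params)
      }
      hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                      train_loss = mean(losses),
                                      val_acc = val_acc)
    }
    if (best$epoch > 0) model$params <- best$params
    structure(list(model = model, provenance = provenance, method = method,
                   best_epoch = best$epoch, seed = seed,
                   history = dplyr::bind_rows(hist)),
              class = "cssl_classifier")
  })
}

#' @export
predict.cssl_classifier <- function(object, x, ...) {
  predict(object$model, x, ...)
}

#' Test-split classification accuracy
#'
#' Deterministic evaluation-mode accuracy: fraction of correct argmax
#' predictions on the requested split, in percent, with no augmentation.
#'
#' @param classifier A `cssl_classifier` (or bare `rb3d_encoder`).
#' @param manifest Dataset manifest.
#' @param split Split to evaluate (default `"test"`).
#' @return Accuracy in percent.
#' @export
evaluate_accuracy <- function(classifier, manifest, split = "test") {
  model <- if (inherits(classifier, "cssl_classifier")) classifier$model
           else classifier
  stopifnot(inherits(model, "rb3d_encoder"))
  te <- load_labelled(manifest, split)
  if (length(te$vols) == 0) abort(sprintf("split '%s' is empty", split))
  if (max(te$labels) >= model$config$n_classes) {
    abort("manifest contains a class index outside the model head")
  }
  accuracy_pct(batch_forward_probs(model, te$vols), te$labels)
}

#' Bundle repeat-run accuracies for one experiment cell
#'
#' One (method, label fraction, SNR) cell of the evaluation grid: the
#' per-run test accuracies with their mean and standard deviation.
#'
#' @param method Method label (`"random_init"`, `"moco"`, `"simclr"`).
#' @param label_fraction Labelled fraction in (0, 1].
#' @param snr SNR of the dataset (may be `NA` when not applicable).
#' @param accuracies Numeric vector of per-run test accuracies in percent.
#' @return A one-row tibble with `accuracies` as a list column.
#' @export
experiment_result <- function(method, label_fraction, snr, accuracies) {
  stopifnot(length(accuracies) >= 1, all(accuracies >= 0),
            all(accuracies <= 100))
  tibble::tibble(method = method, label_fraction = label_fraction,
                 snr = snr, n_runs = length(accuracies),
                 mean_acc = mean(accuracies),
                 sd_acc = if (length(accuracies) > 1) sd(accuracies) else NA_real_,
                 accuracies = list(accuracies))
}

#' Two-sample Student's t-test between two methods
#'
#' Two-tailed t-test on the per-run accuracies of two experiment cells
#' (pooled-variance Student's test by default; Welch via `welch = TRUE`).
#'
#' @param a,b Numeric vectors of per-run accuracies, or one-row
#'   [experiment_result()] tibbles.
#' @param welch Use the Welch (unequal-variance) test instead.
#' @return A tibble with `statistic` (t), `p_value`, `df`, `method`.
#' @export
compare_methods <- function(a, b, welch = FALSE) {
  get_acc <- function(x) {
    if (is.data.frame(x)) x$accuracies[[1]] else as.numeric(x)
  }
  a <- get_acc(a); b <- get_acc(b)
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 runs")
  if (var(a) == 0 && var(b) == 0) {
    abort("t-test undefined: zero variance in both samples")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 method = if (welch) "welch" else "student")
}

#' Run the semi-supervised evaluation grid
#'
#' For every (method, label fraction) cell: resample the labelled subset
#' with the run's seed, fine-tune from the method's initial weights, and
#' evaluate test accuracy; repeated `n_runs` times so each cell carries a
#' mean and standard deviation over runs (label-subset and initialization
#' variance included).
#'
#' @param manifest Dataset manifest.
#' @param methods Character vector from `"random_init"`, `"moco"`,
#'   `"simclr"`.
#' @param checkpoints Named list of `cssl_pretrain` objects (or loaded
#'   checkpoints) for the non-random methods; a missing entry is an error
#'   naming the cell.
#' @param encoder [encoder_config()] used for `random_init` (and checked
#'   against checkpoints).
#' @param label_fractions Labelled fractions to sweep.
#' @param n_runs Repeats per cell.
#' @param control A [finetune_control()].
#' @param snr SNR annotation carried into the results (informational).
#' @param seed Base seed; run seeds are derived deterministically per cell
#'   and run.
#' @return A `cssl_grid` object with tibbles `runs` (one row per run) and
#'   `cells` (one [experiment_result()] row per cell).
#' @export
run_grid <- function(manifest, methods = c("random_init", "moco"),
                     checkpoints = list(), encoder = NULL,
                     label_fractions = c(0.25, 0.5, 0.75, 1),
                     n_runs = 5, control = finetune_control(), snr = NA,
                     seed = 1L) {
  stopifnot(all(methods %in% c("random_init", "moco", "simclr")))
  runs <- list()
  cells <- list()
  ci <- 0L
  for (method in methods) {
    for (fr in label_fractions) {
      ci <- ci + 1L
      ck <- NULL
      if (method != "random_init") {
        ck <- checkpoints[[method]]
        if (is.null(ck)) {
          abort(sprintf("missing pretrained checkpoint for cell (%s, %g%%)",
                        method, 100 * fr))
        }
      }
      accs <- numeric(n_runs)
      for (r in seq_len(n_runs)) {
        run_seed <- as.integer(seed * 1000L + ci * 53L + r)
        man_r <- subsample_labels(manifest, fr, seed = run_seed)
        fit <- finetune(ck, man_r, encoder = encoder, control = control,
                        seed = run_seed)
        accs[r] <- evaluate_accuracy(fit, manifest)
        runs[[length(runs) + 1L]] <-
          tibble::tibble(method = method, label_fraction = fr, snr = snr,
                         run = r, seed = run_seed, accuracy = accs[r])
      }
      cells[[length(cells) + 1L]] <- experiment_result(method, fr, snr, accs)
    }
  }
  structure(list(runs = dplyr::bind_rows(runs),
                 cells = dplyr::bind_rows(cells), seed = seed),
            class = "cssl_grid")
}
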