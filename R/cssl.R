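#' Queue-based contrastive (InfoNCE) loss
#'
#' For each query \eqn{q_j} with positive key \eqn{k_j} and a queue of
#' historical negative keys \eqn{k_i}, the loss is the batch mean of
#' \deqn{-\log \frac{\exp(q_j \cdot k_j / \tau)}
#'   {\exp(q_j \cdot k_j / \tau) + \sum_i \exp(q_j \cdot k_i / \tau)},}
#' a softmax cross-entropy over `1 + K` logits at temperature `tau`. All
#' vectors are expected unit-norm (dot product = cosine similarity).
#'
#' @param q `B x L` matrix of query embeddings (unit rows).
#' @param k_pos `B x L` matrix of positive-key embeddings (unit rows).
#' @param queue `K x L` matrix of negative keys (unit rows).
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(q, k_pos, queue, tau = 0.2) {
  contrastive_loss_grad(q, k_pos, queue, tau)$loss
}

# Loss plus gradient with respect to q (keys and queue receive no gradient:
# that is the momentum-encoder contract).
contrastive_loss_grad <- function(q, k_pos, queue, tau = 0.2) {
  stopifnot(is.matrix(q), is.matrix(k_pos), is.matrix(queue))
  if (tau <= 0) abort("`tau` must be positive")
  if (!all(dim(q) == dim(k_pos)) || ncol(queue) != ncol(q)) {
    abort("`q`, `k_pos` and `queue` must agree on the embedding dimension")
  }
  if (anyNA(q) || anyNA(k_pos) || anyNA(queue)) abort("NaN embedding rows")
  B <- nrow(q)
  logits <- cbind(rowSums(q * k_pos), q %*% t(queue)) / tau   # B x (1 + K)
  lse <- logsumexp_rows(logits)
  loss <- mean(lse - logits[, 1])
  prob <- exp(logits - lse)
  dlogit <- prob
  dlogit[, 1] <- dlogit[, 1] - 1
  dlogit <- dlogit / (B * tau)
  dq <- dlogit[, 1] * k_pos + dlogit[, -1, drop = FALSE] %*% queue
  list(loss = loss, dq = dq)
}

# SimCLR-style in-batch contrastive loss on 2B views (rows i and i + B are
# the positive pair). Negatives for an anchor are the other 2(B - 1) views;
# the denominator has 2B - 1 terms (positive included, self excluded).
simclr_loss_grad <- function(z, tau = 0.2) {
  stopifnot(is.matrix(z), nrow(z) %% 2 == 0)
  if (tau <= 0) abort("`tau` must be positive")
  n2 <- nrow(z)
  B <- n2 / 2
  if (B < 2) abort("SimCLR needs a batch of at least 2 (no negatives otherwise)")
  pos <- c(B + seq_len(B), seq_len(B))      # index of each row's positive
  s <- z %*% t(z) / tau
  diag(s) <- -Inf                           # self-similarity excluded
  lse <- logsumexp_rows(s)
  loss <- mean(lse - s[cbind(seq_len(n2), pos)])
  prob <- exp(s - lse)
  dlogit <- prob
  dlogit[cbind(seq_len(n2), pos)] <- dlogit[cbind(seq_len(n2), pos)] - 1
  dlogit <- dlogit / (n2 * tau)
  dz <- (dlogit + t(dlogit)) %*% z
  list(loss = loss, dz = dz)
}

#' Momentum update of the key parameters
#'
#' The exponential running average \eqn{\theta_k \leftarrow m \theta_k +
#' (1 - m) \theta_q}, applied elementwise to every parameter after each
#' optimizer step on the query encoder. The key encoder never receives
#' gradients; at `m = 1` it is frozen, at `m = 0` it copies the query
#' encoder.
#'
#' @param params_k,params_q Structurally identical parameter lists (or plain
#'   numeric arrays).
#' @param m Momentum coefficient in `[0, 1]`.
#' @return Updated key parameters.
#' @export
momentum_update <- function(params_k, params_q, m) {
  stopifnot(m >= 0, m <= 1)
  if (is.numeric(params_k) && is.numeric(params_q)) {
    if (length(params_k) != length(params_q)) {
      abort("key and query parameters differ in structure")
    }
    return(m * params_k + (1 - m) * params_q)
  }
  if (!identical(names(params_k), names(params_q))) {
    abort("key and query parameters differ in structure")
  }
  purrr::map2(params_k, params_q, momentum_update, m = m)
}

#' FIFO queue insertion
#'
#' Replaces the `B` oldest key rows at the insertion pointer with
#' `new_keys` and advances the pointer by `B` modulo `K` - the
#' first-in-first-out dictionary of negatives.
#'
#' @param queue `K x L` matrix of unit-norm keys.
#' @param ptr 0-based insertion pointer.
#' @param new_keys `B x L` matrix of unit-norm keys, `B <= K`.
#' @return List with updated `queue` and `ptr`.
#' @export
enqueue_dequeue <- function(queue, ptr, new_keys) {
  K <- nrow(queue)
  B <- nrow(new_keys)
  if (B > K) abort("cannot enqueue more keys than the queue holds")
  stopifnot(ptr >= 0, ptr < K, ncol(new_keys) == ncol(queue))
  idx <- ((ptr + seq_len(B) - 1L) %% K) + 1L
  queue[idx, ] <- new_keys
  list(queue = queue, ptr = (ptr + B) %% K)
}

# Fresh contrastive state: random unit-norm queue rows (avoids a degenerate
# all-equal similarity structure in the first steps).
init_queue <- function(queue_size, embed_dim) {
  m <- matrix(rnorm(queue_size * embed_dim), queue_size, embed_dim)
  l2_normalize_rows(m)
}

#' Pretraining hyperparameters
#'
#' Defaults are the published operating point for momentum-contrast
#' pretraining on the simulated datasets: queue size 128 (64 for the
#' smaller real dataset), momentum 0.999, temperature 0.2, Adam with
#' learning rate 1e-4, weight decay 1e-4, batch size 16, 200 epochs.
#'
#' @param queue_size Number of negative keys held (divisible by
#'   `batch_size` so FIFO replacement stays block-aligned).
#' @param momentum Key-encoder momentum coefficient in `[0, 1]`.
#' @param temperature Contrastive temperature (> 0).
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @return A `pretrain_control` list.
#' @export
pretrain_control <- function(queue_size = 128, momentum = 0.999,
                             temperature = 0.2, lr = 1e-4,
                             weight_decay = 1e-4, batch_size = 16,
                             epochs = 200) {
  stopifnot(queue_size >= 1, momentum >= 0, momentum <= 1, temperature > 0,
            lr > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0)
  structure(list(queue_size = as.integer(queue_size), momentum = momentum,
                 temperature = temperature, lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "pretrain_control")
}

# Load the training-split volumes of a manifest, normalized. Only `path` and
# `split` are touched: pretraining is label-blind by construction, and a
# manifest without any class_id column works.
load_unlabelled_train <- function(manifest) {
  if (!all(c("path", "split") %in% names(manifest))) {
    abort("manifest needs `path` and `split` columns")
  }
  paths <- manifest$path[manifest$split == "train"]
  if (length(paths) == 0) abort("training split is empty")
  lapply(paths, function(p) normalize_volume(read_volume(p)))
}

#' Momentum-contrast pretraining
#'
#' Label-free contrastive pretraining of the encoder. Per batch: two
#' augmented views per volume; the query view is embedded by the query
#' encoder (with gradients), the key view by the momentum key encoder
#' (no gradients, re-normalized); the queue-based contrastive loss is
#' computed against the FIFO dictionary; Adam steps the query parameters;
#' the key parameters take the momentum update; the fresh keys replace the
#' oldest queue block. The final partial batch of an epoch is dropped so
#' queue replacement stays block-aligned.
#'
#' @param manifest Dataset manifest; only `path` and `split` of the training
#'   records are read (class labels are never consulted).
#' @param encoder An [encoder_config()].
#' @param policy An [augment_policy()].
#' @param control A [pretrain_control()].
#' @param seed Integer seed covering initialization, queue, augmentation and
#'   batch order; identical seeds give identical loss trajectories.
#' @return A `cssl_pretrain` object: encoder weights (provenance
#'   `"cssl_pretrained"`), the configuration, and a per-epoch loss history
#'   tibble.
#' @export
pretrain_moco <- function(manifest, encoder, policy = augment_policy(),
                          control = pretrain_control(), seed = 1L) {
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(control, "pretrain_control"))
  if (control$queue_size < control$batch_size) {
    abort("queue size must be at least the batch size")
  }
  if (control$queue_size %% control$batch_size != 0) {
    abort("queue size must be divisible by the batch size (block-aligned FIFO)")
  }
  vols <- load_unlabelled_train(manifest)
  local_seed(seed, {
    model_q <- build_encoder(encoder)
    params_k <- model_q$params
    queue <- init_queue(control$queue_size, encoder$embed_dim)
    ptr <- 0L
    opt <- adam_init(model_q$params)
    n <- length(vols)
    B <- control$batch_size
    history <- numeric(control$epochs)
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n)
      n_batches <- n %/% B
      losses <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        take <- ord[((bi - 1) * B + 1):(bi * B)]
        pairs <- lapply(vols[take], make_pair, policy = policy)
        xq <- stack_volumes(lapply(pairs, `[[`, "x_q"))
        xk <- stack_volumes(lapply(pairs, `[[`, "x_k"))
        fq <- encoder_forward(model_q, xq, head = "embed", keep_cache = TRUE)
        model_k <- structure(list(config = encoder, params = params_k),
                             class = "rb3d_encoder")
        k <- l2_normalize_rows(
          encoder_forward(model_k, xk, head = "embed")$embedding)
        lg <- contrastive_loss_grad(fq$embedding, k, queue,
                                    control$temperature)
        losses[bi] <- lg$loss
        bw <- encoder_backward(model_q, fq$cache, g_embed = lg$dq)
        st <- adam_step(model_q$params, bw$grads, opt, control$lr,
                        control$weight_decay)
        model_q$params <- st$params
        opt <- st$state
        params_k <- momentum_update(params_k, model_q$params,
                                    control$momentum)
        qd <- enqueue_dequeue(queue, ptr, k)
        queue <- qd$queue
        ptr <- qd$ptr
      }
      history[epoch] <- mean(losses)
    }
    structure(list(weights = model_q$params, config = encoder,
                   method = "moco", provenance = "cssl_pretrained",
                   control = control, seed = seed,
                   queue = queue, ptr = ptr,
                   history = tibble::tibble(epoch = seq_len(control$epochs),
                                            mean_loss = history)),
              class = "cssl_pretrain")
  })
}

#' In-batch contrastive pretraining (SimCLR style)
#'
#' Same positive-pair construction and temperature-scaled softmax loss, but
#' a single encoder embeds both views and the negatives for each anchor are
#' the `2(B - 1)` other in-batch views; no queue, no momentum encoder.
#'
#' @inheritParams pretrain_moco
#' @return A `cssl_pretrain` object with `method = "simclr"`.
#' @export
pretrain_simclr <- function(manifest, encoder, policy = augment_policy(),
                            control = pretrain_control(), seed = 1L) {
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(control, "pretrain_control"))
  if (control$batch_size < 2) abort("SimCLR needs a batch size of at least 2")
  vols <- load_unlabelled_train(manifest)
  local_seed(seed, {
    model <- build_encoder(encoder)
    opt <- adam_init(model$params)
    n <- length(vols)
    B <- control$batch_size
    history <- numeric(control$epochs)
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n)
      n_batches <- n %/% B
      losses <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        take <- ord[((bi - 1) * B + 1):(bi * B)]
        pairs <- lapply(vols[take], make_pair, policy = policy)
        x <- stack_volumes(c(lapply(pairs, `[[`, "x_q"),
                             lapply(pairs, `[[`, "x_k")))
        f <- encoder_forward(model, x, head = "embed", keep_cache = TRUE)
        lg <- simclr_loss_grad(f$embedding, control$temperature)
        losses[bi] <- lg$loss
        bw <- encoder_backward(model, f$cache, g_embed = lg$dz)
        st <- adam_step(model$params, bw$grads, opt, control$lr,
                        control$weight_decay)
        model$params <- st$params
        opt <- st$state
      }
      history[epoch] <- mean(losses)
    }
    structure(list(weights = model$params, config = encoder,
                   method = "simclr", provenance = "cssl_pretrained",
                   control = control, seed = seed,
                   history = tibble::tibble(epoch = seq_len(control$epochs),
                                            mean_loss = history)),
              class = "cssl_pretrain")
  })
}

#' Save / load encoder weights
#'
#' Checkpoints carry the parameters, the configuration fingerprint and the
#' provenance tag (`random_init` or `cssl_pretrained`); loading against a
#' different configuration is an error.
#'
#' @param object A `cssl_pretrain` or `cssl_classifier` object.
#' @param path Checkpoint path.
#' @param config The [encoder_config()] the weights must match.
#' @return `load_weights()` returns the checkpoint list (`weights`,
#'   `config`, `provenance`, `method`).
#' @export
save_weights <- function(object, path) {
  stopifnot(inherits(object, c("cssl_pretrain", "cssl_classifier")))
  ck <- if (inherits(object, "cssl_pretrain")) {
    list(weights = object$weights, config = object$config,
         provenance = object$provenance, method = object$method)
  } else {
    list(weights = object$model$params, config = object$model$config,
         provenance = object$provenance, method = object$method)
  }
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config) &&
      !identical(config$fingerprint, ck$config$fingerprint)) {
    abort(sprintf("checkpoint fingerprint '%s' does not match config '%s'",
                  ck$config$fingerprint, config$fingerprint))
  }
  ck
}
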