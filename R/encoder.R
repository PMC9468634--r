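#' Residual 3D convolutional encoder configuration
#'
#' The encoder is a residual-block 3D CNN: a 3x3x3 convolutional stem, then
#' `n_stages` residual stages of `[conv3x3x3 -> ReLU -> conv3x3x3]` with an
#' identity skip (stride 1 throughout) each followed by 2x2x2 max pooling,
#' a concatenation junction of the last two same-shaped filter maps (the
#' penultimate stage pooled once more to match), and a fully connected
#' `fc_width` layer feeding two heads: `FC-embed_dim` for L2-normalized
#' contrastive embeddings and `FC-n_classes` with softmax for
#' classification. ReLU activations throughout; no normalization layers, so
#' evaluation-mode forwards are exactly deterministic and the momentum rule
#' covers every parameter.
#'
#' `tiny_mode` is the desk-scale test surface: 2 stages, 16 base filters,
#' fc width 128, embedding dimension 32, pooled stem, intended for 16^3
#' inputs.
#'
#' @param in_side Input side in voxels; must be divisible by
#'   `2^n_stages` (one pooling per stage; one more with `stem_pool`).
#' @param n_classes Number of output classes (>= 2).
#' @param base_filters Filters per convolutional layer.
#' @param n_stages Number of residual stages.
#' @param fc_width Width of the shared fully connected layer.
#' @param embed_dim Contrastive embedding dimension (>= 8).
#' @param use_concat Concatenate the last two stages' maps (when
#'   `n_stages >= 2`).
#' @param stem_pool Max-pool directly after the stem convolution,
#'   quartering the work of the first residual stage.
#' @param tiny_mode Use the reduced desk-scale geometry.
#' @return An `encoder_config` object with a `fingerprint` field; weights
#'   only load into a matching fingerprint.
#' @export
encoder_config <- function(in_side, n_classes, base_filters = 64,
                           n_stages = 3, fc_width = 1024, embed_dim = 128,
                           use_concat = TRUE, stem_pool = FALSE,
                           tiny_mode = FALSE) {
  if (tiny_mode) {
    base_filters <- 16; n_stages <- 2; fc_width <- 128; embed_dim <- 32
    stem_pool <- TRUE
  }
  stopifnot(n_classes >= 2, embed_dim >= 8, base_filters >= 1, n_stages >= 1)
  n_pool <- n_stages + as.integer(stem_pool)
  if (in_side %% 2^n_pool != 0) {
    abort(sprintf(
      "in_side %d is not divisible by 2^%d; pooling stage %d would need a fractional grid",
      in_side, n_pool, which(in_side %% 2^seq_len(n_pool) != 0)[1]))
  }
  use_concat <- use_concat && n_stages >= 2
  cfg <- list(in_side = as.integer(in_side), n_classes = as.integer(n_classes),
              base_filters = as.integer(base_filters),
              n_stages = as.integer(n_stages), fc_width = as.integer(fc_width),
              embed_dim = as.integer(embed_dim), use_concat = use_concat,
              stem_pool = stem_pool, tiny_mode = tiny_mode)
  cfg$fingerprint <- paste(
    "rb3d", cfg$in_side, cfg$n_classes, cfg$base_filters, cfg$n_stages,
    cfg$fc_width, cfg$embed_dim, as.integer(cfg$use_concat),
    as.integer(cfg$stem_pool), sep = "/")
  structure(cfg, class = "encoder_config")
}

feat_geometry <- function(cfg) {
  sf <- cfg$in_side / 2^(cfg$n_stages + as.integer(cfg$stem_pool))
  fc <- if (cfg$use_concat) 2L * cfg$base_filters else cfg$base_filters
  list(side = as.integer(sf), channels = fc,
       flat = as.integer(sf^3 * fc))
}

he_conv <- function(cin, cout) {
  array(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
        c(3, 3, 3, cin, cout))
}

zero_conv <- function(cin, cout) array(0, c(3, 3, 3, cin, cout))

xavier_fc <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(1 / fan_in)), fan_in, fan_out)
}

#' Build a randomly initialized encoder
#'
#' He-normal initialization for convolutions, Xavier for the fully connected
#' layers, zero biases. The second convolution of each residual block starts
#' at zero so every block is the identity at initialization, and the two
#' classification head starts near zero so initial logits are ~0
#' (cross-entropy starts at ln C) - without normalization layers this keeps
#' scales tame across depth and avoids dead-ReLU collapse. The embedding
#' head keeps full Xavier scale: its output is L2-normalized, and a
#' near-zero start there lets a constant bias dominate the normalized
#' direction (representation collapse). The draw is reproducible under
#' `seed`.
#'
#' @param cfg An [encoder_config()].
#' @param seed Optional integer seed.
#' @return An `rb3d_encoder` object (config, parameter list, provenance
#'   `"random_init"`).
#' @export
build_encoder <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "encoder_config"))
  f <- cfg$base_filters
  local_seed(seed, {
    params <- list(stem_w = he_conv(1L, f), stem_b = numeric(f))
    for (k in seq_len(cfg$n_stages)) {
      params[[sprintf("stage%d_c1_w", k)]] <- he_conv(f, f)
      params[[sprintf("stage%d_c1_b", k)]] <- numeric(f)
      params[[sprintf("stage%d_c2_w", k)]] <- zero_conv(f, f)
      params[[sprintf("stage%d_c2_b", k)]] <- numeric(f)
    }
    geo <- feat_geometry(cfg)
    params$fc1_w <- xavier_fc(geo$flat, cfg$fc_width)
    params$fc1_b <- numeric(cfg$fc_width)
    params$embed_w <- xavier_fc(cfg$fc_width, cfg$embed_dim)
    params$embed_b <- numeric(cfg$embed_dim)
    params$cls_w <- 0.01 * xavier_fc(cfg$fc_width, cfg$n_classes)
    params$cls_b <- numeric(cfg$n_classes)
    structure(list(config = cfg, params = params, provenance = "random_init"),
              class = "rb3d_encoder")
  })
}

check_batch <- function(model, x) {
  d <- dim(x)
  s <- model$config$in_side
  if (length(d) != 5 || !all(d[1:3] == s) || d[4] != 1L) {
    abort(sprintf("batch must have shape (%d, %d, %d, 1, n)", s, s, s))
  }
  invisible(x)
}

# Full forward pass. head: "embed", "class" or "both". Returns embeddings as
# an n x L matrix of unit rows, class logits/probabilities as n x C, and the
# caches needed for backprop when keep_cache = TRUE.
encoder_forward <- function(model, x, head = "both", keep_cache = FALSE) {
  check_batch(model, x)
  p <- model$params
  cfg <- model$config
  cache <- if (keep_cache) list(x = x) else NULL
  stem_pre <- conv3d_fwd(x, p$stem_w, p$stem_b)
  h <- pmax(stem_pre, 0)
  dim(h) <- dim(stem_pre)
  if (keep_cache) cache$stem_pre <- stem_pre
  if (cfg$stem_pool) {
    sp <- maxpool3d_fwd(h)
    if (keep_cache) cache$stem_idx <- sp$idx
    h <- sp$y
  }
  if (keep_cache) cache$stages <- vector("list", cfg$n_stages)
  pooled <- vector("list", cfg$n_stages)
  for (k in seq_len(cfg$n_stages)) {
    a1 <- conv3d_fwd(h, p[[sprintf("stage%d_c1_w", k)]],
                     p[[sprintf("stage%d_c1_b", k)]])
    r1 <- pmax(a1, 0); dim(r1) <- dim(a1)
    a2 <- conv3d_fwd(r1, p[[sprintf("stage%d_c2_w", k)]],
                     p[[sprintf("stage%d_c2_b", k)]])
    s <- a2 + h
    hs <- pmax(s, 0); dim(hs) <- dim(s)
    pl <- maxpool3d_fwd(hs)
    if (keep_cache) {
      cache$stages[[k]] <- list(h_in = h, a1 = a1, r1 = r1, s = s, hs = hs,
                                idx = pl$idx)
    }
    h <- pl$y
    pooled[[k]] <- pl$y
  }
  n <- dim(x)[5]
  if (cfg$use_concat) {
    ex <- maxpool3d_fwd(pooled[[cfg$n_stages - 1L]])
    if (keep_cache) cache$extra_idx <- ex$idx
    geo <- feat_geometry(cfg)
    feat <- array(0, c(geo$side, geo$side, geo$side, geo$channels, n))
    f <- cfg$base_filters
    feat[, , , seq_len(f), ] <- ex$y
    feat[, , , f + seq_len(f), ] <- pooled[[cfg$n_stages]]
  } else {
    feat <- pooled[[cfg$n_stages]]
  }
  flat <- matrix(feat, ncol = n)
  f1_pre <- crossprod(p$fc1_w, flat) + p$fc1_b
  f1 <- pmax(f1_pre, 0)
  if (keep_cache) {
    cache$flat <- flat; cache$f1_pre <- f1_pre; cache$f1 <- f1
  }
  out <- list(cache = cache)
  if (head %in% c("embed", "both")) {
    z <- crossprod(p$embed_w, f1) + p$embed_b      # L x n
    znorm <- sqrt(colSums(z^2))
    znorm_safe <- pmax(znorm, 1e-12)
    q <- sweep(z, 2, znorm_safe, "/")
    out$embedding <- t(q)
    if (keep_cache) {
      out$cache$z <- z; out$cache$q <- q; out$cache$znorm <- znorm_safe
    }
  }
  if (head %in% c("class", "both")) {
    logits <- crossprod(p$cls_w, f1) + p$cls_b     # C x n
    mx <- apply(logits, 2, max)
    e <- exp(sweep(logits, 2, mx))
    probs <- sweep(e, 2, colSums(e), "/")
    out$logits <- t(logits)
    out$probs <- t(probs)
    if (keep_cache) out$cache$logits <- logits
  }
  out
}

# Backprop to all parameters. Exactly one of g_embed (n x L, gradient w.r.t.
# the unit-normalized embeddings) or g_logits (n x C) is given. Also returns
# the gradient at the last residual stage's pre-pool activation (Grad-CAM
# hook).
encoder_backward <- function(model, cache, g_embed = NULL, g_logits = NULL) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  df1 <- 0
  if (!is.null(g_embed)) {
    dq <- t(g_embed)                                   # L x n
    q <- cache$q
    dz <- sweep(dq - sweep(q, 2, colSums(q * dq), "*"), 2, cache$znorm, "/")
    grads$embed_w <- cache$f1 %*% t(dz)
    grads$embed_b <- rowSums(dz)
    df1 <- df1 + p$embed_w %*% dz
  }
  if (!is.null(g_logits)) {
    dl <- t(g_logits)                                  # C x n
    grads$cls_w <- cache$f1 %*% t(dl)
    grads$cls_b <- rowSums(dl)
    df1 <- df1 + p$cls_w %*% dl
  }
  df1_pre <- df1 * (cache$f1_pre > 0)
  grads$fc1_w <- cache$flat %*% t(df1_pre)
  grads$fc1_b <- rowSums(df1_pre)
  dflat <- p$fc1_w %*% df1_pre
  n <- ncol(dflat)
  geo <- feat_geometry(cfg)
  dfeat <- array(dflat, c(geo$side, geo$side, geo$side, geo$channels, n))
  f <- cfg$base_filters
  extra_g <- NULL
  if (cfg$use_concat) {
    dA <- dfeat[, , , seq_len(f), , drop = FALSE]
    dpool <- dfeat[, , , f + seq_len(f), , drop = FALSE]
    dim(dpool) <- c(geo$side, geo$side, geo$side, f, n)
    # gradient reaching the penultimate stage's pooled output via the
    # concatenation branch
    prev_dim <- c(rep(2L * geo$side, 3), f, n)
    extra_g <- maxpool3d_bwd(as.numeric(dA), cache$extra_idx,
                             as.integer(prev_dim))
  } else {
    dpool <- dfeat
  }
  g_last_conv <- NULL
  for (k in rev(seq_len(cfg$n_stages))) {
    st <- cache$stages[[k]]
    dhs <- maxpool3d_bwd(dpool, st$idx, dim(st$hs))
    if (k == cfg$n_stages) g_last_conv <- dhs
    ds <- dhs * (st$s > 0); dim(ds) <- dim(dhs)
    b2 <- conv3d_bwd(st$r1, p[[sprintf("stage%d_c2_w", k)]], ds)
    grads[[sprintf("stage%d_c2_w", k)]] <- b2$gw
    grads[[sprintf("stage%d_c2_b", k)]] <- b2$gb
    da1 <- b2$gx * (st$a1 > 0); dim(da1) <- dim(b2$gx)
    b1 <- conv3d_bwd(st$h_in, p[[sprintf("stage%d_c1_w", k)]], da1)
    grads[[sprintf("stage%d_c1_w", k)]] <- b1$gw
    grads[[sprintf("stage%d_c1_b", k)]] <- b1$gb
    dpool <- b1$gx + ds                               # skip connection
    if (cfg$use_concat && k == cfg$n_stages) dpool <- dpool + extra_g
  }
  if (cfg$stem_pool) {
    dpool <- maxpool3d_bwd(dpool, cache$stem_idx, dim(cache$stem_pre))
  }
  dh0 <- dpool * (cache$stem_pre > 0); dim(dh0) <- dim(dpool)
  b0 <- conv3d_bwd(cache$x, p$stem_w, dh0)
  grads$stem_w <- b0$gw
  grads$stem_b <- b0$gb
  # the head that did not receive a loss contributes zero gradient
  for (nm in setdiff(names(p), names(grads))) grads[[nm]] <- p[[nm]] * 0
  list(grads = grads[names(p)], g_last_conv = g_last_conv)
}

#' Embed a batch of volumes
#'
#' Forward pass through the embedding head; every output row is
#' L2-normalized to unit norm (the contrastive similarity is a dot product
#' on the unit sphere, which is what makes a temperature of 0.2 meaningful).
#'
#' @param model An `rb3d_encoder`.
#' @param x Either a list of cubic volumes or a `(side, side, side, 1, n)`
#'   array.
#' @return An `n x embed_dim` matrix of unit-norm embeddings.
#' @export
embed <- function(model, x) {
  stopifnot(inherits(model, "rb3d_encoder"))
  if (is.list(x)) x <- stack_volumes(x)
  encoder_forward(model, x, head = "embed")$embedding
}

#' Classify a batch of volumes
#'
#' @param object An `rb3d_encoder`.
#' @param x A list of volumes or a 5-d batch array.
#' @param ... Unused.
#' @return A tibble with `pred` (0-based class index, first-maximum
#'   tie-break) and one `prob_<c>` column per class.
#' @export
predict.rb3d_encoder <- function(object, x, ...) {
  if (is.list(x)) x <- stack_volumes(x)
  out <- encoder_forward(object, x, head = "class")
  pred <- max.col(out$probs, ties.method = "first") - 1L
  pr <- tibble::as_tibble(out$probs, .name_repair = ~ sprintf(
    "prob_%d", seq_along(.x) - 1L))
  dplyr::bind_cols(tibble::tibble(pred = pred), pr)
}

# ReLU(sum_c w_c A_c) of channel maps A weighted by spatially averaged
# gradients w, max-normalized to [0, 1]; the computational core of Grad-CAM.
gradcam_combine <- function(acts, grads) {
  stopifnot(length(dim(acts)) == 4, all(dim(acts) == dim(grads)))
  ch <- dim(acts)[4]
  w <- apply(grads, 4, mean)
  cam <- array(0, dim(acts)[1:3])
  for (c in seq_len(ch)) cam <- cam + w[c] * acts[, , , c]
  cam <- pmax(cam, 0)
  m <- max(cam)
  all_zero <- m == 0
  if (!all_zero) cam <- cam / m
  attr(cam, "all_zero") <- all_zero
  cam
}

#' 3D Grad-CAM heat volume
#'
#' Gradient-weighted class activation mapping at the last residual stage:
#' channel activations are weighted by the spatial mean of the gradient of
#' the (pre-softmax) target-class score, summed, rectified, trilinearly
#' upsampled to the input shape and max-normalized to `[0, 1]`. A map that
#' is zero everywhere (fully rectified away) is returned as all zeros with
#' attribute `all_zero = TRUE`.
#'
#' @param model An `rb3d_encoder` (or `cssl_classifier`).
#' @param vol A single cubic volume matching the encoder input side.
#' @param target_class 0-based class index.
#' @return A non-negative array of the input shape with values in `[0, 1]`.
#' @export
gradcam <- function(model, vol, target_class) {
  if (inherits(model, "cssl_classifier")) model <- model$model
  stopifnot(inherits(model, "rb3d_encoder"))
  check_volume(vol, cubic = TRUE)
  cfg <- model$config
  stopifnot(target_class >= 0, target_class < cfg$n_classes)
  x <- stack_volumes(list(vol))
  out <- encoder_forward(model, x, head = "class", keep_cache = TRUE)
  g <- matrix(0, 1, cfg$n_classes)
  g[1, target_class + 1L] <- 1
  bw <- encoder_backward(model, out$cache, g_logits = g)
  a <- bw$g_last_conv
  side_a <- dim(a)[1]
  acts <- array(out$cache$stages[[cfg$n_stages]]$hs,
                c(side_a, side_a, side_a, cfg$base_filters))
  grd <- array(a, c(side_a, side_a, side_a, cfg$base_filters))
  cam <- gradcam_combine(acts, grd)
  s <- dim(vol)[1]
  sc <- if (s > 1) (side_a - 1) / (s - 1) else 1
  up <- resample_affine(array(cam, dim(cam)), diag(sc, 3), c(0, 0, 0), dim(vol))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  attr(up, "all_zero") <- attr(cam, "all_zero")
  up
}
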