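naive_queue_loss <- function(q, k_pos, queue, tau) {
  # independent loop-based oracle: softmax cross-entropy over 1 + K logits
  B <- nrow(q); K <- nrow(queue)
  total <- 0
  for (j in 1:B) {
    logits <- numeric(K + 1)
    logits[1] <- sum(q[j, ] * k_pos[j, ]) / tau
    for (i in 1:K) logits[i + 1] <- sum(q[j, ] * queue[i, ]) / tau
    total <- total - (logits[1] - log(sum(exp(logits))))
  }
  total / B
}

test_that("the queue-based loss matches a naive oracle on random instances", {
  set.seed(1)
  for (rep in 1:25) {
    B <- sample(1:8, 1); L <- sample(4:32, 1); K <- sample(4:64, 1)
    q <- random_unit_rows(B, L); kp <- random_unit_rows(B, L)
    qu <- random_unit_rows(K, L)
    tau <- runif(1, 0.05, 1)
    expect_equal(contrastive_loss(q, kp, qu, tau),
                 naive_queue_loss(q, kp, qu, tau), tolerance = 1e-6)
  }
})

test_that("uniform similarity collapses the loss to ln(K + 1)", {
  for (K in c(8, 64, 128)) for (tau in c(0.07, 0.2, 1)) {
    v <- c(1, numeric(7))
    q <- matrix(rep(v, 3), 3, byrow = TRUE)
    kp <- q
    qu <- matrix(rep(v, K), K, byrow = TRUE)
    expect_equal(contrastive_loss(q, kp, qu, tau), log(K + 1),
                 tolerance = 1e-9)
  }
})

test_that("a dominant positive drives the loss to its closed-form limit", {
  K <- 16; tau <- 0.2
  e1 <- c(1, numeric(7))
  q <- matrix(e1, 1); kp <- matrix(e1, 1)
  qu <- matrix(rep(-e1, K), K, byrow = TRUE)
  expected <- -log(exp(5) / (exp(5) + K * exp(-5)))
  expect_equal(contrastive_loss(q, kp, qu, tau), expected, tolerance = 1e-9)
})

test_that("loss inputs are validated", {
  q <- random_unit_rows(2, 8)
  expect_error(contrastive_loss(q, q, random_unit_rows(4, 8), tau = 0), "tau")
  expect_error(contrastive_loss(q, q, random_unit_rows(4, 6)), "dimension")
  qn <- q; qn[1, 1] <- NaN
  expect_error(contrastive_loss(qn, q, random_unit_rows(4, 8)), "NaN")
})

test_that("the in-batch loss matches its oracle and uniform closed form", {
  set.seed(2)
  for (B in c(2, 4, 7)) {
    z <- random_unit_rows(2 * B, 16)
    tau <- 0.2
    # naive oracle: anchors 1..2B, positive at i +/- B, negatives all others
    total <- 0
    for (i in 1:(2 * B)) {
      p <- if (i <= B) i + B else i - B
      others <- setdiff(1:(2 * B), i)
      lg <- sapply(others, function(j) sum(z[i, ] * z[j, ]) / tau)
      total <- total - (sum(z[i, ] * z[p, ]) / tau - log(sum(exp(lg))))
    }
    expect_equal(cryocssl:::simclr_loss_grad(z, tau)$loss, total / (2 * B),
                 tolerance = 1e-6)
    # all-identical views: ln(2B - 1)
    zu <- matrix(rep(c(1, numeric(15)), 2 * B), 2 * B, byrow = TRUE)
    expect_equal(cryocssl:::simclr_loss_grad(zu, tau)$loss, log(2 * B - 1),
                 tolerance = 1e-9)
  }
  expect_error(cryocssl:::simclr_loss_grad(random_unit_rows(2, 8), 0.2), "at least 2")
})

test_that("momentum blending obeys its fixed points and geometric decay", {
  set.seed(3)
  pk <- list(a = matrix(rnorm(12), 3), b = rnorm(5))
  pq <- list(a = matrix(rnorm(12), 3), b = rnorm(5))
  expect_equal(momentum_update(pk, pq, 1), pk)          # frozen keys
  expect_equal(momentum_update(pk, pq, 0), pq)          # exact copy
  for (m in c(0.5, 0.9, 0.999)) {
    cur <- pk
    d0 <- sqrt(sum((unlist(pk) - unlist(pq))^2))
    for (t in 1:20) {
      cur <- momentum_update(cur, pq, m)
      dt <- sqrt(sum((unlist(cur) - unlist(pq))^2))
      expect_equal(dt, m^t * d0, tolerance = 1e-9)
    }
  }
  expect_error(momentum_update(pk, list(a = pq$a), 0.5), "structure")
})

test_that("the FIFO queue replaces the oldest block and wraps the pointer", {
  L <- 4
  # distinguishable unit-norm batches tagged by their second coordinate
  mk <- function(tag, B) {
    m <- matrix(0, B, L); m[, 1] <- 1; m[, 2] <- tag / 100
    m / sqrt(rowSums(m^2))
  }
  q0 <- random_unit_rows(8, L)
  s1 <- enqueue_dequeue(q0, 0L, mk(1, 4))
  expect_equal(s1$ptr, 4)
  expect_identical(s1$queue[5:8, ], q0[5:8, ])          # untouched rows exact
  s2 <- enqueue_dequeue(s1$queue, s1$ptr, mk(2, 4))
  expect_equal(s2$ptr, 0)
  expect_equal(s2$queue, rbind(mk(1, 4), mk(2, 4)))     # fully replaced
  s3 <- enqueue_dequeue(s2$queue, s2$ptr, mk(3, 4))
  expect_equal(s3$queue, rbind(mk(3, 4), mk(2, 4)))     # batches {3, 2} in order
  expect_equal(s3$ptr, 4)
  expect_error(enqueue_dequeue(q0, 0L, random_unit_rows(9, L)), "more keys")
})

test_that("initial loss with a random queue is bounded by the uniform-softmax value", {
  # an untrained encoder already correlates the two views of one volume, so
  # the step-0 loss sits at or below ln(K + 1) (it would equal ln(K + 1)
  # exactly under fully uniform similarities); it never starts above it
  man <- micro_manifest()
  enc <- micro_encoder()
  vols <- lapply(man$path[man$split == "train"],
                 function(p) normalize_volume(read_volume(p)))
  for (s in 1:3) {
    set.seed(s)
    model <- build_encoder(enc)
    queue <- cryocssl:::init_queue(16, enc$embed_dim)
    pr <- lapply(vols[1:4], make_pair)
    q <- embed(model, lapply(pr, `[[`, "x_q"))
    k <- embed(model, lapply(pr, `[[`, "x_k"))
    l0 <- contrastive_loss(q, k, queue, 0.2)
    expect_gt(l0, 0)
    expect_lt(l0, log(17) + 0.5)
  }
})

test_that("momentum-contrast pretraining is label-blind, deterministic and sane", {
  man <- micro_manifest()
  unlabelled <- man[, c("id", "path", "split")]       # no class_id at all
  enc <- micro_encoder()
  ctl <- pretrain_control(queue_size = 8, batch_size = 4, epochs = 2, lr = 1e-3,
                          momentum = 0.9)
  p1 <- pretrain_moco(unlabelled, enc, control = ctl, seed = 5)
  p2 <- pretrain_moco(man, enc, control = ctl, seed = 5)
  expect_identical(p1$history, p2$history)            # labels never consulted
  expect_identical(p1$weights, p2$weights)
  expect_identical(p1$provenance, "cssl_pretrained")
  expect_equal(nrow(p1$history), 2)
  # queue hygiene: rows stay unit-norm through training
  expect_true(all(abs(sqrt(rowSums(p1$queue^2)) - 1) < 1e-4))
  expect_error(pretrain_moco(man, enc, control = pretrain_control(
    queue_size = 2, batch_size = 4, epochs = 1)), "at least the batch")
  expect_error(pretrain_moco(man, enc, control = pretrain_control(
    queue_size = 10, batch_size = 4, epochs = 1)), "divisible")
})

test_that("in-batch pretraining runs deterministically", {
  man <- micro_manifest()
  enc <- micro_encoder()
  ctl <- pretrain_control(batch_size = 4, epochs = 2, lr = 1e-3)
  s1 <- pretrain_simclr(man, enc, control = ctl, seed = 6)
  s2 <- pretrain_simclr(man, enc, control = ctl, seed = 6)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$method, "simclr")
  expect_error(pretrain_simclr(man, enc, control = pretrain_control(
    batch_size = 1, epochs = 1)), "at least 2")
})

test_that("pretrained embeddings separate positive pairs from negatives", {
  man <- micro_manifest()
  enc <- micro_encoder()
  ctl <- pretrain_control(queue_size = 8, batch_size = 4, epochs = 10,
                          lr = 1e-3, momentum = 0.9)
  margins <- sapply(1:3, function(s) {
    pt <- pretrain_moco(man, enc, control = ctl, seed = s)
    model <- build_encoder(enc); model$params <- pt$weights
    vols <- lapply(man$path, function(p) normalize_volume(read_volume(p)))
    set.seed(100 + s)
    pos <- sapply(vols, function(v) {
      pr <- make_pair(v)
      e <- embed(model, list(pr$x_q, pr$x_k))
      sum(e[1, ] * e[2, ])
    })
    e <- embed(model, vols)
    S <- e %*% t(e)
    mean(pos) - mean(S[upper.tri(S)])
  })
  expect_gt(mean(margins), 0)
})

test_that("weight checkpoints enforce the configuration fingerprint", {
  man <- micro_manifest()
  enc <- micro_encoder()
  pt <- pretrain_moco(man, enc, control = pretrain_control(
    queue_size = 8, batch_size = 4, epochs = 1, lr = 1e-3), seed = 1)
  p <- tempfile(fileext = ".ckpt")
  save_weights(pt, p)
  ck <- load_weights(p, config = enc)
  expect_identical(ck$weights, pt$weights)
  expect_identical(ck$provenance, "cssl_pretrained")
  other <- encoder_config(in_side = 8, n_classes = 5, base_filters = 4,
                          n_stages = 1, fc_width = 16, embed_dim = 8)
  expect_error(load_weights(p, config = other), "fingerprint")
})
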