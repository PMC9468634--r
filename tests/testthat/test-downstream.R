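test_that("accuracy is the percentage of correct argmax predictions", {
  # hand-built prediction table: 3 of 5 correct
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4),
                 c(0.3, 0.7), c(0.8, 0.2))
  labels <- c(0L, 1L, 1L, 0L, 0L)
  expect_equal(cryocssl:::accuracy_pct(probs, labels), 60)
  expect_equal(cryocssl:::accuracy_pct(probs, max.col(probs) - 1L), 100)
  # a constant-class predictor scores chance level on a balanced set
  const <- matrix(rep(c(1, 0), each = 10), 10)
  expect_equal(cryocssl:::accuracy_pct(const, rep(0:1, 5)), 50)
})

test_that("a constant classifier scores chance on a balanced test split", {
  man <- micro_manifest()
  enc <- micro_encoder()
  m <- build_encoder(enc, seed = 1)
  m$params$cls_w[] <- 0
  m$params$cls_b <- c(10, 0)          # always predicts class 0
  expect_equal(evaluate_accuracy(m, man), 50)   # 2 balanced classes
  bad <- man; bad$class_id[bad$split == "test"][1] <- 7L
  expect_error(evaluate_accuracy(m, bad), "outside the model head")
})

test_that("zero-epoch fine-tuning is a no-op and seeds reproduce checkpoints", {
  man <- micro_manifest()
  enc <- micro_encoder()
  f0 <- finetune(NULL, man, encoder = enc,
                 control = finetune_control(epochs = 0), seed = 9)
  ref <- build_encoder(enc, seed = 9)
  expect_identical(f0$model$params, ref$params)
  expect_equal(f0$best_epoch, 0L)
  ctl <- finetune_control(lr = 1e-3, epochs = 2)
  f1 <- finetune(NULL, man, encoder = enc, control = ctl, seed = 9)
  f2 <- finetune(NULL, man, encoder = enc, control = ctl, seed = 9)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$best_epoch, which.max(f1$history$val_acc))
})

test_that("fine-tuning validates its labelled subset", {
  man <- micro_manifest()
  enc <- micro_encoder()
  empty <- man; empty$labelled <- FALSE
  expect_error(finetune(NULL, empty, encoder = enc), "no labelled")
  onecls <- man
  onecls$labelled <- onecls$split == "train" & onecls$class_id == 0
  expect_error(finetune(NULL, onecls, encoder = enc), "misses class")
  expect_error(finetune(NULL, man, encoder = NULL), "required")
})

test_that("the pooled t-test matches its closed form and is symmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_methods(a, b)
  # by hand: pooled s2 = 1, se = sqrt(2/3), t = -3/se, df = 4
  t_hand <- -3 / sqrt(2 / 3)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(t_hand, 4), tolerance = 1e-9)
  swap <- compare_methods(b, a)
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
  same <- compare_methods(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_methods(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_methods(1, c(1, 2)), ">= 2 runs")
})

test_that("pooled and Welch tests agree with closed forms on random samples", {
  set.seed(10)
  for (i in 1:50) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:8, 1), mean = rnorm(1), sd = runif(1, 0.5, 2))
    na <- length(a); nb <- length(b)
    s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_hand <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
    p_hand <- 2 * pt(-abs(t_hand), na + nb - 2)
    res <- compare_methods(a, b)
    expect_equal(res$statistic, t_hand, tolerance = 1e-9)
    expect_equal(res$p_value, p_hand, tolerance = 1e-9)
  }
})

test_that("experiment cells carry self-consistent summary statistics", {
  er <- experiment_result("moco", 0.25, 0.05, c(50, 60, 55, 65, 52))
  expect_equal(er$mean_acc, mean(c(50, 60, 55, 65, 52)), tolerance = 1e-9)
  expect_equal(er$sd_acc, sd(c(50, 60, 55, 65, 52)), tolerance = 1e-9)
  expect_equal(er$n_runs, 5)
  expect_error(experiment_result("moco", 1, NA, c(50, 120)))
})

test_that("the evaluation grid assembles, summarizes and round-trips", {
  man <- micro_manifest()
  enc <- micro_encoder()
  g <- run_grid(man, methods = "random_init", encoder = enc,
                label_fractions = c(0.5, 1), n_runs = 2,
                control = finetune_control(epochs = 0), seed = 3)
  expect_s3_class(g, "cssl_grid")
  expect_equal(nrow(g$cells), 2)
  expect_equal(nrow(g$runs), 4)
  expect_true(all(g$cells$n_runs == 2))
  expect_true(all(g$runs$accuracy >= 0 & g$runs$accuracy <= 100))
  # tidy/glance round-trip through CSV
  p <- tempfile(fileext = ".csv")
  readr::write_csv(tidy(g), p, progress = FALSE)
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(back$accuracy, g$runs$accuracy)
  expect_equal(nrow(glance(g)), 2)
  expect_s3_class(summary(g), "data.frame")
  expect_error(run_grid(man, methods = c("random_init", "moco"),
                        encoder = enc, n_runs = 1), "missing pretrained")
})

test_that("tidiers and autoplot methods return well-formed objects", {
  man <- micro_manifest()
  enc <- micro_encoder()
  pt <- pretrain_moco(man, enc, control = pretrain_control(
    queue_size = 8, batch_size = 4, epochs = 2, lr = 1e-3), seed = 2)
  expect_s3_class(tidy(pt), "tbl_df")
  expect_named(tidy(pt), c("epoch", "mean_loss"))
  expect_equal(glance(pt)$epochs, 2)
  expect_s3_class(autoplot(pt), "ggplot")
  ft <- finetune(pt, man, control = finetune_control(lr = 1e-3, epochs = 2),
                 seed = 2)
  expect_named(tidy(ft), c("epoch", "lr", "train_loss", "val_acc"))
  expect_s3_class(autoplot(ft), "ggplot")
  g <- run_grid(man, methods = "random_init", encoder = enc,
                label_fractions = 1, n_runs = 2,
                control = finetune_control(epochs = 0), seed = 1)
  expect_s3_class(autoplot(g), "ggplot")
})
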