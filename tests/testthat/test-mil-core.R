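test_that("attention weights follow the tanh-softmax form", {
  # single patch: softmax of one score
  p1 <- mil_init(d = 4, L = 8, seed = 1)
  expect_equal(attention_weights(matrix(rnorm(4), 1), p1), 1)

  # identical patches share attention by symmetry
  H <- matrix(rnorm(4), nrow = 4, ncol = 4, byrow = TRUE)
  expect_equal(attention_weights(H, p1), rep(0.25, 4))

  # hand-computed two-patch oracle: scores (0, tanh(10)+tanh(0)) with
  # V = I, w = (1, 1) give softmax ~ (0.2689, 0.7311)
  params <- list(V = diag(2), w = c(1, 1))
  a <- attention_weights(rbind(c(0, 0), c(10, 0)), params)
  expect_equal(a, c(0.2689, 0.7311), tolerance = 1e-4)
  expect_equal(sum(a), 1, tolerance = 1e-12)

  expect_error(attention_weights(matrix(0, 2, 3), p1), "dimension")
})

test_that("softmax normalization holds for any parameters and bag size", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(1:60, 1); d <- sample(2:12, 1); L <- sample(2:20, 1)
    H <- matrix(rnorm(n * d, sd = sample(c(0.1, 1, 50), 1)), n)
    a <- attention_weights(H, mil_init(d, L, seed = i))
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-9)
  }
})

test_that("bag aggregation is the attention-weighted sum of patch features", {
  set.seed(3)
  H <- matrix(rnorm(12), 4, 3)
  onehot <- c(0, 0, 1, 0)
  expect_equal(aggregate_bag(H, onehot), H[3, ])
  expect_equal(aggregate_bag(H, rep(0.25, 4)), colMeans(H))
  expect_equal(aggregate_bag(rbind(c(0, 0), c(10, 0)), c(0.2689, 0.7311)),
               c(7.311, 0))
  expect_error(aggregate_bag(H, c(0.5, 0.5)), "one weight per row")
  expect_error(aggregate_bag(H, c(0.5, 0.2, 0.1, 0.1)), "sum to 1")
})

test_that("the sigmoid head maps embeddings to calibrated probabilities", {
  expect_equal(classify_slide(c(0, 0, 0), list(u = c(0, 0, 0), b = 0)), 0.5)
  expect_equal(classify_slide(c(0, 5), list(u = c(1, 0), b = 0)), 0.5)
  expect_equal(classify_slide(log(3), list(u = 1, b = 0)), 0.75)
})

test_that("class weights are inverse-frequency and average to one", {
  cw <- class_weights(50, 50)
  expect_equal(c(cw$w_pcr, cw$w_non_pcr), c(1, 1))

  cw <- class_weights(81, 93)
  expect_equal(cw$w_pcr, 174 / 162)
  expect_equal(cw$w_non_pcr, 174 / 186)
  expect_identical(cw$n_pcr * cw$w_pcr + cw$n_non_pcr * cw$w_non_pcr, 174)

  expect_equal(unlist(class_weights(1, 3)[c("w_pcr", "w_non_pcr")],
                      use.names = FALSE), c(2, 2 / 3))
  expect_error(class_weights(0, 10), "degenerate")

  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(1:500, 1); n0 <- sample(1:500, 1)
    cw <- class_weights(n1, n0)
    expect_equal((n1 * cw$w_pcr + n0 * cw$w_non_pcr) / (n1 + n0), 1)
  }
})

test_that("weighted BCE matches its analytic values and degenerates to plain BCE", {
  expect_lt(weighted_bce(1, 1 - 1e-9, class_weights(3, 7)), 1e-6)
  expect_equal(weighted_bce(1, 0.5), log(2))
  expect_equal(weighted_bce(c(1, 0), c(0.8, 0.2)), -mean(log(c(0.8, 0.8))))

  # unit weights equal unweighted BCE; duplicating the batch changes nothing
  set.seed(6)
  y <- rbinom(8, 1, 0.5); p <- runif(8)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(y, p, class_weights(5, 5)), plain)
  expect_equal(weighted_bce(rep(y, 2), rep(p, 2)), weighted_bce(y, p))
  expect_error(weighted_bce(c(1, 0), 0.5), "equal length")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(5)
  d <- 3; L <- 4; N <- 5
  H <- matrix(rnorm(N * d), N)
  params <- mil_init(d, L, seed = 2)
  params$u <- rnorm(d); params$b <- 0.3
  cw <- class_weights(3, 7)
  for (y in c(0, 1)) {
    fb <- milpath:::mil_grad(H, y, params, cw)
    for (nm in c("V", "w", "u", "b")) {
      th <- params[[nm]]
      num <- th * 0
      for (i in seq_along(th)) {
        pp <- params; pp[[nm]][i] <- th[i] + 1e-6
        pm <- params; pm[[nm]][i] <- th[i] - 1e-6
        num[i] <- (milpath:::mil_grad(H, y, pp, cw)$loss -
                   milpath:::mil_grad(H, y, pm, cw)$loss) / 2e-6
      }
      expect_equal(as.vector(fb$grads[[nm]]), as.vector(num),
                   tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible, logs every epoch, and respects early stopping", {
  cohort <- gen_bags(sim_config(n_bags = 16, bag_size_range = c(10, 20),
                                d = 6, seed = 3))
  cfg <- train_config(max_epochs = 25, patience = 10, L = 8, seed = 2)
  m1 <- train_mil(cohort$bags[1:10], cohort$bags[11:16], cfg)
  m2 <- train_mil(cohort$bags[1:10], cohort$bags[11:16], cfg)
  expect_identical(m1$best_val_loss, m2$best_val_loss)
  expect_identical(m1$params, m2$params)
  expect_lte(nrow(m1$log), cfg$max_epochs)
  expect_equal(m1$best_epoch, which.min(m1$log$val_loss))

  # degenerate single-class training split is rejected
  pos <- Filter(function(b) b$label == 1, cohort$bags)
  expect_error(train_mil(pos, cohort$bags[1:2], cfg), "single class")
})

test_that("prediction is permutation invariant and attends to planted signal", {
  fit <- small_trained_fixture()
  bag <- fit$cohort$bags[[fit$test_idx[1]]]
  res <- predict(fit$model, bag)
  expect_equal(sum(res$alpha), 1, tolerance = 1e-9)

  perm <- sample(nrow(bag$features))
  shuf <- feature_bag(bag$slide_id, bag$features[perm, ],
                      refs = bag$refs[perm, ], label = bag$label)
  res2 <- predict(fit$model, shuf)
  expect_equal(res2$p, res$p, tolerance = 1e-9)
  expect_equal(res2$alpha, res$alpha[perm], tolerance = 1e-9)
  expect_equal(res2$z, res$z, tolerance = 1e-9)

  # N = 1 bag: trivial attention
  one <- feature_bag("S1", bag$features[1, , drop = FALSE], label = 1)
  r1 <- predict(fit$model, one)
  expect_equal(r1$alpha, 1)
  expect_equal(r1$z, bag$features[1, ])

  expect_error(predict(fit$model, rand_bag(d = 5)), "expects d")

  # held-out discrimination and attention recovery at reduced scale
  y <- fit$cohort$labels$label[fit$test_idx]
  p <- vapply(fit$cohort$bags[fit$test_idx],
              function(b) predict(fit$model, b)$p, numeric(1))
  expect_gte(auc_roc(y, p), 0.95)
  pos <- which(fit$cohort$labels$label == 1)
  rec <- vapply(pos, function(i) {
    a <- predict(fit$model, fit$cohort$bags[[i]])$alpha
    sig <- fit$cohort$signal_flags[[i]]
    mean(a[sig]) > mean(a[!sig])
  }, logical(1))
  expect_gt(mean(rec), 0.9)
})

test_that("checkpoints reproduce predictions exactly", {
  fit <- small_trained_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  bag <- fit$cohort$bags[[1]]
  expect_identical(predict(back, bag), predict(fit$model, bag))
})
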