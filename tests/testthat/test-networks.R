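# Architecture construction, parameter accounting, the multi-task loss and
# its oracles, prediction invariants, and full-model gradient checks.

test_that("configuration invariants are enforced", {
  expect_error(backbone_config(conv_filters = 10, groupnorm_groups = 4),
               "divide")
  expect_error(backbone_config(conv_kernel_size = 8), "odd")
  expect_error(backbone_config(window_length = 600), "odd")
  expect_error(backbone_config(dropout_rate = 1), "dropout_rate")
  expect_error(backbone_config(transformer_heads = 3), "divide")
  expect_error(build_model(structure(list(), class = "list")), "m6a_config")
})

test_that("a multitask model exposes exactly two output heads", {
  cfg <- tiny_config(variant = "cnn_bilstm")
  model <- build_model(cfg, "multitask")
  pred <- predict(model, rand_seq(3, 21, alphabet = c("A", "U", "C", "G")))
  expect_named(pred, c("p_positive", "p_negative", "reg_output", "confidence"))
  expect_equal(pred$p_positive + pred$p_negative, rep(1, 3), tolerance = 1e-6)
  expect_true(all(is.finite(pred$reg_output)))

  c_only <- predict(build_model(cfg, "classify_only"),
                    rand_seq(2, 21, alphabet = c("A", "U", "C", "G")))
  expect_false("reg_output" %in% names(c_only))
  r_only <- predict(build_model(cfg, "regress_only"),
                    rand_seq(2, 21, alphabet = c("A", "U", "C", "G")))
  expect_false("p_positive" %in% names(r_only))
})

test_that("the same configuration and seed build identical weights", {
  cfg <- tiny_config(variant = "cnn_bilstm")
  expect_identical(build_model(cfg, "multitask")$params,
                   build_model(cfg, "multitask")$params)
  cfg2 <- tiny_config(variant = "cnn_bilstm")
  cfg2$seed <- 43L
  expect_false(identical(build_model(cfg, "multitask")$params,
                         build_model(cfg2, "multitask")$params))
})

test_that("parameter counts match the analytic layer formulae and ordering", {
  L <- 21; K <- 5; Fh <- 16; G <- 4; H <- 8; P <- 4; D <- 64; ff <- 64
  dflat <- function(ch) ch * (L %/% P)
  base <- function(ch) {
    (4 * K * Fh + Fh) + 2 * Fh +                 # conv + group norm
      (dflat(ch) * D + D) + (D * 2 + 2) + (D + 1)  # dense + both heads
  }
  counts <- c(
    cnn = base(Fh),
    cnn_bilstm = base(2 * H) + 2 * (Fh * 4 * H + H * 4 * H + 4 * H),
    cnn_transformer = base(Fh) + L * Fh + 4 * (Fh * Fh + Fh) +
      2 * (2 * Fh) + (Fh * ff + ff + ff * Fh + Fh))
  for (v in names(counts)) {
    model <- build_model(tiny_config(variant = v), "multitask")
    expect_identical(n_params(model), as.integer(counts[v]))
    expect_identical(sum(tidy(model)$n_parameters),
                     as.integer(counts[v]))
  }
  expect_lt(counts["cnn"], counts["cnn_bilstm"])
  expect_lt(counts["cnn_bilstm"], counts["cnn_transformer"])
})

test_that("the loss matches direct scalar evaluation on single samples", {
  y <- matrix(c(1, 0), 1)
  # p(true) = p(other) = 0.5, no regression residual: both-class CE form
  l <- multitask_loss(y, matrix(c(0.5, 0.5), 1), yr = 0.3, yhat = 0.3)
  expect_equal(attr(l, "ce"), -2 * log(0.5), tolerance = 1e-12)
  expect_equal(attr(l, "ce"), 1.3863, tolerance = 1e-4)
  expect_equal(attr(l, "logcosh"), 0)

  # correct class certain, unit regression residual: log(cosh(1))
  l2 <- multitask_loss(y, matrix(c(1 - 1e-7, 1e-7), 1), yr = 0, yhat = 1)
  expect_equal(attr(l2, "logcosh"), log((exp(1) + exp(-1)) / 2),
               tolerance = 1e-12)
  expect_equal(attr(l2, "logcosh"), 0.43378, tolerance = 1e-5)

  # perfect prediction: loss vanishes to clipping precision
  lp <- multitask_loss(y, matrix(c(1, 0), 1), yr = 0.4, yhat = 0.4)
  expect_lt(as.numeric(lp), 1e-5)

  expect_error(multitask_loss(y, matrix(c(NaN, 0.5), 1), 0, 0), "NaN")
})

test_that("weight ablations reduce the loss to the single-task forms", {
  set.seed(12)
  n <- 16
  y <- m6adeep:::encode_labels(sample(c("positive", "negative"), n, TRUE))
  p <- softmax <- exp(matrix(rnorm(2 * n), n)); p <- p / rowSums(p)
  yr <- runif(n); yhat <- runif(n)
  both <- multitask_loss(y, p, yr, yhat, w_class = 1, w_reg = 1)
  class_only <- multitask_loss(y, p, yr, yhat, w_class = 1, w_reg = 0)
  reg_only <- multitask_loss(y, p, yr, yhat, w_class = 0, w_reg = 1)
  expect_equal(as.numeric(class_only), attr(both, "ce"))
  expect_equal(as.numeric(reg_only), attr(both, "logcosh"))
  expect_equal(as.numeric(both),
               as.numeric(class_only) + as.numeric(reg_only))

  # the preset weight ratio is applied multiplicatively
  wts <- loss_weights_uncertainty()
  lw <- multitask_loss(y, p, yr, yhat, w_class = wts$loss_weight_class,
                       w_reg = wts$loss_weight_reg)
  expect_equal(as.numeric(lw),
               0.06 * attr(both, "ce") + 1.85 * attr(both, "logcosh"))
})

test_that("the log-cosh term is symmetric, non-negative and exact", {
  set.seed(13)
  r <- rnorm(200, sd = 2)
  direct <- log(cosh(r))
  term <- vapply(r, function(ri) {
    attr(multitask_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
                        yr = 0, yhat = ri), "logcosh")
  }, numeric(1))
  expect_equal(term, direct, tolerance = 1e-10)
  neg <- vapply(-r, function(ri) {
    attr(multitask_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
                        yr = 0, yhat = ri), "logcosh")
  }, numeric(1))
  expect_equal(term, neg, tolerance = 1e-12)
  expect_true(all(term >= 0))
  expect_identical(attr(multitask_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
                                       yr = 0.7, yhat = 0.7), "logcosh"), 0)
})

test_that("the printed cross-entropy equals twice the categorical form", {
  set.seed(14)
  n <- 32
  y <- m6adeep:::encode_labels(sample(c("positive", "negative"), n, TRUE))
  p <- exp(matrix(rnorm(2 * n), n)); p <- p / rowSums(p)
  printed <- attr(multitask_loss(y, p, ce_form = "printed",
                                 yr = NULL, yhat = NULL, w_reg = 0), "ce")
  categorical <- attr(multitask_loss(y, p, ce_form = "categorical",
                                     yr = NULL, yhat = NULL, w_reg = 0), "ce")
  expect_equal(printed, 2 * categorical, tolerance = 1e-10)
})

test_that("inference is deterministic and chance-level before training", {
  cfg <- backbone_config(variant = "cnn_bilstm", window_length = 21,
                         conv_kernel_size = 5, pool_size = 4,
                         dropout_rate = 0.5, seed = 42)
  model <- build_model(cfg, "multitask")
  x <- rand_onehot_batch(600, 21, seed = 15)
  p1 <- predict(model, x)
  p2 <- predict(model, x)
  expect_identical(p1, p2)
  expect_equal(p1$p_positive + p1$p_negative, rep(1, 600), tolerance = 1e-6)

  labels <- rep(c(1, 0), 300)
  auroc <- roc_pr_curves(labels, p1$p_positive)$auroc
  expect_gt(auroc, 0.4)
  expect_lt(auroc, 0.6)
})

test_that("analytic gradients match numerical differentiation everywhere", {
  expect_lt(model_gradcheck("cnn", "multitask"), 1e-4)
  expect_lt(model_gradcheck("cnn_bilstm", "multitask"), 1e-4)
  expect_lt(model_gradcheck("cnn_transformer", "multitask"), 1e-4)
  expect_lt(model_gradcheck("cnn_bilstm", "classify_only"), 1e-4)
  expect_lt(model_gradcheck("cnn_bilstm", "regress_only"), 1e-4)
  expect_lt(model_gradcheck("cnn_bilstm", "multitask", task_specific = TRUE),
            1e-4)
})
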