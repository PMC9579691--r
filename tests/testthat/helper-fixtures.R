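# Shared fixture builders and independent oracles used across test files.
# Everything is generated in code; no fixture files.

rand_seq <- function(n, L, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

rand_genome <- function(len, seed = 1, chrom = "chrT") {
  set.seed(seed)
  new_genome(setNames(paste(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = ""), chrom))
}

# Naive reverse complement, independent of Biostrings: per-character loop.
naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Small window tibble over the RNA alphabet with labels and targets.
rand_windows <- function(n, L, seed = 1, with_target = TRUE) {
  set.seed(seed)
  tibble::tibble(
    chrom = "chrT",
    position = seq_len(n) * (L + 2L),
    strand = sample(c("+", "-"), n, TRUE),
    support_num = sample(1:20, n, TRUE),
    source = "test",
    sequence = rand_seq(n, L, alphabet = c("A", "U", "C", "G")),
    motif = "OTHER",
    label = rep(c("positive", "negative"), length.out = n),
    support_target = if (with_target) runif(n) else NULL
  )
}

tiny_config <- function(...) {
  backbone_config(window_length = 21, conv_kernel_size = 5, pool_size = 4,
                  dropout_rate = 0, seed = 42, ...)
}

rand_onehot_batch <- function(n, L, seed = 1) {
  set.seed(seed)
  x <- array(0, c(n, 4, L))
  for (i in seq_len(n)) for (j in seq_len(L)) x[i, sample(4, 1), j] <- 1
  x
}

# Central-difference gradient check of the full model loss for a sampled
# subset of parameters; returns the worst relative error.
model_gradcheck <- function(variant, mode, task_specific = FALSE,
                            n_checks = 4, eps = 1e-5, seed = 7) {
  cfg <- tiny_config(variant = variant, task_specific_dense = task_specific)
  model <- build_model(cfg, mode = mode)
  set.seed(seed)
  n <- 3
  x <- rand_onehot_batch(n, 21, seed = seed)
  y <- m6adeep:::encode_labels(sample(c("positive", "negative"), n, TRUE))
  yr <- runif(n)
  use_class <- mode != "regress_only"
  use_reg <- mode != "classify_only"

  loss_fn <- function(m) {
    out <- m6adeep:::forward_model(m, x, training = FALSE)
    m6adeep:::loss_and_grads(if (use_class) y else NULL, out$p,
                             if (use_reg) yr else NULL, out$yhat,
                             1.3, 0.7, "printed")$total
  }
  out <- m6adeep:::forward_model(model, x, training = FALSE)
  lg <- m6adeep:::loss_and_grads(if (use_class) y else NULL, out$p,
                                 if (use_reg) yr else NULL, out$yhat,
                                 1.3, 0.7, "printed")
  grads <- m6adeep:::backward_model(model, out,
                                    dz_class = if (use_class) lg$dz else NULL,
                                    dyhat = if (use_reg) lg$dyhat else NULL)
  worst <- 0
  for (layer in names(grads)) {
    for (w in names(grads[[layer]])) {
      g <- grads[[layer]][[w]]
      for (ii in sample(length(g), min(n_checks, length(g)))) {
        m2 <- model
        m2$params[[layer]][[w]][ii] <- m2$params[[layer]][[w]][ii] + eps
        lp <- loss_fn(m2)
        m2$params[[layer]][[w]][ii] <- m2$params[[layer]][[w]][ii] - 2 * eps
        lm <- loss_fn(m2)
        num <- (lp - lm) / (2 * eps)
        # absolute floor guards directions whose true gradient is ~0 (for
        # instance the attention key bias, which softmax cancels exactly)
        worst <- max(worst, abs(num - g[ii]) / max(1e-2, abs(num) + abs(g[ii])))
      }
    }
  }
  worst
}

# Small simulated dataset ready for training: windows with labels and
# normalised support targets, split 4:1.
sim_training_data <- function(n_per_class = 60, k = 10, signal_strength = 2,
                              seed = 5, ...) {
  spec <- synthetic_spec(n_pos = n_per_class, n_neg = n_per_class, k = k,
                         signal_strength = signal_strength, seed = seed, ...)
  sim <- simulate_m6a(spec)
  pos <- extract_windows(sim$genome, sim$positives, k = k)
  pos$label <- "positive"
  neg <- extract_windows(sim$genome, sim$negatives, k = k)
  neg$label <- "negative"
  all <- rbind(pos, neg)
  sp <- split_train_test(all, 0.8, seed = seed)
  norm <- fit_support_normalizer(sp$train)
  list(train = apply_support_normalizer(sp$train, norm),
       test = apply_support_normalizer(sp$test, norm),
       normalizer = norm, sim = sim)
}
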