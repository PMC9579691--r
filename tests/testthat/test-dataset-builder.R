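# Redundancy reduction, balancing, splitting, support normalisation and the
# stage-2 set-difference construction.

test_that("redundancy reduction collapses duplicates and keeps dissimilar pairs", {
  w <- tibble::tibble(sequence = rep(strrep("ACGU", 25), 2))
  rr <- reduce_redundancy(w, threshold = 0.7)
  expect_identical(nrow(rr$windows), 1L)
  expect_identical(rr$clusters$cluster, c(1L, 1L))

  w2 <- tibble::tibble(sequence = c(strrep("A", 40), strrep("U", 40)))
  rr2 <- reduce_redundancy(w2, threshold = 0.7)
  expect_identical(nrow(rr2$windows), 2L)

  expect_error(reduce_redundancy(tibble::tibble(sequence = c("AC", "ACG"))),
               "equal length")
})

test_that("no retained pair reaches the threshold (all-pairs brute force)", {
  # correlated random sequences so some pairs do exceed the threshold
  set.seed(31)
  base <- strsplit(rand_seq(1, 50, seed = 31), "")[[1]]
  seqs <- vapply(1:60, function(i) {
    mut <- base
    k <- sample(0:30, 1)
    idx <- sample(50, k)
    mut[idx] <- sample(c("A", "C", "G", "T"), k, TRUE)
    paste(mut, collapse = "")
  }, character(1))
  w <- tibble::tibble(sequence = seqs)
  rr <- reduce_redundancy(w, threshold = 0.7)
  reps <- rr$windows$sequence
  if (length(reps) > 1) {
    pairs <- utils::combn(length(reps), 2)
    idents <- apply(pairs, 2, function(p) {
      pairwise_identity(reps[p[1]], reps[p[2]])
    })
    expect_true(all(idents < 0.7))
  }
  # every clustered-away member matches its representative at >= threshold
  memb <- rr$clusters
  rep_of <- memb$index[memb$representative]
  for (i in memb$index[!memb$representative]) {
    r <- rep_of[memb$cluster[i]]
    expect_gte(pairwise_identity(seqs[i], seqs[r]), 0.7)
  }
})

test_that("under-sampling balances classes deterministically", {
  w <- rand_windows(13, 9, seed = 2)
  w$label <- rep(c("positive", "negative"), c(3, 10))
  b <- balance_by_undersampling(w, seed = 1)
  expect_identical(unname(table(b$label)["positive"]), 3L)
  expect_identical(unname(table(b$label)["negative"]), 3L)
  expect_identical(balance_by_undersampling(w, seed = 1), b)
  expect_false(identical(
    sort(balance_by_undersampling(w, seed = 2)$sequence[b$label == "negative"]),
    sort(b$sequence[b$label == "negative"])) &&
    identical(balance_by_undersampling(w, seed = 2), b))

  weq <- rand_windows(8, 9, seed = 3)
  beq <- balance_by_undersampling(weq, seed = 1)
  expect_setequal(beq$sequence, weq$sequence)  # no-op up to order

  expect_error(
    balance_by_undersampling(dplyr::mutate(w, label = "positive")),
    "non-empty")
})

test_that("stratified 4:1 split follows the flooring convention", {
  w <- rand_windows(20, 9, seed = 4)
  sp <- split_train_test(w, ratio = 0.8, seed = 1)
  expect_identical(as.integer(table(sp$train$label)), c(8L, 8L))
  expect_identical(as.integer(table(sp$test$label)), c(2L, 2L))
  # disjoint and exhaustive partition
  key <- function(d) paste(d$position, d$sequence)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(w))

  # benchmark arithmetic: 10,937 per class -> 8,749 / 2,188
  big <- tibble::tibble(label = rep(c("positive", "negative"), each = 10937))
  spb <- split_train_test(big, ratio = 0.8, seed = 1)
  expect_identical(sum(spb$train$label == "positive"), 8749L)
  expect_identical(sum(spb$test$label == "positive"), 2188L)

  expect_error(split_train_test(rand_windows(2, 9), ratio = 0.8),
               "too small")
})

test_that("support normalisation is min-max with clipping and exact inverse", {
  tr <- tibble::tibble(label = "positive", support_num = c(1, 3, 5))
  nm <- fit_support_normalizer(tr)
  expect_equal(transform_support(nm, c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(transform_support(nm, 7), 1)   # clipped
  expect_equal(transform_support(nm, 0), 0)   # clipped below
  x <- c(1, 2.2, 4.8, 5)
  expect_equal(inverse_support(nm, transform_support(nm, x)), x)

  expect_error(fit_support_normalizer(
    tibble::tibble(label = "positive", support_num = rep(4, 5))), "constant")

  w <- rand_windows(10, 9, seed = 5)
  w$support_num <- 1:10
  out <- apply_support_normalizer(w, fit_support_normalizer(w))
  expect_true(all(out$support_target[out$label == "negative"] == 0))
  expect_true(all(out$support_target >= 0 & out$support_target <= 1))
})

test_that("stage-2 dataset uses the atlas/low-resolution set difference", {
  dat <- sim_training_data(n_per_class = 40, k = 6, seed = 9)
  sim <- dat$sim
  atlas <- sim$positives[sim$truth$stage2[sim$truth$label == "positive"], ]
  ds <- build_stage2_dataset(atlas, sim$positives, sim$genome, k = 6,
                             threshold = 0.7, seed = 1)
  # negatives are exactly the non-atlas positives (before reduction)
  expect_identical(
    ds$manifest$count[ds$manifest$step == "negatives_after_set_difference"],
    nrow(sim$positives) - nrow(atlas))
  expect_identical(sum(ds$train$label == "positive"),
                   sum(ds$train$label == "negative"))
  expect_identical(sum(ds$test$label == "positive"),
                   sum(ds$test$label == "negative"))

  expect_error(
    build_stage2_dataset(sim$positives, sim$positives, sim$genome, k = 6),
    "Empty negative set")
})

test_that("stage-1 dataset builder produces balanced splits with a manifest", {
  dat <- sim_training_data(n_per_class = 30, k = 6, seed = 21)
  sim <- dat$sim
  ds <- build_stage1_dataset(sim$positives, sim$genome, motif = "GAC", k = 6,
                             threshold = 0.9, seed = 2)
  expect_identical(sum(ds$train$label == "positive"),
                   sum(ds$train$label == "negative"))
  expect_true(all(ds$train$support_target[ds$train$label == "negative"] == 0))
  expect_s3_class(ds$manifest, "tbl_df")
  expect_identical(
    ds$manifest$count[ds$manifest$step == "train_per_class"],
    sum(ds$train$label == "positive"))
})
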