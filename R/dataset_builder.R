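# Benchmark-dataset construction: redundancy reduction, class balancing,
# stratified splitting, and support-count normalisation.
#
# A "dataset split" is simply a windows tibble carrying a `label` column
# ("positive"/"negative") and, once a normaliser has been applied, a
# `support_target` column in [0, 1].

#' Greedy redundancy reduction of equal-length windows
#'
#' Sequences are visited in input order; each joins the first existing
#' cluster whose representative it matches with pairwise identity at or
#' above `threshold`, otherwise it founds a new cluster.  Identity is the
#' fraction of exactly matching characters in the ungapped comparison of the
#' two equal-length windows.  Positives and negatives should be reduced
#' separately by the caller.
#'
#' @param windows Windows tibble with a `sequence` column; all sequences must
#'   have equal length.
#' @param threshold Identity threshold in (0, 1]; default 0.7, the clustering
#'   cutoff used for the benchmark datasets.
#' @param seed Accepted for interface stability; the first-fit input-order
#'   policy has no ties to break, so the value is not consumed.
#' @return A list with `windows` (the representatives, a subset of the input
#'   rows), and `clusters`, a tibble mapping every input row to its cluster
#'   and flagging representatives.
#' @export
reduce_redundancy <- function(windows, threshold = 0.7, seed = NULL) {
  check_scalar_number(threshold, "threshold", lower = 1e-12, upper = 1)
  seqs <- windows$sequence
  n <- length(seqs)
  if (n == 0) abort("No windows to reduce.")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) abort("All windows must have equal length.")

  m <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
  rep_mat <- matrix(0L, nrow = L, ncol = n)
  rep_idx <- integer(n)
  n_rep <- 0L
  cluster <- integer(n)

  for (i in seq_len(n)) {
    assigned <- 0L
    if (n_rep > 0) {
      ident <- colMeans(rep_mat[, seq_len(n_rep), drop = FALSE] == m[, i])
      hit <- which(ident >= threshold)
      if (length(hit) > 0) assigned <- hit[1]
    }
    if (assigned == 0L) {
      n_rep <- n_rep + 1L
      rep_mat[, n_rep] <- m[, i]
      rep_idx[n_rep] <- i
      assigned <- n_rep
    }
    cluster[i] <- assigned
  }

  reps <- rep_idx[seq_len(n_rep)]
  list(
    windows = windows[reps, , drop = FALSE],
    clusters = tibble(index = seq_len(n), cluster = cluster,
                      representative = seq_len(n) %in% reps),
    threshold = threshold
  )
}

# Pairwise identity of two equal-length sequences; exported for use as a
# plain utility (tests compare reduce_redundancy against the all-pairs rule).
#' Ungapped pairwise identity of two equal-length sequences
#' @param a,b Single sequences of equal length.
#' @return Fraction of positions with identical characters.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("Sequences must have equal length.")
  mean(utf8ToInt(a) == utf8ToInt(b))
}

#' Balance a dataset by under-sampling the larger class
#'
#' @param windows Windows tibble with a `label` column over
#'   `{"positive", "negative"}`.
#' @param seed Integer seed for the uniform subsample and the final shuffle.
#' @return A balanced windows tibble (equal class counts), deterministically
#'   shuffled.
#' @export
balance_by_undersampling <- function(windows, seed = 1) {
  counts <- table(factor(windows$label, levels = c("positive", "negative")))
  if (any(counts == 0)) {
    abort("Both classes must be non-empty before balancing.")
  }
  target <- min(counts)
  with_seed(seed, {
    kept <- windows |>
      dplyr::group_by(.data$label) |>
      dplyr::slice_sample(n = target) |>
      dplyr::ungroup()
    kept[sample.int(nrow(kept)), , drop = FALSE]
  })
}

#' Stratified train/test split
#'
#' Splits each label class separately so balanced inputs stay balanced.  Per
#' class the training side receives `floor(ratio * n)` samples and the test
#' side the remainder: a 4:1 design on 10,937 per class yields 8,749 train
#' and 2,188 test per class.
#'
#' @param windows Windows tibble with a `label` column.
#' @param ratio Training fraction in (0, 1); 4:1 corresponds to 0.8.
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles; the partition is disjoint
#'   and exhaustive.
#' @export
split_train_test <- function(windows, ratio = 0.8, seed = 1) {
  check_scalar_number(ratio, "ratio", lower = 1e-12, upper = 1 - 1e-12)
  labels <- unique(windows$label)
  idx_train <- with_seed(seed, {
    unlist(lapply(labels, function(lb) {
      idx <- which(windows$label == lb)
      n_tr <- floor(ratio * length(idx))
      if (n_tr < 1 || n_tr >= length(idx)) {
        abort(sprintf("Class '%s' is too small to stratify at ratio %.2f.",
                      lb, ratio))
      }
      sample(idx, n_tr)
    }))
  })
  list(train = windows[sort(idx_train), , drop = FALSE],
       test = windows[setdiff(seq_len(nrow(windows)), idx_train), , drop = FALSE])
}

#' Fit a min-max normaliser for the support count
#'
#' Fitted on the positive training windows only, so the test data is scaled
#' without leakage; values outside the fitted range are clipped to [0, 1]
#' when applied.
#'
#' @param train Windows tibble with `label` and `support_num` columns.
#' @return An object of class `support_normalizer` with fields `min` and
#'   `max`.
#' @export
fit_support_normalizer <- function(train) {
  s <- train$support_num[train$label == "positive"]
  if (length(unique(s)) < 2) {
    abort("Support counts are constant; a min-max normaliser is undefined.")
  }
  structure(list(min = min(s), max = max(s)), class = "support_normalizer")
}

#' Transform support counts to [0, 1]
#' @param normalizer A `support_normalizer`.
#' @param x Numeric support counts.
#' @return `(x - min) / (max - min)`, clipped to [0, 1].
#' @export
transform_support <- function(normalizer, x) {
  pmin(1, pmax(0, (x - normalizer$min) / (normalizer$max - normalizer$min)))
}

#' Invert the support transform for in-range values
#' @param normalizer A `support_normalizer`.
#' @param y Normalised values in [0, 1].
#' @return Support counts on the original scale.
#' @export
inverse_support <- function(normalizer, y) {
  y * (normalizer$max - normalizer$min) + normalizer$min
}

#' Attach regression targets to a dataset split
#'
#' Positives receive the normalised support count; negatives receive exactly
#' 0 (no experimental support), which is the default convention and can be
#' overridden through `negative_target`.
#'
#' @param windows Windows tibble with `label` and `support_num`.
#' @param normalizer A fitted `support_normalizer`.
#' @param negative_target Regression target assigned to negative windows.
#' @return `windows` with a `support_target` column in [0, 1].
#' @export
apply_support_normalizer <- function(windows, normalizer, negative_target = 0) {
  windows$support_target <- ifelse(
    windows$label == "positive",
    transform_support(normalizer, windows$support_num),
    negative_target)
  windows
}

#' Build a stage-1 benchmark dataset for one central motif
#'
#' Extracts positive windows for the given motif, samples (or accepts)
#' motif-matched negative sites, reduces redundancy within each class,
#' balances by under-sampling, splits 4:1, and fits the support normaliser
#' on the training positives.
#'
#' @param sites Positive sites tibble (with `support_num`).
#' @param genome An `m6a_genome`.
#' @param motif `"GAC"` or `"AAC"`; positives whose extracted window carries
#'   a different central motif are dropped.
#' @param k Window half-width (default 300, i.e. 601-nt windows).
#' @param threshold Redundancy-reduction identity threshold.
#' @param ratio Training fraction.
#' @param neg_sites Optional negative sites tibble; when `NULL`, negatives
#'   are sampled from the genome at `neg_ratio` times the positive count.
#' @param neg_ratio Negative oversampling factor before under-sampling.
#' @param seed Integer seed governing sampling, balancing and splitting.
#' @return A list with `train`, `test`, the fitted `normalizer`, and a
#'   `manifest` tibble of per-step counts.
#' @export
build_stage1_dataset <- function(sites, genome, motif = c("GAC", "AAC"),
                                 k = 300, threshold = 0.7, ratio = 0.8,
                                 neg_sites = NULL, neg_ratio = 1.5, seed = 1) {
  motif <- match.arg(motif)
  pos <- extract_windows(genome, sites, k = k, on_reject = "skip")
  pos <- pos[pos$motif == motif, , drop = FALSE]
  if (nrow(pos) == 0) abort(sprintf("No positive windows with %s motif.", motif))
  pos$label <- "positive"

  if (is.null(neg_sites)) {
    neg_sites <- sample_negative_sites(
      genome, exclude = sites, motif = motif,
      n = ceiling(neg_ratio * nrow(pos)), seed = seed)
  } else {
    neg_sites <- dplyr::anti_join(
      neg_sites, dplyr::select(sites, "chrom", "position", "strand"),
      by = c("chrom", "position", "strand"))
  }
  neg <- extract_windows(genome, neg_sites, k = k, on_reject = "skip")
  neg <- neg[neg$motif == motif, , drop = FALSE]
  neg$label <- "negative"

  pos_r <- reduce_redundancy(pos, threshold = threshold)$windows
  neg_r <- reduce_redundancy(neg, threshold = threshold)$windows

  balanced <- balance_by_undersampling(dplyr::bind_rows(pos_r, neg_r), seed = seed)
  split <- split_train_test(balanced, ratio = ratio, seed = seed)
  normalizer <- fit_support_normalizer(split$train)
  train <- apply_support_normalizer(split$train, normalizer)
  test <- apply_support_normalizer(split$test, normalizer)

  manifest <- tibble(
    step = c("positives_extracted", "negatives_extracted",
             "positives_nonredundant", "negatives_nonredundant",
             "train_per_class", "test_per_class"),
    count = c(nrow(pos), nrow(neg), nrow(pos_r), nrow(neg_r),
              sum(train$label == "positive"), sum(test$label == "positive"))
  )
  list(train = train, test = test, normalizer = normalizer, manifest = manifest)
}

#' Build the stage-2 benchmark dataset
#'
#' Positives are windows around base-resolution sites; negatives are the
#' low-resolution sites absent (by `chrom`/`position`/`strand`) from the
#' base-resolution set.  Both classes are redundancy-reduced, the negatives
#' under-sampled to the positive count, and the result split 4:1.
#'
#' @param atlas_sites Base-resolution positive sites tibble.
#' @param rmbase_sites Low-resolution sites tibble (superset candidates for
#'   negatives).
#' @param genome An `m6a_genome`.
#' @param k Window half-width.
#' @param threshold Redundancy threshold.
#' @param ratio Training fraction.
#' @param seed Integer seed.
#' @return A list with `train`, `test`, and a `manifest` tibble.
#' @export
build_stage2_dataset <- function(atlas_sites, rmbase_sites, genome, k = 300,
                                 threshold = 0.7, ratio = 0.8, seed = 1) {
  neg_sites <- dplyr::anti_join(
    rmbase_sites, dplyr::select(atlas_sites, "chrom", "position", "strand"),
    by = c("chrom", "position", "strand"))
  if (nrow(neg_sites) == 0) {
    abort("Empty negative set: every low-resolution site is also base-resolution.")
  }

  pos <- extract_windows(genome, atlas_sites, k = k, on_reject = "skip")
  pos$label <- "positive"
  neg <- extract_windows(genome, neg_sites, k = k, on_reject = "skip")
  neg$label <- "negative"

  pos_r <- reduce_redundancy(pos, threshold = threshold)$windows
  neg_r <- reduce_redundancy(neg, threshold = threshold)$windows
  balanced <- balance_by_undersampling(dplyr::bind_rows(pos_r, neg_r), seed = seed)
  split <- split_train_test(balanced, ratio = ratio, seed = seed)

  manifest <- tibble(
    step = c("positives", "negatives_after_set_difference",
             "positives_nonredundant", "negatives_nonredundant",
             "train_per_class", "test_per_class"),
    count = c(nrow(pos), nrow(neg), nrow(pos_r), nrow(neg_r),
              sum(split$train$label == "positive"),
              sum(split$test$label == "positive"))
  )
  list(train = split$train, test = split$test, manifest = manifest)
}
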