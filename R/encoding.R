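# One-hot encoding of sequence windows and batch assembly.
#
# The alphabet mapping is A -> (1,0,0,0), U -> (0,1,0,0), C -> (0,0,1,0),
# G -> (0,0,0,1), and N -> (0,0,0,0): N is the padding pseudo-nucleotide, so
# its column sums to zero.

ONEHOT_ROWS <- c("A", "U", "C", "G")

onehot_code <- local({
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("U")] <- 2L
  lut[utf8ToInt("C")] <- 3L
  lut[utf8ToInt("G")] <- 4L
  lut[utf8ToInt("N")] <- -1L  # sentinel: legal, encodes to the zero column
  lut
})

#' One-hot encode a batch of windows
#'
#' @param windows Windows tibble (or a bare character vector of sequences)
#'   over the alphabet `A/U/C/G/N`; all sequences must share one length.
#' @return A numeric array of dim `c(N, 4, L)`; channel order `A, U, C, G`.
#' @export
encode_windows <- function(windows) {
  seqs <- if (is.character(windows)) windows else windows$sequence
  n <- length(seqs)
  if (n == 0) abort("No sequences to encode.")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) abort("All sequences must have equal length.")

  ints <- utf8ToInt(paste(seqs, collapse = ""))
  bad <- ints > 127L | onehot_code[pmin(ints, 127L)] == 0L
  if (any(bad)) {
    first <- which(bad)[1]
    abort(sprintf(
      "Unexpected character '%s' at position %d of sequence %d (alphabet is A/U/C/G/N).",
      intToUtf8(ints[first]), (first - 1) %% L + 1, (first - 1) %/% L + 1))
  }
  codes <- onehot_code[ints]

  arr <- array(0, dim = c(n, 4, L))
  keep <- codes > 0L
  if (any(keep)) {
    i <- rep(seq_len(n), each = L)[keep]
    p <- rep(seq_len(L), times = n)[keep]
    arr[cbind(i, codes[keep], p)] <- 1
  }
  arr
}

#' One-hot encode a single window
#'
#' @param sequence A single sequence over `A/U/C/G/N`.
#' @return A 4 x L numeric matrix with rownames `A, U, C, G`; every column
#'   sums to 1 except columns encoding `N`, which sum to 0.
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(length(sequence) == 1)
  m <- matrix(encode_windows(sequence)[1, , ], nrow = 4)
  rownames(m) <- ONEHOT_ROWS
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()]; zero columns decode to `N`.
#'
#' @param m A 4 x L one-hot matrix.
#' @return The decoded sequence.
#' @export
decode_onehot <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4) abort("Expected a 4 x L matrix.")
  if (!all(m %in% c(0, 1)) || !all(colSums(m) %in% c(0, 1))) {
    abort("Not a one-hot matrix: entries must be 0/1 with column sums 0 or 1.")
  }
  chars <- apply(m, 2, function(col) {
    hit <- which(col == 1)
    if (length(hit) == 0) "N" else ONEHOT_ROWS[hit]
  })
  paste(chars, collapse = "")
}

# One-hot class labels, column order (positive, negative).
encode_labels <- function(label) {
  y <- cbind(positive = as.numeric(label == "positive"),
             negative = as.numeric(label != "positive"))
  y
}

#' Assemble shuffled multi-task training batches
#'
#' Shuffles the split deterministically for the requested epoch (epoch `e`
#' uses the `e`-th permutation of the seeded stream, so successive epochs see
#' different but reproducible orders) and cuts it into batches; a final short
#' batch is kept.
#'
#' @param windows Dataset split (windows tibble with `label`, and
#'   `support_target` if regression targets are wanted).
#' @param batch_size Samples per batch (>= 1).
#' @param seed Integer seed.
#' @param epoch Epoch number (>= 1).
#' @param x Optional pre-encoded array from [encode_windows()] to avoid
#'   re-encoding every epoch.
#' @return A list of batches, each with elements `x` (n x 4 x L array), `y`
#'   (n x 2 one-hot labels, columns positive/negative), `yr` (regression
#'   targets), and `index` (row indices into `windows`).
#' @export
make_batches <- function(windows, batch_size, seed = 1, epoch = 1, x = NULL) {
  n <- nrow(windows)
  if (is.null(n) || n == 0) abort("Cannot batch an empty split.")
  batch_size <- check_count(batch_size, "batch_size", min = 1)
  epoch <- check_count(epoch, "epoch", min = 1)

  if (is.null(x)) x <- encode_windows(windows)
  y <- encode_labels(windows$label)
  yr <- if ("support_target" %in% names(windows)) {
    windows$support_target
  } else {
    rep(0, n)
  }

  perm <- with_seed(seed, {
    p <- NULL
    for (e in seq_len(epoch)) p <- sample.int(n)
    p
  })
  starts <- seq(1, n, by = batch_size)
  lapply(starts, function(s) {
    idx <- perm[s:min(s + batch_size - 1, n)]
    list(x = x[idx, , , drop = FALSE],
         y = y[idx, , drop = FALSE],
         yr = yr[idx],
         index = idx)
  })
}
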