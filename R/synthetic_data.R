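# Synthetic genomes with planted motif-bearing m6A sites.
#
# The generator emulates the structure of the real two-stage data: a
# background genome, positive adenosines whose flanks carry a position
# weight matrix (PWM) signal of controllable strength, motif-matched
# negatives with background flanks, an experiment-support count whose mean
# is tied to the planted signal, and a subset of "base-resolution" (stage-2)
# positives with a shifted flank signal.

DNA_BASES <- c("A", "C", "G", "T")

#' Default RRACH-compatible position weight matrix
#'
#' Columns span offsets `-width` to `width` around the methylated adenosine;
#' the central triplet (offsets -1, 0, 1) is fixed to the motif.  Flank
#' columns carry modest enrichments compatible with the RRACH consensus
#' (purine-rich at offset -2, A/C/U at offset +2) plus mild preferences
#' further out so that signal strength is a single continuous dial.
#'
#' @param motif `"GAC"` or `"AAC"`.
#' @param width Flank half-width of the PWM (default 10: a 21-column PWM,
#'   reflecting that the discriminative sequence context of m6A extends
#'   tens of nucleotides beyond the central triplet).
#' @param lean Probability of the preferred base at the outer flank
#'   positions (default 0.6; the remaining mass is spread evenly).
#' @return A 4 x (2*width+1) column-stochastic matrix, rows `A, C, G, T`,
#'   with `dimnames` giving offsets.
#' @export
default_pwm <- function(motif = c("GAC", "AAC"), width = 10, lean = 0.6) {
  motif <- match.arg(motif)
  width <- check_count(width, "width", min = 2)
  check_scalar_number(lean, "lean", lower = 0.25, upper = 0.95)
  offsets <- -width:width
  pwm <- matrix(0.25, 4, length(offsets),
                dimnames = list(DNA_BASES, as.character(offsets)))
  put <- function(off, probs) pwm[, as.character(off)] <<- probs
  motif_bases <- strsplit(motif, "")[[1]]
  for (i in 1:3) {
    col <- rep(0, 4); col[match(motif_bases[i], DNA_BASES)] <- 1
    put(i - 2, col)
  }
  put(-2, c(A = 0.40, C = 0.10, G = 0.40, T = 0.10))  # R = A/G
  put(2, c(A = 0.40, C = 0.30, G = 0.05, T = 0.25))   # H = A/C/U
  lean_col <- function(base) {
    col <- rep((1 - lean) / 3, 4); col[match(base, DNA_BASES)] <- lean
    col
  }
  outer_pref <- c("T", "A", "G", "C")  # fixed rotation over outer offsets
  outer_offs <- setdiff(offsets, -2:2)
  for (i in seq_along(outer_offs)) {
    put(outer_offs[i], lean_col(outer_pref[((i - 1) %% 4) + 1]))
  }
  pwm
}

#' Specification of a synthetic two-stage dataset
#'
#' @param n_pos,n_neg Numbers of positive and negative sites.
#' @param k Window half-width the sites must accommodate without overlap.
#' @param motif Central motif of all sites.
#' @param genome_length Background genome length; `NULL` sizes it to host
#'   all sites without overlapping windows (plus 10% slack).
#' @param gc_content Background GC fraction (default 0.38, yeast-like).
#' @param pwm Positive-class flank PWM; columns must be probability vectors.
#' @param signal_strength Log-odds multiplier `s >= 0`: flank bases are
#'   drawn from `bg^(1-s) * pwm^s` (renormalised), so 0 means background
#'   flanks and 1 means the PWM itself.
#' @param support_lambda,support_beta,support_theta Support-count model:
#'   `SupportNum = 1 + NB(mean = lambda * exp(beta * z), size = theta)`
#'   where `z` is the standardised planted flank signal score.  Defaults
#'   (lambda 2, theta 1.5) reproduce a strongly right-skewed histogram.
#' @param stage2_fraction Fraction of positives flagged base-resolution.
#' @param stage2_shift In [0, 1]: how far the stage-2 positive flank PWM is
#'   displaced towards a rotated PWM (0 = identical to stage 1).
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   spec.
#' @param chrom Chromosome name of the single synthetic sequence.
#' @return An object of class `m6a_synth_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, k = 150, motif = c("GAC", "AAC"),
                           genome_length = NULL, gc_content = 0.38,
                           pwm = default_pwm(match.arg(motif)),
                           signal_strength = 1, support_lambda = 2,
                           support_beta = 1.5, support_theta = 1.5,
                           stage2_fraction = 0.5, stage2_shift = 1,
                           seed = 1, chrom = "chrS") {
  motif <- match.arg(motif)
  n_pos <- check_count(n_pos, "n_pos"); n_neg <- check_count(n_neg, "n_neg")
  k <- check_count(k, "k")
  check_scalar_number(gc_content, "gc_content", 0.01, 0.99)
  check_scalar_number(signal_strength, "signal_strength", lower = 0)
  check_scalar_number(support_lambda, "support_lambda", lower = 1e-9)
  check_scalar_number(support_beta, "support_beta")
  check_scalar_number(support_theta, "support_theta", lower = 1e-9)
  check_scalar_number(stage2_fraction, "stage2_fraction", 1e-9, 1)
  check_scalar_number(stage2_shift, "stage2_shift", 0, 1)
  if (!is.matrix(pwm) || nrow(pwm) != 4 ||
      any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    abort("`pwm` must be a 4-row matrix with probability-vector columns.")
  }
  gap <- 10L
  # sites must not overlap through their windows nor their planted flanks
  reach <- max(k, (ncol(pwm) - 1) %/% 2)
  stride <- 2L * reach + 1L + gap
  if (is.null(genome_length)) {
    genome_length <- ceiling(1.1 * ((n_pos + n_neg) * stride + 2 * reach))
  }
  structure(list(
    n_pos = n_pos, n_neg = n_neg, k = k, motif = motif,
    genome_length = as.integer(genome_length), gc_content = gc_content,
    pwm = pwm, signal_strength = signal_strength,
    support_lambda = support_lambda, support_beta = support_beta,
    support_theta = support_theta, stage2_fraction = stage2_fraction,
    stage2_shift = stage2_shift, seed = as.integer(seed), chrom = chrom,
    gap = gap
  ), class = "m6a_synth_spec")
}

# Rotate base identities (A->C->G->T->A); used to build the stage-2-shifted
# flank PWM.
rotate_pwm <- function(pwm) {
  out <- pwm[c(4, 1, 2, 3), , drop = FALSE]
  rownames(out) <- rownames(pwm)
  out
}

# Geometric interpolation between two column-stochastic matrices.
blend_pwm <- function(p1, p2, tau) {
  if (tau <= 0) return(p1)
  m <- exp((1 - tau) * log(pmax(p1, 1e-12)) + tau * log(pmax(p2, 1e-12)))
  sweep(m, 2, colSums(m), `/`)
}

# Flank sampling distribution at signal strength s: bg^(1-s) * pwm^s.
signal_mixture <- function(pwm_col, bg, s) {
  w <- bg * exp(s * (log(pmax(pwm_col, 1e-12)) - log(bg)))
  w / sum(w)
}

#' Simulate a synthetic genome with planted two-stage m6A sites
#'
#' @param spec An [synthetic_spec()] object.
#' @return A list with `genome` (an `m6a_genome`), `positives` and
#'   `negatives` (site tibbles as consumed by [extract_windows()]), and
#'   `truth` (per-site planted signal score, support count and stage-2
#'   membership).
#' @export
simulate_m6a <- function(spec) {
  stopifnot(inherits(spec, "m6a_synth_spec"))
  k <- spec$k
  reach <- max(k, (ncol(spec$pwm) - 1L) %/% 2L)
  stride <- 2L * reach + 1L + spec$gap
  n_sites <- spec$n_pos + spec$n_neg
  n_slots <- (spec$genome_length - 2L * reach) %/% stride
  if (n_slots < n_sites) {
    abort(sprintf(
      "Genome of %d nt hosts only %d non-overlapping windows; %d needed. Increase `genome_length`.",
      spec$genome_length, n_slots, n_sites))
  }
  bg <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
          spec$gc_content / 2, (1 - spec$gc_content) / 2)
  names(bg) <- DNA_BASES
  flank_w <- (ncol(spec$pwm) - 1) / 2
  offsets <- -flank_w:flank_w
  flank_offs <- offsets[abs(offsets) > 1]
  pwm2 <- blend_pwm(spec$pwm, rotate_pwm(spec$pwm), spec$stage2_shift)
  motif_bases <- strsplit(spec$motif, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  with_seed(spec$seed, {
    genome_chars <- sample(DNA_BASES, spec$genome_length, replace = TRUE,
                           prob = bg)
    centres <- reach + 1L + (sample.int(n_slots, n_sites) - 1L) * stride
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
    pos_idx <- seq_len(spec$n_pos)
    stage2 <- rep(FALSE, spec$n_pos)
    stage2[sample.int(spec$n_pos, round(spec$stage2_fraction * spec$n_pos))] <- TRUE

    # per-offset sampling distributions for the two positive classes
    mix1 <- lapply(as.character(flank_offs), function(o) {
      signal_mixture(spec$pwm[, o], bg, spec$signal_strength)
    })
    mix2 <- lapply(as.character(flank_offs), function(o) {
      signal_mixture(pwm2[, o], bg, spec$signal_strength)
    })
    names(mix1) <- names(mix2) <- as.character(flank_offs)
    logodds <- log(pmax(spec$pwm[, as.character(flank_offs), drop = FALSE],
                        1e-12)) - log(bg)

    write_local <- function(centre, strand, local, offs) {
      # `local` reads 5'->3' on the transcript strand at the given offsets
      if (strand == "+") {
        genome_chars[centre + offs] <<- local
      } else {
        genome_chars[centre - offs] <<- unname(comp[local])
      }
    }
    score_of <- function(flank_bases) {
      sum(logodds[cbind(match(flank_bases, DNA_BASES),
                        seq_along(flank_offs))])
    }

    score <- numeric(n_sites)
    for (i in seq_len(n_sites)) {
      centre <- centres[i]; strand <- strands[i]
      is_pos <- i <= spec$n_pos
      write_local(centre, strand, motif_bases, -1:1)
      if (is_pos) {
        mix <- if (stage2[i]) mix2 else mix1
        flank <- vapply(as.character(flank_offs),
                        function(o) sample(DNA_BASES, 1, prob = mix[[o]]),
                        character(1))
        write_local(centre, strand, flank, flank_offs)
        score[i] <- score_of(flank)
      } else {
        # read the background flank on the transcript strand
        plus <- genome_chars[centre + flank_offs]
        flank <- if (strand == "+") plus else
          unname(comp[genome_chars[centre - flank_offs]])
        score[i] <- score_of(flank)
      }
    }

    z <- (score[pos_idx] - mean(score[pos_idx])) /
      max(stats::sd(score[pos_idx]), 1e-12)
    mu <- spec$support_lambda * exp(spec$support_beta * z)
    support <- 1L + rnbinom(spec$n_pos, size = spec$support_theta, mu = mu)

    genome <- new_genome(
      setNames(paste(genome_chars, collapse = ""), spec$chrom))
    positives <- tibble(
      chrom = spec$chrom, position = centres[pos_idx],
      strand = strands[pos_idx], support_num = as.integer(support),
      source = "synthetic-positive")
    negatives <- tibble(
      chrom = spec$chrom, position = centres[-pos_idx],
      strand = strands[-pos_idx], support_num = 0L,
      source = "synthetic-negative")
    truth <- tibble(
      chrom = spec$chrom, position = centres,
      strand = strands,
      label = rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
      signal_score = score,
      support_num = c(as.integer(support), rep(0L, spec$n_neg)),
      stage2 = c(stage2, rep(FALSE, spec$n_neg)))

    list(genome = genome, positives = positives, negatives = negatives,
         truth = truth, spec = spec)
  })
}

#' Histogram of planted support counts
#'
#' @param truth Truth tibble from [simulate_m6a()].
#' @param breaks Numeric bin breaks covering all positive support counts;
#'   `NULL` uses unit-width bins.
#' @return A tibble with `bin` and `count`; counts sum to the number of
#'   positives.
#' @export
support_histogram <- function(truth, breaks = NULL) {
  s <- truth$support_num[truth$label == "positive"]
  if (length(s) == 0) abort("No positive sites in `truth`.")
  if (is.null(breaks)) breaks <- seq(0.5, max(s) + 0.5, by = 1)
  if (length(breaks) < 2) abort("`breaks` must define at least one bin.")
  cuts <- cut(s, breaks = breaks, include.lowest = TRUE)
  if (anyNA(cuts)) abort("`breaks` do not cover all support counts.")
  tb <- table(cuts)
  tibble(bin = names(tb), count = as.integer(tb))
}

#' Write a complete synthetic fixture directory
#'
#' Emits the genome as FASTA plus the positive/negative site tables and the
#' truth table as TSV — the same formats the genome-input functions consume.
#'
#' @param sim Result of [simulate_m6a()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- sim$genome$sequences
  con <- file.path(dir, "genome.fa")
  lines <- unlist(lapply(names(seqs), function(nm) {
    body <- gsub("(.{80})", "\\1\n", seqs[[nm]])
    c(paste0(">", nm), strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, con)
  write_sites(sim$positives, file.path(dir, "positives.tsv"))
  write_sites(sim$negatives, file.path(dir, "negatives.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
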