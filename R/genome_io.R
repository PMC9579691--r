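# Genome and site-table input, motif-centred window extraction.
#
# Coordinates are 1-based and fully closed, the convention of RMBase-style
# site tables.  Genomes are held internally in the DNA alphabet (T, not U);
# windows are emitted on the transcript strand in the RNA alphabet.

#' Construct a genome object from in-memory sequences
#'
#' @param sequences Named character vector, one element per chromosome, over
#'   the alphabet `A/C/G/T/U/N` (case-insensitive).  `U` is stored as `T`
#'   internally and converted back at window emission.
#' @param alphabet `"DNA"` or `"RNA"`; records how the input was written.
#' @return An object of class `m6a_genome`.
#' @export
new_genome <- function(sequences, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0) abort("A genome needs at least one sequence.")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("Every genome sequence must be named with a chromosome id.")
  }
  if (anyDuplicated(names(sequences))) {
    dup <- names(sequences)[duplicated(names(sequences))][1]
    abort(sprintf("Duplicate chromosome id in genome: '%s'.", dup))
  }
  if (any(!nzchar(sequences))) abort("Genome sequences must be non-empty.")
  seqs <- chartr("u", "t", toupper(sequences))
  seqs <- chartr("U", "T", seqs)
  structure(list(sequences = seqs, alphabet = alphabet), class = "m6a_genome")
}

#' @export
print.m6a_genome <- function(x, ...) {
  cat(sprintf("<m6a_genome> %d sequence(s), %s alphabet, %s nt total\n",
              length(x$sequences), x$alphabet,
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported (parsing is delegated to
#' [Biostrings::readBStringSet()]).  Lowercase input is uppercased; `U` is
#' converted to `T` internally and the genome is flagged as RNA.
#'
#' @param path Path to a FASTA file.
#' @return An `m6a_genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("Genome file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort(sprintf("Empty FASTA file: '%s'.", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("Malformed FASTA at line %d of '%s': expected a '>' header.",
                  first, path))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  # record ids: first whitespace-delimited token of the header
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    abort(sprintf("Duplicate FASTA record id: '%s'.", dup))
  }
  alphabet <- if (any(grepl("U", seqs, fixed = TRUE))) "RNA" else "DNA"
  new_genome(seqs, alphabet = alphabet)
}

#' Read a site table
#'
#' Tab-delimited with a header; required columns `chrom`, `position`,
#' `strand`, optional `support_num` (default 0) and `source`.  Lines starting
#' with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @param source Default source tag used when the file has no `source` column.
#' @return A tibble with columns `chrom`, `position`, `strand`,
#'   `support_num`, `source`.
#' @export
read_sites <- function(path, source = "sites") {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("chrom", "position", "strand")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("Site table '%s' lacks column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"support_num" %in% names(tbl)) tbl$support_num <- 0L
  if (!"source" %in% names(tbl)) tbl$source <- source
  tbl <- dplyr::mutate(tbl,
    chrom = as.character(.data$chrom),
    position = as.integer(.data$position),
    strand = as.character(.data$strand),
    support_num = as.integer(.data$support_num)
  )
  validate_sites(tbl)
  dplyr::select(tbl, "chrom", "position", "strand", "support_num", "source")
}

#' Write a site table as TSV
#'
#' @param sites Sites tibble as returned by [read_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

validate_sites <- function(sites) {
  if (any(sites$position < 1, na.rm = TRUE)) abort("Site positions must be >= 1.")
  bad <- setdiff(unique(sites$strand), c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("Invalid strand value(s): %s.", paste(bad, collapse = ", ")))
  }
  if (any(sites$support_num < 0, na.rm = TRUE)) {
    abort("`support_num` must be non-negative.")
  }
  invisible(sites)
}

#' Classify the central motif of windows
#'
#' The motif is a pure function of the three central characters of the
#' emitted (transcript-strand) sequence: `GAC`, `AAC`, or `OTHER`.
#'
#' @param sequence Character vector of odd-length windows (length >= 3).
#' @return Character vector over `{"GAC", "AAC", "OTHER"}`.
#' @export
classify_motif <- function(sequence) {
  n <- nchar(sequence)
  if (any(n < 3 | n %% 2 == 0)) {
    abort("Windows must have odd length >= 3 to carry a central motif.")
  }
  centre <- (n + 1) / 2
  triplet <- substr(sequence, centre - 1, centre + 1)
  triplet <- chartr("U", "T", triplet)  # motif names use the DNA spelling
  out <- rep("OTHER", length(sequence))
  out[triplet == "GAC"] <- "GAC"
  out[triplet == "AAC"] <- "AAC"
  out
}

# Reverse complement of DNA-alphabet character vectors (may contain N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract motif-centred sequence windows
#'
#' For every site, the `2k + 1` nt window centred on the modified adenosine
#' is read from the genome.  Positions beyond the chromosome ends are padded
#' with `N`; any non-`ACGT` genome character also becomes `N`.  Minus-strand
#' sites are reverse-complemented so the emitted sequence reads 5' to 3' on
#' the transcript strand (toggle with `rc_minus`), and `T` is converted to
#' `U`.  The centre of every accepted window is `A`.
#'
#' @param genome An `m6a_genome`.
#' @param sites Sites tibble (`chrom`, `position`, `strand`, `support_num`,
#'   `source`).
#' @param k Half-width; the window length is `2k + 1`.  Default 300 gives the
#'   601-nt windows used throughout.
#' @param on_reject What to do with sites whose centre base is not `A` on the
#'   requested strand: `"error"` (default) or `"skip"` (drop with a warning).
#' @param rc_minus Reverse-complement minus-strand windows (default `TRUE`).
#' @return The sites tibble with added columns `sequence` and `motif`.
#' @export
extract_windows <- function(genome, sites, k = 300,
                            on_reject = c("error", "skip"), rc_minus = TRUE) {
  stopifnot(inherits(genome, "m6a_genome"))
  on_reject <- match.arg(on_reject)
  k <- check_count(k, "k", min = 1)
  validate_sites(sites)

  unknown <- setdiff(unique(sites$chrom), names(genome$sequences))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown chromosome(s): %s.", paste(unknown, collapse = ", ")))
  }

  chr_seq <- genome$sequences[sites$chrom]
  chr_len <- nchar(chr_seq)
  pos <- sites$position
  if (any(pos > chr_len)) {
    abort("Site position beyond chromosome end.")
  }

  centre_plus <- substr(chr_seq, pos, pos)
  is_minus <- sites$strand == "-"
  centre_ok <- ifelse(is_minus, centre_plus == "T", centre_plus == "A")
  if (any(!centre_ok)) {
    offender <- which(!centre_ok)[1]
    msg <- sprintf(
      "%d site(s) rejected: centre base is not 'A' on the given strand (first: %s:%d%s).",
      sum(!centre_ok), sites$chrom[offender], sites$position[offender],
      sites$strand[offender])
    if (on_reject == "error") abort(msg)
    warn(msg)
    sites <- sites[centre_ok, , drop = FALSE]
    chr_seq <- chr_seq[centre_ok]
    chr_len <- chr_len[centre_ok]
    pos <- pos[centre_ok]
    is_minus <- is_minus[centre_ok]
  }

  start <- pmax(1L, pos - k)
  end <- pmin(chr_len, pos + k)
  left_pad <- k - (pos - start)
  right_pad <- k - (end - pos)
  body <- substr(chr_seq, start, end)
  body <- gsub("[^ACGT]", "N", body)
  seq <- paste0(strrep("N", left_pad), body, strrep("N", right_pad))

  if (rc_minus && any(is_minus)) {
    seq[is_minus] <- revcomp(seq[is_minus])
  }
  seq <- chartr("T", "U", seq)

  out <- as_tibble(sites)
  out$sequence <- unname(seq)
  out$motif <- classify_motif(out$sequence)
  out
}

#' Extract a single window
#'
#' Convenience wrapper around [extract_windows()] for one site.
#'
#' @param genome An `m6a_genome`.
#' @param chrom,position,strand Site coordinates (1-based, fully closed).
#' @param k Half-width.
#' @inheritParams extract_windows
#' @return A one-row windows tibble.
#' @export
extract_window <- function(genome, chrom, position, strand, k = 300,
                           rc_minus = TRUE) {
  site <- tibble(chrom = chrom, position = as.integer(position),
                 strand = strand, support_num = 0L, source = "adhoc")
  extract_windows(genome, site, k = k, on_reject = "error", rc_minus = rc_minus)
}

#' Sample motif-matched negative sites
#'
#' Enumerates every adenosine whose central triplet matches `motif` on either
#' requested strand, removes the exclusion set, and samples `n` sites
#' uniformly without replacement.
#'
#' @param genome An `m6a_genome`.
#' @param exclude Sites tibble of positions that may not be sampled (matched
#'   on `chrom`, `position`, `strand`); may be `NULL`.
#' @param motif `"GAC"` or `"AAC"`.
#' @param n Number of sites to draw.
#' @param seed Integer seed controlling the draw.
#' @param strands Strands to consider (default both).
#' @return A sites tibble with `support_num = 0` and source
#'   `"sampled-negative"`.
#' @export
sample_negative_sites <- function(genome, exclude = NULL, motif = c("GAC", "AAC"),
                                  n, seed = 1, strands = c("+", "-")) {
  stopifnot(inherits(genome, "m6a_genome"))
  motif <- match.arg(motif)
  n <- check_count(n, "n", min = 0)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)

  eligible <- purrr::map_dfr(names(genome$sequences), function(chrom) {
    subj <- Biostrings::DNAString(gsub("[^ACGT]", "N", genome$sequences[[chrom]]))
    per_strand <- list()
    if ("+" %in% strands) {
      hits <- Biostrings::start(Biostrings::matchPattern(motif, subj))
      if (length(hits) > 0) {
        per_strand$plus <- tibble(chrom = chrom, position = hits + 1L, strand = "+")
      }
    }
    if ("-" %in% strands) {
      rc <- revcomp(motif)
      hits <- Biostrings::start(Biostrings::matchPattern(rc, subj))
      if (length(hits) > 0) {
        per_strand$minus <- tibble(chrom = chrom, position = hits + 1L, strand = "-")
      }
    }
    dplyr::bind_rows(per_strand)
  })

  if (!is.null(exclude) && nrow(eligible) > 0 && nrow(exclude) > 0) {
    eligible <- dplyr::anti_join(
      eligible, dplyr::select(exclude, "chrom", "position", "strand"),
      by = c("chrom", "position", "strand"))
  }
  if (nrow(eligible) < n) {
    abort(sprintf(
      "Cannot sample %d %s-motif negative sites: only %d eligible positions (shortfall %d).",
      n, motif, nrow(eligible), n - nrow(eligible)))
  }
  picked <- with_seed(seed, eligible[sample.int(nrow(eligible), n), , drop = FALSE])
  dplyr::mutate(picked, support_num = 0L, source = "sampled-negative")
}

#' Export windows as FASTA
#'
#' Headers carry structured description fields
#' (`label=... motif=... support=...`) so a windows FASTA round-trips the
#' metadata needed downstream.
#'
#' @param windows Windows tibble (needs `sequence`; uses `label`, `motif`,
#'   `support_target` or `support_num` when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  col <- function(nm, default) {
    if (nm %in% names(windows)) windows[[nm]] else rep(default, nrow(windows))
  }
  id <- sprintf("%s:%d%s", windows$chrom, windows$position, windows$strand)
  label <- col("label", NA_character_)
  support <- if ("support_target" %in% names(windows)) {
    windows$support_target
  } else {
    col("support_num", NA_real_)
  }
  header <- sprintf(">%s label=%s motif=%s support=%s", id, label,
                    windows$motif, format(support, trim = TRUE))
  writeLines(rbind(header, windows$sequence), path)
  invisible(path)
}
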