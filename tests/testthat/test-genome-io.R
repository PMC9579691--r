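# Genome parsing, window extraction, motif classification, negative sampling.

test_that("FASTA parsing handles records, wrapping, case and U/T", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrI", "ACGT"), fa)
  g <- read_genome(fa)
  expect_identical(g$sequences[["chrI"]], "ACGT")

  writeLines(c(">chrI desc text", "acg", "taa", ">chrII", "uuGG"), fa)
  g <- read_genome(fa)
  expect_identical(g$sequences[["chrI"]], "ACGTAA")
  expect_identical(g$sequences[["chrII"]], "TTGG")  # U stored as T
  expect_identical(g$alphabet, "RNA")
})

test_that("degenerate FASTA inputs are rejected with informative errors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(read_genome(fa), "Empty FASTA")

  writeLines(c("ACGT", ">chrI", "ACGT"), fa)
  expect_error(read_genome(fa), "line 1")

  writeLines(c(">chrI", "ACGT", ">chrI", "GGCC"), fa)
  expect_error(read_genome(fa), "Duplicate")

  expect_error(read_genome(file.path(tempdir(), "no-such-file.fa")),
               "not found")
  expect_error(new_genome(c(chrI = "ACGT", chrI = "GG")), "Duplicate")
})

test_that("window extraction reads off the plus strand with padding", {
  g <- new_genome(c(chr = "GGGACGG"))
  w <- extract_window(g, "chr", 4, "+", k = 2)
  expect_identical(w$sequence, "GGACG")
  expect_identical(w$motif, "GAC")

  g2 <- new_genome(c(chr = "AC"))
  w2 <- extract_window(g2, "chr", 1, "+", k = 2)
  expect_identical(w2$sequence, "NNACN")
})

test_that("minus-strand windows equal the naive reverse-complement oracle", {
  g <- new_genome(c(chr = "CCGTCCC"))
  w <- extract_window(g, "chr", 4, "-", k = 2)
  # plus-strand slice 2..6 is CGTCC; oracle reverse-complements it
  expect_identical(w$sequence, chartr("T", "U", naive_revcomp("CGTCC")))
  expect_identical(w$sequence, "GGACG")
  expect_identical(w$motif, "GAC")

  # property over random genomes: strand round trip and padding arithmetic
  for (rep in 1:25) {
    g <- rand_genome(60, seed = rep)
    chr <- g$sequences[[1]]
    pos_t <- which(strsplit(chr, "")[[1]] == "T")
    pos_t <- pos_t[pos_t >= 1]
    if (length(pos_t) == 0) next
    pos <- pos_t[1 + (rep %% length(pos_t))]
    k <- 5L + (rep %% 7L)
    w <- extract_window(g, names(g$sequences), pos, "-", k = k)
    expect_identical(nchar(w$sequence), 2L * k + 1L)
    expect_identical(substr(w$sequence, k + 1, k + 1), "A")

    start <- max(1, pos - k); end <- min(nchar(chr), pos + k)
    plus_slice <- paste0(strrep("N", k - (pos - start)),
                         substr(chr, start, end),
                         strrep("N", k - (end - pos)))
    expect_identical(w$sequence, chartr("T", "U", naive_revcomp(plus_slice)))

    expected_pad <- max(0, k - (pos - 1)) + max(0, pos + k - nchar(chr))
    expect_identical(
      lengths(regmatches(w$sequence, gregexpr("N", w$sequence))),
      as.integer(expected_pad))
  }
})

test_that("sites with a non-A centre are rejected or skipped as requested", {
  g <- new_genome(c(chr = "GGGACGG"))
  site_bad <- tibble::tibble(chrom = "chr", position = 3L, strand = "+",
                             support_num = 0L, source = "t")
  expect_error(extract_windows(g, site_bad, k = 2), "not 'A'")
  expect_warning(out <- extract_windows(g, site_bad, k = 2, on_reject = "skip"),
                 "rejected")
  expect_identical(nrow(out), 0L)
  expect_error(extract_windows(
    g, dplyr::mutate(site_bad, chrom = "nope", position = 4L), k = 2),
    "Unknown chromosome")
})

test_that("motif classification is a pure function of the centre triplet", {
  expect_identical(classify_motif(c("GGGACGG", "GGAACGG", "GGUACGG")),
                   c("GAC", "AAC", "OTHER"))
  expect_identical(classify_motif("GAC"), "GAC")
  expect_error(classify_motif("GACU"), "odd length")
  # consistency with string slicing on emitted sequences for both strands
  for (rep in 1:10) {
    g <- rand_genome(500, seed = 100 + rep)
    sites <- sample_negative_sites(g, motif = "GAC", n = 5, seed = rep)
    w <- extract_windows(g, sites, k = 4)
    centre <- substr(w$sequence, 4, 6)
    expect_true(all(centre == "GAC"))
    expect_true(all(w$motif == "GAC"))
  }
})

test_that("negative sampling is exclusion-aware, exact and seeded", {
  g <- new_genome(c(chr = "TTGACTT"))  # single GAC at positions 3..5, plus only
  hit <- sample_negative_sites(g, motif = "GAC", n = 1, seed = 1,
                               strands = "+")
  expect_identical(hit$position, 4L)
  expect_identical(hit$support_num, 0L)
  expect_identical(hit$source, "sampled-negative")

  expect_error(
    sample_negative_sites(g, exclude = hit, motif = "GAC", n = 1, seed = 1,
                          strands = "+"),
    "shortfall")

  g10 <- rand_genome(10000, seed = 3)
  a <- sample_negative_sites(g10, motif = "GAC", n = 50, seed = 10)
  a2 <- sample_negative_sites(g10, motif = "GAC", n = 50, seed = 10)
  b <- sample_negative_sites(g10, motif = "GAC", n = 50, seed = 11)
  expect_identical(a, a2)
  expect_false(identical(a, b))
  # every sampled site is a motif-matched adenosine on its strand
  w <- extract_windows(g10, a, k = 3)
  expect_true(all(w$motif == "GAC"))
})

test_that("site tables round-trip through TSV with comments and defaults", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", "chrom\tposition\tstrand\tsupport_num",
               "chrI\t10\t+\t3", "chrI\t20\t-\t7"), path)
  s <- read_sites(path)
  expect_identical(s$position, c(10L, 20L))
  expect_identical(s$support_num, c(3L, 7L))
  expect_identical(s$source, rep("sites", 2))

  writeLines(c("chrom\tposition", "chrI\t10"), path)
  expect_error(read_sites(path), "lacks column")

  writeLines(c("chrom\tposition\tstrand", "chrI\t10\t*"), path)
  expect_error(read_sites(path), "strand")

  sites <- tibble::tibble(chrom = "chrI", position = 5L, strand = "+",
                          support_num = 2L, source = "x")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sites(sites, out)
  expect_identical(read_sites(out)$position, 5L)
})

test_that("windows export to FASTA with structured description fields", {
  w <- rand_windows(4, 9)
  path <- withr::local_tempfile(fileext = ".fa")
  write_windows_fasta(w, path)
  lines <- readLines(path)
  expect_length(lines, 8)
  expect_match(lines[1], "^>chrT:\\d+[+-] label=.* motif=.* support=")
  expect_identical(lines[2], w$sequence[1])
})
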