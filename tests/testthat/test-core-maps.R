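test_that("in-silico digestion follows the recognition/cut convention", {
  # no site: single fragment covering the whole sequence
  m <- in_silico_digest(strrep("ACGT", 250))
  expect_equal(length(m$fragments), 1L)
  expect_equal(m$fragments, 1.000)
  expect_null(m$cut_coords)

  # blunt cut after the 4th base of ATTTAAAT
  m <- in_silico_digest(paste0("CCCCC", "ATTTAAAT", "GGGGG"))
  expect_equal(m$cut_coords, 9)
  expect_equal(m$fragments, c(0.009, 0.009))

  # N runs never create cuts
  m <- in_silico_digest(paste0("CCCCC", "ATTNAAAT", "GGGGG"))
  expect_equal(length(m$fragments), 1L)

  expect_error(in_silico_digest(""), "empty")
})

test_that("digestion matches a brute-force site scan on random sequence", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE,
                    prob = c(.3, .2, .2, .3)), collapse = "")
  m <- in_silico_digest(s)
  # independent sliding-window scan
  hits <- gregexpr("(?=ATTTAAAT)", s, perl = TRUE)[[1]]
  n_sites <- if (hits[1] == -1) 0L else length(hits)
  expect_equal(length(m$cut_coords %||% numeric(0)), n_sites)
  # conservation: total mass = sequence length
  expect_equal(sum(m$fragments), nchar(s) / 1000, tolerance = 1e-6)
})

test_that("digesting the reverse complement reverses the fragment list", {
  set.seed(72)
  s <- paste(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE,
                    prob = c(.3, .2, .2, .3)), collapse = "")
  fwd <- in_silico_digest(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev_m <- in_silico_digest(rc)
  expect_equal(rev_m$fragments, rev(fwd$fragments))
})

test_that("cut count on i.i.d. sequence is near its expectation", {
  set.seed(73)
  L <- 2e6
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  m <- in_silico_digest(s)
  expected <- (L - 7) * 4^-8
  observed <- length(m$cut_coords %||% numeric(0))
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("small-fragment merging conserves mass, merges left, is idempotent", {
  m <- fragment_map("m", c(0.3, 10.0, 5.0))
  expect_equal(merge_small_fragments(m, 0.4)$fragments, c(10.3, 5.0))
  m2 <- fragment_map("m", c(10.0, 5.0))
  expect_equal(merge_small_fragments(m2, 0.4)$fragments, c(10.0, 5.0))
  m3 <- fragment_map("m", c(0.1, 0.2, 30.0))
  expect_equal(merge_small_fragments(m3, 0.4)$fragments, 30.3)
  # interior smalls merge into the left neighbor
  m4 <- fragment_map("m", c(10, 0.2, 0.1, 5))
  expect_equal(merge_small_fragments(m4, 0.4)$fragments, c(10.3, 5))
  # idempotence and conservation on random maps
  set.seed(74)
  for (i in 1:20) {
    f <- round(rexp(sample(3:30, 1), 1 / 8) + 0.001, 3)
    mm <- merge_small_fragments(fragment_map("r", f), 0.4)
    expect_equal(sum(mm$fragments), sum(round(f, 3)), tolerance = 1e-9)
    expect_equal(merge_small_fragments(mm, 0.4)$fragments, mm$fragments)
    if (sum(f) >= 0.4) expect_true(all(mm$fragments >= 0.4) ||
                                     length(mm$fragments) == 1L)
  }
})

test_that("map TSV IO round-trips and rejects malformed records", {
  set.seed(75)
  rmaps <- lapply(1:10, function(i)
    rmap(sprintf("mol%02d", i), round(rexp(sample(5:20, 1), 1 / 15) + 0.01, 3),
         source_label = sample(c("s1", "s2"), 1)))
  refs <- list(fragment_map("chr1", c(10.5, 22.001, 0.4), chrom = "chr1"))
  path <- tempfile(fileext = ".maps.tsv")
  write_maps(c(rmaps, refs), path)
  back <- read_maps(path)
  expect_length(back, 11L)
  for (i in 1:10) {
    expect_s3_class(back[[i]], "rmap")
    expect_equal(back[[i]]$fragments, rmaps[[i]]$fragments)
    expect_equal(back[[i]]$source_label, rmaps[[i]]$source_label)
  }
  expect_s3_class(back[[11]], "fragment_map")
  expect_equal(back[[11]]$fragments, refs[[1]]$fragments)

  # malformed: negative mass names the line
  bad <- tempfile()
  writeLines(c("# header", "x\t.\t2\t1.0,-3.0\ts1"), bad)
  expect_error(read_maps(bad), "line 2")
  # wrong field count
  writeLines(c("x\t.\t1"), bad)
  expect_error(read_maps(bad), "5 tab-separated")
  # only comments -> empty with warning
  writeLines(c("# nothing"), bad)
  expect_warning(out <- read_maps(bad), "no map records")
  expect_length(out, 0L)
})

test_that("BED IO uses 0-based half-open coordinates", {
  path <- tempfile(fileext = ".bed")
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 201), c(200, 250)),
                               name = c("a", "b"))
  write_bed(gr, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[1], "\t")[[1]][2:3], c("100", "200"))
  back <- read_bed(path)
  expect_equal(BiocGenerics::start(back), c(101, 201))
  expect_equal(back$name, c("a", "b"))
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "line 1")
})
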