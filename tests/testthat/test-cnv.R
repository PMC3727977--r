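test_that("midpoints are per-chromosome, sorted and shuffle-stable", {
  tab <- data.frame(molecule_id = c("a", "b", "c", "d"),
                    chrom = c("chr1", "chr1", "chr2", "chr1"),
                    start = c(1e5, 5e5, 2e5, 9e5), end = c(3e5, 7e5, 4e5, 11e5),
                    midpoint = c(2e5, 6e5, 3e5, 10e5),
                    source_label = "s", status = c("aligned", "aligned",
                                                   "aligned", "rejected_score"),
                    stringsAsFactors = FALSE)
  mp <- midpoints(tab)
  expect_equal(mp$chr1, c(2e5, 6e5))
  expect_equal(mp$chr2, 3e5)
  expect_equal(midpoints(tab[c(3, 1, 4, 2), ]), mp[order(names(mp))])
  expect_length(midpoints(tab[0, ]), 0L)
})

test_that("equal-count intervals track the normal midpoint density", {
  # 100 uniform midpoints, m = 10 -> 10 intervals of exactly 10
  mids <- list(chr1 = seq(5e4, 1e7 - 5e4, length.out = 100))
  iv <- build_intervals(mids, c(chr1 = 1e7), m = 10)
  expect_equal(nrow(iv), 10L)
  expect_true(all(iv$normal_count == 10L))
  expect_equal(iv$start[1], 0)
  expect_equal(tail(iv$end, 1), 1e7)
  expect_true(all(iv$start[-1] == head(iv$end, -1)))

  # clustered-left midpoints give narrower intervals on the left
  set.seed(11)
  x <- sort(c(runif(150, 0, 2e6), runif(50, 2e6, 1e7)))
  iv2 <- build_intervals(list(chr1 = x), c(chr1 = 1e7), m = 10)
  widths <- iv2$end - iv2$start
  expect_lt(mean(widths[1:5]), mean(tail(widths, 5)))

  # fewer than m midpoints -> single whole-chromosome interval with warning
  expect_warning(iv3 <- build_intervals(list(chr1 = c(1e5, 2e5)),
                                        c(chr1 = 1e6), m = 10),
                 "fewer than m")
  expect_equal(nrow(iv3), 1L)
})

test_that("the NB model anchors on the diploid rate and detects Poisson", {
  set.seed(12)
  x <- rpois(200, 20)
  model <- fit_model(x)
  expect_lt(abs(model$mu - 20), 2)
  expect_lt(model$phi, 0.03) # near the Poisson limit
  expect_equal(fit_model(rep(17L, 50))$mu, 17)
  expect_error(fit_model(rpois(10, 20)), "insufficient")
  # strongly bimodal counts trigger the anchor warning
  set.seed(13)
  y <- c(rpois(110, 6), rpois(90, 25))
  expect_warning(fit_model(y), "multimodal|median")
})

test_that("Viterbi decoding matches direct NB likelihood and finds two states", {
  model <- structure(list(mu = 20, phi = 0.05, states = 0:4,
                          emission_means = pmax(20 * (0:4) / 2, 1),
                          stay_prob = 1 - 1e-4), class = "cnv_model")
  # emission equals the negative-binomial mass function
  expect_equal(rmapforge:::nb_loglik(13, 20, 0.05),
               dnbinom(13, size = 20, mu = 20, log = TRUE))
  expect_equal(rmapforge:::nb_loglik(13, 20, 0), dpois(13, 20, log = TRUE))

  # constant counts decode to a single diploid segment
  iv <- data.frame(chrom = "chr1", start = seq(0, 99) * 1e5,
                   end = seq(1, 100) * 1e5, tumor_count = 20L)
  dec <- viterbi_decode(iv, model)
  expect_true(all(dec$path == 2L))
  expect_equal(nrow(dec$segments), 1L)

  # half at mu/2, half at mu: two segments, breakpoint within 2 intervals
  set.seed(14)
  ok <- 0
  for (rep in 1:10) {
    cnt <- c(rpois(50, 10), rpois(50, 20))
    iv$tumor_count <- cnt
    dec <- viterbi_decode(iv, model)
    runs <- rle(dec$path)
    if (length(runs$values) == 2 && all(runs$values == c(1, 2)) &&
        abs(runs$lengths[1] - 50) <= 2) ok <- ok + 1
  }
  expect_gte(ok, 9)
  # segments tile the decoded intervals
  expect_equal(sum(dec$segments$n_intervals), 100L)
  expect_error(viterbi_decode(transform(iv, tumor_count = -1), model))
})

test_that("decoded states are invariant to joint rescaling of counts and mu", {
  model <- structure(list(mu = 10, phi = 0, states = 0:4,
                          emission_means = pmax(10 * (0:4) / 2, 0.5),
                          stay_prob = 1 - 1e-4), class = "cnv_model")
  set.seed(15)
  iv <- data.frame(chrom = "c", start = 0:59 * 1e5, end = 1:60 * 1e5,
                   tumor_count = c(rpois(30, 5), rpois(30, 10)))
  p1 <- viterbi_decode(iv, model)$path
  model2 <- model
  model2$mu <- 30; model2$emission_means <- pmax(30 * (0:4) / 2, 1.5)
  iv2 <- transform(iv, tumor_count = tumor_count * 3L)
  p2 <- viterbi_decode(iv2, model2)$path
  expect_equal(p1, p2)
})

test_that("per-slice analysis flags only discordant intervals", {
  # synthetic alignment tables: two labels, one with an extra arm loss
  set.seed(16)
  mk_mid <- function(n, lo, hi) sort(runif(n, lo, hi))
  norm <- list(chr1 = mk_mid(600, 0, 1e7))
  tab <- function(mids, label)
    data.frame(molecule_id = paste0(label, seq_along(mids)), chrom = "chr1",
               start = mids - 2e5, end = mids + 2e5, midpoint = mids,
               source_label = label, status = "aligned",
               stringsAsFactors = FALSE)
  # slice1 diploid everywhere; slice2 has copy-1 on [6e6, 1e7)
  s1 <- mk_mid(600, 0, 1e7)
  s2 <- sort(c(mk_mid(450, 0, 6e6), mk_mid(150, 6e6, 1e7)))
  full <- rbind(tab(s1, "s1"), tab(s2, "s2"))
  res <- per_slice_cnv(full, norm, c(chr1 = 1e7), m = 20)
  expect_named(res$per_label, c("s1", "s2"))
  disc <- res$discordance
  expect_gt(nrow(disc), 0)
  frac_in_arm <- mean((disc$start + disc$end) / 2 >= 6e6)
  expect_gte(frac_in_arm, 0.8)
  # identical labels -> empty report
  full2 <- rbind(tab(s1, "a"), tab(s1, "b"))
  res2 <- per_slice_cnv(full2, norm, c(chr1 = 1e7), m = 20)
  expect_equal(nrow(res2$discordance), 0L)
  # label with no aligned data is skipped with a warning
  full3 <- rbind(tab(s1, "a"),
                 transform(tab(s2, "c"), status = "rejected_score"))
  expect_warning(per_slice_cnv(full3, norm, c(chr1 = 1e7), m = 20,
                               labels = c("a", "c")),
                 "no aligned molecules")
})
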