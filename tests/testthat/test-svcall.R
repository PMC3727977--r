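# a consensus identical to the reference except where stated, with full
# provenance, built directly for classifier unit tests
consensus_from_ref <- function(ref_map, fragments = ref_map$fragments,
                               prov = seq_len(length(fragments) - 1L)) {
  cm <- fragment_map(ref_map$map_id, fragments, chrom = ref_map$chrom,
                     origin = "consensus")
  attr(cm, "start_bp") <- attr(ref_map, "start_bp") %||% 0
  attr(cm, "cut_seed_id") <- prov
  cm
}

ref_3frag <- function(mid_kb) {
  m <- fragment_map("w", c(50, mid_kb, 50), chrom = "chrT",
                    cut_coords = c(50000, 50000 + mid_kb * 1000))
  attr(m, "start_bp") <- 0
  m
}

test_that("identical maps yield no calls and the indel rule is exact", {
  ref <- ref_3frag(10)
  expect_equal(nrow(classify_differences(consensus_from_ref(ref), ref)), 0L)

  # 10 kb reference fragment: threshold max(0.13*10, 4.5) = 4.5 kb
  c1 <- consensus_from_ref(ref, c(50, 14.4, 50))
  expect_equal(nrow(classify_differences(c1, ref)), 0L)
  c2 <- consensus_from_ref(ref, c(50, 14.6, 50))
  calls <- classify_differences(c2, ref)
  expect_equal(calls$class, "INS")
  expect_equal(calls$size_delta_kb, 4.6)
  c3 <- consensus_from_ref(ref, c(50, 14.5, 50))
  expect_equal(classify_differences(c3, ref)$size_delta_kb, 4.5)

  # 100 kb fragment: relative rule dominates (13 kb)
  ref100 <- ref_3frag(100)
  expect_equal(nrow(classify_differences(
    consensus_from_ref(ref100, c(50, 112.9, 50)), ref100)), 0L)
  expect_equal(classify_differences(
    consensus_from_ref(ref100, c(50, 113.0, 50)), ref100)$class, "INS")

  # deletions mirror insertions
  expect_equal(classify_differences(
    consensus_from_ref(ref, c(50, 5.5, 50)), ref)$class, "DEL")
})

test_that("threshold boundary equals max(0.13 r, 4.5) over a fragment scan", {
  for (r in c(5, 10, 34, 35, 60, 150)) {
    ref <- ref_3frag(r)
    thr <- NA
    for (dev in seq(0.1, 25, by = 0.1)) {
      cc <- consensus_from_ref(ref, c(50, round(r + dev, 3), 50))
      if (nrow(classify_differences(cc, ref))) { thr <- dev; break }
    }
    expect_equal(thr, round(max(0.13 * r, 4.5), 3),
                 tolerance = 0.051, info = paste("r =", r))
  }
})

test_that("split and missing cuts classify as EC / MC, runs collapse to OTHER", {
  ref <- fragment_map("w", c(30, 40, 30, 25, 35), chrom = "chrT",
                      cut_coords = cumsum(c(30, 40, 30, 25)) * 1000)
  attr(ref, "start_bp") <- 0
  # consensus splits the 40 kb fragment into 22 + 18 -> one EC, no indel
  cm <- consensus_from_ref(ref, c(30, 22, 18, 30, 25, 35),
                           prov = c(1L, NA, 2L, 3L, 4L))
  calls <- classify_differences(cm, ref)
  expect_equal(calls$class, "EC")
  expect_lt(abs(calls$cut_bp - 52000), 1500)

  # consensus lacking an interior cut -> one MC at the reference coordinate
  cm2 <- consensus_from_ref(ref, c(30, 70, 25, 35), prov = c(1L, 3L, 4L))
  calls2 <- classify_differences(cm2, ref)
  expect_equal(calls2$class, "MC")
  expect_equal(calls2$cut_bp, 70000)

  # two cut differences within three reference fragments -> one OTHER
  cm3 <- consensus_from_ref(ref, c(30, 70, 12, 13, 35),
                            prov = c(1L, 3L, NA, 4L))
  calls3 <- classify_differences(cm3, ref)
  expect_equal(calls3$class, "OTHER")
  expect_equal(calls3$n_diffs, 2L)
})

test_that("support scoring matches direct binomial/normal computation", {
  ep <- list(p_d = 0.8, false_cut_rate = 5, sizing_cv = 0.06)
  # EC: 20/20 concordant over a 50 kb fragment is overwhelming
  p_ec <- score_variant("EC", 20, 20, 50, error_params = ep)
  p_fc <- 1 - exp(-5 * 50 / 1000)
  expect_equal(p_ec, p_fc^20)
  expect_lt(p_ec, 1e-10)
  # MC where 19/20 molecules do show the cut is not significant
  expect_gt(score_variant("MC", 19, 20, 50, error_params = ep), 0.95)
  expect_equal(score_variant("MC", 19, 20, 50, error_params = ep),
               pbinom(19, 20, 0.8))
  # INS with zero mean deviation has p = 1
  expect_equal(score_variant("INS", NA, 10, 40, delta_kb = 0,
                             error_params = ep), 1)
  expect_equal(score_variant("DEL", NA, 16, 40, delta_kb = -8,
                             error_params = ep),
               2 * pnorm(-8 / (0.06 * 40 / 4)))
  expect_error(score_variant("EC", 0, 0, 50), "n = 0")
})

test_that("calls repeated by overlapping windows are reported once", {
  tab <- data.frame(class = c("EC", "EC"), chrom = "chrA",
                    start = c(1e6, 1e6 + 1500), end = c(1e6 + 1, 1e6 + 1501),
                    size_delta_kb = 0, ref_frag_lo = 1L, ref_frag_hi = 1L,
                    cut_bp = c(1e6, 1e6 + 1500), consensus_frag = NA_integer_,
                    n_diffs = 1L, window_id = c("w1", "w2"),
                    n_support = c(12L, 9L), confidence_p = 1e-9,
                    stringsAsFactors = FALSE)
  out <- rmapforge:::dedup_window_calls(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_support, 12L)
})
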