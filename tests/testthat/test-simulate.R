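test_that("reference simulation is deterministic and density tracks GC", {
  a <- simulate_reference(c(chr1 = 2e5), 0.5, seed = 42)
  b <- simulate_reference(c(chr1 = 2e5), 0.5, seed = 42)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  expect_error(simulate_reference(c(chr1 = 0)), "zero-length")

  # gc = 0.5, mean fragment ~ 4^8 bp = 65.5 kb
  big <- simulate_reference(c(chr1 = 1e7), 0.5, seed = 43)
  mean_kb <- mean(big$maps$maps$chr1$fragments)
  expect_lt(abs(mean_kb - 65.5) / 65.5, 0.15)

  # AT-richer sequence cuts more densely
  at <- simulate_reference(c(chr1 = 5e6), 0.4, seed = 44)
  expect_gt(length(at$maps$maps$chr1$fragments) / 5,
            length(big$maps$maps$chr1$fragments) / 10)
})

test_that("variant implantation alters the sequence as specified", {
  ref <- test_ref_small
  ft <- frag_table(ref, "chrA")

  # DEL conserves length bookkeeping
  del <- implant_variants(ref$seqs,
                          list(variant_spec("DEL", "chrA", 1e6, 10000)))
  expect_equal(Biostrings::width(del$seqs)[[1]], 2e6 - 10000)

  # INS adds exactly size_bp and no new site beyond the length change
  ins <- implant_variants(ref$seqs,
                          list(variant_spec("INS", "chrA",
                                            pick_fragment_mid(ft, 20, 80, 5e5,
                                                              1e6), 5000)))
  expect_equal(Biostrings::width(ins$seqs)[[1]], 2e6 + 5000)
  expect_equal(length(ins$maps$maps$chrA$cut_coords),
               length(ref$maps$maps$chrA$cut_coords))

  # INV spanning k interior cuts: total mass conserved, interior spacings
  # reversed (the site is palindromic)
  s <- 4e5; e_sz <- 6e5
  inv <- implant_variants(ref$seqs,
                          list(variant_spec("INV", "chrA", s, e_sz)))
  expect_equal(Biostrings::width(inv$seqs)[[1]], 2e6)
  interior <- ft$cuts[ft$cuts > s & ft$cuts < s + e_sz]
  new_cuts <- inv$maps$maps$chrA$cut_coords
  new_interior <- new_cuts[new_cuts > s & new_cuts < s + e_sz]
  expect_equal(diff(new_interior), rev(diff(interior)))

  # SITE_GAIN adds exactly one cut; SITE_LOSS removes exactly one
  gain <- implant_variants(ref$seqs,
                           list(variant_spec("SITE_GAIN", "chrA", 1.2e6)))
  expect_equal(length(gain$maps$maps$chrA$cut_coords),
               length(ref$maps$maps$chrA$cut_coords) + 1L)
  loss_at <- ft$cuts[5]
  loss <- implant_variants(ref$seqs,
                           list(variant_spec("SITE_LOSS", "chrA", loss_at)))
  expect_equal(length(loss$maps$maps$chrA$cut_coords),
               length(ref$maps$maps$chrA$cut_coords) - 1L)
  expect_false(loss_at %in% loss$maps$maps$chrA$cut_coords)
  expect_error(implant_variants(ref$seqs,
                                list(variant_spec("SITE_LOSS", "chrA",
                                                  loss_at + 3000))),
               "no recognition site")
  # overlapping specs rejected
  expect_error(implant_variants(ref$seqs,
                                list(variant_spec("DEL", "chrA", 1e5, 5e4),
                                     variant_spec("INS", "chrA", 1.2e5, 100))),
               "overlapping")
})

test_that("noise-free molecules are exact contiguous slices of the digest", {
  ref <- test_ref_small
  cfg <- sim_config(seed = 5, coverage = 5, digest_efficiency = 1,
                    false_cut_rate = 0, sizing_cv = 0,
                    desorption_drop_prob = 0)
  sim <- simulate_rmaps(list(s1 = list(maps = ref$maps)), cfg)
  cmap <- ref$maps$maps$chrA
  all_frag_str <- paste(sprintf("%.3f", cmap$fragments), collapse = ",")
  for (r in sim$rmaps[1:10]) {
    fr <- if (r$truth$true_orientation == "-") rev(r$fragments) else r$fragments
    n <- length(fr)
    if (n < 3) next
    interior <- sprintf("%.3f", fr[2:(n - 1)])
    expect_true(grepl(paste(interior, collapse = ","), all_frag_str,
                      fixed = TRUE),
                info = r$molecule_id)
  }
})

test_that("simulated mass matches configured coverage and digest efficiency", {
  ref <- test_ref_small
  cfg <- sim_config(seed = 6, coverage = 30)
  sim <- simulate_rmaps(list(s1 = list(maps = ref$maps)), cfg)
  total_kb <- sum(vapply(sim$rmaps, function(r) sum(r$fragments), numeric(1)))
  expect_lt(abs(total_kb * 1000 / ref$maps$total_length_bp - 30) / 30, 0.05)

  # fraction of true interior sites observed ~ digest_efficiency
  cmap <- ref$maps$maps$chrA
  cfg2 <- sim_config(seed = 7, coverage = 30, false_cut_rate = 0,
                     sizing_cv = 0, desorption_drop_prob = 0)
  sim2 <- simulate_rmaps(list(s1 = list(maps = ref$maps)), cfg2)
  seen <- 0; avail <- 0
  for (r in sim2$rmaps) {
    tr <- r$truth
    cuts <- cmap$cut_coords
    inside <- sum(cuts > tr$true_start_bp & cuts < tr$true_end_bp)
    avail <- avail + inside
    seen <- seen + (length(r$fragments) - 1L)
  }
  expect_lt(abs(seen / avail - 0.8), 0.02)
})

test_that("two-subclone coverage follows fraction times copy number", {
  ref <- test_ref_small
  prof2 <- data.frame(chrom = "chrA", start = c(0, 1e6), end = c(1e6, 2e6),
                      copy = c(1, 2))
  cfg <- sim_config(seed = 8, coverage = 40,
                    subclones = list(
                      list(label = "s1", fraction = 0.5, copy_profile = NULL,
                           variant_set = list()),
                      list(label = "s2", fraction = 0.5, copy_profile = prof2,
                           variant_set = list())))
  sim <- simulate_rmaps(list(s1 = list(maps = ref$maps),
                             s2 = list(maps = ref$maps)), cfg)
  tr <- sim$truth
  s2 <- tr[tr$source_label == "s2", ]
  # mass delivered into each half, by span overlap
  m_s2_left <- sum(pmax(pmin(s2$end_bp, 1e6) - s2$start_bp, 0)) / 1000
  m_s2_right <- sum(pmax(s2$end_bp - pmax(s2$start_bp, 1e6), 0)) / 1000
  # copy 1 vs copy 2 halves: mass ratio ~ 1:2
  expect_lt(abs(m_s2_left / m_s2_right - 0.5), 0.5 * 0.15)
  # deterministic under seed
  sim_b <- simulate_rmaps(list(s1 = list(maps = ref$maps),
                               s2 = list(maps = ref$maps)), cfg)
  expect_identical(sim$truth, sim_b$truth)
  expect_identical(sim$rmaps[[1]]$fragments, sim_b$rmaps[[1]]$fragments)
})

test_that("truth coordinates round-trip through independent digestion", {
  ref <- test_ref_small
  specs <- five_variant_specs(ref, "chrA", k = 2)
  # scale positions into the 2 Mb test genome
  out <- implant_variants(ref$seqs, specs[1:2], seed = 3)
  redigest <- digest_genome(out$seqs)
  expect_equal(redigest$maps$chrA$fragments, out$maps$maps$chrA$fragments)
  expect_equal(redigest$chrom_lengths_bp, out$maps$chrom_lengths_bp)
})
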