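test_that("window partitioning covers every base with the right overlap", {
  w <- partition_windows(5e6)
  expect_equal(nrow(w), 9L)
  expect_true(all(w$end - w$start == 1e6))
  expect_true(all(w$start[-1] - w$start[-9] == 5e5))
  # degenerate: chromosome shorter than one window
  w2 <- partition_windows(8e5)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$end, 8e5)
  # coverage of [0, L) including a clipped final window
  w3 <- partition_windows(5.2e6)
  expect_equal(w3$start[1], 0)
  expect_equal(max(w3$end), 5.2e6)
  expect_true(all(w3$start[-1] <= head(w3$end, -1))) # no gaps
  expect_error(partition_windows(5e6, 1e6, 1.5e6))
})

test_that("noise-free assembly reproduces the reference window exactly", {
  ref <- test_ref_small
  cfg0 <- sim_config(seed = 41, coverage = 20, digest_efficiency = 1,
                     false_cut_rate = 0, sizing_cv = 0,
                     desorption_drop_prob = 0)
  sim0 <- simulate_rmaps(list(s1 = list(maps = ref$maps)), cfg0)
  ab <- align_batch(sim0$rmaps, ref$maps)
  names(sim0$rmaps) <- vapply(sim0$rmaps, `[[`, character(1), "molecule_id")
  mem <- ab$table$molecule_id[ab$table$status == "aligned" &
                                ab$table$midpoint >= 5e5 &
                                ab$table$midpoint < 1.5e6]
  seed_map <- rmapforge:::window_seed_map(ref$maps$maps$chrA, 0, 2e6, "w")
  cm <- assemble_window(sim0$rmaps[mem], seed_map, n_rounds = 2)
  expect_equal(attr(cm, "status"), "assembled")
  merged_seed <- merge_small_fragments(seed_map, 0.4)
  expect_equal(cm$fragments, merged_seed$fragments, tolerance = 1e-6)
  # support: concordant equals spanning wherever molecules span
  sup <- attr(cm, "support")
  covered <- sup$spanning >= 2
  expect_true(all(sup$concordant[covered] == sup$spanning[covered]))
  # under min_depth molecules -> unassembled
  cm2 <- assemble_window(sim0$rmaps[mem[1:2]], seed_map)
  expect_equal(attr(cm2, "status"), "unassembled")
})

test_that("a cut carried by every molecule enters the consensus", {
  ref <- test_ref_small
  alt <- implant_variants(ref$seqs,
                          list(variant_spec("SITE_GAIN", "chrA", 1.02e6)),
                          seed = 4)
  cfg <- sim_config(seed = 42, coverage = 30)
  cfg$subclones[[1]]$label <- "t"
  sim <- simulate_rmaps(list(t = list(maps = alt$maps)), cfg)
  ab <- align_batch(sim$rmaps, ref$maps)
  names(sim$rmaps) <- vapply(sim$rmaps, `[[`, character(1), "molecule_id")
  mem <- ab$table$molecule_id[ab$table$status == "aligned" &
                                ab$table$midpoint >= 5e5 &
                                ab$table$midpoint < 1.5e6]
  seed_map <- rmapforge:::window_seed_map(ref$maps$maps$chrA, 0, 2e6, "w")
  cm <- assemble_window(sim$rmaps[mem], seed_map, n_rounds = 2)
  new_cut <- setdiff(alt$maps$maps$chrA$cut_coords,
                     ref$maps$maps$chrA$cut_coords)
  cb <- rmapforge:::map_boundaries(cm)
  # the added cut's position is estimated from noisy molecule masses and is
  # accurate to well under one fragment (~15 kb here)
  expect_lt(min(abs(cb - new_cut)), 6000)
  # the added cut is well supported
  sup <- attr(cm, "support")
  j <- which.min(abs(sup$cut_bp - new_cut))
  expect_gte(sup$concordant[j] / sup$spanning[j], 0.5)
})

test_that("consensus masses converge to truth with no spurious cuts", {
  ref <- test_ref_small
  n_calls <- 0; relerr <- c()
  for (sd in 43:47) {
    sim <- simulate_rmaps(list(s1 = list(maps = ref$maps)),
                          sim_config(seed = sd, coverage = 30))
    asm <- iterate_assembly(sim$rmaps, ref$maps, n_rounds = 2)
    sv <- call_genome(asm, ref$maps)
    n_calls <- n_calls + nrow(sv$calls)
    cm <- asm$consensus[["chrA:0-1000000"]]
    seedm <- merge_small_fragments(asm$seeds[[1]], 0.4)
    if (length(cm$fragments) == length(seedm$fragments)) {
      rb <- c(0, seedm$cut_coords, attr(seedm, "end_bp") %||% 2e6)
      core <- rb[-length(rb)] < 1e6
      sel <- seedm$fragments > 5 & core
      relerr <- c(relerr, abs(cm$fragments - seedm$fragments)[sel] /
                    seedm$fragments[sel])
    }
  }
  # no structural differences are called on unaltered data
  expect_lte(n_calls, 1)
  # fragment masses track the truth: ~1.5% typical error (the best an
  # unbiased estimator can do at this depth is ~1.4% sd per fragment)
  expect_gt(length(relerr), 20)
  expect_lt(median(relerr), 0.02)
  expect_lt(unname(stats::quantile(relerr, 0.9)), 0.05)
})

test_that("iterative assembly incorporates molecules bearing a 30 kb insertion", {
  ref <- test_ref_small
  ft <- frag_table(ref, "chrA")
  pos <- pick_fragment_mid(ft, 30, 60, 8e5, 8e5)
  alt <- implant_variants(ref$seqs, list(variant_spec("INS", "chrA", pos, 30000)),
                          seed = 5)
  cfg48 <- sim_config(seed = 48, coverage = 30)
  cfg48$subclones[[1]]$label <- "t"
  sim <- simulate_rmaps(list(t = list(maps = alt$maps)), cfg48)
  asm <- iterate_assembly(sim$rmaps, ref$maps, n_rounds = 8)
  # aligned counts never decrease and strictly grow past round 1
  expect_true(all(diff(asm$aligned_per_round) >= 0))
  expect_gt(tail(asm$aligned_per_round, 1), asm$aligned_per_round[1])
  # the consensus carries the inserted mass
  grew <- FALSE
  for (w in seq_along(asm$consensus)) {
    cm <- asm$consensus[[w]]
    if (attr(cm, "status") != "assembled") next
    cb <- rmapforge:::map_boundaries(cm)
    ri <- findInterval(pos, cb)
    if (ri >= 1 && ri <= length(cm$fragments)) {
      i <- findInterval(pos, ft$bounds)
      if (cm$fragments[ri] - ft$kb[i] > 20) grew <- TRUE
    }
  }
  expect_true(grew)
})

test_that("hypothesis maps conserve mass and reflect the rearrangement", {
  ref <- test_ref_small
  spec_inv <- hypothesis_spec("chrA", "inversion", 8e5, 4e5, flank_bp = 3e5)
  h <- make_hypothesis_map(ref$maps, spec_inv)
  span_mass <- sum(diff(c(5e5,
                          ref$maps$maps$chrA$cut_coords[
                            ref$maps$maps$chrA$cut_coords > 5e5 &
                            ref$maps$maps$chrA$cut_coords < 1.5e6],
                          1.5e6))) / 1000
  expect_equal(sum(h$fragments), span_mass, tolerance = 1e-6)
  # deletion removes exactly the interval mass
  h_del <- make_hypothesis_map(ref$maps,
                               hypothesis_spec("chrA", "deletion", 8e5, 4e5,
                                               flank_bp = 3e5))
  expect_equal(sum(h_del$fragments), span_mass - 400, tolerance = 1e-6)
  # null spec reproduces the reference span
  h0 <- make_hypothesis_map(ref$maps,
                            hypothesis_spec("chrA", "none", 8e5, 4e5,
                                            flank_bp = 3e5))
  expect_equal(sum(h0$fragments), span_mass, tolerance = 1e-6)
  expect_error(make_hypothesis_map(ref$maps,
                                   hypothesis_spec("chrA", "deletion",
                                                   1.9e6, 4e5)),
               "outside")
  # the inversion hypothesis equals the digest of the truly inverted genome
  alt <- implant_variants(ref$seqs, list(variant_spec("INV", "chrA", 8e5, 4e5)))
  tm <- alt$maps$maps$chrA
  lo <- attr(h, "start_bp"); hi <- attr(h, "end_bp")
  cuts_true <- tm$cut_coords[tm$cut_coords > lo & tm$cut_coords < hi]
  expect_equal(h$cut_coords, cuts_true)
})
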