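osa_row <- function(class, start, end = start + 1, cut = NA) {
  data.frame(class = class, chrom = "chr1", start = start, end = end,
             size_delta_kb = 0, ref_frag_lo = 1L, ref_frag_hi = 1L,
             cut_bp = cut, consensus_frag = NA_integer_, n_diffs = 1L,
             window_id = "w", n_support = 10L, confidence_p = 1e-9,
             stringsAsFactors = FALSE)
}

gr1 <- function(chrom, start, end, name)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), name = name)

test_that("type-specific windows govern OSA-versus-panel matching", {
  rules <- intersection_rules()
  # MC 80 bp from a panel MC matches under the 100 bp window
  osas <- osa_row("MC", 1e6, cut = 1e6)
  panel <- gr1("chr1", 1000080, 1000081, "MC")
  expect_true(intersect_panel(osas, panel, "om", rules)$matched)
  # but not at 150 bp
  panel2 <- gr1("chr1", 1000150, 1000151, "MC")
  expect_false(intersect_panel(osas, panel2, "om", rules)$matched)
  # classes must correspond
  panel3 <- gr1("chr1", 1000080, 1000081, "EC")
  expect_false(intersect_panel(osas, panel3, "om", rules)$matched)
  # EC vs SNP: 3500 bp exceeds the 3000 bp window, 2500 bp does not
  ec <- osa_row("EC", 2e6, cut = 2e6)
  snp_far <- gr1("chr1", 2003500, 2003501, "snp")
  snp_near <- gr1("chr1", 2002500, 2002501, "snp")
  expect_false(intersect_panel(ec, snp_far, "snp", rules)$matched)
  expect_true(intersect_panel(ec, snp_near, "snp", rules)$matched)
  # unknown class in an OM panel errors
  expect_error(intersect_panel(ec, gr1("chr1", 1, 2, "WEIRD"), "om", rules),
               "unknown OSA class")
})

test_that("external panels route by the 3 kb size partition", {
  rules <- intersection_rules()
  # a 2.9 kb external deletion is compared to cut classes, never to DEL
  ext_small <- gr1("chr1", 3e6, 3e6 + 2900, "del")
  del_call <- osa_row("DEL", 3e6, 3e6 + 2900)
  expect_false(intersect_panel(del_call, ext_small, "external",
                               rules)$matched)
  ec_call <- osa_row("EC", 3e6 + 1000, cut = 3e6 + 1000)
  expect_true(intersect_panel(ec_call, ext_small, "external", rules)$matched)
  # a 5 kb external event matches DEL with a 0 bp window
  ext_big <- gr1("chr1", 3e6, 3e6 + 5000, "del")
  del_call2 <- osa_row("DEL", 3e6 + 1000, 3e6 + 4000)
  expect_true(intersect_panel(del_call2, ext_big, "external", rules)$matched)
  del_nonoverlap <- osa_row("DEL", 3e6 + 6000, 3e6 + 9000)
  expect_false(intersect_panel(del_nonoverlap, ext_big, "external",
                               rules)$matched)
})

test_that("window expansion is symmetric", {
  rules <- intersection_rules()
  set.seed(21)
  for (i in 1:50) {
    a <- sort(sample(1:1e6, 2)); b <- sort(sample(1:1e6, 2))
    w <- sample(c(0, 100, 4200), 1)
    gra <- gr1("chr1", a[1], a[2], "EC"); grb <- gr1("chr1", b[1], b[2], "EC")
    m1 <- GenomicRanges::countOverlaps(rmapforge:::expand_gr(gra, w), grb) > 0
    m2 <- GenomicRanges::countOverlaps(gra, rmapforge:::expand_gr(grb, w)) > 0
    expect_equal(m1, m2)
  }
})

test_that("somatic filtering partitions calls and is monotone in panels", {
  set.seed(22)
  classes <- c("EC", "MC", "INS", "DEL")
  shared_pos <- sort(sample(seq(1e5, 4.9e6, by = 1e4), 50))
  private_pos <- sort(sample(seq(5.1e6, 9e6, by = 1e4), 10))
  osas <- do.call(rbind, c(
    lapply(seq_along(shared_pos), function(i)
      osa_row(classes[i %% 4 + 1], shared_pos[i],
              shared_pos[i] + ifelse(classes[i %% 4 + 1] %in%
                                       c("INS", "DEL"), 8000, 1),
              cut = shared_pos[i])),
    lapply(seq_along(private_pos), function(i)
      osa_row(classes[i %% 4 + 1], private_pos[i],
              private_pos[i] + ifelse(classes[i %% 4 + 1] %in%
                                        c("INS", "DEL"), 8000, 1),
              cut = private_pos[i]))))
  osas$id <- seq_len(nrow(osas))
  # two normal panels each holding a subset of the shared calls (with small
  # jitter within the class windows), jointly covering all of them
  jitter_of <- function(cls) ifelse(cls %in% c("INS", "DEL"), 0,
                                    ifelse(cls == "EC", 2000, 50))
  mk_panel <- function(rows) {
    j <- jitter_of(osas$class[rows])
    gr1("chr1", osas$start[rows] + j, osas$end[rows] + j, osas$class[rows])
  }
  panels <- list(panelA = mk_panel(1:30), panelB = mk_panel(16:50))
  res <- filter_somatic(osas, panels)
  expect_equal(nrow(res$candidates) + nrow(res$removed), nrow(osas))
  expect_equal(sort(res$candidates$id), 51:60)
  expect_equal(unname(res$tally["panelA"]), 30)
  expect_true(all(grepl("panelA", res$removed$matched_panels[1:15])))
  # monotone: dropping a panel never shrinks the candidate set
  res1 <- filter_somatic(osas, panels["panelA"])
  expect_true(all(res$candidates$id %in% res1$candidates$id))
  expect_warning(res0 <- filter_somatic(osas, list()), "no panels")
  expect_equal(nrow(res0$candidates), nrow(osas))
})

test_that("gene annotation reports every half-open overlap", {
  genes <- gr1("chr1", c(1000, 5000, 5400), c(2000, 6000, 9000),
               c("G1", "G2", "G3"))
  osas <- rbind(osa_row("DEL", 1500, 1800),   # inside G1
                osa_row("DEL", 2000, 2100),   # touches G1 only at its end
                osa_row("INS", 5300, 5600))   # spans G2 and G3
  ann <- annotate_genes(osas, genes)
  expect_equal(ann$genes, c("G1", "", "G2,G3"))
})
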