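mkpair <- function(l_start = 1000L, l_end = 1200L, r_start = 2200L,
                   r_end = 2400L, id = "pA") {
  data.frame(pair_id = id, chrom = "chr1",
             l_name = paste0(id, "L"), l_start = l_start, l_end = l_end,
             r_name = paste0(id, "R"), r_start = r_start, r_end = r_end,
             inter_start = l_end, inter_end = r_start,
             d_h = interval_midpoint(r_start, r_end) -
               interval_midpoint(l_start, l_end),
             stringsAsFactors = FALSE)
}

test_that("flat tracks give identical summaries in all four regions", {
  pairs <- mkpair()
  tracks <- list(flat_track(3, "T01", "H3K27ac"))
  s <- region_summaries(pairs, tracks)
  expect_equal(nrow(s), 4L)
  expect_equal(unique(s$value), 3)
  expect_false(any(s$flag_short))
})

test_that("best 200-bp window finds an embedded spike and dominates the regional mean", {
  ## inter-CNE [1200, 2200): 1000 bp, spike of 10 on [1400,1600), baseline 1
  pairs <- mkpair()
  bins <- data.frame(chrom = "chr1",
                     start = c(0L, 1400L, 1600L),
                     end = c(1400L, 1600L, 5000L),
                     value = c(1, 10, 1))
  tr <- signal_track("T01", "H3K4me1", bins)
  s <- region_summaries(pairs, list(tr))
  expect_equal(s$value[s$region == "best200"], 10)
  expect_equal(s$value[s$region == "inter"], (200 * 10 + 800 * 1) / 1000)
  expect_gte(s$value[s$region == "best200"], s$value[s$region == "inter"])
})

test_that("short inter-CNE sequences fall back to the whole-region mean with a flag", {
  pairs <- mkpair(l_start = 1000L, l_end = 1200L, r_start = 1350L, r_end = 1550L)
  s <- region_summaries(pairs, list(flat_track(2)))
  b <- s[s$region == "best200", ]
  expect_true(b$flag_short)
  expect_equal(b$value, s$value[s$region == "inter"])
})

test_that("CNE_h/CNE_l sorting uses mean H3K27ac across tissues with left tie-break", {
  pairs <- mkpair()
  left_sig <- function(tissue, lv, rv) {
    signal_track(tissue, "H3K27ac",
                 data.frame(chrom = "chr1", start = c(0L, 1500L),
                            end = c(1500L, 5000L), value = c(lv, rv)))
  }
  ## left CNE window [950,1250) sees lv; right [2150,2450) sees rv
  s <- region_summaries(pairs, list(left_sig("T01", 4, 2), left_sig("T02", 4, 2)))
  srt <- sort_cne_h_l(s)
  expect_equal(srt$sides$cne_h_side, "left")
  expect_equal(sort(unique(srt$summaries$region)),
               sort(c("CNE_h", "CNE_l", "inter", "best200")))
  ## right side higher
  s2 <- region_summaries(pairs, list(left_sig("T01", 1, 6)))
  expect_equal(sort_cne_h_l(s2)$sides$cne_h_side, "right")
  ## exact tie goes left
  s3 <- region_summaries(pairs, list(left_sig("T01", 3, 3)))
  expect_equal(sort_cne_h_l(s3)$sides$cne_h_side, "left")
  ## invariant to tissue order
  s4 <- region_summaries(pairs, list(left_sig("T02", 4, 2), left_sig("T01", 4, 2)))
  expect_equal(sort_cne_h_l(s4)$sides, srt$sides)
})

test_that("feature matrix has tissue x region x mark columns in fixed order", {
  pairs <- mkpair()
  tracks <- list()
  for (ts in c("T01", "T02")) {
    for (mk in HISTONE_MARKS) tracks[[paste(ts, mk)]] <- flat_track(2, ts, mk)
  }
  s <- sort_cne_h_l(region_summaries(pairs, tracks))
  fm <- build_feature_matrix(s$summaries)
  expect_equal(dim(fm), c(1L, 2L * 4L * 5L))
  expect_equal(colnames(fm)[1:5],
               paste0("T01.CNE_h.", sort(HISTONE_MARKS)))
  expect_equal(colnames(fm)[21], paste0("T02.CNE_h.", sort(HISTONE_MARKS)[1]))
  expect_true(all(fm == 2))
  ## single tissue -> 20 columns
  fm1 <- build_feature_matrix(s$summaries[s$summaries$tissue == "T01", ])
  expect_equal(ncol(fm1), 20L)
  ## absent combinations fill with baseline
  drop_one <- s$summaries[!(s$summaries$tissue == "T02" &
                              s$summaries$mark == "H3K9me3"), ]
  fm2 <- build_feature_matrix(drop_one, tissues = c("T01", "T02"))
  expect_equal(unname(fm2[1, "T02.CNE_h.H3K9me3"]), 1.0)
})

test_that("coactivity table and background threshold behave as specified", {
  expect_false(above_background(1.0))   # fold 1 is background, strictly above
  expect_true(above_background(1.0001))
  ## synthetic counts: both=30, h-only=20, l-only=20, neither=30 -> OR 2.25
  tab <- matrix(c(30, 20, 20, 30), 2, byrow = TRUE)
  expect_equal(odds_ratio(tab), 2.25)
  ## build the same table through coactivity_counts
  vals_h <- c(rep(2, 30), rep(2, 20), rep(0.5, 20), rep(0.5, 30))
  vals_l <- c(rep(2, 30), rep(0.5, 20), rep(2, 20), rep(0.5, 30))
  s <- data.frame(pair_id = rep(sprintf("p%03d", 1:100), 2),
                  tissue = "T01", mark = "H3K27ac",
                  region = rep(c("CNE_h", "CNE_l"), each = 100),
                  value = c(vals_h, vals_l), flag_short = FALSE,
                  stringsAsFactors = FALSE)
  tab2 <- coactivity_counts(s, "T01", "H3K27ac")
  expect_equal(unname(tab2), matrix(c(30, 20, 20, 30), 2, byrow = TRUE))
  expect_equal(odds_ratio(tab2), 2.25)
  ## all below background -> everything in the 'neither' cell
  s$value <- 0.5
  tab3 <- coactivity_counts(s, "T01", "H3K27ac")
  expect_equal(unname(tab3), matrix(c(0, 0, 0, 100), 2, byrow = TRUE))
})

test_that("best200 dominates the inter-CNE mean on generated data", {
  sim <- simulate_cne_data(tiny_config(seed = 17L, n_pairs = 10L))
  res <- run_cne_pipeline(sim, n_rep = 0L)
  s <- res$summaries
  wide <- merge(s[s$region == "best200", c("pair_id", "tissue", "mark", "value")],
                s[s$region == "inter", c("pair_id", "tissue", "mark", "value")],
                by = c("pair_id", "tissue", "mark"), suffixes = c("_best", "_inter"))
  expect_true(all(wide$value_best >= wide$value_inter - 1e-9))
})

test_that("inter-CNE enrichment randomization reacts to planted hotspots", {
  set.seed(30)
  ## 40 pairs whose inter-CNE sequences all carry a strong 200-bp hotspot
  n <- 40L
  l_start <- seq(10000L, by = 20000L, length.out = n)
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    mkpair(l_start[i], l_start[i] + 200L, l_start[i] + 2200L,
           l_start[i] + 2400L, id = sprintf("p%03d", i))
  }))
  hot <- pairs$inter_start + 800L
  bins <- data.frame(chrom = "chr1",
                     start = c(0L, rbind(hot, hot + 200L)),
                     end = c(rbind(hot, hot + 200L), 1e6L),
                     value = c(rbind(rep(1, n), rep(8, n)), 1))
  tr <- signal_track("T01", "H3K4me1", bins)
  r <- empirical_inter_cne_test(pairs, list(tr), c(chr1 = 1e6),
                                n_rep = 30L, seed = 6L)
  expect_gte(r$prop_significant, 0.9)
  expect_equal(r$direction, "enriched")
  expect_error(empirical_inter_cne_test(pairs, list(tr), c(chr1 = 1e6),
                                        n_rep = 0L), "n_rep")
})
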