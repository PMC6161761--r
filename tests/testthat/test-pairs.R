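el <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(chrom = "chr1", start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             stringsAsFactors = FALSE)
}

test_that("merging joins gaps under 100 bp and drops short elements", {
  ## gap 50 merges, gap 580 does not
  out <- merge_and_filter(el(100, 250, 300, 420, 1000, 1100))
  expect_equal(out$start, c(100L, 1000L))
  expect_equal(out$end, c(420L, 1100L))
  ## gap 99 merges (strictly-smaller-than-100 rule)
  out <- merge_and_filter(el(0, 150, 249, 400))
  expect_equal(out$start, 0L)
  expect_equal(out$end, 400L)
  ## exactly 100 does not merge
  out <- merge_and_filter(el(0, 150, 250, 400))
  expect_equal(nrow(out), 2L)
  ## post-merge length < 100 removed
  expect_equal(nrow(merge_and_filter(el(0, 99))), 0L)
  ## 40+40 with gap 19 merges into 99 -> still removed
  expect_equal(nrow(merge_and_filter(el(0, 40, 59, 99))), 0L)
})

test_that("merge_and_filter is idempotent on random element sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    s <- sort(sample.int(10000, n))
    e <- s + sample(20:400, n, replace = TRUE)
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = s, end = e, stringsAsFactors = FALSE)
    once <- suppressMessages(merge_and_filter(df))
    twice <- suppressMessages(merge_and_filter(once))
    expect_equal(twice[, c("chrom", "start", "end")],
                 once[, c("chrom", "start", "end")])
  }
})

test_that("element classification follows exon > UTR > intron > intergenic", {
  ann <- list(genes = data.frame(chrom = "chr1", start = 1000L, end = 5000L,
                                 strand = "+", gene_id = "g1"),
              exons = data.frame(chrom = "chr1", start = 2000L, end = 2500L,
                                 strand = "+", gene_id = "g1"),
              utrs = data.frame(chrom = "chr1", start = 1900L, end = 2000L,
                                strand = "+", gene_id = "g1"))
  e <- el(1950, 2100,   # overlaps UTR + exon + intron -> exon
          1850, 1950,   # UTR + intron -> UTR
          3000, 3200,   # inside gene only -> intron
          8000, 8100)   # no gene -> intergenic
  out <- classify_elements(e, ann)
  expect_equal(as.character(out$category),
               c("exon", "UTR", "intron", "intergenic"))
})

test_that("pair building respects adjacency over all elements and size limits", {
  mk <- function(starts, ends, cats) {
    data.frame(chrom = "chr1", start = starts, end = ends,
               name = paste0("e", seq_along(starts)),
               category = factor(cats, levels = c("exon", "UTR", "intron",
                                                  "intergenic")),
               stringsAsFactors = FALSE)
  }
  ## three consecutive CNEs -> two pairs
  p <- build_pairs(mk(c(0L, 1000L, 2500L), c(200L, 1300L, 2700L),
                      rep("intergenic", 3)))
  expect_equal(nrow(p), 2L)
  expect_equal(p$l_name, c("e1", "e2"))
  expect_equal(p$inter_start, p$l_end)
  expect_equal(p$inter_end, p$r_start)
  expect_equal(p$d_h, interval_midpoint(p$r_start, p$r_end) -
                 interval_midpoint(p$l_start, p$l_end))
  ## a coding element in between breaks CNE adjacency entirely
  p <- build_pairs(mk(c(0L, 1000L, 2500L), c(200L, 1300L, 2700L),
                      c("intergenic", "exon", "intergenic")))
  expect_equal(nrow(p), 0L)
  ## an element longer than 1000 bp excludes its pairs
  p <- build_pairs(mk(c(0L, 2000L), c(1200L, 2300L), rep("intron", 2)))
  expect_equal(nrow(p), 0L)
  p <- build_pairs(mk(c(0L, 2000L), c(1000L, 2300L), rep("intron", 2)))
  expect_equal(nrow(p), 1L)  # exactly 1000 bp is allowed
})

test_that("RBH acceptance requires the reverse best hit to overlap the query", {
  qe <- data.frame(chrom = "chr1", start = 100L, end = 300L, name = "q1",
                   stringsAsFactors = FALSE)
  fwd <- data.frame(query_id = "q1", species = "mouse", chrom = "chrM",
                    start = c(5000L, 9000L), end = c(5200L, 9200L),
                    score = c(95, 60), stringsAsFactors = FALSE)
  rev_ok <- data.frame(species = "mouse", q_chrom = "chrM", q_start = 5000L,
                       q_end = 5200L, chrom = "chr1", start = 150L, end = 350L,
                       score = 90, stringsAsFactors = FALSE)
  out <- rbh_orthologs(fwd, rev_ok, qe)
  expect_equal(out$start, 5000L)  # the best forward hit, accepted
  ## reverse best maps elsewhere (0 bp overlap) -> rejected
  rev_bad <- transform(rev_ok, start = 5000L, end = 5200L)
  expect_equal(nrow(rbh_orthologs(fwd, rev_bad, qe)), 0L)
  ## no forward hits -> no ortholog
  expect_equal(nrow(rbh_orthologs(fwd[0, ], rev_ok, qe)), 0L)
  ## score tie broken by smallest target start
  fwd_tie <- transform(fwd, score = 95)
  rev2 <- rbind(rev_ok, data.frame(species = "mouse", q_chrom = "chrM",
                                   q_start = 9000L, q_end = 9200L,
                                   chrom = "chr1", start = 150L, end = 350L,
                                   score = 90))
  out <- rbh_orthologs(fwd_tie, rev2, qe)
  expect_equal(out$start, 5000L)
})

test_that("RBH equals brute-force resolution on random hit tables", {
  set.seed(99)
  for (rep in 1:10) {
    nq <- 5L
    qe <- data.frame(chrom = "chr1", start = (0:4) * 1000L,
                     end = (0:4) * 1000L + 200L, name = paste0("q", 1:5),
                     stringsAsFactors = FALSE)
    nf <- sample(20:60, 1)
    fwd <- data.frame(query_id = sample(qe$name, nf, TRUE),
                      species = sample(c("mouse", "dog"), nf, TRUE),
                      chrom = "chrM",
                      start = sample.int(50000L, nf), score = round(runif(nf, 10, 100), 1),
                      stringsAsFactors = FALSE)
    fwd$end <- fwd$start + 200L
    nr <- sample(20:80, 1)
    ## reverse rows for a subset of the forward targets
    src <- fwd[sample.int(nf, nr, replace = TRUE), ]
    rev_ <- data.frame(species = src$species, q_chrom = src$chrom,
                       q_start = src$start, q_end = src$end, chrom = "chr1",
                       start = sample.int(6000L, nr), score = round(runif(nr, 10, 100), 1),
                       stringsAsFactors = FALSE)
    rev_$end <- rev_$start + 200L
    mine <- rbh_orthologs(fwd, rev_, qe)
    mine <- mine[order(mine$element, mine$species), ]
    rownames(mine) <- NULL
    oracle <- rbh_brute_force(fwd, rev_, qe)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
    } else {
      rownames(oracle) <- NULL
      expect_equal(mine, oracle)
    }
  }
})

test_that("conservation categories and the 250 kb discard rule", {
  els <- data.frame(chrom = "chr1",
                    start = c(0L, 2000L), end = c(200L, 2200L),
                    name = c("A", "B"),
                    category = factor(c("intergenic", "intergenic"),
                                      levels = c("exon", "UTR", "intron",
                                                 "intergenic")),
                    stringsAsFactors = FALSE)
  pairs <- build_pairs(els)
  orth <- function(...) {
    do.call(rbind, lapply(list(...), function(x) {
      data.frame(element = x[[1]], species = x[[2]], chrom = x[[3]],
                 start = as.integer(x[[4]]), end = as.integer(x[[4]]) + 200L,
                 stringsAsFactors = FALSE)
    }))
  }
  species <- c("platypus", "dog", "chicken", "frog")
  ## platypus orthologs 3 kb apart -> mammalian
  r <- classify_conservation(pairs, orth(list("A", "platypus", "c", 0),
                                         list("B", "platypus", "c", 3000)),
                             species)
  expect_equal(r$pairs$category, "mammalian")
  ## chicken + frog only -> deeply, not mammalian
  r <- classify_conservation(pairs, orth(list("A", "chicken", "c", 0),
                                         list("B", "chicken", "c", 2500),
                                         list("A", "frog", "c", 0),
                                         list("B", "frog", "c", 4000)),
                             species)
  expect_equal(r$pairs$category, "deeply")
  ## orthologs 260 kb apart in dog -> pair discarded entirely
  r <- classify_conservation(pairs, orth(list("A", "platypus", "c", 0),
                                         list("B", "platypus", "c", 3000),
                                         list("A", "dog", "c", 0),
                                         list("B", "dog", "c", 260000)),
                             species)
  expect_equal(nrow(r$pairs), 0L)
  expect_equal(r$discarded$pair_id, pairs$pair_id)
  ## orthologs on different chromosomes -> rearrangement, discarded
  om <- orth(list("A", "dog", "c", 0), list("B", "dog", "d", 3000))
  r <- classify_conservation(pairs, om, species)
  expect_equal(nrow(r$pairs), 0L)
})

test_that("AO pairs require orthologs that are adjacent and paired in the other genome", {
  sim <- simulate_cne_data(tiny_config(seed = 21L, n_pairs = 10L,
                                       decoy_fraction = 0,
                                       n_decoy_genes = 0L))
  res_h <- run_cne_pipeline(sim, n_rep = 0L)
  res_m <- run_cne_pipeline(sim, reference = "mouse", n_rep = 0L)
  ao <- find_ao_pairs(res_h$pairs, res_m$pairs, res_h$orthologs,
                      sim$elements$mouse)
  ## with decoys off, the AO set is exactly the planted pair set
  expect_equal(sort(ao$pair_id_a), sort(sim$truth$pair_id))
  expect_true(all(ao$pair_id_b == ao$pair_id_a))
  ## category labels follow the 9-way binning
  expect_match(ao$category, "^H(1-3|4-7|8-10); M(1-3|4-7|8-10)$")
  ## an intervening conserved element in the other genome breaks condition 2
  extra <- sim$elements$mouse
  mid <- res_m$pairs[res_m$pairs$pair_id == ao$pair_id_b[1], ]
  wedge <- data.frame(chrom = mid$chrom,
                      start = mid$inter_start + 2L,
                      end = min(mid$inter_start + 152L, mid$inter_end - 2L),
                      name = "wedge", stringsAsFactors = FALSE)
  ao2 <- find_ao_pairs(res_h$pairs, res_m$pairs, res_h$orthologs,
                       rbind(extra, wedge))
  expect_false(mid$pair_id %in% ao2$pair_id_b)
  expect_equal(nrow(ao2), nrow(ao) - 1L)
})

test_that("every emitted pair satisfies the size and distance invariants", {
  sim <- simulate_cne_data(tiny_config(seed = 31L, n_pairs = 15L))
  res <- run_cne_pipeline(sim, n_rep = 0L)
  p <- res$pairs
  expect_true(all(p$l_end - p$l_start >= 100))
  expect_true(all(p$r_end - p$r_start <= 1000))
  expect_true(all(p$d_h > 0))
  expect_true(all(p$l_end <= p$r_start))
})
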