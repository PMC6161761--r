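test_that("zero-noise conserved pairs put the planted distance at every tip", {
  cfg <- tiny_config(seed = 41L, n_pairs = 8L, sigma2 = 0,
                     class_fractions = c(contracted = 0, conserved = 1,
                                         expanded = 0))
  d <- simulate_distances(cfg)
  expect_true(all(d$tips == d$truth$d_r_true))
})

test_that("class shifts act only on the focal terminal branch", {
  cfg <- tiny_config(seed = 42L, n_pairs = 30L, sigma2 = 0)
  d <- simulate_distances(cfg)
  non_focal <- setdiff(colnames(d$tips), "human")
  expect_true(all(d$tips[, non_focal] == d$truth$d_r_true))
  con <- d$truth$class == "contracted"
  exp_ <- d$truth$class == "expanded"
  expect_equal(d$tips[con, "human"],
               as.integer(round(pmax(0.5 * d$truth$d_r_true[con], 200))))
  expect_equal(d$tips[exp_, "human"],
               as.integer(round(1.5 * d$truth$d_r_true[exp_])))
})

test_that("distances are clipped at the configured minimum", {
  cfg <- tiny_config(seed = 43L, n_pairs = 40L, sigma2 = 3000,
                     d_range = c(200, 400), min_distance = 200L)
  d <- simulate_distances(cfg)
  expect_true(all(d$tips >= 200L))
})

test_that("emitted element midpoints reproduce the simulated distances exactly", {
  cfg <- tiny_config(seed = 44L, n_pairs = 10L)
  d <- simulate_distances(cfg)
  lay <- emit_elements_and_pairs(cfg, d)
  for (sp in c("human", "platypus", "zebrafish")) {
    e <- lay$elements[[sp]]
    l <- e[match(sprintf("p%04dL", 1:10), e$name), ]
    r <- e[match(sprintf("p%04dR", 1:10), e$name), ]
    got <- interval_midpoint(r$start, r$end) - interval_midpoint(l$start, l$end)
    expect_equal(got, unname(d$tips[, sp]))
    ## legal element sizes, disjoint placement
    expect_true(all(e$end - e$start >= 100))
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] >= e$end[-nrow(e)] + 100))
  }
})

test_that("RBH recovers every planted ortholog when decoys are off, and decoys do not hurt", {
  cfg <- tiny_config(seed = 45L, n_pairs = 8L, decoy_fraction = 0)
  sim <- simulate_cne_data(cfg)
  om <- rbh_orthologs(sim$hits$human$forward, sim$hits$human$reverse,
                      sim$elements$human)
  expect_equal(nrow(om), 2L * 8L * 22L)  # both CNEs x all non-focal species
  ## with decoys on, best hits still win and recovery stays complete
  cfg2 <- tiny_config(seed = 45L, n_pairs = 8L, decoy_fraction = 0.5)
  sim2 <- simulate_cne_data(cfg2)
  om2 <- rbh_orthologs(sim2$hits$human$forward, sim2$hits$human$reverse,
                       sim2$elements$human)
  expect_equal(nrow(om2), 2L * 8L * 22L)
  ## reciprocal-best violations remove exactly those orthologs
  cfg3 <- tiny_config(seed = 45L, n_pairs = 8L, decoy_fraction = 0,
                      rbh_violation_fraction = 1)
  sim3 <- simulate_cne_data(cfg3)
  om3 <- rbh_orthologs(sim3$hits$human$forward, sim3$hits$human$reverse,
                       sim3$elements$human)
  expect_equal(nrow(om3), 0L)
})

test_that("transposon emission honours class structure and truth", {
  cfg <- tiny_config(seed = 46L, n_pairs = 12L)
  sim <- simulate_cne_data(cfg)
  tt <- sim$transposon_truth
  ## truth covers every pair x class
  expect_equal(nrow(tt), 12L * 4L)
  ## transposon-free pairs have zero overlap in every species
  free <- sim$truth$pair_id[sim$truth$tp_free]
  if (length(free)) {
    for (sp in c("human", "mouse", "platypus")) {
      e <- sim$elements[[sp]]
      pe <- sim$pair_elements[sim$pair_elements$pair_id %in% free, ]
      l <- e[match(pe$l_name, e$name), ]; r <- e[match(pe$r_name, e$name), ]
      reg <- data.frame(chrom = l$chrom,
                        start = interval_midpoint(l$start, l$end),
                        end = interval_midpoint(r$start, r$end))
      dd <- transposon_density(reg, sim$transposons[[sp]])
      expect_true(all(dd$covered_total == 0))
    }
  }
  ## planted content in a non-focal species matches the ancestral truth
  sp <- "platypus"
  e <- sim$elements[[sp]]
  pe <- sim$pair_elements
  l <- e[match(pe$l_name, e$name), ]; r <- e[match(pe$r_name, e$name), ]
  reg <- data.frame(chrom = l$chrom,
                    start = interval_midpoint(l$start, l$end),
                    end = interval_midpoint(r$start, r$end))
  dd <- transposon_density(reg, sim$transposons[[sp]])
  for (cl in TRANSPOSON_CLASSES) {
    want <- tt$T_r_true[tt$class == cl]
    expect_equal(dd[[paste0("covered_", cl)]], want)
  }
})

test_that("zero class densities give an empty inter-CNE transposon annotation", {
  cfg <- tiny_config(seed = 47L, n_pairs = 6L, tp_level = 0, tp_gain_frac = 0)
  sim <- simulate_cne_data(cfg)
  ## non-reference species receive only inter-CNE content, which is now zero
  expect_equal(nrow(sim$transposons$platypus), 0L)
  expect_true(all(sim$transposon_truth$T_r_true == 0))
})

test_that("background transposon coverage sits near the configured density", {
  cfg <- tiny_config(seed = 48L, n_pairs = 25L)
  sim <- simulate_cne_data(cfg)
  L <- sim$chrom_lengths$human[["chr1"]]
  ## a 1-Mb slab of pure background in the empty chromosome tail
  s0 <- L - 1200000L
  reg <- data.frame(chrom = "chr1", start = s0, end = s0 + 1000000L)
  d <- transposon_density(reg, sim$transposons$human)
  expect_lt(abs(d$density_total - 0.46), 0.03)
})

test_that("track emission realizes the archetype signal model", {
  cfg0 <- tiny_config(seed = 49L, n_pairs = 6L, noise_sd = 0,
                      archetype_fractions = c(inactive = 1, inter_poised = 0,
                                              cne_poised = 0, cne_active = 0),
                      n_tissues = 1L)
  sim0 <- simulate_cne_data(cfg0)
  res0 <- run_cne_pipeline(sim0, n_rep = 0L)
  on_track <- res0$summaries$pair_id %in% sim0$truth$pair_id
  expect_true(all(abs(res0$summaries$value[on_track] - 1) < 1e-12))

  cfg1 <- tiny_config(seed = 49L, n_pairs = 6L, noise_sd = 0,
                      archetype_fractions = c(inactive = 0, inter_poised = 0,
                                              cne_poised = 0, cne_active = 1),
                      signal_amplitude = 5, n_tissues = 1L)
  sim1 <- simulate_cne_data(cfg1)
  res1 <- run_cne_pipeline(sim1, n_rep = 0L)
  s <- res1$summaries
  planted <- s$pair_id %in% sim1$truth$pair_id
  cne <- planted & s$region %in% c("CNE_h", "CNE_l") & s$mark == "H3K27ac"
  expect_true(all(abs(s$value[cne] - 6.0) < 1e-12))
  ## repressive marks stay at baseline for active pairs
  rep_ <- planted & s$mark == "H3K9me3"
  expect_true(all(abs(s$value[rep_] - 1.0) < 1e-12))
})

test_that("identical seeds give byte-identical serialized data sets", {
  cfg <- tiny_config(seed = 50L, n_pairs = 5L, n_tissues = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_data(simulate_cne_data(cfg), d1)
  write_sim_data(simulate_cne_data(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
  ## a different seed changes the data
  write_sim_data(simulate_cne_data(tiny_config(seed = 51L, n_pairs = 5L,
                                               n_tissues = 1L)), d2)
  h3 <- tools::md5sum(file.path(d2, f1))
  expect_false(all(unname(h1) == unname(h3)))
})

test_that("serialized data sets round-trip through the io readers", {
  cfg <- tiny_config(seed = 52L, n_pairs = 4L, n_tissues = 1L)
  sim <- simulate_cne_data(cfg)
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  els <- read_bed(file.path(d, "elements", "human.bed"))
  expect_equal(els[, c("chrom", "start", "end", "name")],
               sim$elements$human[, c("chrom", "start", "end", "name")])
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(sim$tree$tip.label))
  ann <- read_gtf(file.path(d, "genes_human.gtf"))
  expect_equal(sort(ann$genes$gene_id), sort(sim$annotation$human$genes$gene_id))
  key <- names(sim$tracks)[1]
  tk <- read_track(file.path(d, "tracks", paste0(sim$tracks[[key]]$tissue, "_",
                                                 sim$tracks[[key]]$mark,
                                                 ".bedGraph")),
                   sim$tracks[[key]]$tissue, sim$tracks[[key]]$mark)
  expect_equal(tk$bins$start, sim$tracks[[key]]$bins$start)
  expect_equal(tk$bins$value, sim$tracks[[key]]$bins$value, tolerance = 1e-4)
})
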