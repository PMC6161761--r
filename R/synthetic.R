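#' Default 23-species dated phylogeny (Newick, branch lengths in My)
#'
#' Ultrametric topology with approximate divergence times for the species
#' panel used throughout: 16 mammals (platypus as the deepest mammal,
#' defining the common mammalian ancestor at ~177 My) plus 7 nonmammalian
#' vertebrates. The internal node labelled \code{Mammalia} is the target of
#' ancestral reconstruction.
#' @export
DEFAULT_TREE_NEWICK <- paste0(
  "(((((((((((human:7,chimp:7):22,rhesus:29):14,marmoset:43):47,",
  "(mouse:21,rat:21):69):6,(((dog:55,panda:55):22,((pig:64,dolphin:64):12,",
  "rhinoceros:76):1):1,microbat:78):18):9,(elephant:99,armadillo:99):6):54,",
  "opossum:159):18,platypus:177)Mammalia:135,(((chicken:98,zebra_finch:98):157,",
  "turtle:255):25,lizard:280):32):40,frog:352):83,",
  "(zebrafish:235,fugu:235):200);")

#' Mammalian species of the default panel
#' @export
DEFAULT_MAMMALS <- c("human", "chimp", "rhesus", "marmoset", "mouse", "rat",
                     "dog", "panda", "pig", "dolphin", "rhinoceros", "microbat",
                     "elephant", "armadillo", "opossum", "platypus")

#' Nonmammalian vertebrates used for deep conservation
#' @export
DEFAULT_DEEP_SPECIES <- c("lizard", "turtle", "chicken", "zebra_finch", "frog",
                          "fugu", "zebrafish")

.default_genome_sizes <- c(
  human = 3.10e9, chimp = 3.20e9, rhesus = 3.20e9, marmoset = 2.90e9,
  mouse = 2.73e9, rat = 2.87e9, dog = 2.40e9, panda = 2.30e9, pig = 2.80e9,
  dolphin = 2.40e9, rhinoceros = 2.50e9, microbat = 2.00e9, elephant = 3.20e9,
  armadillo = 3.20e9, opossum = 3.60e9, platypus = 2.00e9, chicken = 1.00e9,
  zebra_finch = 1.20e9, turtle = 2.20e9, lizard = 1.80e9, frog = 1.50e9,
  zebrafish = 1.40e9, fugu = 0.40e9)

#' Configuration for the synthetic-data generator
#'
#' Defines the simulated study conditions: a panel of 23 vertebrate species
#' on a dated tree, CNE-CNE pairs with ancestral inter-CNE distances planted
#' at the common mammalian ancestor, Brownian-motion evolution of the
#' distances along the tree, a contraction/conservation/expansion class per
#' pair (deterministic +-50% shift on the focal terminal branch), transposon
#' content tied to the classes, and per-pair epigenetic archetypes realized
#' as histone-mark fold-enrichment tracks.
#'
#' @param seed Master seed; every random choice derives from it.
#' @param n_pairs Number of CNE-CNE pairs to plant (default 500).
#' @param species Species panel (default: the 23-species set of
#'   \code{DEFAULT_TREE_NEWICK}).
#' @param focal,secondary Reference genomes (default human, mouse).
#' @param tree_newick Dated tree over \code{species}.
#' @param genome_sizes Named assembly sizes (bp) used by nRDD/nRTD.
#' @param G_r Ancestor genome size (bp, default 3,270,000,000).
#' @param class_fractions Mixture over contracted/conserved/expanded
#'   (default 0.3/0.4/0.3, mirroring nRDD group ranges 1-3/4-7/8-10).
#' @param sigma2 BM rate in bp^2/My (default 25: distance sd of ~70 bp over
#'   the tree depth, i.e. strong conservation relative to kb-scale
#'   distances). 0 is allowed for exact-recovery checks.
#' @param shift_frac Deterministic contraction/expansion applied to the
#'   focal terminal branch, as a fraction of the ancestral distance
#'   (default 0.5).
#' @param d_range Ancestral distances are log-uniform over this range
#'   (default 1,000-20,000 bp, spanning the observed kb-scale medians).
#' @param min_distance Lower clip for simulated distances (default 200 bp).
#' @param gap_between Distance between consecutive planted pairs on the
#'   synthetic chromosome (default 20,000 bp); a spacer element overlapping
#'   a protein-coding exon sits halfway so that between-pair adjacencies are
#'   coding and never form CNE-CNE pairs.
#' @param decoy_fraction Fraction of (element, species) alignments that gain
#'   an extra sub-optimal decoy hit (default 0.2).
#' @param rbh_violation_fraction Fraction whose best forward hit is made
#'   reciprocal-best-violating, removing that ortholog (default 0).
#' @param tp_level Ancestral transposon content of an inter-CNE span as a
#'   fraction of the ancestral distance (default 0.15).
#' @param tp_class_shares Split of that content across classes.
#' @param tp_gain_frac Extra focal-genome transposon content of expanded
#'   pairs (fraction of ancestral distance; SINE/LINE 0.7/0.3).
#' @param tp_free_fraction Fraction of conserved-class pairs that are
#'   transposon-free everywhere (default 0.1).
#' @param tp_background Genome-wide transposon coverage outside pair
#'   regions (default 0.46, the random expectation).
#' @param n_tissues Number of tissues with signal tracks (default 3).
#' @param archetype_fractions Mixture over epigenetic archetypes
#'   inactive / inter_poised / cne_poised / cne_active (default
#'   0.56/0.34/0.05/0.05, the observed cluster proportions).
#' @param signal_amplitude Fold-enrichment added over baseline 1.0 in
#'   signal regions (default 5).
#' @param noise_sd Gaussian track noise sd (default 0.25).
#' @param track_bin Track bin size in bp (default 25).
#' @param n_decoy_genes Decoy protein-coding genes in the chromosome tail,
#'   each with exon/UTR/intron-overlapping conserved elements to exercise
#'   annotation-based filtering (default 4).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 500L,
                       species = names(.default_genome_sizes),
                       focal = "human", secondary = "mouse",
                       tree_newick = DEFAULT_TREE_NEWICK,
                       genome_sizes = .default_genome_sizes,
                       G_r = G_R_ANCESTOR,
                       class_fractions = c(contracted = 0.3, conserved = 0.4,
                                           expanded = 0.3),
                       sigma2 = 25,
                       shift_frac = 0.5,
                       d_range = c(1000, 20000),
                       min_distance = 200L,
                       gap_between = 20000L,
                       decoy_fraction = 0.2,
                       rbh_violation_fraction = 0,
                       tp_level = 0.15,
                       tp_class_shares = c(DNA = 0.1, LTR = 0.1,
                                           LINE = 0.4, SINE = 0.4),
                       tp_gain_frac = 0.5,
                       tp_free_fraction = 0.1,
                       tp_background = 0.46,
                       n_tissues = 3L,
                       archetype_fractions = c(inactive = 0.56,
                                               inter_poised = 0.34,
                                               cne_poised = 0.05,
                                               cne_active = 0.05),
                       signal_amplitude = 5,
                       noise_sd = 0.25,
                       track_bin = 25L,
                       n_decoy_genes = 4L) {
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 1L, sigma2 >= 0, all(genome_sizes > 0), G_r > 0,
            min_distance >= 200L, d_range[1] >= min_distance,
            focal %in% species, secondary %in% species)
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("class_fractions must sum to 1")
  if (abs(sum(archetype_fractions) - 1) > 1e-8) stop("archetype_fractions must sum to 1")
  if (abs(sum(tp_class_shares) - 1) > 1e-8) stop("tp_class_shares must sum to 1")
  if (!all(species %in% names(genome_sizes))) stop("genome_sizes must cover all species")
  class(cfg) <- "sim_config"
  cfg
}

## traversal of the tree as an undirected graph from a start node;
## returns matrix of edges (from, to, length) in visiting order
.tree_walk <- function(tree, start) {
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; l <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }
  seen <- logical(nn); seen[start] <- TRUE
  queue <- start
  out <- matrix(numeric(0), ncol = 3)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      w <- nb[j, 1]
      if (!seen[w]) {
        seen[w] <- TRUE
        out <- rbind(out, c(v, w, nb[j, 2]))
        queue <- c(queue, w)
      }
    }
  }
  out
}

#' Simulate tip inter-CNE distances with planted ancestral truth
#'
#' Each pair receives a true ancestral distance d_r* (log-uniform over
#' \code{d_range}) planted at the mammalian MRCA node; tip values arise by
#' Brownian motion with rate \code{sigma2} along the tree rerooted at that
#' node (BM is direction-free, so this equals root simulation conditioned on
#' the MRCA state). Contracted/expanded pairs get a deterministic
#' -/+ \code{shift_frac} * d_r* added on the focal terminal branch.
#' Distances are clipped at \code{min_distance} and rounded to integers.
#'
#' @param config A \code{sim_config}.
#' @return List: \code{tips} (n_pairs x species integer matrix),
#'   \code{truth} (data.frame \code{pair_id, d_r_true, class, archetype}),
#'   \code{tree} (the parsed phylo).
#' @export
simulate_distances <- function(config) {
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$tree_newick)
  stopifnot(all(config$species %in% tree$tip.label))
  n <- config$n_pairs
  d_r <- round(exp(stats::runif(n, log(config$d_range[1]), log(config$d_range[2]))))
  cls <- sample(names(config$class_fractions), n, replace = TRUE,
                prob = config$class_fractions)
  arch <- sample(names(config$archetype_fractions), n, replace = TRUE,
                 prob = config$archetype_fractions)
  mam <- intersect(DEFAULT_MAMMALS, tree$tip.label)
  node <- ape::getMRCA(tree, mam)
  walk <- .tree_walk(tree, node)
  vals <- matrix(NA_real_, max(tree$edge), n)
  vals[node, ] <- d_r
  for (k in seq_len(nrow(walk))) {
    from <- walk[k, 1]; to <- walk[k, 2]; len <- walk[k, 3]
    eps <- if (config$sigma2 > 0 && len > 0)
      stats::rnorm(n, 0, sqrt(config$sigma2 * len)) else 0
    vals[to, ] <- vals[from, ] + eps
  }
  tipidx <- match(config$species, tree$tip.label)
  tips <- t(vals[tipidx, , drop = FALSE])
  colnames(tips) <- config$species
  shift <- ifelse(cls == "contracted", -config$shift_frac,
                  ifelse(cls == "expanded", config$shift_frac, 0))
  tips[, config$focal] <- tips[, config$focal] + shift * d_r
  tips <- round(pmax(tips, config$min_distance))
  storage.mode(tips) <- "integer"
  truth <- data.frame(
    pair_id = sprintf("p%04dL|p%04dR", seq_len(n), seq_len(n)),
    d_r_true = as.integer(d_r), class = cls, archetype = arch,
    stringsAsFactors = FALSE)
  list(tips = tips, truth = truth, tree = tree)
}

#' Place elements on synthetic chromosomes and build alignment hit tables
#'
#' For every species, the two CNEs of each pair are placed on one synthetic
#' chromosome so that their midpoint distance equals the simulated tip value
#' exactly. CNE lengths are drawn once per pair (shared across species, as
#' orthologs have similar lengths) from [100, min(1000, d_min - 101)] so that
#' the inter-CNE gap is always >= 100 bp (elements never merge away).
#' Between consecutive pairs sits a spacer conserved element overlapping a
#' protein-coding exon, so between-pair adjacencies never yield CNE-CNE
#' pairs. A chromosome tail carries decoy genes with exon-, UTR- and
#' intron-overlapping conserved elements. Hit tables contain the true
#' ortholog as best hit, optional lower-scoring decoy hits, and optionally
#' reciprocal-best-violating top hits.
#'
#' @param config A \code{sim_config}.
#' @param dist Output of \code{\link{simulate_distances}}.
#' @return List: \code{elements} (per-species data.frames), \code{annotation}
#'   (focal/secondary gene annotation in \code{\link{read_gtf}} layout),
#'   \code{hits} (per reference: \code{forward}, \code{reverse} tables),
#'   \code{chrom_lengths} (per species), \code{pair_elements}
#'   (\code{pair_id, l_name, r_name}).
#' @export
emit_elements_and_pairs <- function(config, dist) {
  set.seed(config$seed + 1L)
  n <- config$n_pairs
  species <- config$species
  tips <- dist$tips
  dmin <- apply(tips, 1L, min)
  lmax <- pmin(1000L, pmax(100L, dmin - 101L))
  l_len <- as.integer(floor(stats::runif(n, 100, lmax + 1)))
  r_len <- as.integer(floor(stats::runif(n, 100, lmax + 1)))
  l_name <- sprintf("p%04dL", seq_len(n))
  r_name <- sprintf("p%04dR", seq_len(n))
  sp_name <- sprintf("sp%04d", seq_len(n))
  gap <- config$gap_between
  elements <- list(); chrom_lengths <- list()
  genes_by_ref <- list()
  for (sp in species) {
    d <- tips[, sp]
    cursor <- 10000L
    s1 <- e1 <- s2 <- e2 <- integer(n)
    spacer_s <- integer(n)
    for (i in seq_len(n)) {
      s1[i] <- cursor
      e1[i] <- s1[i] + l_len[i]
      m1 <- interval_midpoint(s1[i], e1[i])
      ## midpoint of [s2, s2+r_len) is s2 + r_len %/% 2; solve for s2
      s2[i] <- m1 + d[i] - (r_len[i] %/% 2L)
      e2[i] <- s2[i] + r_len[i]
      spacer_s[i] <- e2[i] + gap %/% 2L
      cursor <- e2[i] + gap
    }
    df <- data.frame(
      chrom = "chr1",
      start = as.vector(rbind(s1, s2, spacer_s)),
      end = as.vector(rbind(e1, e2, spacer_s + 150L)),
      name = as.vector(rbind(l_name, r_name, sp_name)),
      stringsAsFactors = FALSE)
    ## decoy-gene region in the tail (reference genomes only)
    if (sp %in% c(config$focal, config$secondary) && config$n_decoy_genes > 0L) {
      g0 <- cursor + 5000L
      gs <- g0 + (seq_len(config$n_decoy_genes) - 1L) * 8000L
      genes <- data.frame(chrom = "chr1", start = gs, end = gs + 3000L,
                          strand = rep(c("+", "-"), length.out = length(gs)),
                          gene_id = sprintf("dg%02d", seq_along(gs)),
                          stringsAsFactors = FALSE)
      exons <- transform(genes, start = start + 1000L, end = start + 1400L)
      utrs <- transform(genes, start = start + 900L, end = start + 1000L)
      spacer_genes <- data.frame(chrom = "chr1", start = spacer_s - 50L,
                                 end = spacer_s + 200L,
                                 strand = "+", gene_id = sprintf("sg%04d", seq_len(n)),
                                 stringsAsFactors = FALSE)
      genes_by_ref[[sp]] <- list(
        genes = rbind(genes, spacer_genes),
        exons = rbind(exons, spacer_genes),
        utrs = utrs)
      decoys <- data.frame(
        chrom = "chr1",
        start = as.vector(rbind(gs + 1100L, gs + 850L, gs + 2000L)),
        end = as.vector(rbind(gs + 1250L, gs + 990L, gs + 2150L)),
        name = as.vector(rbind(sprintf("dx%02d", seq_along(gs)),
                               sprintf("du%02d", seq_along(gs)),
                               sprintf("di%02d", seq_along(gs)))),
        stringsAsFactors = FALSE)
      df <- rbind(df, decoys)
      cursor <- max(genes$end) + 5000L
    }
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    elements[[sp]] <- df
    chrom_lengths[[sp]] <- c(chr1 = as.integer(3) * cursor)
  }
  ## gene annotations -> read_gtf layout (with TSS)
  annotation <- lapply(genes_by_ref, function(g) {
    tss <- data.frame(chrom = g$genes$chrom,
                      pos = ifelse(g$genes$strand == "-", g$genes$end - 1L,
                                   g$genes$start),
                      strand = g$genes$strand, gene_id = g$genes$gene_id,
                      stringsAsFactors = FALSE)
    c(g, list(tss = tss))
  })
  ## hit tables for each reference genome
  pair_el_names <- c(l_name, r_name)
  hits <- list()
  for (ref in c(config$focal, config$secondary)) {
    eref <- elements[[ref]]
    ref_pos <- eref[match(pair_el_names, eref$name), ]
    fwd <- list(); rev_ <- list()
    for (sp in setdiff(species, ref)) {
      esp <- elements[[sp]]
      tgt <- esp[match(pair_el_names, esp$name), ]
      ne <- length(pair_el_names)
      score <- stats::runif(ne, 85, 100)
      f <- data.frame(query_id = pair_el_names, species = sp,
                      chrom = tgt$chrom, start = tgt$start, end = tgt$end,
                      score = score, stringsAsFactors = FALSE)
      r <- data.frame(species = sp, q_chrom = tgt$chrom, q_start = tgt$start,
                      q_end = tgt$end, chrom = ref_pos$chrom,
                      start = ref_pos$start, end = ref_pos$end,
                      score = stats::runif(ne, 85, 100), stringsAsFactors = FALSE)
      L <- chrom_lengths[[sp]][["chr1"]]
      Lr <- chrom_lengths[[ref]][["chr1"]]
      is_decoy <- stats::runif(ne) < config$decoy_fraction
      if (any(is_decoy)) {
        k <- sum(is_decoy)
        ds <- as.integer(floor(stats::runif(k, L * 0.75, L - 500)))
        fd <- data.frame(query_id = pair_el_names[is_decoy], species = sp,
                         chrom = "chr1", start = ds, end = ds + 300L,
                         score = score[is_decoy] * stats::runif(k, 0.5, 0.95),
                         stringsAsFactors = FALSE)
        rs <- as.integer(floor(stats::runif(k, Lr * 0.75, Lr - 500)))
        rd <- data.frame(species = sp, q_chrom = "chr1", q_start = ds,
                         q_end = ds + 300L, chrom = "chr1", start = rs,
                         end = rs + 300L, score = stats::runif(k, 85, 100),
                         stringsAsFactors = FALSE)
        f <- rbind(f, fd); r <- rbind(r, rd)
      }
      is_viol <- stats::runif(ne) < config$rbh_violation_fraction
      if (any(is_viol)) {
        k <- sum(is_viol)
        vs <- as.integer(floor(stats::runif(k, L * 0.6, L * 0.7)))
        fv <- data.frame(query_id = pair_el_names[is_viol], species = sp,
                         chrom = "chr1", start = vs, end = vs + 300L,
                         score = 101, stringsAsFactors = FALSE)
        rs <- as.integer(floor(stats::runif(k, Lr * 0.6, Lr * 0.7)))
        rv <- data.frame(species = sp, q_chrom = "chr1", q_start = vs,
                         q_end = vs + 300L, chrom = "chr1", start = rs,
                         end = rs + 300L, score = stats::runif(k, 85, 100),
                         stringsAsFactors = FALSE)
        f <- rbind(f, fv); r <- rbind(r, rv)
      }
      fwd[[sp]] <- f; rev_[[sp]] <- r
    }
    hits[[ref]] <- list(forward = do.call(rbind, fwd),
                        reverse = do.call(rbind, rev_))
    rownames(hits[[ref]]$forward) <- rownames(hits[[ref]]$reverse) <- NULL
  }
  list(elements = elements, annotation = annotation, hits = hits,
       chrom_lengths = chrom_lengths,
       pair_elements = data.frame(pair_id = dist$truth$pair_id,
                                  l_name = l_name, r_name = r_name,
                                  stringsAsFactors = FALSE))
}

## lay non-overlapping intervals with given lengths inside [s, e) by
## stick-breaking the free space into random gaps
.scatter_intervals <- function(s, e, lens, classes) {
  total <- sum(lens)
  free <- (e - s) - total
  stopifnot(free >= 0)
  k <- length(lens)
  o <- sample.int(k)
  lens <- lens[o]; classes <- classes[o]
  g <- stats::runif(k + 1L)
  gaps <- floor(g / sum(g) * free)
  pos <- s + cumsum(c(gaps[1L], lens[-k] + gaps[-c(1L, k + 1L)]))
  data.frame(chrom = "chr1", start = as.integer(pos),
             end = as.integer(pos + lens), name = classes,
             stringsAsFactors = FALSE)
}

#' Emit per-species transposon annotations with ancestral truth
#'
#' Every pair gets a true ancestral transposon length per class
#' (\code{tp_level} x d_r*, split by \code{tp_class_shares}); a
#' \code{tp_free_fraction} of conserved pairs is transposon-free everywhere.
#' Tip contents mirror the pair class: conserved pairs carry the ancestral
#' content in all species; contracted pairs lose all focal-genome
#' transposons; expanded pairs gain extra focal SINE/LINE content matching
#' the planted distance expansion. Intervals are placed non-overlapping
#' inside each species' inter-CNE midpoint span. The focal and secondary
#' genomes additionally receive background transposons at coverage
#' \code{tp_background} outside the pair regions (one uniform-length
#' interval per 5-kb window).
#'
#' @param config A \code{sim_config}.
#' @param dist Output of \code{\link{simulate_distances}}.
#' @param layout Output of \code{\link{emit_elements_and_pairs}}.
#' @return List: \code{transposons} (per-species data.frames with class in
#'   \code{name}), \code{truth} (\code{pair_id, class, T_r_true}),
#'   \code{tips} (per-class matrices pairs x species).
#' @export
emit_transposons <- function(config, dist, layout) {
  set.seed(config$seed + 2L)
  n <- config$n_pairs
  classes <- names(config$tp_class_shares)
  d_r <- dist$truth$d_r_true
  Tr <- outer(d_r, config$tp_class_shares * config$tp_level)
  Tr <- round(Tr)
  conserved <- which(dist$truth$class == "conserved")
  n_free <- round(config$tp_free_fraction * length(conserved))
  free_idx <- if (n_free > 0) sample(conserved, n_free) else integer()
  Tr[free_idx, ] <- 0
  dist$truth$tp_free <- seq_len(n) %in% free_idx
  gain <- round(outer(d_r * config$tp_gain_frac, c(SINE = 0.7, LINE = 0.3)))
  gain[dist$truth$class != "expanded" | dist$truth$tp_free, ] <- 0
  tips <- lapply(classes, function(cl) {
    m <- matrix(rep(Tr[, cl], length(config$species)), nrow = n,
                dimnames = list(dist$truth$pair_id, config$species))
    if (cl %in% colnames(gain)) m[, config$focal] <- m[, config$focal] + gain[, cl]
    m[dist$truth$class == "contracted", config$focal] <- 0
    m
  })
  names(tips) <- classes
  ## element midpoints per species for interval placement
  transposons <- list()
  for (sp in config$species) {
    esp <- layout$elements[[sp]]
    lpos <- esp[match(sprintf("p%04dL", seq_len(n)), esp$name), ]
    rpos <- esp[match(sprintf("p%04dR", seq_len(n)), esp$name), ]
    m1 <- interval_midpoint(lpos$start, lpos$end)
    m2 <- interval_midpoint(rpos$start, rpos$end)
    rows <- list()
    for (i in seq_len(n)) {
      lens_i <- vapply(classes, function(cl) tips[[cl]][i, sp], numeric(1))
      lens_i <- lens_i[lens_i > 0]
      if (!length(lens_i)) next
      pieces <- unlist(lapply(seq_along(lens_i), function(j) {
        L <- lens_i[j]
        k <- max(1L, round(L / 350))
        sizes <- rep(L %/% k, k); sizes[seq_len(L %% k)] <- sizes[seq_len(L %% k)] + 1L
        stats::setNames(sizes, rep(names(lens_i)[j], k))
      }))
      rows[[i]] <- .scatter_intervals(m1[i], m2[i], as.integer(pieces),
                                      names(pieces))
    }
    tp <- do.call(rbind, rows)
    if (is.null(tp)) {
      tp <- data.frame(chrom = character(), start = integer(), end = integer(),
                       name = character(), stringsAsFactors = FALSE)
    }
    if (sp %in% c(config$focal, config$secondary)) {
      L <- layout$chrom_lengths[[sp]][["chr1"]]
      pitch <- 5000L
      w0 <- seq.int(0L, L - pitch, by = pitch)
      ## skip windows near planted pairs so their content stays exact
      mask <- rep(TRUE, length(w0))
      for (i in seq_len(n)) {
        lo <- lpos$start[i] - 1000L; hi <- rpos$end[i] + 1000L
        mask[w0 + pitch > lo & w0 < hi] <- FALSE
      }
      w0 <- w0[mask]
      blen <- as.integer(floor(stats::runif(length(w0), 0,
                                            2 * config$tp_background * pitch)))
      keep <- blen > 0L
      w0 <- w0[keep]; blen <- blen[keep]
      off <- as.integer(floor(stats::runif(length(w0)) * (pitch - blen + 1L)))
      bg <- data.frame(chrom = "chr1", start = w0 + off, end = w0 + off + blen,
                       name = sample(classes, length(w0), replace = TRUE,
                                     prob = c(0.10, 0.15, 0.45, 0.30)),
                       stringsAsFactors = FALSE)
      tp <- rbind(tp, bg)
    }
    tp <- tp[order(tp$start), , drop = FALSE]
    rownames(tp) <- NULL
    transposons[[sp]] <- tp
  }
  truth <- data.frame(pair_id = rep(dist$truth$pair_id, length(classes)),
                      class = rep(classes, each = n),
                      T_r_true = as.vector(Tr[, classes]),
                      stringsAsFactors = FALSE)
  list(transposons = transposons, truth = truth, tips = tips,
       tp_free = dist$truth$tp_free)
}

#' Emit histone-modification signal tracks for the focal genome
#'
#' One bedGraph-style binned track per (tissue, mark), covering each pair's
#' span plus a margin at \code{track_bin} resolution, baseline
#' fold-enrichment 1.0 plus archetype-dependent signal plus Gaussian noise
#' (truncated at 0). Archetypes: \code{cne_active} adds
#' H3K27ac/H3K4me1/H3K4me3 amplitude over the whole CNE-to-CNE span;
#' \code{cne_poised} adds H3K27me3/H3K4me1 over the two 300-bp CNE windows;
#' \code{inter_poised} adds H3K4me1/H3K27me3/H3K9me3 over one 200-bp hotspot
#' inside the inter-CNE sequence; \code{inactive} stays at baseline.
#'
#' @param config A \code{sim_config}.
#' @param dist Output of \code{\link{simulate_distances}}.
#' @param layout Output of \code{\link{emit_elements_and_pairs}}.
#' @return List of \code{signal_track} objects (length n_tissues x 5),
#'   plus attribute \code{"hotspots"} (per-pair hotspot starts, NA if none).
#' @export
emit_tracks <- function(config, dist, layout) {
  set.seed(config$seed + 3L)
  n <- config$n_pairs
  bin <- config$track_bin
  esp <- layout$elements[[config$focal]]
  lpos <- esp[match(sprintf("p%04dL", seq_len(n)), esp$name), ]
  rpos <- esp[match(sprintf("p%04dR", seq_len(n)), esp$name), ]
  m1 <- interval_midpoint(lpos$start, lpos$end)
  m2 <- interval_midpoint(rpos$start, rpos$end)
  snap_lo <- function(x) (x %/% bin) * bin
  snap_hi <- function(x) ((x + bin - 1L) %/% bin) * bin
  ## hotspot start per pair (bin-aligned, inside the inter-CNE sequence)
  hot <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    lo <- snap_hi(lpos$end[i]); hi <- rpos$start[i] - 200L
    if (lo > hi) next
    st <- seq.int(lo, hi, by = bin)
    hot[i] <- if (length(st) == 1L) st else sample(st, 1L)
  }
  ## concatenated bins over all pair spans
  b_start <- integer(0); b_pair <- integer(0)
  for (i in seq_len(n)) {
    bs <- seq.int(snap_lo(lpos$start[i] - 500L), rpos$end[i] + 500L, by = bin)
    b_start <- c(b_start, bs)
    b_pair <- c(b_pair, rep.int(i, length(bs)))
  }
  b_end <- b_start + bin
  ovl <- function(lo, hi) b_start < hi[b_pair] & b_end > lo[b_pair]
  m_span <- ovl(snap_lo(m1 - 150L), snap_hi(m2 + 150L))
  m_cne <- ovl(snap_lo(m1 - 150L), snap_hi(m1 + 150L)) |
    ovl(snap_lo(m2 - 150L), snap_hi(m2 + 150L))
  hot_lo <- ifelse(is.na(hot), 0L, hot)
  hot_hi <- ifelse(is.na(hot), 0L, hot + 200L)
  m_hot <- ovl(hot_lo, hot_hi) & !is.na(hot[b_pair])
  arch <- dist$truth$archetype[b_pair]
  amp <- config$signal_amplitude
  sig_for <- function(mark) {
    active <- arch == "cne_active" & mark %in% c("H3K27ac", "H3K4me1", "H3K4me3") & m_span
    poised <- arch == "cne_poised" & mark %in% c("H3K27me3", "H3K4me1") & m_cne
    inter <- arch == "inter_poised" & mark %in% c("H3K4me1", "H3K27me3", "H3K9me3") & m_hot
    amp * (active | poised | inter)
  }
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))
  tracks <- list()
  for (ts in tissues) {
    for (mk in HISTONE_MARKS) {
      noise <- if (config$noise_sd > 0)
        stats::rnorm(length(b_start), 0, config$noise_sd) else 0
      val <- pmax(0, 1 + sig_for(mk) + noise)
      tracks[[paste(ts, mk, sep = "|")]] <- signal_track(
        ts, mk, data.frame(chrom = "chr1", start = b_start, end = b_end,
                           value = val, stringsAsFactors = FALSE))
    }
  }
  attr(tracks, "hotspots") <- hot
  tracks
}

#' Generate a complete synthetic data set with planted ground truth
#'
#' Runs \code{\link{simulate_distances}},
#' \code{\link{emit_elements_and_pairs}}, \code{\link{emit_transposons}} and
#' \code{\link{emit_tracks}} under the config's master seed. Identical
#' config (including seed) gives identical output.
#'
#' @param config A \code{sim_config}.
#' @return List of class \code{cne_sim} bundling all generator outputs.
#' @export
simulate_cne_data <- function(config = sim_config()) {
  dist <- simulate_distances(config)
  layout <- emit_elements_and_pairs(config, dist)
  tp <- emit_transposons(config, dist, layout)
  tracks <- emit_tracks(config, dist, layout)
  truth <- dist$truth
  truth$tp_free <- tp$tp_free
  structure(list(config = config, tree = dist$tree, truth = truth,
                 tips = dist$tips, elements = layout$elements,
                 annotation = layout$annotation, hits = layout$hits,
                 chrom_lengths = layout$chrom_lengths,
                 pair_elements = layout$pair_elements,
                 transposons = tp$transposons, transposon_truth = tp$truth,
                 transposon_tips = tp$tips, tracks = tracks),
            class = "cne_sim")
}

#' Write a synthetic data set to a directory tree
#'
#' Serializes all generator outputs to plain-text files (BED, GTF, Newick,
#' bedGraph, TSV, JSON). Reruns with the same config are byte-identical.
#'
#' @param sim A \code{cne_sim}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(file.path(dir, "elements"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "transposons"), showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  for (sp in names(sim$elements)) {
    write_bed(sim$elements[[sp]], file.path(dir, "elements", paste0(sp, ".bed")))
  }
  for (sp in names(sim$transposons)) {
    write_bed(sim$transposons[[sp]], file.path(dir, "transposons", paste0(sp, ".bed")))
  }
  for (key in names(sim$tracks)) {
    tr <- sim$tracks[[key]]
    write_track(tr, file.path(dir, "tracks",
                              paste0(tr$tissue, "_", tr$mark, ".bedGraph")))
  }
  for (ref in names(sim$hits)) {
    utils::write.table(sim$hits[[ref]]$forward,
                       file.path(dir, paste0("hits_", ref, "_forward.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$hits[[ref]]$reverse,
                       file.path(dir, paste0("hits_", ref, "_reverse.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ref in names(sim$annotation)) {
    write_gtf(sim$annotation[[ref]], file.path(dir, paste0("genes_", ref, ".gtf")))
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(list(truth = sim$truth,
                            transposon_truth = sim$transposon_truth,
                            chrom_lengths = sim$chrom_lengths),
                       file.path(dir, "truth.json"), digits = NA)
  cfg <- sim$config; class(cfg) <- NULL
  cfg$tree_newick <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
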