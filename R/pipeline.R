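#' Run the full CNE-CNE pair analysis on a synthetic (or loaded) data set
#'
#' Chains every stage for one reference genome: element merging/filtering,
#' annotation-based classification, pair building, RBH orthology,
#' conservation classification, ancestral distance and transposon
#' reconstruction, nRDD/nRTD metrics with decile groups, TSS distances,
#' transposon gain/loss and transposon-free calls, region summaries, the
#' SOM feature matrix, SOM training/assignment/unit clustering, and
#' group-in-unit enrichment. Stage outputs are plain data.frames so that
#' every intermediate is inspectable; optional \code{outdir} writes them as
#' TSV with a JSON run manifest.
#'
#' @param sim A \code{cne_sim} from \code{\link{simulate_cne_data}} (or a
#'   list with the same components loaded from files).
#' @param reference Reference genome (default the sim's focal species).
#' @param n_rep Replicates for the transposon depletion randomization
#'   (default 200; set 0 to skip the stage).
#' @param som_seed Seed for SOM training (default derived from the sim seed).
#' @param outdir Optional output directory for TSV results + manifest.
#' @return List of class \code{cne_result} with elements \code{elements,
#'   pairs, orthologs, conservation, ancestors, metrics, transposons,
#'   depletion, summaries, features, som, assignments, unit_clusters,
#'   enrichment, truth}.
#' @export
run_cne_pipeline <- function(sim, reference = sim$config$focal,
                             n_rep = 200L, som_seed = sim$config$seed + 11L,
                             outdir = NULL) {
  cfg <- sim$config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ## --- elements & pairs -------------------------------------------------
  elements <- stage("elements", {
    raw <- sim$elements[[reference]]
    if (is.null(raw)) stop("no element set for reference ", reference)
    merged <- merge_and_filter(raw)
    classify_elements(merged, sim$annotation[[reference]])
  })
  pairs <- stage("pairs", build_pairs(elements))
  ## --- orthology & conservation ----------------------------------------
  orthologs <- stage("orthologs", {
    h <- sim$hits[[reference]]
    if (is.null(h)) stop("no hit tables for reference ", reference)
    rbh_orthologs(h$forward, h$reverse, elements)
  })
  other <- setdiff(cfg$species, reference)
  cons <- stage("conservation",
                classify_conservation(pairs, orthologs, other))
  pairs <- cons$pairs
  ## per-species distance matrix including the reference's own distance
  dist_mat <- cbind(cons$dist, matrix(pairs$d_h, ncol = 1,
                                      dimnames = list(NULL, reference)))
  ## --- ancestral reconstruction -----------------------------------------
  ancestors <- stage("ancestral",
                     reconstruct_pair_ancestors(dist_mat, sim$tree,
                                                DEFAULT_MAMMALS))
  ## --- metrics -----------------------------------------------------------
  metrics <- stage("metrics", {
    G_h <- cfg$genome_sizes[[reference]]
    m <- data.frame(pair_id = pairs$pair_id, d_h = pairs$d_h,
                    category = pairs$category,
                    d_r = ancestors$d_r, flag = ancestors$flag,
                    stringsAsFactors = FALSE)
    ok <- !is.na(m$d_r) & m$d_r > 0
    m$nrdd <- NA_real_
    m$nrdd[ok] <- nrdd(m$d_h[ok], m$d_r[ok], G_h, cfg$G_r)
    m$nrdd_group <- NA_integer_
    grp_ok <- which(!is.na(m$nrdd))
    if (length(grp_ok) >= 10L) {
      m$nrdd_group[grp_ok] <- decile_groups(m$nrdd[grp_ok],
                                            m$pair_id[grp_ok])
    }
    ann <- sim$annotation[[reference]]
    if (!is.null(ann)) m$tss_distance <- tss_distance(pairs, ann$tss)
    m
  })
  pairs$nrdd_group <- metrics$nrdd_group
  ## --- transposons -------------------------------------------------------
  transposons <- stage("transposons", {
    classes <- TRANSPOSON_CLASSES
    ## per-species transposon lengths within each pair's midpoint span
    okey <- paste(orthologs$element, orthologs$species, sep = "\r")
    t_arr <- lapply(classes, function(cl) {
      m <- matrix(NA_real_, nrow(pairs), length(other),
                  dimnames = list(pairs$pair_id, other))
      m
    })
    names(t_arr) <- classes
    for (sp in other) {
      li <- match(paste(pairs$l_name, sp, sep = "\r"), okey)
      ri <- match(paste(pairs$r_name, sp, sep = "\r"), okey)
      have <- which(!is.na(li) & !is.na(ri) & !is.na(cons$dist[, sp]))
      if (!length(have)) next
      reg <- data.frame(
        chrom = orthologs$chrom[li[have]],
        start = pmin(interval_midpoint(orthologs$start[li[have]],
                                       orthologs$end[li[have]]),
                     interval_midpoint(orthologs$start[ri[have]],
                                       orthologs$end[ri[have]])),
        end = pmax(interval_midpoint(orthologs$start[li[have]],
                                     orthologs$end[li[have]]),
                   interval_midpoint(orthologs$start[ri[have]],
                                     orthologs$end[ri[have]])),
        stringsAsFactors = FALSE)
      dens <- transposon_density(reg, sim$transposons[[sp]])
      for (cl in classes) {
        t_arr[[cl]][have, sp] <- dens[[paste0("covered_", cl)]]
      }
    }
    ## focal-genome lengths over the midpoint span
    lm <- interval_midpoint(pairs$l_start, pairs$l_end)
    rm_ <- interval_midpoint(pairs$r_start, pairs$r_end)
    reg_h <- data.frame(chrom = pairs$chrom, start = lm, end = rm_,
                        stringsAsFactors = FALSE)
    dens_h <- transposon_density(reg_h, sim$transposons[[reference]])
    anc_t <- reconstruct_transposon_ancestors(t_arr, sim$tree, DEFAULT_MAMMALS)
    G_h <- cfg$genome_sizes[[reference]]
    res <- do.call(rbind, lapply(classes, function(cl) {
      a <- anc_t[anc_t$class == cl, ]
      T_h <- dens_h[[paste0("covered_", cl)]]
      data.frame(pair_id = pairs$pair_id, class = cl, T_h = T_h,
                 T_r = a$T_r, flag = a$flag,
                 nrtd = ifelse(is.na(a$T_r), NA_real_,
                               nrtd(T_h, a$T_r, G_h, cfg$G_r)),
                 status = ifelse(is.na(a$T_r), NA_character_,
                                 gain_loss(T_h, a$T_r)),
                 stringsAsFactors = FALSE)
    }))
    wide_h <- matrix(res$T_h, nrow(pairs), length(classes))
    wide_r <- matrix(res$T_r, nrow(pairs), length(classes))
    free <- vapply(seq_len(nrow(pairs)), function(i) {
      if (anyNA(wide_r[i, ])) NA else transposon_free(wide_h[i, ], wide_r[i, ])
    }, logical(1))
    list(table = res, density_h = dens_h, free = free)
  })
  depletion <- if (n_rep > 0L) stage("depletion", {
    reg <- data.frame(chrom = pairs$chrom,
                      start = interval_midpoint(pairs$l_start, pairs$l_end),
                      end = interval_midpoint(pairs$r_start, pairs$r_end),
                      stringsAsFactors = FALSE)
    empirical_depletion_test(reg, sim$chrom_lengths[[reference]],
                             sim$transposons[[reference]], n_rep = n_rep,
                             seed = cfg$seed + 7L)
  }) else NULL
  ## --- epigenetics (focal genome only: tracks exist there) ---------------
  epi <- NULL
  if (identical(reference, cfg$focal) && length(sim$tracks)) {
    epi <- stage("epigenetics", {
      summ <- region_summaries(pairs, sim$tracks, step = cfg$track_bin)
      srt <- sort_cne_h_l(summ)
      feats <- build_feature_matrix(srt$summaries)
      list(summaries = srt$summaries, sides = srt$sides, features = feats)
    })
  }
  som <- assignments <- unit_clusters <- enrichment <- NULL
  if (!is.null(epi) && nrow(epi$features) >= 12L) {
    som <- stage("som", train_som(epi$features, seed = som_seed))
    assignments <- stage("som", som_assign(som, epi$features))
    us <- stage("som", unit_summaries(epi$features, assignments))
    unit_clusters <- stage("som", cluster_units(us, k = 4L))
    grp <- metrics$nrdd_group[match(rownames(epi$features), metrics$pair_id)]
    keep <- !is.na(grp)
    if (sum(keep) > 0L && length(unique(grp[keep])) > 1L) {
      enrichment <- stage("enrichment",
                          group_unit_enrichment(assignments[keep], grp[keep],
                                                units = seq_len(12L)))
    }
  }
  res <- structure(list(reference = reference, elements = elements,
                        pairs = pairs, orthologs = orthologs,
                        conservation = cons, dist_mat = dist_mat,
                        ancestors = ancestors, metrics = metrics,
                        transposons = transposons, depletion = depletion,
                        summaries = if (is.null(epi)) NULL else epi$summaries,
                        features = if (is.null(epi)) NULL else epi$features,
                        som = som, assignments = assignments,
                        unit_clusters = unit_clusters,
                        enrichment = enrichment,
                        truth = sim$truth), class = "cne_result")
  if (!is.null(outdir)) write_cne_result(res, sim, outdir)
  res
}

#' Write pipeline results and a run manifest
#'
#' Emits the main result tables as TSV plus \code{manifest.json} recording
#' the configuration, seeds and package version; reruns with the same
#' config and seed produce byte-identical output.
#'
#' @param result A \code{cne_result}.
#' @param sim The \code{cne_sim} it was computed from.
#' @param outdir Output directory.
#' @export
write_cne_result <- function(result, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(result$pairs, "pairs.tsv")
  wt(result$orthologs, "orthologs.tsv")
  wt(result$ancestors, "ancestors.tsv")
  wt(result$metrics, "metrics.tsv")
  wt(result$transposons$table, "transposons.tsv")
  wt(result$depletion, "depletion.tsv")
  wt(result$summaries, "summaries.tsv")
  wt(result$enrichment, "enrichment.tsv")
  if (!is.null(result$assignments)) {
    wt(data.frame(pair_id = names(result$assignments),
                  unit = as.integer(result$assignments),
                  cluster = result$unit_clusters[result$assignments]),
       "assignments.tsv")
  }
  cfg <- sim$config; class(cfg) <- NULL
  manifest <- list(
    package = "cnepairs",
    version = as.character(utils::packageVersion("cnepairs")),
    reference = result$reference,
    config = cfg[!vapply(cfg, is.function, logical(1))],
    config_hash = .config_hash(cfg))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
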