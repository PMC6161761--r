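#' Merge and filter conserved elements
#'
#' Adjacent conserved elements separated by less than \code{merge_gap} bp are
#' merged (transitively, left to right per chromosome); merged elements
#' shorter than \code{min_len} bp are then removed. Unsorted input is sorted
#' internally with a message. The operation is idempotent.
#'
#' @param elements data.frame \code{chrom,start,end} with an optional
#'   \code{name} column. Elements that survive unmerged keep their input
#'   name; genuinely merged elements are new entities and get fresh ids
#'   \code{ce1..}.
#' @param merge_gap Gap threshold in bp (default 100; gaps < 100 merge).
#' @param min_len Minimum element length after merging (default 100).
#' @return data.frame \code{chrom,start,end,name}, sorted.
#' @export
merge_and_filter <- function(elements, merge_gap = 100L, min_len = 100L) {
  .validate_intervals(elements, "merge_and_filter")
  if (nrow(elements) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  o <- order(elements$chrom, elements$start, elements$end)
  if (is.unsorted(o)) message("merge_and_filter: input not sorted; sorting")
  gr <- .as_gr(elements[o, , drop = FALSE])
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap)
  df <- .gr_to_df(merged)
  df <- df[df$end - df$start >= min_len, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$name <- if (nrow(df)) paste0("ce", seq_len(nrow(df))) else character()
  ## an element untouched by merging keeps its input name (if it had one)
  if ("name" %in% names(elements) && nrow(df)) {
    m <- match(paste(df$chrom, df$start, df$end),
               paste(elements$chrom, elements$start, elements$end))
    keep <- !is.na(m) & !is.na(elements$name[m])
    df$name[keep] <- elements$name[m[keep]]
  }
  df
}

#' Classify conserved elements by genomic annotation
#'
#' Assigns each element a single category by descending precedence
#' exon > UTR > intron > intergenic, based on >= 1 bp overlap with
#' protein-coding gene features ("intron" means overlapping a gene span
#' without overlapping any exon/UTR of it). Elements whose category is not
#' \code{exon} are conserved noncoding elements (CNEs).
#'
#' @param elements data.frame \code{chrom,start,end,...}.
#' @param annotation As returned by \code{\link{read_gtf}}.
#' @return \code{elements} with a \code{category} factor column.
#' @export
classify_elements <- function(elements, annotation) {
  n <- nrow(elements)
  cat <- rep("intergenic", n)
  if (n) {
    gr <- .as_gr(elements)
    overlaps_any <- function(df) {
      if (is.null(df) || nrow(df) == 0L) return(logical(n))
      IRanges::overlapsAny(gr, .as_gr(df))
    }
    cat[overlaps_any(annotation$genes)] <- "intron"
    cat[overlaps_any(annotation$utrs)] <- "UTR"
    cat[overlaps_any(annotation$exons)] <- "exon"
  }
  elements$category <- factor(cat, levels = c("exon", "UTR", "intron", "intergenic"))
  elements
}

#' Build pairs of adjacent CNEs
#'
#' Adjacency is computed over all conserved elements (coding included): two
#' elements are adjacent when no conserved element lies between them on the
#' chromosome. A pair is emitted only when both members are noncoding
#' (category != exon) and neither exceeds \code{max_len} bp (large elements
#' likely collapse several conserved elements and are excluded). The
#' inter-CNE interval is \code{[left.end, right.start)}; the pair distance
#' d_h is midpoint-to-midpoint.
#'
#' @param elements Classified, merged elements (sorted per chromosome) with
#'   columns \code{chrom,start,end,name,category}.
#' @param max_len Maximum member length (default 1000).
#' @return data.frame, one row per CNE-CNE pair: \code{pair_id, chrom,
#'   l_name, l_start, l_end, r_name, r_start, r_end, inter_start, inter_end,
#'   d_h}.
#' @export
build_pairs <- function(elements, max_len = 1000L) {
  o <- order(elements$chrom, elements$start)
  e <- elements[o, , drop = FALSE]
  res <- list()
  for (chr in unique(e$chrom)) {
    s <- e[e$chrom == chr, , drop = FALSE]
    if (nrow(s) < 2L) next
    i <- seq_len(nrow(s) - 1L)
    left <- s[i, ]; right <- s[i + 1L, ]
    keep <- left$category != "exon" & right$category != "exon" &
      (left$end - left$start) <= max_len & (right$end - right$start) <= max_len
    if (!any(keep)) next
    left <- left[keep, ]; right <- right[keep, ]
    res[[chr]] <- data.frame(
      chrom = chr,
      l_name = left$name, l_start = left$start, l_end = left$end,
      r_name = right$name, r_start = right$start, r_end = right$end,
      inter_start = left$end, inter_end = right$start,
      d_h = interval_midpoint(right$start, right$end) -
        interval_midpoint(left$start, left$end),
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) {
    return(data.frame(pair_id = character(), chrom = character(),
                      l_name = character(), l_start = integer(), l_end = integer(),
                      r_name = character(), r_start = integer(), r_end = integer(),
                      inter_start = integer(), inter_end = integer(),
                      d_h = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  stopifnot(all(out$d_h > 0))
  cbind(pair_id = paste(out$l_name, out$r_name, sep = "|"), out,
        stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit orthologs
#'
#' For each (query element, target species): take the highest-scoring forward
#' hit; it is accepted as the ortholog iff the highest-scoring reverse hit of
#' that target interval overlaps (>= 1 bp) the original query element. Score
#' ties are broken deterministically (highest score, then smallest target
#' start, then lexicographic chromosome).
#'
#' @param hits_forward data.frame \code{query_id, species, chrom, start, end,
#'   score}: alignments of reference elements into each target genome.
#' @param hits_reverse data.frame \code{species, q_chrom, q_start, q_end,
#'   chrom, start, end, score}: alignments of target-genome sequences
#'   (identified by their target coordinates) back into the reference genome.
#' @param query_elements data.frame \code{chrom,start,end,name} of the
#'   reference elements (gives the intervals the reverse hits must recover).
#' @return Ortholog map data.frame \code{element, species, chrom, start, end}
#'   with at most one row per (element, species).
#' @export
rbh_orthologs <- function(hits_forward, hits_reverse, query_elements) {
  if (nrow(hits_forward) == 0L) {
    return(data.frame(element = character(), species = character(),
                      chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  qe <- query_elements
  ## best forward hit per (query, species)
  fo <- hits_forward[order(hits_forward$query_id, hits_forward$species,
                           -hits_forward$score, hits_forward$start,
                           hits_forward$chrom), , drop = FALSE]
  first <- !duplicated(fo[, c("query_id", "species")])
  best_f <- fo[first, , drop = FALSE]
  ## best reverse hit per target sequence (keyed by species + target coords)
  rkey <- function(sp, chr, s, e) paste(sp, chr, s, e, sep = ":")
  ro <- hits_reverse[order(rkey(hits_reverse$species, hits_reverse$q_chrom,
                                hits_reverse$q_start, hits_reverse$q_end),
                           -hits_reverse$score, hits_reverse$start,
                           hits_reverse$chrom), , drop = FALSE]
  rfirst <- !duplicated(rkey(ro$species, ro$q_chrom, ro$q_start, ro$q_end))
  best_r <- ro[rfirst, , drop = FALSE]
  idx <- match(rkey(best_f$species, best_f$chrom, best_f$start, best_f$end),
               rkey(best_r$species, best_r$q_chrom, best_r$q_start, best_r$q_end))
  qi <- match(best_f$query_id, qe$name)
  if (anyNA(qi)) stop("forward hit query not in query_elements: ",
                      best_f$query_id[which(is.na(qi))[1]])
  ok <- !is.na(idx)
  ## reverse best must overlap the original query element by >= 1 bp
  ok[ok] <- {
    r <- best_r[idx[ok], , drop = FALSE]
    q <- qe[qi[ok], , drop = FALSE]
    r$chrom == q$chrom & r$start < q$end & r$end > q$start
  }
  out <- best_f[ok, c("query_id", "species", "chrom", "start", "end")]
  names(out)[1] <- "element"
  rownames(out) <- NULL
  out
}

#' Per-species ortholog distances and conservation category for pairs
#'
#' A pair is "conserved in species S" iff both CNEs have orthologs in S on
#' the same chromosome with midpoint distance <= \code{max_dist} bp. Any
#' species in which the two orthologs are more than \code{max_dist} bp apart
#' (or on different chromosomes — a rearrangement) discards the pair
#' entirely, to avoid spurious inferences from incorrect orthology or large
#' rearrangements. Categories: "mammalian" = conserved in the key outgroup
#' mammal (platypus); "deeply" = conserved in >= \code{deep_min} nonmammalian
#' vertebrates; "both"; or "neither".
#'
#' @param pairs Output of \code{\link{build_pairs}}.
#' @param orthologs Ortholog map from \code{\link{rbh_orthologs}}.
#' @param species All species to evaluate (columns of the distance matrix).
#' @param key_species Mammalian conservation anchor (default "platypus").
#' @param deep_species Nonmammalian vertebrates for deep conservation.
#' @param deep_min Minimum count of deep species (default 2).
#' @param max_dist Ortholog distance cap in bp (default 250000).
#' @return List: \code{pairs} (kept pairs with \code{category} column),
#'   \code{dist} (pairs x species midpoint-distance matrix, NA = absent),
#'   \code{discarded} (data.frame \code{pair_id, reason}).
#' @export
classify_conservation <- function(pairs, orthologs, species,
                                  key_species = "platypus",
                                  deep_species = c("lizard", "turtle", "chicken",
                                                   "zebra_finch", "frog", "fugu",
                                                   "zebrafish"),
                                  deep_min = 2L, max_dist = 250000L) {
  n <- nrow(pairs)
  dist <- matrix(NA_real_, n, length(species),
                 dimnames = list(pairs$pair_id, species))
  discard <- rep(FALSE, n)
  okey <- paste(orthologs$element, orthologs$species, sep = "\r")
  omid <- interval_midpoint(orthologs$start, orthologs$end)
  for (j in seq_along(species)) {
    sp <- species[j]
    li <- match(paste(pairs$l_name, sp, sep = "\r"), okey)
    ri <- match(paste(pairs$r_name, sp, sep = "\r"), okey)
    have <- !is.na(li) & !is.na(ri)
    if (!any(have)) next
    same_chr <- orthologs$chrom[li[have]] == orthologs$chrom[ri[have]]
    d <- abs(omid[ri[have]] - omid[li[have]])
    too_far <- !same_chr | d > max_dist
    discard[which(have)[too_far]] <- TRUE
    dist[which(have)[same_chr], j] <- d[same_chr]
  }
  conserved_in <- !is.na(dist) & dist <= max_dist
  n_deep <- rowSums(conserved_in[, intersect(deep_species, species), drop = FALSE])
  is_mam <- if (key_species %in% species) conserved_in[, key_species] else rep(FALSE, n)
  is_deep <- n_deep >= deep_min
  category <- ifelse(is_mam & is_deep, "both",
                     ifelse(is_mam, "mammalian",
                            ifelse(is_deep, "deeply", "neither")))
  kept <- pairs[!discard, , drop = FALSE]
  kept$category <- category[!discard]
  rownames(kept) <- NULL
  list(pairs = kept,
       dist = dist[!discard, , drop = FALSE],
       discarded = data.frame(pair_id = pairs$pair_id[discard],
                              reason = rep("ortholog_distance_gt_cap", sum(discard)),
                              stringsAsFactors = FALSE))
}

## nRDD group (1..10) -> coarse range label used in the 9-category scheme
.group_range <- function(g) {
  ifelse(g <= 3L, "1-3", ifelse(g <= 7L, "4-7", "8-10"))
}

#' Adjacent-orthologous (AO) pairs between two genomes
#'
#' A pair in genome A is an AO pair iff (1) both of its CNEs have orthologs
#' in genome B, (2) those orthologs are adjacent in B (no conserved element
#' of B's element set in between), and (3) the orthologs were themselves
#' identified as a CNE-CNE pair in B. AO pairs are assigned one of nine
#' categories from the coarse nRDD-group ranges (1-3 contracted, 4-7
#' conserved, 8-10 expanded) in each genome, e.g. \code{"H1-3; M8-10"}.
#'
#' @param pairs_a Pairs of genome A with an \code{nrdd_group} column.
#' @param pairs_b Pairs of genome B with an \code{nrdd_group} column.
#' @param orthologs_a Ortholog map of genome A's elements; rows with
#'   \code{species == species_b} give the B-coordinates of A's CNEs.
#' @param elements_b Genome B's full conserved-element set
#'   (\code{chrom,start,end}).
#' @param species_b Name of genome B in the ortholog map (default "mouse").
#' @param prefix_a,prefix_b Category-label prefixes (default "H", "M").
#' @return data.frame of AO pairs: \code{pair_id_a, pair_id_b, group_a,
#'   group_b, category}.
#' @export
find_ao_pairs <- function(pairs_a, pairs_b, orthologs_a, elements_b,
                          species_b = "mouse", prefix_a = "H", prefix_b = "M") {
  ob <- orthologs_a[orthologs_a$species == species_b, , drop = FALSE]
  okey <- ob$element
  eb_gr <- .as_gr(elements_b)
  pb_l <- .as_gr(data.frame(chrom = pairs_b$chrom, start = pairs_b$l_start,
                            end = pairs_b$l_end))
  pb_r <- .as_gr(data.frame(chrom = pairs_b$chrom, start = pairs_b$r_start,
                            end = pairs_b$r_end))
  out <- list()
  for (i in seq_len(nrow(pairs_a))) {
    li <- match(pairs_a$l_name[i], okey)
    ri <- match(pairs_a$r_name[i], okey)
    if (is.na(li) || is.na(ri)) next                       # (1)
    if (ob$chrom[li] != ob$chrom[ri]) next
    lo <- ob[li, ]; ro <- ob[ri, ]
    if (lo$start > ro$start) { tmp <- lo; lo <- ro; ro <- tmp }
    gap_s <- min(lo$end, ro$start); gap_e <- max(lo$end, ro$start)
    if (gap_e > gap_s) {                                   # (2) nothing in between
      gap <- GenomicRanges::GRanges(lo$chrom,
                                    IRanges::IRanges(gap_s + 1L, gap_e))
      mid_hits <- GenomicRanges::findOverlaps(gap, eb_gr)
      if (length(mid_hits)) {
        ## elements overlapping the gap that are not the orthologs themselves
        cand <- .gr_to_df(eb_gr[S4Vectors::subjectHits(mid_hits)])
        self <- (cand$start < lo$end & cand$end > lo$start) |
          (cand$start < ro$end & cand$end > ro$start)
        if (any(!self)) next
      }
    }
    ## (3) the orthologs form a pair in B: members overlap the orthologs
    lhit <- IRanges::overlapsAny(pb_l, GenomicRanges::GRanges(
      lo$chrom, IRanges::IRanges(lo$start + 1L, lo$end)))
    rhit <- IRanges::overlapsAny(pb_r, GenomicRanges::GRanges(
      ro$chrom, IRanges::IRanges(ro$start + 1L, ro$end)))
    j <- which(lhit & rhit & pairs_b$chrom == lo$chrom)
    if (!length(j)) next
    j <- j[1]
    out[[length(out) + 1L]] <- data.frame(
      pair_id_a = pairs_a$pair_id[i], pair_id_b = pairs_b$pair_id[j],
      group_a = pairs_a$nrdd_group[i], group_b = pairs_b$nrdd_group[j],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(pair_id_a = character(), pair_id_b = character(),
                      group_a = integer(), group_b = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$category <- ifelse(is.na(res$group_a) | is.na(res$group_b), NA_character_,
                         paste0(prefix_a, .group_range(res$group_a), "; ",
                                prefix_b, .group_range(res$group_b)))
  res
}
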