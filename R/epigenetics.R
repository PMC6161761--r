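#' Histone marks profiled around CNE-CNE pairs
#' @export
HISTONE_MARKS <- c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me3", "H3K9me3")

## candidate 200-bp windows inside [s, e): starts at stride `step` plus an
## end-anchored window so the region tail is always covered
.best_windows <- function(s, e, win = 200L, step = 25L) {
  if (e - s < win) return(NULL)
  starts <- seq.int(s, e - win, by = step)
  if (starts[length(starts)] != e - win) starts <- c(starts, e - win)
  starts
}

#' Per-pair region summaries of a set of signal tracks
#'
#' For each pair and each (tissue, mark) track, computes the mean
#' fold-enrichment over four regions: a 300-bp window centered at each CNE
#' midpoint (\code{[mid-150, mid+150)}), the inter-CNE sequence (inner edges,
#' \code{[left.end, right.start)}), and the best 200-bp window — the maximum
#' windowed mean over 200-bp windows sliding at the track bin resolution
#' (default 25 bp) fully inside the inter-CNE sequence, with an extra
#' end-anchored window so the tail is covered. Inter-CNE sequences shorter
#' than 200 bp fall back to the whole-region mean and are flagged.
#'
#' @param pairs Pair table from \code{\link{build_pairs}}.
#' @param tracks List of \code{signal_track} objects.
#' @param step Window stride in bp (default 25, the track bin size).
#' @return Long data.frame \code{pair_id, tissue, mark, region, value,
#'   flag_short} with region in \code{cne_left, cne_right, inter, best200}.
#' @export
region_summaries <- function(pairs, tracks, step = 25L) {
  n <- nrow(pairs)
  lm <- interval_midpoint(pairs$l_start, pairs$l_end)
  rm_ <- interval_midpoint(pairs$r_start, pairs$r_end)
  base_regions <- data.frame(
    chrom = rep(pairs$chrom, 3L),
    start = c(lm - 150L, rm_ - 150L, pairs$inter_start),
    end = c(lm + 150L, rm_ + 150L, pairs$inter_end),
    region = rep(c("cne_left", "cne_right", "inter"), each = n),
    pair = rep(seq_len(n), 3L),
    stringsAsFactors = FALSE
  )
  winlist <- lapply(seq_len(n), function(i) {
    st <- .best_windows(pairs$inter_start[i], pairs$inter_end[i], step = step)
    if (is.null(st)) return(NULL)
    data.frame(chrom = pairs$chrom[i], start = st, end = st + 200L,
               region = "best200", pair = i, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, winlist)
  short <- vapply(winlist, is.null, logical(1))
  out <- list()
  for (tr in tracks) {
    vals <- track_means(tr, base_regions)
    best <- rep(NA_real_, n)
    if (!is.null(windows) && nrow(windows)) {
      wv <- track_means(tr, windows)
      mx <- tapply(wv, windows$pair, max)
      best[as.integer(names(mx))] <- mx
    }
    ## short inter-CNE: best200 falls back to the whole-region mean
    inter_vals <- vals[base_regions$region == "inter"]
    best[short] <- inter_vals[short]
    out[[length(out) + 1L]] <- data.frame(
      pair_id = rep(pairs$pair_id, 4L),
      tissue = tr$tissue, mark = tr$mark,
      region = c(base_regions$region, rep("best200", n)),
      value = c(vals, best),
      flag_short = rep(short, 4L),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sort the two CNEs of each pair into CNE_h / CNE_l
#'
#' The CNE with the higher overall H3K27ac enrichment (mean of the 300-bp CNE
#' window summaries across all tissues) becomes CNE_h, the other CNE_l; ties
#' go to the left CNE. The labels are invariant to tissue order.
#'
#' @param summaries Output of \code{\link{region_summaries}}.
#' @return List: \code{summaries} with region recoded to \code{CNE_h, CNE_l,
#'   inter, best200}, and \code{sides} (data.frame \code{pair_id, cne_h_side}).
#' @export
sort_cne_h_l <- function(summaries) {
  ac <- summaries[summaries$mark == "H3K27ac" &
                    summaries$region %in% c("cne_left", "cne_right"), ]
  agg <- stats::aggregate(value ~ pair_id + region, data = ac, FUN = mean)
  wide <- stats::reshape(agg, idvar = "pair_id", timevar = "region",
                         direction = "wide")
  lv <- wide$value.cne_left
  rv <- wide$value.cne_right
  side <- ifelse(!is.na(rv) & !is.na(lv) & rv > lv, "right", "left")
  sides <- data.frame(pair_id = wide$pair_id, cne_h_side = side,
                      stringsAsFactors = FALSE)
  m <- match(summaries$pair_id, sides$pair_id)
  sde <- sides$cne_h_side[m]
  region <- summaries$region
  is_l <- region == "cne_left"; is_r <- region == "cne_right"
  region[is_l] <- ifelse(sde[is_l] == "left", "CNE_h", "CNE_l")
  region[is_r] <- ifelse(sde[is_r] == "right", "CNE_h", "CNE_l")
  summaries$region <- region
  list(summaries = summaries, sides = sides)
}

#' Assemble the SOM feature matrix
#'
#' Rows are pairs; columns are tissue x region x mark mean fold-enrichments
#' in a fixed order: tissue-major, region in (CNE_h, CNE_l, inter, best200),
#' mark alphabetical within region. Column count is enforced to be
#' n_tissues x 4 x 5 (420 for 21 tissues, 1160 for 58). Missing combinations
#' are filled with the background fold-enrichment (1.0).
#'
#' @param summaries Sorted summaries (\code{\link{sort_cne_h_l}}).
#' @param tissues,marks Level sets fixing the column order.
#' @param fill Baseline fill for absent signal (default 1.0).
#' @return Numeric matrix with rownames = pair ids.
#' @export
build_feature_matrix <- function(summaries,
                                 tissues = sort(unique(summaries$tissue)),
                                 marks = sort(unique(summaries$mark)),
                                 fill = 1.0) {
  regions <- c("CNE_h", "CNE_l", "inter", "best200")
  pair_ids <- unique(summaries$pair_id)
  cols <- as.vector(t(outer(tissues, as.vector(t(outer(regions, sort(marks),
                                                       paste, sep = "."))),
                            paste, sep = ".")))
  stopifnot(length(cols) == length(tissues) * 4L * length(marks))
  mat <- matrix(fill, nrow = length(pair_ids), ncol = length(cols),
                dimnames = list(pair_ids, cols))
  key <- paste(summaries$tissue, summaries$region, summaries$mark, sep = ".")
  ri <- match(summaries$pair_id, pair_ids)
  ci <- match(key, cols)
  ok <- !is.na(ci) & !is.na(summaries$value)
  mat[cbind(ri[ok], ci[ok])] <- summaries$value[ok]
  mat
}

#' Above-background indicator
#'
#' Tracks are fold enrichments over the control experiment, whose level (1.0)
#' is the background signal; a summary is "above background" iff it strictly
#' exceeds 1.
#'
#' @param x Fold-enrichment value(s).
#' @return Logical vector.
#' @export
above_background <- function(x) {
  x > 1
}

#' CNE co-activity contingency table
#'
#' Cross-tabulates, over pairs, whether the CNE_h and CNE_l 300-bp windows
#' are above background for a given tissue and mark. The resulting 2x2 table
#' (\code{[[both, h_only], [l_only, neither]]}) feeds the Fisher test for
#' whether both CNEs are active together more often than chance.
#'
#' @param summaries Sorted summaries.
#' @param tissue,mark Track selection.
#' @return 2x2 integer matrix.
#' @export
coactivity_counts <- function(summaries, tissue, mark) {
  s <- summaries[summaries$tissue == tissue & summaries$mark == mark &
                   summaries$region %in% c("CNE_h", "CNE_l"), ]
  h <- s$value[s$region == "CNE_h"][match(unique(s$pair_id),
                                          s$pair_id[s$region == "CNE_h"])]
  l <- s$value[s$region == "CNE_l"][match(unique(s$pair_id),
                                          s$pair_id[s$region == "CNE_l"])]
  ha <- above_background(h); la <- above_background(l)
  matrix(c(sum(ha & la), sum(ha & !la), sum(!ha & la), sum(!ha & !la)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("h_above", "h_below"), c("l_above", "l_below")))
}

#' Randomization test for inter-CNE best-window enrichment
#'
#' For each (tissue, mark) track: the observed statistic per pair is the
#' best-200-bp-window mean within the inter-CNE sequence. Each replicate
#' samples one random genomic interval of the same length per inter-CNE
#' sequence, computes the best 200-bp window identically, and compares real
#' vs random values with an unpaired two-sided Wilcoxon rank-sum test.
#' Reports \code{prop_significant} (fraction of replicates with p <= alpha)
#' and \code{empirical_p = 1 - prop_significant}, as in
#' \code{\link{empirical_depletion_test}}.
#'
#' @param pairs Pair table (inter-CNE intervals are used).
#' @param tracks List of \code{signal_track}s.
#' @param chrom_lengths Named chromosome lengths for random sampling.
#' @param n_rep Replicates (default 1000).
#' @param alpha Per-replicate threshold (default 0.05).
#' @param seed Optional seed.
#' @param step Window stride (default 25).
#' @return data.frame \code{tissue, mark, prop_significant, empirical_p,
#'   direction, n_rep}.
#' @export
empirical_inter_cne_test <- function(pairs, tracks, chrom_lengths,
                                     n_rep = 1000L, alpha = 0.05, seed = NULL,
                                     step = 25L) {
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- pairs$inter_end - pairs$inter_start
  keep <- lens >= 200L
  if (!any(keep)) stop("no inter-CNE sequence of at least 200 bp")
  lens <- lens[keep]
  sub <- pairs[keep, , drop = FALSE]
  best_of <- function(track, regions) {
    w <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      st <- .best_windows(regions$start[i], regions$end[i], step = step)
      data.frame(chrom = regions$chrom[i], start = st, end = st + 200L,
                 id = i, stringsAsFactors = FALSE)
    }))
    v <- track_means(track, w)
    as.numeric(tapply(v, w$id, max))
  }
  res <- lapply(tracks, function(tr) {
    real <- best_of(tr, data.frame(chrom = sub$chrom, start = sub$inter_start,
                                   end = sub$inter_end))
    sig <- logical(n_rep); md <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      rnd <- .random_regions(lens, chrom_lengths)
      rv <- best_of(tr, rnd)
      p <- suppressWarnings(stats::wilcox.test(real, rv, exact = FALSE)$p.value)
      sig[r] <- !is.na(p) && p <= alpha
      md[r] <- stats::median(real) - stats::median(rv)
    }
    data.frame(tissue = tr$tissue, mark = tr$mark,
               prop_significant = mean(sig), empirical_p = 1 - mean(sig),
               direction = ifelse(stats::median(md) > 0, "enriched",
                                  ifelse(stats::median(md) < 0, "depleted", "none")),
               n_rep = n_rep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
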