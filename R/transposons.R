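#' Transposon classes
#' @export
TRANSPOSON_CLASSES <- c("DNA", "LTR", "LINE", "SINE")

## merged GRanges per class (cached by callers where it matters)
.class_granges <- function(annotation, classes = TRANSPOSON_CLASSES) {
  out <- lapply(classes, function(cl) {
    sel <- annotation$name == cl
    if (!any(sel)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(.as_gr(annotation[sel, , drop = FALSE]))
  })
  names(out) <- classes
  out$total <- GenomicRanges::reduce(do.call(c, unname(out)))
  out
}

## covered bp of each region by a (merged) GRanges subject
.covered_bp <- function(regions_gr, subject_gr) {
  out <- numeric(length(regions_gr))
  if (!length(subject_gr) || !length(regions_gr)) return(out)
  hits <- GenomicRanges::findOverlaps(regions_gr, subject_gr)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(regions_gr)[qi], GenomicRanges::end(subject_gr)[si]) -
      pmax(GenomicRanges::start(regions_gr)[qi], GenomicRanges::start(subject_gr)[si]) + 1L
    s <- rowsum(ov, group = qi)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Transposon density of genomic regions
#'
#' Fraction of base pairs of each region covered by transposons, per class
#' and in total. Intervals of a class are merged before counting so that
#' overlapping annotations are not double-counted; the total is the coverage
#' by the union of all classes (hence total <= sum of class densities and
#' >= their max).
#'
#' @param regions data.frame \code{chrom,start,end} with positive lengths.
#' @param annotation data.frame \code{chrom,start,end,name} where \code{name}
#'   is the transposon class (DNA, LTR, LINE, SINE).
#' @return data.frame with one row per region: \code{covered_<class>},
#'   \code{density_<class>}, \code{covered_total}, \code{density_total}.
#' @export
transposon_density <- function(regions, annotation) {
  stopifnot(all(regions$end > regions$start))
  cls <- .class_granges(annotation)
  gr <- .as_gr(regions)
  len <- regions$end - regions$start
  out <- data.frame(row.names = seq_len(nrow(regions)))
  for (cl in c(TRANSPOSON_CLASSES, "total")) {
    cov <- .covered_bp(gr, cls[[cl]])
    out[[paste0("covered_", cl)]] <- cov
    out[[paste0("density_", cl)]] <- cov / len
  }
  out
}

## cumulative-coverage index for repeated covered-bp queries against a fixed
## merged interval set: per chromosome, sorted starts/ends plus cumulative
## covered length, so covered bp of [s,e) is F(e) - F(s) via findInterval
.coverage_index <- function(gr) {
  if (!length(gr)) return(list())
  df <- .gr_to_df(gr)
  lapply(split(df, df$chrom), function(d) {
    o <- order(d$start)
    S <- d$start[o]; E <- d$end[o]
    list(S = S, E = E, cum = c(0, cumsum(as.numeric(E - S))))
  })
}

.cov_at <- function(ix, x) {
  idx <- findInterval(x, ix$S)
  out <- ix$cum[idx + 1L]
  inside <- idx > 0L
  out[inside] <- out[inside] - pmax(0, ix$E[idx[inside]] - x[inside])
  out
}

.covered_fast <- function(index, chrom, s, e) {
  out <- numeric(length(s))
  for (ch in unique(chrom)) {
    ix <- index[[ch]]
    if (is.null(ix)) next
    sel <- chrom == ch
    out[sel] <- .cov_at(ix, e[sel]) - .cov_at(ix, s[sel])
  }
  out
}

## length-matched uniform random regions, fully inside a chromosome
.random_regions <- function(lens, chrom_lengths) {
  chroms <- names(chrom_lengths)
  if (max(lens) > max(chrom_lengths)) {
    stop("region longer than any chromosome: ", max(lens), " bp")
  }
  if (all(lens <= min(chrom_lengths))) {
    ## fast path: every chromosome is eligible for every region
    chr <- if (length(chroms) == 1L) rep(chroms, length(lens)) else
      sample(chroms, length(lens), replace = TRUE, prob = chrom_lengths)
    start <- floor(stats::runif(length(lens)) * (chrom_lengths[chr] - lens + 1))
    return(data.frame(chrom = chr, start = as.integer(start),
                      end = as.integer(start + lens), stringsAsFactors = FALSE))
  }
  out_chr <- character(length(lens)); out_start <- integer(length(lens))
  for (i in seq_along(lens)) {
    ok <- chroms[chrom_lengths >= lens[i]]
    if (!length(ok)) stop("region longer than any chromosome: ", lens[i], " bp")
    chr <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = chrom_lengths[ok])
    out_chr[i] <- chr
    out_start[i] <- floor(stats::runif(1, 0, chrom_lengths[chr] - lens[i] + 1))
  }
  data.frame(chrom = out_chr, start = out_start, end = out_start + lens,
             stringsAsFactors = FALSE)
}

#' Randomization test for transposon-density depletion
#'
#' For each replicate, samples one length-matched random genomic interval per
#' real region (uniform start, fully inside a chromosome), computes per-class
#' transposon densities for real and random sets, and compares them with a
#' paired two-sided Wilcoxon signed-rank test. Reported per class:
#' \code{prop_significant}, the proportion of replicates with p <= alpha
#' (the literal empirical quantity); \code{empirical_p = 1 - prop_significant}
#' (the headline empirical P-value: small when the real densities differ
#' consistently from random); and \code{direction}, the sign of the median
#' (over replicates) of the median paired real-minus-random difference
#' ("depleted", "enriched" or "none").
#'
#' @param regions data.frame \code{chrom,start,end} of real regions.
#' @param chrom_lengths Named vector of chromosome lengths (the sampling
#'   universe; a gap mask can be applied upstream by shrinking it).
#' @param annotation Transposon annotation (see \code{\link{transposon_density}}).
#' @param n_rep Number of replicates (default 1000).
#' @param alpha Per-replicate significance threshold (default 0.05).
#' @param seed Optional integer seed.
#' @param null_calibration If TRUE, every replicate also redraws the "real"
#'   set as length-matched random regions, so each replicate compares two
#'   samples from the same null process; the replicate p-values are then
#'   independent and \code{prop_significant} estimates the per-replicate
#'   test's actual size (should be ~alpha). With the default FALSE the real
#'   regions stay fixed, as in the analysis proper, and replicate p-values
#'   are correlated through them.
#' @return data.frame \code{class, prop_significant, empirical_p, direction,
#'   median_real, median_random, n_rep}.
#' @export
empirical_depletion_test <- function(regions, chrom_lengths, annotation,
                                     n_rep = 1000L, alpha = 0.05, seed = NULL,
                                     null_calibration = FALSE) {
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (nrow(regions) == 0L) stop("no regions")
  if (!is.null(seed)) set.seed(seed)
  cls <- .class_granges(annotation)
  classes <- c(TRANSPOSON_CLASSES, "total")
  idx <- lapply(cls, .coverage_index)
  lens <- regions$end - regions$start
  dens_of <- function(reg) {
    m <- vapply(classes, function(cl)
      .covered_fast(idx[[cl]], reg$chrom, reg$start, reg$end) / lens,
      numeric(nrow(regions)))
    matrix(m, ncol = length(classes), dimnames = list(NULL, classes))
  }
  real <- dens_of(regions)
  sig <- matrix(FALSE, n_rep, length(classes), dimnames = list(NULL, classes))
  meddiff <- matrix(NA_real_, n_rep, length(classes), dimnames = list(NULL, classes))
  med_rand <- matrix(NA_real_, n_rep, length(classes), dimnames = list(NULL, classes))
  for (r in seq_len(n_rep)) {
    if (null_calibration) {
      real <- dens_of(.random_regions(lens, chrom_lengths))
    }
    rnd <- .random_regions(lens, chrom_lengths)
    drm <- dens_of(rnd)
    for (cl in classes) {
      dr <- drm[, cl]
      p <- suppressWarnings(stats::wilcox.test(real[, cl], dr, paired = TRUE,
                                               exact = FALSE)$p.value)
      sig[r, cl] <- !is.na(p) && p <= alpha
      meddiff[r, cl] <- stats::median(real[, cl] - dr)
      med_rand[r, cl] <- stats::median(dr)
    }
  }
  prop <- colMeans(sig)
  md <- apply(meddiff, 2, stats::median)
  data.frame(
    class = classes,
    prop_significant = prop,
    empirical_p = 1 - prop,
    direction = ifelse(md < 0, "depleted", ifelse(md > 0, "enriched", "none")),
    median_real = apply(real, 2, stats::median),
    median_random = apply(med_rand, 2, stats::median),
    n_rep = n_rep,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Transposon gain/loss classification per class
#'
#' Compares present-day and reconstructed ancestral transposon lengths with a
#' tolerance \code{epsilon} (ancestral lengths are continuous ML estimates, so
#' exact zeros are not expected): \code{loss} if present only in the ancestor,
#' \code{gain} if present only today, \code{stable} if present in both,
#' \code{absent} if in neither.
#'
#' @param T_h,T_r Nonnegative lengths (vectorized).
#' @param epsilon Presence threshold in bp (default 1).
#' @return Character vector of labels.
#' @export
gain_loss <- function(T_h, T_r, epsilon = 1) {
  ifelse(T_r > epsilon & T_h <= epsilon, "loss",
         ifelse(T_h > epsilon & T_r <= epsilon, "gain",
                ifelse(T_h > epsilon & T_r > epsilon, "stable", "absent")))
}

#' Transposon-free pair detection
#'
#' TRUE iff the inter-CNE span contains (up to \code{epsilon}) no transposons
#' of any class in either the focal genome or the reconstructed ancestor.
#'
#' @param T_h,T_r Numeric vectors of per-class lengths (all classes).
#' @param epsilon Tolerance (default 1 bp); values equal to epsilon count as
#'   absent.
#' @return Single logical.
#' @export
transposon_free <- function(T_h, T_r, epsilon = 1) {
  all(c(T_h, T_r) <= epsilon)
}
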