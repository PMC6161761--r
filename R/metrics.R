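#' Ancestor genome size (bp)
#'
#' Estimated genome size of the common mammalian ancestor used to normalize
#' ancestral distances, 3,270,000,000 bp.
#' @export
G_R_ANCESTOR <- 3270000000

#' Genome size-normalized relative distance difference (nRDD)
#'
#' \deqn{nRDD = \frac{d_h/G_h - d_r/G_r}{(d_h/G_h + d_r/G_r)/2}}
#' where \eqn{d_h} is the midpoint-to-midpoint distance between the two CNEs
#' of a pair in the focal genome, \eqn{d_r} the reconstructed distance between
#' their orthologs in the common mammalian ancestor, and \eqn{G_h, G_r} the
#' respective genome sizes. Values lie strictly between -2 and 2 for positive
#' inputs; positive values are expansions relative to the ancestor, negative
#' values contractions, and values near 0 indicate a conserved distance.
#'
#' @param d_h,d_r Positive distances (bp); vectorized.
#' @param G_h Focal genome size (bp).
#' @param G_r Ancestor genome size (bp), default \code{G_R_ANCESTOR}.
#' @return Numeric vector of nRDD values.
#' @export
nrdd <- function(d_h, d_r, G_h, G_r = G_R_ANCESTOR) {
  if (any(G_h <= 0) || any(G_r <= 0)) stop("genome sizes must be positive")
  if (any(d_h <= 0, na.rm = TRUE) || any(d_r <= 0, na.rm = TRUE)) {
    stop("nrdd: distances must be positive")
  }
  a <- d_h / G_h
  b <- d_r / G_r
  (a - b) / ((a + b) / 2)
}

#' Genome size-normalized relative transposon difference (nRTD)
#'
#' Same normalized-difference form as \code{\link{nrdd}}, applied to the
#' number of transposon-annotated base pairs \eqn{T} within the inter-CNE
#' span (midpoint to midpoint). Transposon lengths may legitimately be 0:
#' \eqn{T_h = 0, T_r > 0} gives exactly -2 (complete loss), the reverse
#' exactly +2 (pure gain), and \eqn{T_h = T_r = 0} is undefined (NA) —
#' transposon-free regions are a category of their own and are excluded from
#' downstream summaries.
#'
#' @param T_h,T_r Nonnegative transposon-covered lengths (bp); vectorized.
#' @param G_h Focal genome size (bp).
#' @param G_r Ancestor genome size (bp).
#' @return Numeric vector; NA where both lengths are 0.
#' @export
nrtd <- function(T_h, T_r, G_h, G_r = G_R_ANCESTOR) {
  if (any(G_h <= 0) || any(G_r <= 0)) stop("genome sizes must be positive")
  if (any(T_h < 0, na.rm = TRUE) || any(T_r < 0, na.rm = TRUE)) {
    stop("nrtd: transposon lengths must be nonnegative")
  }
  a <- T_h / G_h
  b <- T_r / G_r
  out <- (a - b) / ((a + b) / 2)
  out[a == 0 & b == 0] <- NA_real_
  out
}

#' Equal-sized decile groups
#'
#' Splits values into \code{n_groups} contiguous blocks from lowest to
#' highest (group 1 = most negative / most contracted). Blocks are as equal
#' as possible: with remainder r, the first r groups receive one extra
#' element. Ties are broken deterministically by id.
#'
#' @param values Finite numeric vector (NA not allowed).
#' @param ids Optional ids used for the tie-break (defaults to input order).
#' @param n_groups Number of groups (default 10).
#' @return Integer vector of group indices (1..n_groups) in input order.
#' @export
decile_groups <- function(values, ids = seq_along(values), n_groups = 10L) {
  n <- length(values)
  if (n < n_groups) stop(sprintf("need at least %d values, got %d", n_groups, n))
  if (anyNA(values)) stop("decile_groups: NA values not allowed")
  o <- order(values, ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp <- rep(seq_len(n_groups), times = sizes)
  out <- integer(n)
  out[o] <- grp
  out
}

#' Distance to the nearest transcription start site
#'
#' Distance from the midpoint of the complete pair sequence
#' \code{[left.start, right.end)} to the nearest protein-coding TSS on the
#' same chromosome (TSS = strand-aware 5' end of the transcript). NA (with a
#' warning) if the chromosome has no TSS.
#'
#' @param pairs data.frame with \code{chrom, l_start, r_end}.
#' @param tss data.frame \code{chrom, pos} as from \code{\link{read_gtf}}.
#' @return Integer vector of distances (bp), NA where undefined.
#' @export
tss_distance <- function(pairs, tss) {
  mid <- interval_midpoint(pairs$l_start, pairs$r_end)
  out <- rep(NA_integer_, nrow(pairs))
  for (chr in unique(pairs$chrom)) {
    p <- which(pairs$chrom == chr)
    tp <- tss$pos[tss$chrom == chr]
    if (!length(tp)) {
      warning("no TSS on chromosome ", chr, "; distance undefined")
      next
    }
    tp <- sort(tp)
    idx <- findInterval(mid[p], tp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tp))
    out[p] <- pmin(abs(mid[p] - tp[lo]), abs(mid[p] - tp[hi]))
  }
  out
}

#' Mean conservation score over an element
#'
#' Base-weighted mean of a per-base (or binned) score track over each CNE
#' interval, with bases missing from the track scoring 0.
#'
#' @param elements data.frame \code{chrom,start,end}.
#' @param score_track Bins data.frame \code{chrom,start,end,value} or a
#'   \code{signal_track}.
#' @return Numeric vector of mean scores.
#' @export
mean_conservation <- function(elements, score_track) {
  track_means(score_track, elements)
}
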