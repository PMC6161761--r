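# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force ML ancestral states under Brownian motion: minimize the
# negative log-likelihood sum((v_child - v_parent)^2 / edge_length) over all
# internal-node states by numerical optimization (BFGS on the quadratic).
bm_brute_force <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  x <- as.numeric(tip_values[tree$tip.label])
  objective <- function(v) {
    all_states <- c(x, v)
    sum((all_states[tree$edge[, 2]] - all_states[tree$edge[, 1]])^2 /
          tree$edge.length)
  }
  fit <- stats::optim(rep(mean(x), nint), objective, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
  stats::setNames(fit$par, ntip + seq_len(nint))
}

# Exact one-sided (greater) Fisher p by hypergeometric term summation.
fisher_enum <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  xs <- seq(a, min(k, m))
  if (!length(xs)) return(1)
  sum(stats::dhyper(xs, m, n, k))
}

# Brute-force reciprocal-best-hit resolution by explicit per-query loops.
rbh_brute_force <- function(fwd, rev_, qe) {
  out <- list()
  for (q in unique(fwd$query_id)) {
    for (sp in unique(fwd$species[fwd$query_id == q])) {
      f <- fwd[fwd$query_id == q & fwd$species == sp, , drop = FALSE]
      f <- f[order(-f$score, f$start, f$chrom), , drop = FALSE]
      best <- f[1, ]
      r <- rev_[rev_$species == sp & rev_$q_chrom == best$chrom &
                  rev_$q_start == best$start & rev_$q_end == best$end, ,
                drop = FALSE]
      if (!nrow(r)) next
      r <- r[order(-r$score, r$start, r$chrom), , drop = FALSE][1, ]
      e <- qe[qe$name == q, ]
      if (nrow(e) && r$chrom == e$chrom && r$start < e$end && r$end > e$start) {
        out[[length(out) + 1L]] <- data.frame(
          element = q, species = sp, chrom = best$chrom,
          start = best$start, end = best$end, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$element, res$species), ]
}

# Small flat helper: a signal_track with one constant-value bin.
flat_track <- function(value, tissue = "T01", mark = "H3K27ac",
                       chrom = "chr1", start = 0L, end = 100000L) {
  signal_track(tissue, mark,
               data.frame(chrom = chrom, start = start, end = end,
                          value = value, stringsAsFactors = FALSE))
}

# Tiny simulation config used by several integration tests.
tiny_config <- function(seed = 11L, n_pairs = 12L, n_tissues = 2L, ...) {
  sim_config(seed = seed, n_pairs = n_pairs, n_tissues = n_tissues, ...)
}
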