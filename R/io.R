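#' Midpoint of a half-open genomic interval
#'
#' All coordinates in this package are 0-based, half-open \code{[start, end)}
#' (the BED convention). The midpoint of \code{[s, e)} is defined as
#' \code{floor((s + e) / 2)}, which is deterministic for odd lengths.
#'
#' @param start,end Integer vectors of interval bounds, \code{start < end}.
#' @return Integer vector of midpoints.
#' @export
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

## internal: data.frame(chrom,start,end) -> GRanges (shift to 1-based closed)
.as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## internal: GRanges -> data.frame(chrom,start,end) in 0-based half-open
.gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.validate_intervals <- function(df, where = "interval set") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (need 0 <= start < end, got [%s, %s))",
                 where, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

#' Read a BED3/BED6 file
#'
#' Reads tab-separated BED with at least three columns. Coordinates are kept
#' 0-based half-open, input order is preserved. Column 4 (if present) is kept
#' as \code{name} (transposon files carry the repeat class there), column 5 as
#' \code{score}.
#'
#' @param path Path to an existing BED file.
#' @return A data.frame with columns \code{chrom, start, end, name, score}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated columns",
                 lineno[which(nf < 3L)[1]], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d in %s: non-integer coordinate",
                 lineno[which(is.na(start) | is.na(end))[1]], path))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval at BED line %d in %s: need 0 <= start < end",
                 lineno[bad[1]], path))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, character(1)), NA_character_)
  ))
  data.frame(chrom = chrom, start = start, end = end, name = name, score = score,
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' Integer fields are written exactly; scores with a fixed 6-decimal format so
#' that read/write round trips are value-identical.
#'
#' @param df data.frame with \code{chrom,start,end} and optional \code{name,score}.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  .validate_intervals(df, "write_bed")
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  has_name <- "name" %in% names(df) && !all(is.na(df$name))
  has_score <- "score" %in% names(df) && !all(is.na(df$score))
  if (has_name || has_score) {
    nm <- if ("name" %in% names(df)) df$name else rep(NA_character_, nrow(df))
    cols <- c(cols, list(ifelse(is.na(nm), ".", nm)))
  }
  if (has_score) cols <- c(cols, list(sprintf("%.6f", df$score)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted dated phylogeny from Newick
#'
#' Branch lengths are interpreted as divergence times (My). Polytomies are
#' accepted (ancestral-state estimation handles them directly, see
#' \code{\link{resolve_polytomies}}); negative branch lengths and duplicate tip
#' labels are errors.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (!inherits(tr, "phylo")) stop("could not parse a tree from ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree: ",
                                        tr$tip.label[duplicated(tr$tip.label)][1])
  if (is.null(tr$edge.length)) stop("tree has no branch lengths: ", path)
  if (any(tr$edge.length < 0)) stop("negative branch length in tree: ", path)
  tr
}

#' Resolve polytomies with zero-length branches
#'
#' Arbitrary (seeded) breakdown of multifurcations into bifurcations separated
#' by zero-length branches. Under Brownian motion this leaves all tip-to-node
#' path lengths, and therefore all ancestral-state estimates, unchanged.
#'
#' @param tree A \code{phylo} object.
#' @param seed Integer seed controlling the (likelihood-neutral) resolution.
#' @return A binary \code{phylo} object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  tr <- ape::multi2di(tree, random = TRUE)
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' Signal track constructor
#'
#' A signal track is a sparse, binned fold-enrichment signal for one
#' (tissue, histone mark) combination; positions not covered by any bin have
#' value 0 (bedGraph convention). Fold-enrichment 1.0 is the background level.
#'
#' @param tissue,mark Track identity.
#' @param bins data.frame \code{chrom,start,end,value}, non-overlapping per
#'   chromosome, value >= 0.
#' @return An object of class \code{signal_track}.
#' @export
signal_track <- function(tissue, mark, bins) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end", "value") %in% names(bins)))
  .validate_intervals(bins, "signal_track")
  if (any(bins$value < 0, na.rm = TRUE)) stop("signal_track: negative fold-enrichment")
  o <- order(bins$chrom, bins$start)
  bins <- bins[o, , drop = FALSE]
  by_chr <- split(seq_len(nrow(bins)), bins$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L) {
      s <- bins$start[idx]; e <- bins$end[idx]
      if (any(s[-1L] < e[-length(e)])) {
        stop(sprintf("signal_track: overlapping bins on %s", bins$chrom[idx[1]]))
      }
    }
  }
  rownames(bins) <- NULL
  structure(list(tissue = tissue, mark = mark, bins = bins), class = "signal_track")
}

#' Read a bedGraph signal track
#'
#' @param path 4-column bedGraph file.
#' @param tissue,mark Identity attached to the track.
#' @return A \code{signal_track}.
#' @export
read_track <- function(path, tissue, mark) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  signal_track(tissue, mark, df)
}

#' Write a signal track as bedGraph
#' @param track A \code{signal_track}.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  b <- track$bins
  writeLines(sprintf("%s\t%d\t%d\t%.4f", b$chrom, b$start, b$end, b$value), path)
  invisible(path)
}

#' Mean signal over genomic regions
#'
#' Base-weighted mean of the track value over each half-open query region,
#' with positions outside all bins contributing 0 (sparse convention).
#' Zero-width regions return 0.
#'
#' @param track A \code{signal_track}, or a bare bins data.frame
#'   (\code{chrom,start,end,value}) as used for conservation-score tracks.
#' @param regions data.frame with \code{chrom,start,end}.
#' @return Numeric vector of means, one per region.
#' @export
track_means <- function(track, regions) {
  bins <- if (inherits(track, "signal_track")) track$bins else track
  n <- nrow(regions)
  out <- numeric(n)
  if (n == 0L || nrow(bins) == 0L) return(out)
  w <- regions$end - regions$start
  ok <- which(w > 0L)
  if (!length(ok)) return(out)
  q <- .as_gr(regions[ok, , drop = FALSE])
  b <- .as_gr(bins)
  hits <- GenomicRanges::findOverlaps(q, b)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(q)[qi], GenomicRanges::end(b)[bi]) -
      pmax(GenomicRanges::start(q)[qi], GenomicRanges::start(b)[bi]) + 1L
    contrib <- ov * bins$value[bi]
    sums <- rowsum(contrib, group = qi)
    out[ok[as.integer(rownames(sums))]] <- sums[, 1L]
  }
  out / pmax(w, 1L)
}

#' Read a minimal protein-coding gene annotation from GTF
#'
#' Imports a GTF (1-based closed; converted to the package's 0-based half-open
#' convention on read), restricts to protein-coding genes, and extracts the
#' feature sets needed downstream: exons, UTRs, gene spans and strand-aware
#' transcription start sites.
#'
#' @param path GTF file with \code{gene}, \code{transcript}, \code{exon} and
#'   optionally \code{UTR} features; gene biotype in attribute
#'   \code{gene_type} or \code{gene_biotype}.
#' @return List with data.frames \code{genes}, \code{exons}, \code{utrs}
#'   (each \code{chrom,start,end,strand,gene_id}) and \code{tss}
#'   (\code{chrom,pos,strand,gene_id}).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% names(m)) m$gene_type else m$gene_biotype
  if (is.null(biotype)) biotype <- rep("protein_coding", length(gr))
  gr <- gr[!is.na(biotype) & biotype == "protein_coding"]
  m <- S4Vectors::mcols(gr)
  to_df <- function(sel) {
    g <- gr[sel]
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               strand = as.character(GenomicRanges::strand(g)),
               gene_id = as.character(S4Vectors::mcols(g)$gene_id),
               stringsAsFactors = FALSE)
  }
  genes <- to_df(m$type == "gene")
  exons <- to_df(m$type == "exon")
  utrs <- to_df(m$type %in% c("UTR", "five_prime_utr", "three_prime_utr"))
  tx <- to_df(m$type == "transcript")
  if (nrow(tx) == 0L) tx <- genes
  tss <- data.frame(chrom = tx$chrom,
                    pos = ifelse(tx$strand == "-", tx$end - 1L, tx$start),
                    strand = tx$strand, gene_id = tx$gene_id,
                    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, utrs = utrs, tss = unique(tss))
}

#' Write a minimal GTF gene annotation
#'
#' Inverse of \code{\link{read_gtf}} for the synthetic generator: emits
#' gene/transcript/exon (and UTR) features, converting the internal 0-based
#' half-open coordinates to the GTF 1-based closed convention.
#'
#' @param annotation List as returned by \code{read_gtf} (the \code{utrs}
#'   element may be empty).
#' @param path Output path.
#' @export
write_gtf <- function(annotation, path) {
  fmt <- function(df, type) {
    if (is.null(df) || nrow(df) == 0L) return(character())
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; gene_type \"protein_coding\";",
            df$chrom, type, df$start + 1L, df$end, df$strand, df$gene_id, df$gene_id)
  }
  lines <- c(fmt(annotation$genes, "gene"),
             fmt(annotation$genes, "transcript"),
             fmt(annotation$exons, "exon"),
             fmt(annotation$utrs, "UTR"))
  writeLines(lines, path)
  invisible(path)
}
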