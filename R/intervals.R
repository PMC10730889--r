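#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom stats rbinom rnbinom rnorm runif rexp setNames
#' @importFrom utils write.table read.delim packageVersion
NULL

# ---------------------------------------------------------------------------
# Region construction. All user-facing coordinates are BED-style: 0-based,
# half-open [start, end). Internally regions are GRanges (1-based closed);
# conversion happens only here and in the I/O layer.
# ---------------------------------------------------------------------------

#' Build a region set from BED-style coordinates
#'
#' Constructs a `GRanges` from 0-based half-open intervals, the convention of
#' BED, narrowPeak and UCSC cpgIslandExt files. All interval operations in
#' this package take and return `GRanges` built this way; use [regions_df()]
#' to get BED-style coordinates back.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @param id optional unique region identifiers, stored as names.
#' @return A `GRanges` object.
#' @examples
#' regions("chr1", c(0, 50), c(10, 80))
#' @export
regions <- function(chrom, start, end, strand = "*", id = NULL) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges())
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("region coordinates must be numeric and non-missing")
  }
  if (any(start < 0)) stop("region start must be >= 0")
  if (any(start >= end)) stop("region start must be < end")
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  if (!is.null(id)) {
    if (anyDuplicated(id)) stop("region ids must be unique")
    names(gr) <- id
  }
  gr
}

#' Region set as a BED-style data frame
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `strand`, and `id` (names, if set).
#' @export
regions_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(names(gr))) df$id <- names(gr)
  df
}

#' Merge regions closer than a gap
#'
#' Collapses a region set so that the output intervals are pairwise
#' non-overlapping and separated by more than `gap` bases. With `gap = 0`
#' overlapping and book-ended intervals are merged and the covered-base set
#' is unchanged.
#'
#' @param rs a `GRanges`.
#' @param gap non-negative distance (bp); intervals separated by at most
#'   `gap` bases are merged.
#' @return merged `GRanges`, strand-agnostic.
#' @export
merge_regions <- function(rs, gap = 0) {
  if (length(gap) != 1L || is.na(gap) || gap < 0) {
    stop("gap must be a single non-negative number")
  }
  GenomicRanges::reduce(
    GenomicRanges::GRanges(GenomicRanges::seqnames(rs), GenomicRanges::ranges(rs)),
    min.gapwidth = gap + 1
  )
}

#' Intersection of two region sets
#'
#' Maximal intervals covered by both `a` and `b` (strand-agnostic), the
#' bedtools-intersect analogue used for mark co-occurrence.
#'
#' @param a,b `GRanges` region sets.
#' @return `GRanges` of intersection intervals.
#' @export
intersect_sets <- function(a, b) {
  a <- GenomicRanges::GRanges(GenomicRanges::seqnames(a), GenomicRanges::ranges(a))
  b <- GenomicRanges::GRanges(GenomicRanges::seqnames(b), GenomicRanges::ranges(b))
  suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Drop regions touching a mask
#'
#' Removes every region of `rs` that shares at least one base with `mask`.
#' Whole regions are dropped, never clipped: this is the exclusion used when
#' candidate enhancers overlapping TSS windows are discarded.
#'
#' @param rs `GRanges` to filter.
#' @param mask `GRanges` of excluded territory.
#' @return the surviving subset of `rs`.
#' @export
exclude_overlapping <- function(rs, mask) {
  if (length(mask) == 0L || length(rs) == 0L) return(rs)
  hits <- GenomicRanges::findOverlaps(rs, mask, minoverlap = 1L,
                                      ignore.strand = TRUE)
  keep <- setdiff(seq_along(rs), unique(S4Vectors::queryHits(hits)))
  rs[keep]
}

# ---------------------------------------------------------------------------
# TSS annotation
# ---------------------------------------------------------------------------

#' Build a TSS index for nearest-distance queries
#'
#' @param tss data.frame with columns `chrom`, `position` (0-based bp),
#'   `strand` (`"+"`/`"-"`), `transcript_id`, and optionally `gene_id`.
#' @return an object of class `tss_index`: per-chromosome tables sorted by
#'   position with per-position representative transcripts (ties between
#'   transcripts sharing a position are resolved towards the
#'   lexicographically smallest `transcript_id`).
#' @export
tss_index <- function(tss) {
  required <- c("chrom", "position", "strand", "transcript_id")
  if (!all(required %in% names(tss))) {
    stop("tss table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(tss$position < 0)) stop("TSS positions must be >= 0")
  if (anyDuplicated(tss$transcript_id)) stop("transcript_id must be unique")
  if (!"gene_id" %in% names(tss)) tss$gene_id <- tss$transcript_id
  tss <- tss[order(tss$chrom, tss$position, tss$transcript_id), , drop = FALSE]
  by_chrom <- split(tss, tss$chrom)
  idx <- lapply(by_chrom, function(d) {
    # one representative per distinct position: smallest transcript_id
    first <- !duplicated(d$position)
    list(
      positions = d$position[first],
      transcript_id = d$transcript_id[first],
      strand = d$strand[first],
      gene_id = d$gene_id[first],
      table = d
    )
  })
  structure(list(chroms = idx, tss = tss), class = "tss_index")
}

#' @export
print.tss_index <- function(x, ...) {
  cat("tss_index:", nrow(x$tss), "TSS on", length(x$chroms), "chromosome(s)\n")
  invisible(x)
}

#' Signed distance from region midpoints to the nearest TSS
#'
#' The anchor is the region midpoint, `floor((start + end) / 2)` in 0-based
#' coordinates. The distance is signed in the orientation of the matched
#' TSS: negative when the midpoint lies upstream of the TSS (left of a
#' plus-strand TSS, right of a minus-strand TSS). Ties in absolute distance
#' are broken towards the lexicographically smallest `transcript_id`.
#'
#' @param rs `GRanges` of query regions.
#' @param idx a [tss_index()].
#' @return data.frame with one row per region: `transcript_id`, `gene_id`,
#'   `distance` (signed bp), and `missing_chrom` (TRUE when the region's
#'   chromosome has no TSS; distance is then NA).
#' @export
nearest_tss_distance <- function(rs, idx) {
  stopifnot(inherits(idx, "tss_index"))
  n <- length(rs)
  out <- data.frame(
    transcript_id = rep(NA_character_, n),
    gene_id = rep(NA_character_, n),
    distance = rep(NA_real_, n),
    missing_chrom = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  chrom <- as.character(GenomicRanges::seqnames(rs))
  # midpoint of [start0, end0) = floor((start0 + end0) / 2)
  mid <- floor(((GenomicRanges::start(rs) - 1) + GenomicRanges::end(rs)) / 2)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    entry <- idx$chroms[[ch]]
    if (is.null(entry)) {
      out$missing_chrom[sel] <- TRUE
      next
    }
    pos <- entry$positions
    m <- mid[sel]
    left <- findInterval(m, pos)              # rightmost position <= m
    right <- pmin(left + 1L, length(pos))
    left_ok <- left >= 1L
    li <- pmax(left, 1L)
    d_left <- ifelse(left_ok, abs(m - pos[li]), Inf)
    d_right <- abs(m - pos[right])
    use_right <- d_right < d_left
    tie <- d_right == d_left & right != li
    # tie between two distinct positions: smaller transcript_id wins
    if (any(tie)) {
      use_right[tie] <- entry$transcript_id[right[tie]] <
        entry$transcript_id[li[tie]]
    }
    pick <- ifelse(use_right, right, li)
    tss_pos <- pos[pick]
    tss_strand <- entry$strand[pick]
    signed <- ifelse(tss_strand == "-", tss_pos - m, m - tss_pos)
    out$transcript_id[sel] <- entry$transcript_id[pick]
    out$gene_id[sel] <- entry$gene_id[pick]
    out$distance[sel] <- signed
  }
  out
}

#' Window around a TSS
#'
#' Returns the `position +/- flank` window, clipped at the chromosome
#' boundaries, as a 0-based half-open interval with the TSS strand.
#'
#' @param tss data.frame of TSS records (see [tss_index()]).
#' @param flank positive flank size in bp.
#' @param chrom_length single chromosome length, or a named vector giving
#'   per-chromosome lengths; `Inf` disables right clipping.
#' @return `GRanges` named by transcript_id.
#' @export
window_around_tss <- function(tss, flank, chrom_length = Inf) {
  if (flank <= 0) stop("flank must be > 0")
  len <- if (length(chrom_length) > 1L || !is.null(names(chrom_length))) {
    unname(chrom_length[tss$chrom])
  } else {
    rep(chrom_length, nrow(tss))
  }
  if (any(is.na(len))) stop("chromosome length missing for some TSS")
  if (any(tss$position >= len)) {
    stop("TSS position beyond chromosome length")
  }
  start0 <- pmax(0, tss$position - flank)
  end0 <- pmin(len, tss$position + flank)
  regions(tss$chrom, start0, end0, strand = tss$strand, id = tss$transcript_id)
}

#' Promoter vs non-promoter attribution of regions
#'
#' A region is promoter-associated when its midpoint lies within
#' `window` bp of the nearest TSS (boundary inclusive: `|d| <= window`).
#'
#' @param rs `GRanges` of regions.
#' @param idx a [tss_index()].
#' @param window window half-width in bp (default 1000).
#' @return data.frame: `promoter` (logical; NA when the chromosome is absent
#'   from the index), plus the [nearest_tss_distance()] columns.
#' @export
classify_promoter_association <- function(rs, idx, window = 1000) {
  if (window <= 0) stop("window must be > 0")
  nd <- nearest_tss_distance(rs, idx)
  nd$promoter <- abs(nd$distance) <= window
  nd$promoter[nd$missing_chrom] <- NA
  nd[, c("promoter", "transcript_id", "gene_id", "distance", "missing_chrom")]
}

#' Keep only intergenic regions
#'
#' Retains regions whose midpoint lies strictly more than `min_distance` bp
#' from every TSS ("more than 3 kb" is strict: a region at exactly
#' `min_distance` is dropped).
#'
#' @param rs `GRanges`.
#' @param idx a [tss_index()].
#' @param min_distance minimum distance in bp (default 3000).
#' @return the intergenic subset of `rs`.
#' @export
intergenic_filter <- function(rs, idx, min_distance = 3000) {
  if (min_distance <= 0) stop("min_distance must be > 0")
  nd <- nearest_tss_distance(rs, idx)
  keep <- !is.na(nd$distance) & abs(nd$distance) > min_distance
  rs[keep]
}
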