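# ---------------------------------------------------------------------------
# Region-level analyses: enhancer definition by triple mark intersection,
# CGI promoter classification, ATAC fragment-size partitioning, and binned
# TSS / enhancer-center metaprofiles.
# ---------------------------------------------------------------------------

#' Define putative enhancers
#'
#' Enhancers are the merged intervals jointly positive for H3K4me1,
#' H3K27ac and ATAC peaks in untreated cells, after dropping every
#' candidate that overlaps a TSS +/- 1 kb window (whole-region exclusion).
#' The enhancer region is the triple intersection, i.e. the minimal
#' territory supported by all three signals; its midpoint is the anchor
#' used for metaprofiles.
#'
#' @param me1,k27ac,atac `GRanges` peak sets from control samples.
#' @param tss_windows `GRanges` of TSS +/- flank windows (see
#'   [window_around_tss()]).
#' @return `GRanges` of enhancers (ids `enh_00001`, ...) with a `center`
#'   metadata column (0-based midpoint).
#' @export
define_enhancers <- function(me1, k27ac, atac, tss_windows) {
  if (length(me1) == 0L || length(k27ac) == 0L || length(atac) == 0L) {
    warning("empty input peak set; no enhancers defined")
    return(GenomicRanges::GRanges())
  }
  enh <- intersect_sets(intersect_sets(me1, k27ac), atac)
  enh <- merge_regions(enh, gap = 0)
  enh <- exclude_overlapping(enh, tss_windows)
  if (length(enh) > 0L) {
    names(enh) <- sprintf("enh_%05d", seq_along(enh))
    S4Vectors::mcols(enh)$center <-
      floor(((GenomicRanges::start(enh) - 1) + GenomicRanges::end(enh)) / 2)
  }
  enh
}

#' Classify TSSs as CGI or non-CGI promoters
#'
#' A promoter is CGI-positive when the TSS +/- `window` interval shares at
#' least one base with a CpG island.
#'
#' @param tss TSS table (see [tss_index()]).
#' @param cgis `GRanges` of CpG islands.
#' @param window half-width in bp (default 1000).
#' @return logical vector along `tss` rows.
#' @export
classify_cgi_promoters <- function(tss, cgis, window = 1000) {
  win <- regions(tss$chrom, pmax(0, tss$position - window),
                 tss$position + window)
  if (length(cgis) == 0L) return(rep(FALSE, nrow(tss)))
  GenomicRanges::countOverlaps(win, cgis, minoverlap = 1L,
                               ignore.strand = TRUE) > 0
}

#' CGI stratification of changed promoter sites
#'
#' Among significantly changed sites attributed to promoters (midpoint
#' within `window` of a TSS), counts how many fall at CGI vs non-CGI
#' promoters, per direction of change.
#'
#' @param changed `GRanges` of changed sites with a `call` metadata column
#'   (gain/loss).
#' @param idx a [tss_index()].
#' @param cgi_promoter logical per TSS record of `idx` (same order as
#'   `idx$tss`), from [classify_cgi_promoters()].
#' @param window attribution half-width in bp (default 3000 for the
#'   summary stratification; use 1000 for strict promoter attribution).
#' @return data.frame per direction: `n_cgi`, `n_non_cgi`, `n_total`,
#'   `fraction_cgi`.
#' @export
cgi_stratify <- function(changed, idx, cgi_promoter, window = 3000) {
  stopifnot(inherits(idx, "tss_index"))
  if (length(cgi_promoter) != nrow(idx$tss)) {
    stop("cgi_promoter must align with the TSS table of the index")
  }
  cgi_of_transcript <- stats::setNames(cgi_promoter, idx$tss$transcript_id)
  nd <- nearest_tss_distance(changed, idx)
  at_promoter <- !is.na(nd$distance) & abs(nd$distance) <= window
  call <- as.character(S4Vectors::mcols(changed)$call)
  rows <- list()
  for (dir in c("gain", "loss")) {
    sel <- at_promoter & call == dir
    cgi <- cgi_of_transcript[nd$transcript_id[sel]]
    n_cgi <- sum(cgi, na.rm = TRUE)
    n_tot <- sum(sel)
    rows[[dir]] <- data.frame(
      direction = dir, n_cgi = n_cgi, n_non_cgi = n_tot - n_cgi,
      n_total = n_tot,
      fraction_cgi = if (n_tot > 0) n_cgi / n_tot else NaN,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition ATAC fragments by length into nucleosome classes
#'
#' Sub-nucleosomal ("nucleosome-free") fragments are shorter than 120 bp;
#' mono-nucleosome fragments span 130-200 bp inclusive; everything else
#' (120-129 bp and > 200 bp) is `other`.
#'
#' @param lengths positive fragment lengths in bp (or a `GRanges`, whose
#'   widths are used).
#' @return factor with levels `nucleosome_free`, `mono_nucleosome`,
#'   `other`.
#' @export
partition_fragments <- function(lengths) {
  if (inherits(lengths, "GRanges")) lengths <- GenomicRanges::width(lengths)
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  cls <- ifelse(lengths < 120, "nucleosome_free",
                ifelse(lengths >= 130 & lengths <= 200, "mono_nucleosome",
                       "other"))
  factor(cls, levels = c("nucleosome_free", "mono_nucleosome", "other"))
}

#' Binned CPM metaprofile around anchors
#'
#' Computes, for each anchor (TSS or enhancer center), the mean per-base
#' fragment coverage in consecutive bins across `+/- flank`, scaled to
#' counts per million: `bin_value = mean_coverage * 1e6 / library_size`.
#' Rows of minus-strand anchors are flipped so upstream is always on the
#' left. Anchors closer than `flank` to a chromosome edge get `NaN` bins
#' on the missing side and are excluded from the mean profile column-wise.
#'
#' @param fragments `GRanges` of fragments (or reads) providing coverage.
#' @param anchors `GRanges` of single-base anchors (0-based position =
#'   `start - 1`); strand respected.
#' @param flank half-window in bp; must be divisible by `bin_size`.
#' @param bin_size bin width in bp (default 10 for 1 kb flanks, 50 is
#'   sensible for 3 kb).
#' @param library_size total fragments in the library; defaults to
#'   `length(fragments)`.
#' @param chrom_lengths named vector of chromosome lengths; when omitted
#'   chromosomes are treated as unbounded on the right (coverage 0 beyond
#'   the last fragment), so only the left edge can truncate a window.
#' @return list: `matrix` (anchors x bins, CPM), `mean_profile` (column
#'   means over complete rows), `bin_centers` (bp offsets from anchor).
#' @export
tss_metaprofile <- function(fragments, anchors, flank = 1000, bin_size = 10,
                            library_size = NULL, chrom_lengths = NULL) {
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  if (is.null(library_size)) library_size <- length(fragments)
  if (library_size <= 0) stop("library_size must be positive")
  n_bins <- 2L * flank %/% bin_size
  frag_plain <- GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
                                       GenomicRanges::ranges(fragments))
  cov <- GenomicRanges::coverage(frag_plain)
  n <- length(anchors)
  mat <- matrix(NaN, nrow = n, ncol = n_bins)
  a_chrom <- as.character(GenomicRanges::seqnames(anchors))
  a_pos <- GenomicRanges::start(anchors) - 1L     # 0-based anchor bp
  a_strand <- as.character(GenomicRanges::strand(anchors))
  for (i in seq_len(n)) {
    ch <- a_chrom[i]
    rle <- if (ch %in% names(cov)) cov[[ch]] else NULL
    chlen <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      Inf
    }
    lo <- a_pos[i] - flank        # 0-based window [lo, hi)
    hi <- a_pos[i] + flank
    vals <- rep(NaN, 2L * flank)
    in_lo <- max(lo, 0L)
    in_hi <- min(hi, chlen)
    if (in_hi > in_lo) {
      seg <- if (is.null(rle) || in_lo >= length(rle)) {
        rep(0, in_hi - in_lo)
      } else {
        v <- as.numeric(S4Vectors::window(rle, start = in_lo + 1L,
                                          end = min(in_hi, length(rle))))
        c(v, rep(0, (in_hi - in_lo) - length(v)))
      }
      vals[(in_lo - lo + 1L):(in_hi - lo)] <- seg
    }
    binned <- colMeans(matrix(vals, nrow = bin_size))
    if (a_strand[i] == "-") binned <- rev(binned)
    mat[i, ] <- binned * 1e6 / library_size
  }
  rownames(mat) <- names(anchors)
  complete <- stats::complete.cases(mat) & !apply(is.nan(mat), 1, any)
  mean_profile <- if (any(complete)) {
    colMeans(mat[complete, , drop = FALSE])
  } else {
    rep(NaN, n_bins)
  }
  centers <- seq(-flank + bin_size / 2, flank - bin_size / 2, by = bin_size)
  list(matrix = mat, mean_profile = mean_profile, bin_centers = centers)
}

#' Overlap of changed intergenic sites with enhancers
#'
#' Partitions intergenic changed sites (pre-filtered with
#' [intergenic_filter()]) into enhancer-overlapping vs remaining genome,
#' per direction of change.
#'
#' @param changed `GRanges` of intergenic changed sites with a `call`
#'   metadata column.
#' @param enhancers `GRanges` from [define_enhancers()].
#' @return data.frame per direction: `at_enhancer`, `remaining_genome`.
#' @export
enhancer_overlap_summary <- function(changed, enhancers) {
  at_enh <- if (length(enhancers) == 0L) {
    rep(FALSE, length(changed))
  } else {
    GenomicRanges::countOverlaps(changed, enhancers, minoverlap = 1L,
                                 ignore.strand = TRUE) > 0
  }
  call <- as.character(S4Vectors::mcols(changed)$call)
  rows <- lapply(c("gain", "loss"), function(dir) {
    sel <- call == dir
    data.frame(direction = dir,
               at_enhancer = sum(sel & at_enh),
               remaining_genome = sum(sel & !at_enh),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
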