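test_that("merge_regions unions overlap and respects the gap", {
  rs <- regions(c("chr1", "chr1"), c(0, 5), c(10, 15))
  out <- regions_df(merge_regions(rs, gap = 0))
  expect_equal(out$start, 0)
  expect_equal(out$end, 15)

  expect_length(merge_regions(GenomicRanges::GRanges(), gap = 0), 0)

  # book-ended intervals merge at gap 0; separated ones only with a gap
  rs2 <- regions("chr1", c(0, 10), c(5, 20))
  expect_length(merge_regions(rs2, gap = 0), 2)
  rs3 <- regions("chr1", c(0, 5), c(5, 20))
  expect_length(merge_regions(rs3, gap = 0), 1)
  expect_length(merge_regions(rs2, gap = 5), 1)

  expect_error(merge_regions(rs, gap = -1), "non-negative")
})

test_that("merged covered bases match a per-base oracle", {
  set.seed(101)
  for (rep in 1:40) {
    df <- random_region_df(200, 5000)
    merged <- merge_regions(df_to_gr(df), gap = 0)
    expect_identical(gr_cover(merged, 5000), oracle_cover(df, 5000))
    # output pairwise separated by > 0 bases
    md <- regions_df(merged)
    if (nrow(md) > 1) {
      expect_true(all(md$start[-1] > md$end[-nrow(md)]))
    }
  }
})

test_that("intersect_sets equals per-base AND", {
  a <- regions("chr1", 0, 10)
  b <- regions("chr1", 5, 15)
  expect_equal(regions_df(intersect_sets(a, b))[, c("start", "end")],
               data.frame(start = 5, end = 10))
  expect_length(intersect_sets(regions("chr1", 0, 10),
                               regions("chr1", 20, 30)), 0)

  set.seed(102)
  for (rep in 1:40) {
    da <- random_region_df(60, 8000)
    db <- random_region_df(60, 8000)
    got <- intersect_sets(df_to_gr(da), df_to_gr(db))
    expect_identical(gr_cover(got, 8000),
                     oracle_cover(da, 8000) & oracle_cover(db, 8000))
  }
})

test_that("exclude_overlapping drops whole regions on any shared base", {
  rs <- regions("chr1", 100, 200, id = "r1")
  expect_length(exclude_overlapping(rs, regions("chr1", 150, 160)), 0)
  expect_length(exclude_overlapping(rs, regions("chr1", 300, 400)), 1)
  # touching boundary (half-open): no shared base, region kept
  expect_length(exclude_overlapping(rs, regions("chr1", 200, 210)), 1)

  # identities
  expect_identical(length(exclude_overlapping(rs, GenomicRanges::GRanges())),
                   1L)
  expect_length(exclude_overlapping(rs, rs), 0)

  set.seed(103)
  for (rep in 1:40) {
    df <- random_region_df(50, 6000)
    mask <- random_region_df(30, 6000)
    got <- exclude_overlapping(df_to_gr(df), df_to_gr(mask))
    maskv <- oracle_cover(mask, 6000)
    keep <- vapply(seq_len(nrow(df)), function(i) {
      !any(maskv[(df$start[i] + 1):df$end[i]])
    }, logical(1))
    expect_equal(length(got), sum(keep))
    expect_identical(gr_cover(got, 6000),
                     oracle_cover(df[keep, , drop = FALSE], 6000))
  }
})

test_that("window_around_tss clips at chromosome bounds", {
  tss <- data.frame(chrom = "chr1", position = c(5000, 300, 5000),
                    strand = c("+", "-", "+"),
                    transcript_id = c("a", "b", "c"))
  w <- regions_df(window_around_tss(tss[1, ], 1000, chrom_length = 1e6))
  expect_equal(c(w$start, w$end), c(4000, 6000))
  w <- regions_df(window_around_tss(tss[2, ], 1000, chrom_length = 1e6))
  expect_equal(c(w$start, w$end), c(0, 1300))
  w <- regions_df(window_around_tss(tss[3, ], 3000, chrom_length = 1e6))
  expect_equal(c(w$start, w$end), c(2000, 8000))
  expect_error(window_around_tss(tss[1, ], 1000, chrom_length = 4000),
               "beyond chromosome")
  expect_error(window_around_tss(tss, 0), "flank")
})

test_that("nearest_tss_distance sign and tie conventions hold", {
  tss <- data.frame(
    chrom = "chr1",
    position = c(1000, 1000, 3000),
    strand = c("+", "-", "-"),
    transcript_id = c("txB", "txA", "txC"),
    stringsAsFactors = FALSE
  )
  idx <- tss_index(tss)

  # midpoint at the TSS
  r <- regions("chr1", 1000, 1001)   # midpoint 1000
  nd <- nearest_tss_distance(r, idx)
  expect_equal(nd$distance, 0)
  expect_equal(nd$transcript_id, "txA")  # shared position: smaller id

  # 500 bp left of a plus-strand TSS is upstream (negative)
  tssp <- tss_index(data.frame(chrom = "chr1", position = 1000,
                               strand = "+", transcript_id = "tx1"))
  nd <- nearest_tss_distance(regions("chr1", 500, 501), tssp)
  expect_equal(nd$distance, -500)

  # same geometry at a minus-strand TSS is downstream (positive)
  tssm <- tss_index(data.frame(chrom = "chr1", position = 1000,
                               strand = "-", transcript_id = "tx1"))
  nd <- nearest_tss_distance(regions("chr1", 500, 501), tssm)
  expect_equal(nd$distance, 500)

  # chromosome missing from the index is flagged, not fatal
  nd <- nearest_tss_distance(regions("chrUn", 0, 10), idx)
  expect_true(nd$missing_chrom)
  expect_true(is.na(nd$distance))
})

test_that("nearest_tss_distance matches an exhaustive scan oracle", {
  set.seed(104)
  tss <- data.frame(
    chrom = "chr1",
    position = c(50, 120, 120, 500, 900, 901),
    strand = sample(c("+", "-"), 6, replace = TRUE),
    transcript_id = c("t4", "t9", "t2", "t7", "t1", "t3"),
    stringsAsFactors = FALSE
  )
  idx <- tss_index(tss)
  mids <- 0:999
  got <- nearest_tss_distance(regions("chr1", mids, mids + 1), idx)
  for (k in seq_along(mids)) {
    o <- oracle_nearest(mids[k], tss)
    expect_identical(got$transcript_id[k], o$id)
    expect_identical(got$distance[k], as.numeric(o$signed))
  }
})

test_that("promoter association boundary is inclusive", {
  idx <- tss_index(data.frame(chrom = "chr1", position = 10000,
                              strand = "+", transcript_id = "tx1"))
  at <- function(mid) {
    classify_promoter_association(regions("chr1", mid, mid + 1), idx,
                                  window = 1000)$promoter
  }
  expect_true(at(9000))    # |d| = 1000 exactly
  expect_true(at(11000))
  expect_false(at(8999))   # |d| = 1001
  expect_error(classify_promoter_association(regions("chr1", 1, 2), idx,
                                             window = 0), "window")
})

test_that("intergenic_filter is strict at the distance bound", {
  idx <- tss_index(data.frame(chrom = "chr1", position = 10000,
                              strand = "+", transcript_id = "tx1"))
  # midpoint exactly 3000 away: dropped ("more than")
  r_at <- regions("chr1", 7000, 7001)
  expect_length(intergenic_filter(r_at, idx, 3000), 0)
  r_past <- regions("chr1", 6999, 7000)   # midpoint 6999, distance 3001
  expect_length(intergenic_filter(r_past, idx, 3000), 1)

  # random set against a linear-scan oracle
  set.seed(105)
  tss <- data.frame(chrom = "chr1", position = sample.int(9000, 10),
                    strand = "+",
                    transcript_id = sprintf("tx%02d", 1:10))
  idx2 <- tss_index(tss)
  df <- random_region_df(80, 10000, max_width = 100, chrom = "chr1")
  got <- intergenic_filter(df_to_gr(df), idx2, 500)
  mids <- floor((df$start + df$end) / 2)
  keep <- vapply(mids, function(m) {
    min(abs(m - tss$position)) > 500
  }, logical(1))
  expect_equal(length(got), sum(keep))
})

test_that("merge then intersect with self preserves covered bases", {
  set.seed(106)
  df <- random_region_df(100, 4000)
  gr <- df_to_gr(df)
  merged <- merge_regions(gr, gap = 0)
  back <- intersect_sets(merged, gr)
  expect_identical(gr_cover(back, 4000), gr_cover(merged, 4000))
})
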