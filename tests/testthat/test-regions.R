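test_that("enhancers require all three marks and no TSS window overlap", {
  tss_win <- regions("chr1", 9000, 11000)    # TSS 10000 +/- 1 kb

  me1 <- regions("chr1", c(2000, 9500), c(2500, 9900))
  k27 <- regions("chr1", c(2000, 9500), c(2500, 9900))
  atac <- regions("chr1", c(2000, 9500), c(2500, 9900))
  enh <- define_enhancers(me1, k27, atac, tss_win)
  # the triple overlap inside the TSS window is excluded
  df <- regions_df(enh)
  expect_equal(nrow(df), 1)
  expect_equal(c(df$start, df$end), c(2000, 2500))
  expect_equal(S4Vectors::mcols(enh)$center, 2250)

  # missing one mark kills the candidate
  enh2 <- define_enhancers(me1, k27, regions("chr1", 5000, 5100), tss_win)
  expect_length(enh2, 0)

  expect_warning(
    enh3 <- define_enhancers(GenomicRanges::GRanges(), k27, atac, tss_win),
    "empty"
  )
  expect_length(enh3, 0)
})

test_that("defined enhancers never overlap TSS windows on simulated data", {
  cfg <- tiny_config(seed = 51)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation
  tss_win <- window_around_tss(ann$tss, 1000, ann$chrom_lengths)
  enh <- define_enhancers(sim$peaks$H3K4me1, sim$peaks$H3K27ac,
                          sim$peaks$ATAC, tss_win)
  expect_gt(length(enh), 0)
  expect_equal(length(exclude_overlapping(enh, tss_win)), length(enh))
  # every true enhancer core is recovered
  hits <- GenomicRanges::countOverlaps(ann$enhancer_truth, enh,
                                       ignore.strand = TRUE)
  expect_true(all(hits >= 1))
})

test_that("CGI promoter classification respects the half-open boundary", {
  tss <- data.frame(chrom = "chr1", position = c(5000, 5000, 5000),
                    strand = "+",
                    transcript_id = c("a", "b", "c"))
  # spanning the TSS
  expect_true(classify_cgi_promoters(tss[1, ],
                                     regions("chr1", 4900, 5100)))
  # CGI ending exactly at the window start: no shared base
  expect_false(classify_cgi_promoters(tss[1, ],
                                      regions("chr1", 3000, 4000)))
  # one base inside
  expect_true(classify_cgi_promoters(tss[1, ],
                                     regions("chr1", 3000, 4001)))
  expect_false(any(classify_cgi_promoters(tss, GenomicRanges::GRanges())))

  # random layouts against the per-base oracle
  set.seed(52)
  for (rep in 1:20) {
    tssr <- data.frame(chrom = "chr1",
                       position = sample(1000:9000, 15),
                       strand = "+",
                       transcript_id = sprintf("t%02d", 1:15))
    cgi_df <- random_region_df(10, 10000, max_width = 600, chrom = "chr1")
    got <- classify_cgi_promoters(tssr, df_to_gr(cgi_df), window = 500)
    cov <- oracle_cover(cgi_df, 10000)
    want <- vapply(tssr$position, function(p) {
      any(cov[(max(0, p - 500) + 1):min(10000, p + 500)])
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("cgi_stratify reports per-direction CGI fractions", {
  tss <- data.frame(chrom = "chr1",
                    position = c(1000, 3000, 5000, 7000, 9000) * 10,
                    strand = "+",
                    transcript_id = sprintf("t%d", 1:5))
  idx <- tss_index(tss)
  cgi_flag <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  # five changed sites, each at one promoter, all losses
  ch <- regions("chr1", tss$position - 50, tss$position + 50)
  S4Vectors::mcols(ch)$call <- "loss"
  out <- cgi_stratify(ch, idx, cgi_flag, window = 3000)
  expect_equal(out$fraction_cgi[out$direction == "loss"], 0.8)
  expect_equal(out$n_total[out$direction == "gain"], 0)

  out2 <- cgi_stratify(ch, idx, rep(TRUE, 5), window = 3000)
  expect_equal(out2$fraction_cgi[out2$direction == "loss"], 1.0)
})

test_that("fragment partition boundaries follow the stated bounds", {
  lens <- c(119, 120, 125, 130, 200, 201, 60)
  got <- as.character(partition_fragments(lens))
  expect_equal(got, c("nucleosome_free", "other", "other",
                      "mono_nucleosome", "mono_nucleosome", "other",
                      "nucleosome_free"))
  # classes are exclusive and exhaustive over positive lengths
  all_lens <- 1:500
  tab <- table(partition_fragments(all_lens))
  expect_equal(sum(tab), 500)
  expect_equal(unname(tab["nucleosome_free"]), 119, ignore_attr = TRUE)
  expect_equal(unname(tab["mono_nucleosome"]), 71, ignore_attr = TRUE)
  expect_error(partition_fragments(c(10, 0)), "positive")
})

test_that("metaprofiles are linear in library size and flip with strand", {
  # uniform coverage: one fragment covering the whole chromosome
  frag <- regions("chr1", 0, 4000)
  anchor <- regions("chr1", 2000, 2001, strand = "+")
  mp <- tss_metaprofile(frag, anchor, flank = 500, bin_size = 10,
                        library_size = 1)
  expect_equal(unique(as.numeric(mp$matrix)), 1e6)
  expect_equal(mp$mean_profile, rep(1e6, 100))

  mp2 <- tss_metaprofile(frag, anchor, flank = 500, bin_size = 10,
                         library_size = 2)
  expect_equal(mp2$matrix, mp$matrix / 2)

  # asymmetric coverage flips for minus-strand anchors
  frag_l <- regions("chr1", 1500, 2000)   # only upstream of the anchor
  for (s in c("+", "-")) {
    anc <- regions("chr1", 2000, 2001, strand = s)
    m <- tss_metaprofile(frag_l, anc, flank = 500, bin_size = 50,
                         library_size = 1)$matrix
    left_half <- mean(m[1, 1:10]); right_half <- mean(m[1, 11:20])
    if (s == "+") expect_gt(left_half, right_half)
    else expect_gt(right_half, left_half)
  }

  # single fragment centered on the only anchor: signal confined there
  frag_c <- regions("chr1", 1990, 2010)
  m <- tss_metaprofile(frag_c, anchor, flank = 500, bin_size = 10,
                       library_size = 1)$matrix
  expect_equal(sum(m[1, ] > 0), 2)
  expect_equal(which(m[1, ] > 0), c(50, 51))

  # edge anchors get NaN padding and drop out of the mean profile
  anc_edge <- regions("chr1", 100, 101)
  both <- c(anc_edge, anchor)
  mp3 <- tss_metaprofile(frag, both, flank = 500, bin_size = 10,
                         library_size = 1)
  expect_true(any(is.nan(mp3$matrix[1, ])))
  expect_equal(mp3$mean_profile, mp$mean_profile)

  expect_error(tss_metaprofile(frag, anchor, flank = 500, bin_size = 7),
               "divisible")
})

test_that("metaprofile column sums ignore anchor order", {
  set.seed(53)
  frag <- df_to_gr(random_region_df(300, 20000, max_width = 200,
                                    chrom = "chr1"))
  pos <- sample(2000:18000, 20)
  anchors <- regions("chr1", pos, pos + 1,
                     strand = sample(c("+", "-"), 20, replace = TRUE))
  m1 <- tss_metaprofile(frag, anchors, flank = 1000, bin_size = 50)$matrix
  perm <- sample(20)
  m2 <- tss_metaprofile(frag, anchors[perm], flank = 1000,
                        bin_size = 50)$matrix
  expect_equal(colSums(m2), colSums(m1))
})

test_that("enhancer overlap partition matches a per-base oracle", {
  enh <- regions("chr1", c(1000, 5000), c(1500, 5600))
  ch <- regions("chr1", c(1100, 3000, 5550, 8000),
                c(1200, 3100, 5650, 8100))
  S4Vectors::mcols(ch)$call <- c("loss", "loss", "gain", "gain")
  out <- enhancer_overlap_summary(ch, enh)
  expect_equal(out$at_enhancer[out$direction == "loss"], 1)
  expect_equal(out$remaining_genome[out$direction == "loss"], 1)
  expect_equal(out$at_enhancer[out$direction == "gain"], 1)

  # no enhancers: everything is remaining genome
  out0 <- enhancer_overlap_summary(ch, GenomicRanges::GRanges())
  expect_equal(sum(out0$at_enhancer), 0)
  expect_equal(sum(out0$remaining_genome), 4)

  set.seed(54)
  for (rep in 1:15) {
    enh_df <- random_region_df(10, 8000, chrom = "chr1")
    ch_df <- random_region_df(40, 8000, max_width = 150, chrom = "chr1")
    gr <- df_to_gr(ch_df)
    S4Vectors::mcols(gr)$call <- sample(c("gain", "loss"), 40,
                                        replace = TRUE)
    got <- enhancer_overlap_summary(gr, df_to_gr(enh_df))
    cov <- oracle_cover(enh_df, 8000)
    hit <- vapply(seq_len(40), function(i) {
      any(cov[(ch_df$start[i] + 1):ch_df$end[i]])
    }, logical(1))
    call <- S4Vectors::mcols(gr)$call
    for (dir in c("gain", "loss")) {
      expect_equal(got$at_enhancer[got$direction == dir],
                   sum(hit & call == dir))
      expect_equal(got$remaining_genome[got$direction == dir],
                   sum(!hit & call == dir))
    }
  }
})
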