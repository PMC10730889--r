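# Independent per-base oracles and small generators used across tests.
# The oracles mark covered bases in a plain logical vector, one element
# per bp of a short chromosome, and never call the package's interval
# code.

# logical coverage vector of length chrom_len for 0-based half-open df
oracle_cover <- function(df, chrom_len) {
  v <- logical(chrom_len)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) {
      v[(df$start[i] + 1):df$end[i]] <- TRUE   # base b occupies v[b + 1]
    }
  }
  v
}

# covered-base vector of a GRanges on one chromosome
gr_cover <- function(gr, chrom_len) {
  oracle_cover(chromkinetics::regions_df(gr), chrom_len)
}

# random single-chromosome region set (0-based half-open data.frame)
random_region_df <- function(n, chrom_len, max_width = 400, chrom = "chrS") {
  start <- sample.int(chrom_len - 1L, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  end <- pmin(chrom_len, start + width)
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df, id = NULL) {
  chromkinetics::regions(df$chrom, df$start, df$end, id = id)
}

# brute-force nearest-TSS oracle: scan every TSS, smallest |d|, ties to
# the smallest transcript_id; signed in the TSS orientation
oracle_nearest <- function(mid, tss) {
  best <- NULL
  for (i in seq_len(nrow(tss))) {
    d_abs <- abs(mid - tss$position[i])
    if (is.null(best) || d_abs < best$d_abs ||
        (d_abs == best$d_abs && tss$transcript_id[i] < best$id)) {
      signed <- if (tss$strand[i] == "-") tss$position[i] - mid else mid - tss$position[i]
      best <- list(d_abs = d_abs, id = tss$transcript_id[i],
                   signed = signed)
    }
  }
  best
}

# literal translation of the fast/slow wording, used as the classifier
# oracle: fast = loss after 2 h; slow = loss after 16 h, excluding
# promoters losing at 30 min, 2 h, 4 h or 8 h
oracle_fast_slow <- function(calls) {
  loss <- function(tp) calls[[tp]] == "loss"
  if (loss("t2")) return("fast")
  if (loss("t16") && !loss("t0.5") && !loss("t2") && !loss("t4") &&
      !loss("t8")) {
    return("slow")
  }
  "other"
}

# hand-coded BH step-up (no monotonicity shortcut from p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  # enforce step-up monotonicity from the largest rank down
  for (i in (m - 1):1) {
    q[ord[i]] <- min(q[ord[i]], q[ord[i + 1]])
  }
  pmin(q, 1)
}

# small simulated experiment shared by several test files
tiny_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_promoters = 120, n_enhancers = 20,
               chrom_length = 1.5e6, fragments_per_site = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(chromkinetics::simulation_config, args)
}
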