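# ---------------------------------------------------------------------------
# Normalization and per-site differential testing.
#
# The pipeline deliberately replaces a DESeq2 call with a self-contained,
# calibratable negative-binomial Wald test: per-site log-link NB GLM with a
# fixed dispersion, two groups (treated timepoint vs the 0 h control). The
# scientific logic downstream depends only on thresholded calls
# (q < 0.05 and |log2FC| > 0.58), not on shrunken effect sizes.
# ---------------------------------------------------------------------------

#' Assemble a count matrix with sample metadata
#'
#' @param counts integer matrix, sites x samples; rownames are site ids,
#'   colnames sample ids.
#' @param samples data.frame with columns `sample_id`, `assay`,
#'   `timepoint_h`, `replicate`, `treated`; rows match `counts` columns.
#' @param spike_in logical per site; defaults to ids starting with the
#'   `spike_prefix`.
#' @param spike_prefix id prefix marking exogenous spike-in rows
#'   (default `"ERCC-"`).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, spike_in = NULL,
                         spike_prefix = "ERCC-") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have site-id rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicated site ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  required <- c("sample_id", "assay", "timepoint_h", "replicate", "treated")
  if (!all(required %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  }
  if (ncol(counts) != nrow(samples)) {
    stop("counts columns and sample sheet rows differ")
  }
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), samples$sample_id)) {
    stop("counts column names do not match sample sheet sample_id")
  }
  key <- with(samples, paste(assay, timepoint_h, replicate, treated))
  if (anyDuplicated(key)) stop("(assay, timepoint, replicate, treated) must be unique")
  colnames(counts) <- samples$sample_id
  if (is.null(spike_in)) {
    spike_in <- startsWith(rownames(counts), spike_prefix)
  }
  structure(
    list(counts = counts, samples = samples, spike_in = spike_in),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "sites x", ncol(x$counts), "samples (",
      sum(x$spike_in), "spike-in rows )\n")
  invisible(x)
}

#' Minimum-coverage scale multipliers
#'
#' Scales every sample down to the lowest coverage:
#' `factor_s = min(totals) / total_s`, so that `totals * factor` are all
#' equal to the minimum. This is the normalization used for the ChIP and
#' ATAC count tables. The totals are per-library mapped-read counts when
#' the sample sheet carries a `library_size` column (the realistic case:
#' genome-wide coverage is dominated by stable background, so a global
#' in-peak signal loss remains measurable after normalization); otherwise
#' the column sums of the count table are used. Spike-in rows, if any,
#' are excluded from column sums.
#'
#' @param cm a [count_matrix()], a counts matrix, or a numeric vector of
#'   per-sample totals.
#' @return named numeric vector of per-sample multipliers (all in (0, 1]).
#' @export
size_factors_min_coverage <- function(cm) {
  totals <- if (inherits(cm, "count_matrix")) {
    if ("library_size" %in% names(cm$samples)) {
      stats::setNames(cm$samples$library_size, cm$samples$sample_id)
    } else {
      colSums(cm$counts[!cm$spike_in, , drop = FALSE])
    }
  } else if (is.matrix(cm)) {
    colSums(cm)
  } else {
    cm
  }
  if (any(totals <= 0)) stop("sample with zero total counts")
  min(totals) / totals
}

#' Spike-in size factors (median-of-ratios on spike-in rows)
#'
#' DESeq2-style median-of-ratios computed on the exogenous spike-in rows
#' only, so global shifts of the endogenous transcriptome do not distort
#' the scaling: `factor_s = median_i counts[i, s] / geomean_i`, over
#' spike-in rows `i` with positive geometric mean, rescaled so the factors'
#' geometric mean is 1. Normalized counts are `counts / factor`.
#'
#' @param cm a [count_matrix()] with spike-in rows flagged.
#' @param min_rows minimum usable spike-in rows (default 10).
#' @return named numeric vector of per-sample size factors (divisors).
#' @export
size_factors_spike_in <- function(cm, min_rows = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  sp <- cm$counts[cm$spike_in, , drop = FALSE]
  if (nrow(sp) == 0L) {
    stop("no spike-in rows; use size_factors_min_coverage() instead")
  }
  logmeans <- rowMeans(log(sp))
  usable <- is.finite(logmeans)
  if (sum(usable) < min_rows) {
    stop("need >= ", min_rows, " spike-in rows with nonzero geometric mean")
  }
  ratios <- sp[usable, , drop = FALSE] / exp(logmeans[usable])
  f <- apply(ratios, 2, stats::median)
  f / exp(mean(log(f)))
}

#' Method-of-moments NB dispersion for one site
#'
#' `alpha = max(alpha_floor, (var - mean) / mean^2)` on normalized counts
#' (`counts / size_factors`); returns the floor for empty or
#' under-dispersed rows. With only a handful of replicates this is noisy;
#' the pipeline pools it across sites (see [differential_timecourse()]).
#'
#' @param counts_row numeric vector of raw counts for one site.
#' @param size_factors per-sample size factors (divisors); default 1.
#' @param alpha_floor lower bound (default 1e-8).
#' @return dispersion alpha >= alpha_floor.
#' @export
estimate_dispersion <- function(counts_row, size_factors = NULL,
                                alpha_floor = 1e-8) {
  if (length(counts_row) < 2L) stop("need >= 2 samples")
  if (is.null(size_factors)) size_factors <- rep(1, length(counts_row))
  y <- counts_row / size_factors
  m <- mean(y)
  if (m == 0) return(alpha_floor)
  v <- stats::var(y)
  max(alpha_floor, (v - m) / m^2)
}

# Vectorized two-group NB Wald test by Fisher scoring.
# Model: mu_ij = s_j * exp(b0_i + b1_i * x_j), Var = mu + alpha_i mu^2.
# Returns per-site coefficient b1 (natural log), its SE, and two-sided p.
nb_wald_fit <- function(counts, x, size_factors, alpha, max_iter = 50,
                        tol = 1e-8) {
  counts <- as.matrix(counts)
  n_sites <- nrow(counts)
  n_samp <- ncol(counts)
  stopifnot(length(x) == n_samp, length(size_factors) == n_samp)
  alpha <- rep_len(alpha, n_sites)
  s <- matrix(size_factors, n_sites, n_samp, byrow = TRUE)
  xr <- matrix(x, n_sites, n_samp, byrow = TRUE)

  norm <- counts / s
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  b0 <- log(pmax(m0, 0.1))
  b1 <- log(pmax(m1, 0.1)) - b0

  for (iter in seq_len(max_iter)) {
    eta <- b0 + b1 * xr
    mu <- s * exp(pmin(eta, 30))
    w <- mu / (1 + alpha * mu)          # Fisher weights for log link
    r <- (counts - mu) / mu             # working residual factor
    # score and information for (b0, b1)
    u0 <- rowSums(w * r)
    u1 <- rowSums(w * r * xr)
    i00 <- rowSums(w)
    i01 <- rowSums(w * xr)
    i11 <- rowSums(w * xr * xr)
    det <- i00 * i11 - i01^2
    det[det <= 0 | !is.finite(det)] <- NA
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    d0[!is.finite(d0)] <- 0
    d1[!is.finite(d1)] <- 0
    # dampen huge steps for stability at extreme starts
    d0 <- pmax(pmin(d0, 5), -5)
    d1 <- pmax(pmin(d1, 5), -5)
    b0 <- b0 + d0
    b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- b0 + b1 * xr
  mu <- s * exp(pmin(eta, 30))
  w <- mu / (1 + alpha * mu)
  i00 <- rowSums(w)
  i01 <- rowSums(w * xr)
  i11 <- rowSums(w * xr * xr)
  det <- i00 * i11 - i01^2
  se <- sqrt(i00 / det)
  z <- b1 / se
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = b1, se = se, p = p)
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per site, a log-link NB GLM with fixed dispersion and a single
#' group coefficient (treated vs control), with log size factors as
#' offsets, and tests the coefficient with a two-sided Wald z against the
#' standard normal. The reported `log2fc` is the log2 ratio of group mean
#' normalized counts with a pseudocount of 0.5 added to each group mean
#' (treated over control, so loss of signal is negative); the test
#' statistic uses the GLM coefficient. Sites with zero counts throughout
#' are untestable: `p = 1`, `log2fc = 0`.
#'
#' @param treated_counts matrix (or vector) of treated-sample counts,
#'   sites x samples.
#' @param control_counts matching control-sample counts.
#' @param size_factors per-sample size factors (divisors), ordered as
#'   `cbind(treated, control)` columns; default all 1.
#' @param alpha fixed NB dispersion, scalar or per site.
#' @return data.frame: `base_mean` (mean normalized count over all
#'   samples), `log2fc`, `se` (of the log2 coefficient), `p`, `untestable`.
#' @export
nb_wald_test <- function(treated_counts, control_counts, size_factors = NULL,
                         alpha = 0.05) {
  tm <- as.matrix(treated_counts)
  cmat <- as.matrix(control_counts)
  if (is.null(dim(treated_counts))) tm <- matrix(treated_counts, nrow = 1)
  if (is.null(dim(control_counts))) cmat <- matrix(control_counts, nrow = 1)
  if (nrow(tm) != nrow(cmat)) stop("site dimension mismatch")
  counts <- cbind(tm, cmat)
  x <- c(rep(1, ncol(tm)), rep(0, ncol(cmat)))
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  norm <- sweep(counts, 2, size_factors, "/")
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  log2fc <- log2((m1 + 0.5) / (m0 + 0.5))
  base_mean <- rowMeans(norm)
  untestable <- rowSums(counts) == 0

  fit <- nb_wald_fit(counts, x, size_factors, alpha)
  se2 <- fit$se / log(2)
  p <- fit$p
  p[untestable] <- 1
  log2fc[untestable] <- 0
  se2[untestable] <- NA
  p[is.na(p) & !untestable] <- 1
  data.frame(
    base_mean = base_mean, log2fc = log2fc, se = se2, p = p,
    untestable = untestable,
    row.names = rownames(counts) %||% NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity, applied per contrast (all
#' sites of one assay and timepoint together). `NA`/`NaN` p-values are
#' excluded from the ranking and propagated as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Default analysis thresholds
#'
#' The significance rule for all marks is `q < q_max` and
#' `|log2fc| > lfc_min` (both strict). Windows: promoter attribution
#' within +/- 1 kb of a TSS, intergenic means more than 3 kb away. ATAC
#' fragment classes: nucleosome-free below 120 bp, mono-nucleosome
#' 130-200 bp inclusive.
#'
#' @param q_max,lfc_min,promoter_window,intergenic_min,nfr_max,mono_range
#'   threshold overrides.
#' @return named list of thresholds.
#' @export
analysis_thresholds <- function(q_max = 0.05, lfc_min = 0.58,
                                promoter_window = 1000, intergenic_min = 3000,
                                nfr_max = 119, mono_range = c(130, 200)) {
  stopifnot(q_max > 0, lfc_min >= 0, promoter_window > 0, intergenic_min > 0,
            nfr_max > 0, length(mono_range) == 2, all(mono_range > 0))
  list(q_max = q_max, lfc_min = lfc_min, promoter_window = promoter_window,
       intergenic_min = intergenic_min, nfr_max = nfr_max,
       mono_range = mono_range)
}

#' Call significantly changed sites
#'
#' gain: `q < q_max` and `log2fc > lfc_min`; loss: `q < q_max` and
#' `log2fc < -lfc_min`; otherwise none.
#'
#' @param dt data.frame with `log2fc` and `q` columns.
#' @param th thresholds from [analysis_thresholds()].
#' @return `dt` with a `call` factor column (levels gain/loss/none).
#' @export
call_significant <- function(dt, th = analysis_thresholds()) {
  if (!all(c("log2fc", "q") %in% names(dt))) stop("need log2fc and q columns")
  call <- rep("none", nrow(dt))
  sig <- !is.na(dt$q) & dt$q < th$q_max
  call[sig & dt$log2fc > th$lfc_min] <- "gain"
  call[sig & dt$log2fc < -th$lfc_min] <- "loss"
  dt$call <- factor(call, levels = c("gain", "loss", "none"))
  dt
}

#' Differential testing across a time course
#'
#' Runs the NB Wald test for every treated timepoint against the 0 h
#' control, with per-contrast BH adjustment and threshold calls. Size
#' factors come from minimum-coverage scaling (ChIP/ATAC) or spike-in
#' median-of-ratios (RNA assays with spike-in rows). With two replicates
#' per group a per-site dispersion is practically unidentifiable, so the
#' dispersion is pooled: the median across sites of per-site
#' method-of-moments estimates from within-group residuals of the
#' contrast.
#'
#' @param cm a [count_matrix()] for one assay.
#' @param th thresholds ([analysis_thresholds()]).
#' @param normalization `"min_coverage"` or `"spike_in"`.
#' @param timepoints which treated timepoints to contrast; default all
#'   nonzero timepoints present.
#' @param dispersion optional fixed alpha overriding pooling.
#' @return data.frame with one row per site x contrast: `site_id`,
#'   `timepoint_h`, `base_mean`, `log2fc`, `se`, `p`, `q`, `call`.
#' @export
differential_timecourse <- function(cm, th = analysis_thresholds(),
                                    normalization = c("min_coverage", "spike_in"),
                                    timepoints = NULL, dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  normalization <- match.arg(normalization)
  sf_all <- if (normalization == "spike_in") {
    size_factors_spike_in(cm)
  } else {
    1 / size_factors_min_coverage(cm)   # convert multiplier to divisor
  }
  meta <- cm$samples
  counts <- cm$counts[!cm$spike_in, , drop = FALSE]
  ctrl <- which(meta$timepoint_h == 0)
  if (length(ctrl) == 0L) stop("no 0 h control samples")
  tps <- sort(unique(meta$timepoint_h[meta$timepoint_h > 0]))
  if (!is.null(timepoints)) tps <- tps[tps %in% timepoints]
  res <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    trt <- which(meta$timepoint_h == tps[k])
    sf <- sf_all[c(trt, ctrl)]
    tc <- counts[, trt, drop = FALSE]
    cc <- counts[, ctrl, drop = FALSE]
    alpha <- dispersion
    if (is.null(alpha)) {
      alpha <- pooled_dispersion(cbind(tc, cc),
                                 group = c(rep(1, length(trt)), rep(0, length(ctrl))),
                                 size_factors = sf)
    }
    dt <- nb_wald_test(tc, cc, size_factors = sf, alpha = alpha)
    dt$q <- bh_adjust(replace(dt$p, dt$untestable, NA))
    dt$q[dt$untestable] <- 1
    dt <- call_significant(dt, th)
    dt$site_id <- rownames(counts)
    dt$timepoint_h <- tps[k]
    res[[k]] <- dt
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("site_id", "timepoint_h", "base_mean", "log2fc", "se", "p", "q",
          "call", "untestable")]
}

# Contrast-level pooled dispersion: per-site MoM on within-group residuals
# of normalized counts. With two replicates a per-site variance has one
# degree of freedom, so the site-wise estimates are pooled by their MEAN
# (which is unbiased for the common alpha; a median of df = 1 estimates
# would be biased low by more than half).
pooled_dispersion <- function(counts, group, size_factors, floor = 1e-4) {
  norm <- sweep(counts, 2, size_factors, "/")
  alphas <- numeric(0)
  for (g in unique(group)) {
    y <- norm[, group == g, drop = FALSE]
    if (ncol(y) < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    ok <- m > 1
    alphas <- c(alphas, (v[ok] - m[ok]) / m[ok]^2)
  }
  if (length(alphas) == 0) return(floor)
  max(floor, mean(alphas))
}
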