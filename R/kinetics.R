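# ---------------------------------------------------------------------------
# Kinetic classification of promoters from time-resolved H3K4me3 calls.
#
# fast: significant loss already at the 2 h contrast.
# slow: significant loss at 16 h and at none of 0.5, 2, 4 or 8 h.
# Everything else (including first loss at 0.5 h without a 2 h call, or
# first loss at 4 or 8 h) is "other".
# ---------------------------------------------------------------------------

#' Build a promoter x timepoint significance grid
#'
#' Reshapes a long differential table (one row per site x timepoint) into
#' the call grid consumed by [classify_fast_slow()].
#'
#' @param dt output of [differential_timecourse()] for one mark.
#' @param timepoints timepoints (h) to keep as grid columns; default
#'   `c(0.5, 2, 4, 8, 16)`.
#' @return data.frame: `promoter_id` plus one call column (`"gain"`,
#'   `"loss"`, `"none"`) per timepoint, named `t<hours>`.
#' @export
significance_grid <- function(dt, timepoints = c(0.5, 2, 4, 8, 16)) {
  stopifnot(all(c("site_id", "timepoint_h", "call") %in% names(dt)))
  ids <- unique(dt$site_id)
  grid <- data.frame(promoter_id = ids, stringsAsFactors = FALSE)
  for (tp in timepoints) {
    sub <- dt[dt$timepoint_h == tp, ]
    if (nrow(sub) == 0L) stop("timepoint ", tp, " h absent from table")
    grid[[paste0("t", tp)]] <-
      as.character(sub$call[match(ids, sub$site_id)])
  }
  grid
}

#' Classify promoters as fast, slow, or other
#'
#' Implements the kinetic rule for H3K4me3 loss: a promoter is `fast` when
#' its 2 h contrast is a significant loss; `slow` when the 16 h contrast is
#' a loss and none of the 0.5, 2, 4 or 8 h contrasts are; otherwise
#' `other`. The classes are disjoint by construction.
#'
#' @param grid a [significance_grid()] containing columns `t0.5`, `t2`,
#'   `t4`, `t8`, `t16`.
#' @return data.frame: `promoter_id`, `speed_class` (factor
#'   fast/slow/other).
#' @export
classify_fast_slow <- function(grid) {
  need <- c("t0.5", "t2", "t4", "t8", "t16")
  if (!all(need %in% names(grid))) {
    stop("grid must contain call columns: ", paste(need, collapse = ", "))
  }
  loss <- function(col) !is.na(grid[[col]]) & grid[[col]] == "loss"
  fast <- loss("t2")
  early <- loss("t0.5") | loss("t2") | loss("t4") | loss("t8")
  slow <- loss("t16") & !early
  cls <- ifelse(fast, "fast", ifelse(slow, "slow", "other"))
  data.frame(
    promoter_id = grid$promoter_id,
    speed_class = factor(cls, levels = c("fast", "slow", "other")),
    stringsAsFactors = FALSE
  )
}

#' Split sites into high / medium / low intensity tertiles
#'
#' Sites are ranked by intensity, descending, ties broken by site id, and
#' split into three contiguous rank blocks whose sizes differ by at most
#' one (extra sites go to the higher blocks first, so n = 4 gives sizes
#' 2, 1, 1). The labels are independent of input order.
#'
#' @param intensity numeric signal per site (e.g. mean normalized control
#'   signal).
#' @param ids site identifiers (used for deterministic tie-breaking).
#' @return factor of labels `high`/`medium`/`low`, in input order.
#' @export
tertile_split <- function(intensity, ids = NULL) {
  n <- length(intensity)
  if (n < 3L) stop("need at least 3 sites for a tertile split")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyDuplicated(ids)) stop("site ids must be unique")
  ord <- order(-intensity, ids)
  q <- n %/% 3L
  r <- n %% 3L
  sizes <- c(q + (r >= 1L), q + (r >= 2L), q)
  lab_sorted <- rep(c("high", "medium", "low"), times = sizes)
  out <- character(n)
  out[ord] <- lab_sorted
  factor(out, levels = c("high", "medium", "low"))
}

#' Per-class log2 fold-change trajectories
#'
#' Median and quartiles of per-promoter log2 fold changes of one mark, per
#' class and timepoint — the numeric content of class-trajectory boxplots.
#'
#' @param classes data.frame with `promoter_id` and a class column
#'   (`speed_class` or `tertile`).
#' @param dt long differential table for the mark ([differential_timecourse()]).
#' @param class_col name of the class column (default `"speed_class"`).
#' @return data.frame: class, `timepoint_h`, `n`, `median`, `q1`, `q3`.
#'   Timepoints with no data for a class are omitted; an empty class keeps
#'   rows with `n = 0` and `NaN` statistics.
#' @export
trajectory_summary <- function(classes, dt, class_col = "speed_class") {
  stopifnot(class_col %in% names(classes))
  tps <- sort(unique(dt$timepoint_h))
  lvls <- levels(factor(classes[[class_col]]))
  rows <- list()
  for (cl in lvls) {
    members <- classes$promoter_id[classes[[class_col]] == cl &
                                     !is.na(classes[[class_col]])]
    for (tp in tps) {
      sub <- dt[dt$timepoint_h == tp & dt$site_id %in% members, ]
      if (length(members) > 0L && nrow(sub) == 0L) next
      lfc <- sub$log2fc
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, timepoint_h = tp, n = length(lfc),
        median = if (length(lfc)) stats::median(lfc) else NaN,
        q1 = if (length(lfc)) unname(stats::quantile(lfc, 0.25)) else NaN,
        q3 = if (length(lfc)) unname(stats::quantile(lfc, 0.75)) else NaN,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Link kinetic classes to late gene-expression changes
#'
#' Counts, per kinetic class, how many linked genes are up, down, or
#' unchanged in a late RNA contrast (typically 24 h). Genes reached by
#' several promoters of a class are counted once; conflicting calls for
#' one gene resolve with precedence loss > gain > none.
#'
#' @param classes data.frame with `promoter_id` and `speed_class`.
#' @param rna_calls data.frame with `gene_id` and `call` (gain/loss/none)
#'   for the late RNA contrast.
#' @param promoter_genes data.frame mapping `promoter_id` to `gene_id`.
#' @return data.frame per class: `up`, `down`, `unchanged`, `unmatched`
#'   (promoters whose gene is absent from the RNA table).
#' @export
expression_by_class <- function(classes, rna_calls, promoter_genes) {
  stopifnot(all(c("promoter_id", "gene_id") %in% names(promoter_genes)))
  # resolve duplicated gene rows with precedence loss > gain > none
  prec <- order(factor(as.character(rna_calls$call),
                       levels = c("loss", "gain", "none")))
  rna_calls <- rna_calls[prec, , drop = FALSE]
  rna_calls <- rna_calls[!duplicated(rna_calls$gene_id), , drop = FALSE]
  rows <- list()
  for (cl in levels(factor(classes$speed_class))) {
    prom <- classes$promoter_id[classes$speed_class == cl]
    genes <- promoter_genes$gene_id[match(prom, promoter_genes$promoter_id)]
    unmatched_prom <- sum(is.na(genes))
    genes <- unique(genes[!is.na(genes)])
    calls <- as.character(rna_calls$call[match(genes, rna_calls$gene_id)])
    unmatched <- unmatched_prom + sum(is.na(calls))
    calls <- calls[!is.na(calls)]
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl,
      up = sum(calls == "gain"),
      down = sum(calls == "loss"),
      unchanged = sum(calls == "none"),
      unmatched = unmatched,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
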