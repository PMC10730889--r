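# ---------------------------------------------------------------------------
# Cross-mark integration: promoter Venn overlaps, TF-activity filtering,
# MA summaries, and the machine-readable run report.
# ---------------------------------------------------------------------------

#' Three-way promoter overlap counts
#'
#' Exact set-algebra counts of the seven regions of a three-set Venn
#' diagram, for promoter id sets such as H3K4me3-loss, H3K4me1-gain and
#' H3K27ac-loss.
#'
#' @param a,b,c character vectors of promoter ids (duplicates ignored).
#' @param labels names of the three sets, used in the output keys.
#' @return named integer vector with the seven exclusive region counts
#'   (`a_only`, ..., `a_b`, ..., `a_b_c`) plus `union`.
#' @export
promoter_mark_venn <- function(a, b, c,
                               labels = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(base::c(a, b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  key <- paste0(as.integer(in_a), as.integer(in_b), as.integer(in_c))
  cnt <- function(k) sum(key == k)
  out <- c(
    cnt("100"), cnt("010"), cnt("001"),
    cnt("110"), cnt("101"), cnt("011"),
    cnt("111"), length(u)
  )
  names(out) <- c(
    paste0(labels[1], "_only"), paste0(labels[2], "_only"),
    paste0(labels[3], "_only"),
    paste(labels[1], labels[2], sep = "_"),
    paste(labels[1], labels[3], sep = "_"),
    paste(labels[2], labels[3], sep = "_"),
    paste(labels, collapse = "_"), "union"
  )
  out
}

#' Filter TF footprint activity records
#'
#' Keeps transcription factors with more than `min_sites` identified
#' binding sites (strictly over) and significant differential activity
#' (`q < q_max`, strict). Footprint scores are consumed, not computed.
#'
#' @param records data.frame with columns `tf_name`, `n_sites`,
#'   `activity_change`, `p`, `q`.
#' @param min_sites site-count bound (default 1000, exclusive).
#' @param q_max significance bound (default 0.05, exclusive).
#' @return the highlighted subset, same columns.
#' @export
tf_activity_filter <- function(records, min_sites = 1000, q_max = 0.05) {
  stopifnot(all(c("n_sites", "q") %in% names(records)))
  if (any(records$n_sites < 0)) stop("n_sites must be >= 0")
  records[records$n_sites > min_sites & !is.na(records$q) &
            records$q < q_max, , drop = FALSE]
}

#' MA table for one contrast
#'
#' @param dt differential table for a single contrast (one row per site).
#' @return data.frame `site_id`, `base_mean`, `log2fc`, `call` — the
#'   numeric content of an MA plot.
#' @export
ma_table <- function(dt) {
  stopifnot(all(c("base_mean", "log2fc", "call") %in% names(dt)))
  out <- data.frame(
    site_id = if ("site_id" %in% names(dt)) dt$site_id else rownames(dt),
    base_mean = dt$base_mean,
    log2fc = dt$log2fc,
    call = dt$call,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Assemble the structured run report
#'
#' Collects per-mark changed-site counts by timepoint and direction with
#' promoter / non-promoter attribution, kinetic class sizes, enhancer
#' counts, thresholds and the seed into one JSON-serializable list.
#' Missing stages are reported as absent, not fatal. Two runs with the
#' same seed and configuration serialize byte-identically (no
#' timestamps).
#'
#' @param diff_tables named list (per mark) of [differential_timecourse()]
#'   outputs, each optionally carrying a `promoter` logical column.
#' @param class_table [classify_fast_slow()] output, or NULL.
#' @param enhancers enhancer `GRanges`, or NULL.
#' @param venn [promoter_mark_venn()] output, or NULL.
#' @param thresholds [analysis_thresholds()].
#' @param seed integer seed the run used.
#' @return list of class `ck_report`.
#' @export
run_report <- function(diff_tables = list(), class_table = NULL,
                       enhancers = NULL, venn = NULL,
                       thresholds = analysis_thresholds(), seed = NA) {
  marks <- list()
  for (mk in names(diff_tables)) {
    dt <- diff_tables[[mk]]
    per_tp <- list()
    for (tp in sort(unique(dt$timepoint_h))) {
      sub <- dt[dt$timepoint_h == tp, ]
      entry <- list(
        gain = sum(sub$call == "gain"),
        loss = sum(sub$call == "loss"),
        none = sum(sub$call == "none")
      )
      if ("promoter" %in% names(sub)) {
        changed <- sub$call != "none"
        entry$promoter_associated <- sum(changed & sub$promoter %in% TRUE)
        entry$remaining_genome <- sum(changed & !(sub$promoter %in% TRUE))
      }
      per_tp[[paste0("t", tp)]] <- entry
    }
    marks[[mk]] <- per_tp
  }
  classes <- if (is.null(class_table)) "absent" else {
    as.list(table(class_table$speed_class))
  }
  report <- list(
    package = "chromkinetics",
    version = as.character(utils::packageVersion("chromkinetics")),
    seed = seed,
    thresholds = thresholds,
    marks = if (length(marks)) marks else "absent",
    kinetic_classes = classes,
    n_enhancers = if (is.null(enhancers)) "absent" else length(enhancers),
    venn = if (is.null(venn)) "absent" else as.list(venn)
  )
  class(report) <- "ck_report"
  report
}

#' Write a run report as JSON (and a text summary)
#'
#' @param report a `ck_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.ck_report <- function(x, ...) {
  cat("chromkinetics run report (seed", x$seed, ")\n")
  if (!identical(x$marks, "absent")) {
    for (mk in names(x$marks)) {
      tps <- names(x$marks[[mk]])
      tot <- sum(vapply(x$marks[[mk]],
                        function(e) e$gain + e$loss, numeric(1)))
      cat("  ", mk, ": ", tot, " changed site-contrasts over ",
          length(tps), " timepoints\n", sep = "")
    }
  }
  if (!identical(x$kinetic_classes, "absent")) {
    cat("  kinetic classes:",
        paste(names(x$kinetic_classes), unlist(x$kinetic_classes),
              sep = "=", collapse = ", "), "\n")
  }
  if (!identical(x$n_enhancers, "absent")) {
    cat("  enhancers:", x$n_enhancers, "\n")
  }
  invisible(x)
}
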