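# ---------------------------------------------------------------------------
# End-to-end pipeline on a simulated experiment: differential testing per
# mark, promoter attribution, kinetic classification, tertiles, CGI
# stratification, enhancer definition and overlap, cross-mark Venn, and
# the run report.
# ---------------------------------------------------------------------------

#' Run the full analysis pipeline on a simulated experiment
#'
#' @param cfg a [simulation_config()], or an existing
#'   [simulate_experiment()] result.
#' @param th thresholds ([analysis_thresholds()]).
#' @return list of class `ck_run`: the simulation, per-mark differential
#'   tables, significance grid, kinetic classes (`speed_class` and
#'   `tertile`), trajectory summaries, CGI stratification, enhancers and
#'   their overlap with changed intergenic sites, promoter Venn counts,
#'   expression linkage, and the [run_report()].
#' @export
run_pipeline <- function(cfg = simulation_config(),
                         th = analysis_thresholds()) {
  sim <- if (inherits(cfg, "sim_experiment")) cfg else simulate_experiment(cfg)
  cfg <- sim$config
  ann <- sim$annotation
  idx <- tss_index(ann$tss)

  # per-mark differential tables (each timepoint vs the 0 h control)
  diff <- list()
  for (mk in names(sim$marks)) {
    diff[[mk]] <- differential_timecourse(sim$marks[[mk]], th)
  }
  diff$ATAC <- differential_timecourse(sim$atac$counts, th)
  diff$RNA <- differential_timecourse(sim$rna$counts, th,
                                      normalization = "spike_in")

  # promoter attribution of changed sites (site regions = their windows)
  site_regions <- c(ann$promoter_windows, ann$enhancer_truth)
  assoc <- classify_promoter_association(site_regions, idx,
                                         window = th$promoter_window)
  promoter_of_site <- stats::setNames(assoc$promoter, names(site_regions))
  for (mk in names(diff)) {
    if (mk == "RNA") next
    diff[[mk]]$promoter <- unname(promoter_of_site[diff[[mk]]$site_id])
  }

  # kinetic classification from the H3K4me3 grid
  me3 <- diff$H3K4me3[diff$H3K4me3$site_id %in% ann$truth$promoter_id, ]
  grid <- significance_grid(me3)
  classes <- classify_fast_slow(grid)

  # intensity tertiles on mean normalized control H3K4me3 signal
  cm <- sim$marks$H3K4me3
  mult <- size_factors_min_coverage(cm)
  ctrl <- cm$samples$timepoint_h == 0
  norm_ctrl <- sweep(cm$counts[, ctrl, drop = FALSE], 2, mult[ctrl], "*")
  prom_rows <- rownames(cm$counts) %in% ann$truth$promoter_id
  intensity <- rowMeans(norm_ctrl[prom_rows, , drop = FALSE])
  tert <- tertile_split(intensity, ids = rownames(norm_ctrl)[prom_rows])
  classes$tertile <- tert[match(classes$promoter_id,
                                rownames(norm_ctrl)[prom_rows])]

  trajectories <- list()
  for (mk in c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC")) {
    trajectories[[mk]] <- trajectory_summary(classes, diff[[mk]])
  }

  # CGI stratification of changed H3K4me3 promoter sites at 16 h
  cgi_prom <- classify_cgi_promoters(ann$tss, ann$cgis,
                                     window = th$promoter_window)
  changed16 <- diff$H3K4me3[diff$H3K4me3$timepoint_h == 16 &
                              diff$H3K4me3$call != "none", ]
  changed_gr <- ann$promoter_windows[match(changed16$site_id,
                                           names(ann$promoter_windows))]
  S4Vectors::mcols(changed_gr)$call <- as.character(changed16$call)
  cgi_strat <- cgi_stratify(changed_gr, idx, cgi_prom, window = 3000)

  # enhancer definition from untreated peak sets
  tss_win <- window_around_tss(ann$tss, flank = th$promoter_window,
                               chrom_length = ann$chrom_lengths)
  enhancers <- define_enhancers(sim$peaks$H3K4me1, sim$peaks$H3K27ac,
                                sim$peaks$ATAC, tss_win)

  # changed intergenic H3K4me1/H3K27ac (16 h) and ATAC (24 h) vs enhancers
  enhancer_overlap <- list()
  for (spec in list(c("H3K4me1", 16), c("H3K27ac", 16), c("ATAC", 24))) {
    mk <- spec[1]; tp <- as.numeric(spec[2])
    ch <- diff[[mk]][diff[[mk]]$timepoint_h == tp &
                       diff[[mk]]$call != "none", ]
    gr <- site_regions[match(ch$site_id, names(site_regions))]
    S4Vectors::mcols(gr)$call <- as.character(ch$call)
    gr <- intergenic_filter(gr, idx, min_distance = th$intergenic_min)
    enhancer_overlap[[mk]] <- enhancer_overlap_summary(gr, enhancers)
  }

  # cross-mark promoter Venn at 16 h
  pick <- function(mk, dir, tp = 16) {
    d <- diff[[mk]]
    d$site_id[d$timepoint_h == tp & d$call == dir &
                d$site_id %in% ann$truth$promoter_id]
  }
  venn <- promoter_mark_venn(pick("H3K4me3", "loss"),
                             pick("H3K4me1", "gain"),
                             pick("H3K27ac", "loss"),
                             labels = c("me3_loss", "me1_gain",
                                        "k27ac_loss"))

  # late expression linkage
  rna24 <- diff$RNA[diff$RNA$timepoint_h == 24, ]
  rna24$gene_id <- rna24$site_id
  expression <- expression_by_class(
    classes, rna24,
    ann$truth[, c("promoter_id", "gene_id")]
  )

  report <- run_report(diff_tables = diff[names(diff) != "RNA"],
                       class_table = classes, enhancers = enhancers,
                       venn = venn, thresholds = th, seed = cfg$seed)

  structure(
    list(sim = sim, diff = diff, grid = grid, classes = classes,
         trajectories = trajectories, cgi_stratification = cgi_strat,
         enhancers = enhancers, enhancer_overlap = enhancer_overlap,
         venn = venn, expression = expression, report = report),
    class = "ck_run"
  )
}

#' @export
print.ck_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write generator output), `all` (simulate and
#' run the full pipeline, writing the report and stage tables). Shared
#' flags: `--seed`, `--out`, `--config` (YAML), `--q-max`, `--lfc-min`,
#' `--promoter-window`, `--intergenic-min`. Returns a shell exit code (0
#' on success, 2 on usage errors) rather than calling `quit()`, so it is
#' testable; wrap it in a small Rscript for shell use (see
#' `system.file("scripts", "chromkinetics", package = "chromkinetics")`).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: chromkinetics <simulate|all> [--seed N] [--out DIR]",
    "[--config FILE] [--q-max X] [--lfc-min X]",
    "[--promoter-window N] [--intergenic-min N]"
  )
  if (length(args) == 0L) {
    message(usage)
    return(2L)
  }
  sub <- args[1]
  if (!sub %in% c("simulate", "all")) {
    message("unknown subcommand '", sub, "'\n", usage)
    return(2L)
  }
  opts <- list(seed = 1, out = "chromkinetics_out", q_max = 0.05,
               lfc_min = 0.58, promoter_window = 1000,
               intergenic_min = 3000)
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    flag <- rest[i]
    key <- switch(flag,
                  "--seed" = "seed", "--out" = "out", "--config" = "config",
                  "--q-max" = "q_max", "--lfc-min" = "lfc_min",
                  "--promoter-window" = "promoter_window",
                  "--intergenic-min" = "intergenic_min", NULL)
    if (is.null(key)) {
      message("unknown flag '", flag, "'\n", usage)
      return(2L)
    }
    if (i == length(rest)) {
      message("flag '", flag, "' needs a value\n", usage)
      return(2L)
    }
    val <- rest[i + 1L]
    opts[[key]] <- if (key %in% c("out", "config")) val else as.numeric(val)
    i <- i + 2L
  }
  cfg_over <- list()
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) {
      message("config file not found: ", opts$config)
      return(2L)
    }
    cfg_over <- read_config(opts$config)
    for (k in intersect(names(cfg_over),
                        c("q_max", "lfc_min", "promoter_window",
                          "intergenic_min", "seed"))) {
      opts[[k]] <- cfg_over[[k]]
    }
  }
  sim_args <- cfg_over[names(cfg_over) %in% names(formals(simulation_config))]
  sim_args <- lapply(sim_args, function(x) if (is.list(x)) unlist(x) else x)
  sim_args$seed <- opts$seed
  cfg <- do.call(simulation_config, sim_args)
  th <- analysis_thresholds(q_max = opts$q_max, lfc_min = opts$lfc_min,
                            promoter_window = opts$promoter_window,
                            intergenic_min = opts$intergenic_min)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  message("chromkinetics ", as.character(utils::packageVersion("chromkinetics")),
          " | ", sub, " | seed=", opts$seed,
          " q_max=", th$q_max, " lfc_min=", th$lfc_min)
  sim <- simulate_experiment(cfg)
  write_simulation(sim, file.path(opts$out, "simulated"))
  if (sub == "all") {
    run <- run_pipeline(sim, th)
    write_report(run$report, file.path(opts$out, "report.json"))
    write.table(run$classes, file.path(opts$out, "kinetic_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(run$cgi_stratification,
                file.path(opts$out, "cgi_stratification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(run$enhancers, file.path(opts$out, "enhancers.bed"))
    for (mk in names(run$diff)) {
      write.table(run$diff[[mk]],
                  file.path(opts$out, paste0("differential_", mk, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  0L
}
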