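# ---------------------------------------------------------------------------
# Readers and writers for the plain-text interchange formats: BED3/6,
# ENCODE narrowPeak, UCSC cpgIslandExt dumps, counts TSV + sample sheet,
# fragment BED, YAML config. All coordinates on disk are BED-style
# (0-based half-open); parsers reject malformed input with line numbers.
# ---------------------------------------------------------------------------

read_lines_nocomment <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_int_col <- function(x, lineno, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    stop(sprintf("%s: line %d: non-integer %s '%s'",
                 path, lineno[which(bad)[1]], what, x[which(bad)[1]]))
  }
  v
}

#' Read a BED file as a region set
#'
#' Accepts 3+ tab-separated columns; `track`, `browser` and `#` lines are
#' skipped. Column 4 (name), when present, becomes region ids; column 6
#' the strand.
#'
#' @param path BED file path.
#' @return `GRanges` (0-based half-open intervals preserved exactly).
#' @export
read_bed <- function(path) {
  lc <- read_lines_nocomment(path)
  if (length(lc$lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lc$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop(sprintf("%s: line %d: fewer than 3 BED columns",
                 path, lc$lineno[which(ncol < 3L)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_int_col(vapply(fields, `[[`, "", 2L), lc$lineno,
                         "start", path)
  end <- parse_int_col(vapply(fields, `[[`, "", 3L), lc$lineno, "end", path)
  bad <- start >= end
  if (any(bad)) {
    stop(sprintf("%s: line %d: start >= end", path,
                 lc$lineno[which(bad)[1]]))
  }
  id <- if (all(ncol >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  if (!is.null(id) && anyDuplicated(id)) id <- NULL
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "*"
  }, "")
  regions(chrom, start, end, strand = strand, id = id)
}

#' Write a region set as BED
#'
#' @param gr `GRanges`.
#' @param path output path.
#' @param scores optional numeric column 5.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, scores = NULL) {
  df <- regions_df(gr)
  name <- if (!is.null(df$id)) df$id else rep(".", nrow(df))
  score <- if (!is.null(scores)) scores else rep(0L, nrow(df))
  out <- data.frame(df$chrom, df$start, df$end, name, score, df$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' Ten tab-separated columns; the summit is `start + offset` (column 10),
#' undefined when the offset is -1.
#'
#' @param path narrowPeak path.
#' @return `GRanges` with metadata columns `score`, `signal_value`,
#'   `p_score`, `q_score`, `summit` (0-based bp; NA when undefined).
#' @export
read_narrowpeak <- function(path) {
  lc <- read_lines_nocomment(path)
  if (length(lc$lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lc$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 10L)) {
    stop(sprintf("%s: line %d: narrowPeak requires 10 columns, found %d",
                 path, lc$lineno[which(ncol != 10L)[1]],
                 ncol[which(ncol != 10L)[1]]))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  start <- parse_int_col(col(2), lc$lineno, "start", path)
  end <- parse_int_col(col(3), lc$lineno, "end", path)
  offset <- parse_int_col(col(10), lc$lineno, "summit offset", path)
  id <- col(4)
  if (anyDuplicated(id)) id <- NULL
  strand <- ifelse(col(6) %in% c("+", "-"), col(6), "*")
  gr <- regions(col(1), start, end, strand = strand, id = id)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = col(4),
    score = as.numeric(col(5)),
    signal_value = as.numeric(col(7)),
    p_score = as.numeric(col(8)),
    q_score = as.numeric(col(9)),
    summit = ifelse(offset < 0, NA_real_, start + offset)
  )
  gr
}

#' Write a narrowPeak file
#'
#' @param gr `GRanges` with the metadata columns produced by
#'   [read_narrowpeak()] (missing ones get placeholders).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  df <- regions_df(gr)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  getcol <- function(nm, default) if (nm %in% names(mc)) mc[[nm]] else default
  n <- nrow(df)
  name <- getcol("name", if (!is.null(df$id)) df$id else rep(".", n))
  summit <- getcol("summit", rep(NA_real_, n))
  offset <- ifelse(is.na(summit), -1, summit - df$start)
  out <- data.frame(df$chrom, df$start, df$end, name,
                    getcol("score", rep(0, n)), df$strand,
                    getcol("signal_value", rep(0, n)),
                    getcol("p_score", rep(-1, n)),
                    getcol("q_score", rep(-1, n)), offset)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read CpG islands in the UCSC cpgIslandExt dialect
#'
#' Accepts UCSC table dumps with or without the leading numeric `bin`
#' column: the layout is auto-detected by checking whether column 1 is
#' integer and column 2 a chromosome name (non-numeric).
#'
#' @param path cpgIslandExt-style file.
#' @return `GRanges` of CpG islands with island names as ids when unique.
#' @export
read_cpg_islands <- function(path) {
  lc <- read_lines_nocomment(path)
  if (length(lc$lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lc$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 4L)) {
    stop(sprintf("%s: line %d: expected cpgIslandExt layout (with or without bin column): chrom, chromStart, chromEnd, name",
                 path, lc$lineno[which(ncol < 4L)[1]]))
  }
  first <- vapply(fields, `[[`, "", 1L)
  second <- vapply(fields, `[[`, "", 2L)
  has_bin <- all(grepl("^[0-9]+$", first)) &&
    !all(grepl("^[0-9]+$", second))
  off <- if (has_bin) 1L else 0L
  if (any(ncol < off + 3L)) {
    stop(sprintf("%s: line %d: expected cpgIslandExt layout (with or without bin column)",
                 path, lc$lineno[1]))
  }
  col <- function(i) vapply(fields, `[[`, "", i + off)
  start <- parse_int_col(col(2), lc$lineno, "chromStart", path)
  end <- parse_int_col(col(3), lc$lineno, "chromEnd", path)
  id <- if (all(ncol >= off + 4L)) col(4) else NULL
  if (!is.null(id) && anyDuplicated(id)) id <- NULL
  regions(col(1), start, end, id = id)
}

#' Write CpG islands in cpgIslandExt layout (without bin column)
#'
#' @param gr `GRanges` of islands.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_islands <- function(gr, path) {
  df <- regions_df(gr)
  name <- if (!is.null(df$id)) df$id else sprintf("CpG:_%d", seq_len(nrow(df)))
  out <- data.frame(df$chrom, df$start, df$end, name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a counts TSV plus sample sheet into a count matrix
#'
#' The counts file has a `site_id` column then one integer column per
#' sample; the sample sheet columns are `sample_id`, `assay`,
#' `timepoint_h`, `replicate`, `treated`. Header sample ids must match
#' the sheet exactly; rows with ids starting `ERCC-` are flagged as
#' spike-ins.
#'
#' @param path_counts counts TSV.
#' @param path_samplesheet sample sheet TSV.
#' @param spike_prefix spike-in id prefix (default `"ERCC-"`).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path_counts, path_samplesheet,
                        spike_prefix = "ERCC-") {
  tab <- read.delim(path_counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "site_id") {
    stop(path_counts, ": first column must be 'site_id'")
  }
  if (anyDuplicated(tab$site_id)) {
    stop(path_counts, ": duplicated site id '",
         tab$site_id[duplicated(tab$site_id)][1], "'")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    stop(path_counts, ": counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab$site_id
  sheet <- read.delim(path_samplesheet, stringsAsFactors = FALSE)
  if (!identical(colnames(m), sheet$sample_id)) {
    stop("sample ids in ", path_counts,
         " do not match the sample sheet ", path_samplesheet)
  }
  sheet$treated <- as.logical(sheet$treated)
  count_matrix(m, sheet, spike_prefix = spike_prefix)
}

#' Write a count matrix as counts TSV + sample sheet TSV
#'
#' @param cm a [count_matrix()].
#' @param path_counts,path_samplesheet output paths.
#' @return `path_counts`, invisibly.
#' @export
write_counts <- function(cm, path_counts, path_samplesheet) {
  tab <- data.frame(site_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path_counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cm$samples, path_samplesheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_counts)
}

#' Write a TSS table TSV
#' @param tss TSS data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS table TSV
#' @param path TSV with columns chrom, position, strand, transcript_id
#'   (and optionally gene_id, promoter_id).
#' @return data.frame.
#' @export
read_tss <- function(path) {
  tss <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "position", "strand", "transcript_id")
  if (!all(required %in% names(tss))) {
    stop(path, ": TSS table needs columns ",
         paste(required, collapse = ", "))
  }
  tss
}

#' Read a pipeline configuration (YAML or flat key=value / key: value)
#'
#' @param path config file.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.list(cfg)) return(cfg)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "[=:]\\s*")
  if (any(lengths(kv) != 2L)) stop(path, ": cannot parse configuration")
  vals <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(x[2]))
    if (is.na(v)) x[2] else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 1L))
}

#' Write the emitted files of a simulated experiment
#'
#' Emits, under `dir`: TSS TSV, CGI file, per-mark control peak BEDs,
#' per-assay counts + sample sheet TSVs, per-sample fragment BEDs, and
#' the ground-truth table as JSON.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$annotation
  write_tss(ann$tss, file.path(dir, "tss.tsv"))
  write_cpg_islands(ann$cgis, file.path(dir, "cpg_islands.txt"))
  for (mk in names(sim$peaks)) {
    write_bed(sim$peaks[[mk]], file.path(dir, paste0("peaks_", mk, ".bed")))
  }
  for (mk in names(sim$marks)) {
    write_counts(sim$marks[[mk]],
                 file.path(dir, paste0("counts_", mk, ".tsv")),
                 file.path(dir, paste0("samples_", mk, ".tsv")))
  }
  write_counts(sim$atac$counts, file.path(dir, "counts_ATAC.tsv"),
               file.path(dir, "samples_ATAC.tsv"))
  write_counts(sim$rna$counts, file.path(dir, "counts_RNA.tsv"),
               file.path(dir, "samples_RNA.tsv"))
  frag_dir <- file.path(dir, "fragments")
  dir.create(frag_dir, showWarnings = FALSE)
  for (sid in names(sim$atac$fragments)) {
    write_bed(sim$atac$fragments[[sid]],
              file.path(frag_dir, paste0(sid, ".bed")))
  }
  write_bed(ann$enhancer_truth, file.path(dir, "enhancer_truth.bed"))
  jsonlite::write_json(ann$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
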