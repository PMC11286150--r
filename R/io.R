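## File formats.  On disk, pore-model tables store the level standard
## deviation (the community convention); internally the package works in
## variances, converting only at this boundary.  All writers order rows
## deterministically (lexicographic k-mer, ascending position).

#' Write an emission table as a pore-model TSV
#'
#' Columns `kmer`, `level_mean`, `level_stdv` and (for emission tables) a
#' `provenance` column; rows sorted by k-mer.
#'
#' @param x An `emission_table` or `pore_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pore_model <- function(x, path) {
  df <- data.frame(kmer = x$kmer,
                   level_mean = x$mean,
                   level_stdv = sqrt(x$var))
  if (!is.null(x$provenance)) df$provenance <- x$provenance
  df <- df[order(df$kmer), , drop = FALSE]
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pore-model TSV into an emission table
#'
#' Expects columns `kmer`, `level_mean`, `level_stdv` and an optional
#' `provenance` column (defaulting to `"learned"`).  Variance is the square
#' of the on-disk standard deviation.  Duplicate k-mers, non-positive
#' standard deviations or bad symbols raise a parse error naming the
#' offending line.
#'
#' @param path Input path.
#' @param min_events Support threshold to record on the table.
#' @return An `emission_table`.
#' @export
read_pore_model <- function(path, min_events = 10L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kmer", "level_mean", "level_stdv")
  if (!all(need %in% colnames(df)))
    stop("pore-model file must have columns ", paste(need, collapse = ", "))
  lineno <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- !grepl("^[ACGTM]+$", df$kmer)
  if (any(bad))
    stop("bad k-mer symbol at line ", lineno[which(bad)[1L]], ": ",
         df$kmer[which(bad)[1L]])
  dup <- duplicated(df$kmer)
  if (any(dup))
    stop("duplicate k-mer at line ", lineno[which(dup)[1L]], ": ",
         df$kmer[which(dup)[1L]])
  nonpos <- !is.finite(df$level_stdv) | df$level_stdv <= 0
  if (any(nonpos))
    stop("non-positive level_stdv at line ", lineno[which(nonpos)[1L]])
  prov <- if ("provenance" %in% colnames(df)) df$provenance
          else rep("learned", nrow(df))
  emission_table(df$kmer, df$level_mean, df$level_stdv^2, prov,
                 min_events = min_events)
}

#' Write / read an aligned-event table
#'
#' TSV with columns `read_id`, `position` (0-based k-mer start), `kmer`,
#' `current`; rows ordered by read then position.
#'
#' @param events Event `data.frame`.
#' @param path File path.
#' @return `path` (writer, invisibly) or the event `data.frame` (reader).
#' @export
write_events <- function(events, path) {
  ev <- events[order(events$read_id, events$position), , drop = FALSE]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "position", "kmer", "current")
  if (!all(need %in% colnames(df)))
    stop("event file must have columns ", paste(need, collapse = ", "))
  df
}

#' Write site calls
#'
#' TSV dialect: columns `position`, `llr` (6 decimal places), `call`,
#' `coverage`.  BED dialect: 0-based half-open intervals of length 2 (the
#' CG dinucleotide) with the call state and coverage.
#'
#' @param calls `data.frame` with `position`, `llr`, `call`, `coverage`
#'   (e.g. the `sites` element of [call_sites()]).
#' @param path Output path.
#' @param dialect `"tsv"` or `"bed"`.
#' @param chrom Chromosome name for the BED dialect.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, dialect = c("tsv", "bed"),
                        chrom = "ref") {
  dialect <- match.arg(dialect)
  calls <- calls[order(calls$position), , drop = FALSE]
  if (dialect == "tsv") {
    df <- data.frame(position = calls$position,
                     llr = sprintf("%.6f", calls$llr),
                     call = ifelse(calls$call, "methylated", "unmethylated"),
                     coverage = calls$coverage)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(chrom = chrom,
                     start = calls$position,
                     end = calls$position + 2L,
                     state = ifelse(calls$call, "methylated",
                                    "unmethylated"),
                     coverage = calls$coverage)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$call <- df$call == "methylated"
  df
}

#' Write / read site labels as BED-like text
#'
#' Columns: chrom, start, end (0-based half-open CG interval), state,
#' coverage.
#'
#' @param labels Output of [filter_confident_sites()].
#' @param path File path.
#' @param chrom Chromosome name.
#' @return `path` (writer, invisibly) or a labels `data.frame` (reader).
#' @export
write_site_labels <- function(labels, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = labels$position,
                   end = labels$position + 2L, state = labels$state,
                   coverage = labels$coverage)
  write.table(df[order(df$start), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_site_labels
#' @export
read_site_labels <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("chrom", "start", "end", "state", "coverage")
  data.frame(position = df$start, coverage = df$coverage, state = df$state)
}

#' Write / read a plain-text k-mer list (one k-mer per line)
#'
#' @param kmers Character vector.
#' @param path File path.
#' @return `path` (writer, invisibly) or a character vector (reader).
#' @export
write_kmer_list <- function(kmers, path) {
  writeLines(sort(kmers), path)
  invisible(path)
}

#' @rdname write_kmer_list
#' @export
read_kmer_list <- function(path) {
  kmers <- toupper(trimws(readLines(path)))
  kmers <- kmers[nzchar(kmers)]
  bad <- !grepl("^[ACGTM]+$", kmers)
  if (any(bad)) stop("bad k-mer in list: ", kmers[which(bad)[1L]])
  kmers
}

#' Serialize / load a fitted amortizer as JSON
#'
#' Stores layer sizes, row-major weight matrices, biases, the target
#' standardization constants and a feature-layout version tag.
#'
#' @param predictor A fitted `amortizer`.
#' @param path JSON path.
#' @return `path` (writer, invisibly) or an `amortizer` (reader).
#' @export
write_amortizer <- function(predictor, path) {
  obj <- list(
    feature_version = predictor$feature_version,
    d = predictor$d, h = predictor$h,
    mu_center = predictor$mu_center, mu_scale = predictor$mu_scale,
    shortcut = as.vector(t(predictor$Ws)),        # row-major, nin x 2
    layers = lapply(seq_along(predictor$W), function(l) list(
      nrow = nrow(predictor$W[[l]]), ncol = ncol(predictor$W[[l]]),
      weights = as.vector(t(predictor$W[[l]])),   # row-major
      bias = predictor$b[[l]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_amortizer
#' @export
read_amortizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$feature_version, "mono30.di105.cm6"))
    stop("unsupported feature layout: ", obj$feature_version)
  W <- lapply(seq_len(nrow(obj$layers)), function(l)
    matrix(obj$layers$weights[[l]], obj$layers$nrow[l], obj$layers$ncol[l],
           byrow = TRUE))
  b <- lapply(obj$layers$bias, as.numeric)
  Ws <- matrix(obj$shortcut, nrow = nrow(W[[1L]]), ncol = 2L, byrow = TRUE)
  structure(list(W = W, b = b, Ws = Ws, d = obj$d, h = obj$h,
                 mu_center = obj$mu_center, mu_scale = obj$mu_scale,
                 history = NULL, cfg = NULL,
                 feature_version = obj$feature_version),
            class = "amortizer")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML path.
#' @return An `experiment_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, cfg)
}

#' Write a sweep report as tidy CSV plus a JSON summary
#'
#' @param report Output of [run_p_sweep()].
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  csv <- paste0(prefix, ".csv")
  jsn <- paste0(prefix, ".json")
  utils::write.csv(report, csv, row.names = FALSE, quote = FALSE)
  summ <- summarize_sweep(report)
  jsonlite::write_json(summ, jsn, dataframe = "rows", digits = NA)
  invisible(c(csv, jsn))
}
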