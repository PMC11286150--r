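## Desk-scale experimental protocol: read-level folds, k-mer panel selection
## on the training folds, restricted HMM training with and without emission
## amortization, and evaluation on k-mer complete held-out folds with the
## error decomposed into sensor / k-mer generalization and low/high novelty.

#' Read-level cross-validation folds
#'
#' @param read_ids Vector of read identifiers.
#' @param n_folds Number of folds (default 6).
#' @param seed Integer seed.
#' @return Named integer vector mapping read id to fold, with near-equal
#'   fold sizes.
#' @export
make_folds <- function(read_ids, n_folds = 6L, seed = 1L) {
  n <- length(read_ids)
  if (n < n_folds) stop("need at least ", n_folds, " reads, got ", n)
  perm <- with_seed(seed, sample.int(n))
  fold <- rep(seq_len(n_folds), length.out = n)[order(perm)]
  setNames(fold, read_ids)
}

#' Balance methylated and unmethylated site classes
#'
#' Randomly downsamples the majority class, without replacement, to the
#' minority class's size.  Intended for training folds only.
#'
#' @param sites `data.frame` with a `state` column
#'   (`"methylated"`/`"unmethylated"`).
#' @param seed Integer seed.
#' @return Row-subset of `sites` with equal class counts.
#' @export
balance_classes <- function(sites, seed = 1L) {
  meth <- which(sites$state == "methylated")
  unmeth <- which(sites$state == "unmethylated")
  if (!length(meth) || !length(unmeth))
    stop("both classes must be present")
  n <- min(length(meth), length(unmeth))
  keep <- with_seed(seed, c(
    if (length(meth) > n) sample(meth, n) else meth,
    if (length(unmeth) > n) sample(unmeth, n) else unmeth))
  sites[sort(keep), , drop = FALSE]
}

#' Equalize training-set sizes across completeness levels
#'
#' Downsamples every training set (vector or `data.frame`) to the size of
#' the reference set (the smallest completeness level), so that accuracy
#' differences across `p` reflect k-mer diversity rather than data volume.
#'
#' @param training_sets Named list of vectors or `data.frame`s, one per `p`.
#' @param reference Name (or index) of the reference element, typically the
#'   smallest `p`.
#' @param seed Integer seed.
#' @return List of the same shape with every element downsampled to the
#'   reference size.
#' @export
normalize_training_size <- function(training_sets, reference, seed = 1L) {
  target <- NROW(training_sets[[reference]])
  sizes <- vapply(training_sets, NROW, integer(1))
  if (any(sizes < target))
    stop("cannot upsample: reference size ", target,
         " exceeds a training set of size ", min(sizes))
  with_seed(seed, lapply(training_sets, function(x) {
    if (NROW(x) == target) return(x)
    keep <- sort(sample.int(NROW(x), target))
    if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
  }))
}

#' Partition test sites into sensor and k-mer generalization subsets
#'
#' A site belongs to the sensor subset iff every constituent modified k-mer
#' of its window occurred in the (restricted) training data; otherwise it
#' requires k-mer generalization.
#'
#' @param windows Character vector of test-site methyl windows.
#' @param training_kmers Modified k-mers present in training.
#' @return Logical vector, `TRUE` = sensor subset.
#' @export
split_by_seen <- function(windows, training_kmers) {
  vapply(windows,
         function(w) all(decompose_window(w) %in% training_kmers),
         logical(1), USE.NAMES = FALSE)
}

#' Split k-mer-generalization sites by novelty
#'
#' Computes each window's novelty (mean one-hot Hamming distance to the
#' unique training windows) and splits at a threshold, by default the median
#' novelty within the subset; scores at or below the threshold are
#' low-novelty.
#'
#' @param windows Character vector of k-mer-subset windows (non-empty).
#' @param training_windows Training methyl windows (non-empty).
#' @param threshold Numeric threshold, or `NULL` for the median rule.
#' @return List with `score` (numeric), `low` (logical, `TRUE` =
#'   low-novelty) and `threshold`.
#' @export
split_by_novelty <- function(windows, training_windows, threshold = NULL) {
  if (!length(windows) || !length(training_windows))
    stop("windows and training_windows must be non-empty")
  score <- vapply(windows, novelty_score, numeric(1),
                  training = training_windows, USE.NAMES = FALSE)
  if (is.null(threshold)) threshold <- median(score)
  list(score = score, low = score <= threshold, threshold = threshold)
}

#' Experiment configuration for the completeness sweep
#'
#' Defaults define the desk-scale study conditions: a 50 kb reference with
#' ~2000 spaced CpG sites, half methylated; 30 full-length reads (30x
#' coverage, deterministic so the confident-label filter retains every
#' site); six read-level folds; completeness levels p in \{5, 10, 30, 100\}.
#'
#' @param seeds Integer seeds, one sweep replicate per seed.
#' @param p_grid Completeness percentages in (0, 100].
#' @param n_folds Read-level folds (default 6).
#' @param reference_length Reference length in bases.
#' @param cpg_density CpG sites per base.
#' @param methylated_fraction Fraction of sites methylated.
#' @param coverage Mean read coverage.
#' @param read_length Read length, `NULL` for full-length reads.
#' @param min_events Emission-table support threshold.
#' @param amortizer_d,amortizer_h,amortizer_epochs,amortizer_lr Amortizer
#'   architecture and optimization settings (frozen across `p`).
#' @param node_cap Branch-and-bound node cap per selection solve.
#' @param methods Callers to evaluate; subset of
#'   `c("plain", "amortized", "override", "combined")`.
#' @param balance,normalize_size Apply training-class balancing / size
#'   normalization to the HMM training data (default `FALSE`; these
#'   corrections matter for high-capacity callers trained on site examples,
#'   while the per-k-mer HMM estimates depend on per-k-mer support).
#' @param model_settings List passed to [generate_pore_model()].
#' @return An `experiment_config`.
#' @export
experiment_config <- function(seeds = 1:5,
                              p_grid = c(5, 10, 30, 100),
                              n_folds = 6L,
                              reference_length = 50000L,
                              cpg_density = 0.04,
                              methylated_fraction = 0.5,
                              coverage = 30L,
                              read_length = NULL,
                              min_events = 5L,
                              amortizer_d = 3L,
                              amortizer_h = 64L,
                              amortizer_epochs = 1000L,
                              amortizer_lr = 4e-2,
                              node_cap = 2e4,
                              methods = c("plain", "amortized",
                                          "override", "combined"),
                              balance = FALSE,
                              normalize_size = FALSE,
                              model_settings = list()) {
  stopifnot(all(p_grid > 0), all(p_grid <= 100), n_folds >= 2L,
            length(seeds) >= 1L)
  methods <- match.arg(methods,
                       c("plain", "amortized", "override", "combined"),
                       several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

## tidy metric rows for one (seed, p, fold, method)
metric_rows <- function(seed, p, fold, method, subset, read_df, site_df,
                        truth) {
  if (!nrow(site_df))
    return(NULL)
  tr_site <- truth[match(site_df$position, as.numeric(names(truth)))]
  tr_read <- truth[match(read_df$position, as.numeric(names(truth)))]
  data.frame(seed = seed, p = p, fold = fold, method = method,
             subset = subset,
             metric = c("read_error", "site_error"),
             value = c(mean(read_df$call != tr_read),
                       mean(abs(site_df$meth_frac - as.numeric(tr_site)))),
             n = c(nrow(read_df), nrow(site_df)))
}

#' Run the k-mer completeness sweep
#'
#' For every seed, fold and completeness level `p`: selects a coherent
#' modified-k-mer panel from the training folds' methylated-window
#' frequencies, restricts the training events to it, trains the plain
#' emission table, fits the amortizer on its learned rows and imputes the
#' missing ones, then calls every confidently labelled site on the held-out
#' fold (never k-mer filtered) and records per-read and per-site error
#' overall, for the sensor and k-mer generalization subsets, and for the
#' low/high-novelty halves of the k-mer subset.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-stage progress lines (default `FALSE`).
#' @return A tidy `data.frame` with columns `seed`, `p`, `fold`, `method`,
#'   `subset` (`overall`, `sensor`, `kmer`, `low_novelty`, `high_novelty`),
#'   `metric` (`read_error`: fraction of per-read calls wrong;
#'   `site_error`: mean absolute difference between predicted and true
#'   methylation fraction), `value`, `n`, plus attribute `"selection"`
#'   summarizing each ILP solve.
#' @export
run_p_sweep <- function(cfg = experiment_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- list()
  selinfo <- list()
  say <- function(...) if (progress) message(sprintf(...))
  for (s in cfg$seeds) {
    say("seed %d: simulating", s)
    ref <- generate_reference(seed = s * 1000L + 1L,
                              length = cfg$reference_length,
                              cpg_density = cfg$cpg_density,
                              methylated_fraction = cfg$methylated_fraction)
    model <- do.call(generate_pore_model,
                     c(list(seed = s * 1000L + 2L), cfg$model_settings))
    n_reads <- if (is.null(cfg$read_length)) cfg$coverage
               else reads_for_coverage(cfg$reference_length,
                                       cfg$read_length, cfg$coverage)
    events <- simulate_events(ref, model, n_reads = n_reads,
                              read_length = cfg$read_length,
                              seed = s * 1000L + 3L)

    # confident binary labels: per-read calls equal the site's true state
    cov_rows <- events[events$position %in% ref$cpg_sites,
                       c("read_id", "position")]
    truth_all <- setNames(ref$methylated, ref$cpg_sites)
    labels_per_read <- data.frame(
      position = cov_rows$position, read_id = cov_rows$read_id,
      call = truth_all[as.character(cov_rows$position)])
    conf_all <- filter_confident_sites(labels_per_read)
    conf <- conf_all[conf_all$state != "ambiguous", , drop = FALSE]
    sites <- conf$position
    truth <- setNames(conf$state == "methylated", sites)
    win <- substring(ref$seq, sites - 4L, sites + 6L)
    substr(win, 6L, 6L) <- "M"

    folds <- make_folds(sort(unique(events$read_id)), cfg$n_folds,
                        seed = s * 1000L + 4L)
    for (f in seq_len(cfg$n_folds)) {
      test_reads <- as.integer(names(folds)[folds == f])
      is_test <- events$read_id %in% test_reads
      tr_ev <- events[!is_test, , drop = FALSE]
      te_ev <- events[is_test, , drop = FALSE]

      # methylated training windows weighted by training-read occurrences
      msites <- sites[truth]
      mwin <- win[truth]
      mtab <- rowsum(rep(1L, nrow(tr_ev)), tr_ev$position)
      mcount <- mtab[match(as.character(msites), rownames(mtab)), 1L]
      mcount[is.na(mcount)] <- 0
      keepw <- mcount > 0
      train_sites <- conf
      if (cfg$balance)
        train_sites <- balance_classes(conf, seed = s * 1000L + 6L + f)

      ev_by_p <- list()
      for (p in cfg$p_grid) {
        prob <- build_selection_problem(mwin[keepw], mcount[keepw], p = p)
        sol <- solve_selection_ilp(prob, node_cap = cfg$node_cap)
        selinfo[[length(selinfo) + 1L]] <- data.frame(
          seed = s, fold = f, p = p, budget = sol$budget,
          universe = sol$universe_size,
          n_kmers = length(sol$selected_kmers),
          n_windows = sum(sol$y), objective = sol$objective,
          status = sol$status)
        ev_p <- restrict_training_events(tr_ev, sol$selected_kmers)
        if (cfg$balance) {
          dropped <- setdiff(conf$position, train_sites$position)
          if (length(dropped)) {
            bad <- unique(as.vector(outer(dropped, 0:5, `-`)))
            ev_p <- ev_p[!(ev_p$position %in% bad), , drop = FALSE]
          }
        }
        ev_by_p[[as.character(p)]] <- ev_p
      }
      if (cfg$normalize_size) {
        ref_p <- as.character(min(cfg$p_grid))
        ev_by_p <- normalize_training_size(ev_by_p, ref_p,
                                           seed = s * 1000L + 5L + f)
      }

      for (p in cfg$p_grid) {
        say("seed %d fold %d p %g: training + calling", s, f, p)
        ev_p <- ev_by_p[[as.character(p)]]
        em_plain <- train_emission_table(ev_p, site_labels = conf_all,
                                         min_events = cfg$min_events)
        pairs <- build_training_pairs(em_plain)
        amor <- fit_amortizer(pairs, amortizer_config(
          d = cfg$amortizer_d, h = cfg$amortizer_h,
          lr = cfg$amortizer_lr, epochs = cfg$amortizer_epochs,
          seed = s * 1000L + 7L + f))
        tables <- list()
        if ("plain" %in% cfg$methods || "combined" %in% cfg$methods)
          tables$plain <- em_plain
        if ("amortized" %in% cfg$methods || "combined" %in% cfg$methods)
          tables$amortized <- impute_emission_table(em_plain, amor)
        if ("override" %in% cfg$methods)
          tables$override <- override_all_emissions(em_plain, amor)

        training_kmers <- unique(ev_p$kmer[grepl("M", ev_p$kmer,
                                                 fixed = TRUE)])
        training_windows <- unique(mwin[keepw][
          vapply(mwin[keepw], function(w)
            all(decompose_window(w) %in% training_kmers), logical(1))])
        seen <- split_by_seen(win, training_kmers)

        calls <- lapply(tables, function(em) call_sites(te_ev, sites,
                                                        win, em))
        if ("combined" %in% cfg$methods) {
          comb <- calls$plain
          swap_s <- !seen[match(comb$sites$position, sites)]
          comb$sites[swap_s, ] <- calls$amortized$sites[swap_s, ]
          swap_r <- !seen[match(comb$reads$position, sites)]
          comb$reads[swap_r, ] <- calls$amortized$reads[swap_r, ]
          calls$combined <- comb
        }

        nov <- NULL
        if (any(!seen) && length(training_windows))
          nov <- split_by_novelty(win[!seen], training_windows)

        for (method in intersect(cfg$methods, names(calls))) {
          cs <- calls[[method]]
          site_seen <- seen[match(cs$sites$position, sites)]
          read_seen <- seen[match(cs$reads$position, sites)]
          add <- function(name, smask, rmask)
            metric_rows(s, p, f, method, name,
                        cs$reads[rmask, , drop = FALSE],
                        cs$sites[smask, , drop = FALSE], truth)
          out[[length(out) + 1L]] <- add("overall", TRUE, TRUE)
          out[[length(out) + 1L]] <- add("sensor", site_seen, read_seen)
          out[[length(out) + 1L]] <- add("kmer", !site_seen, !read_seen)
          if (!is.null(nov)) {
            lowpos <- sites[!seen][nov$low]
            out[[length(out) + 1L]] <-
              add("low_novelty", cs$sites$position %in% lowpos,
                  cs$reads$position %in% lowpos)
            highpos <- sites[!seen][!nov$low]
            out[[length(out) + 1L]] <-
              add("high_novelty", cs$sites$position %in% highpos,
                  cs$reads$position %in% highpos)
          }
        }
      }
    }
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  attr(report, "selection") <- do.call(rbind, selinfo)
  report
}

#' Aggregate a sweep report across folds and seeds
#'
#' @param report Output of [run_p_sweep()].
#' @param metric Which metric to aggregate (default `"read_error"`).
#' @return `data.frame` with mean and SD of the metric per
#'   (p, method, subset), following the error-bar convention of one SD
#'   across folds.
#' @export
summarize_sweep <- function(report, metric = "read_error") {
  r <- report[report$metric == metric, , drop = FALSE]
  agg <- aggregate(value ~ p + method + subset, data = r,
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  out <- data.frame(agg[c("p", "method", "subset")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = agg$value[, "n"])
  out[order(out$subset, out$method, out$p), , drop = FALSE]
}
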