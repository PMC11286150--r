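## Gaussian-emission HMM methylation calling.  Each (modified) k-mer state
## carries an independent Normal(mean, var) over observed current; training
## estimates these from aligned events, and calling compares the
## log-likelihood of a site's events under the methylated k-mer path against
## the unmethylated (M -> C) path.

VAR_FLOOR <- 1e-6  # pA^2; keeps log-densities finite

all_cpg_kmers_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- enumerate_kmers(mod_alphabet(), cpg_only = TRUE)
    cache
  }
})

#' Construct an emission table
#'
#' @param kmer Character vector of k-mers.
#' @param mean,var Gaussian parameters per k-mer (current units, squared).
#' @param provenance `"learned"`, `"default"` or `"imputed"` per k-mer.
#' @param min_events Training support threshold recorded with the table.
#' @param pooled Length-2 numeric, the pooled default (mean, var).
#' @return An object of class `emission_table`.
#' @export
emission_table <- function(kmer, mean, var, provenance, min_events = 10L,
                           pooled = c(NA_real_, NA_real_)) {
  stopifnot(length(kmer) == length(mean), length(mean) == length(var),
            length(var) == length(provenance), all(var > 0),
            all(provenance %in% c("learned", "default", "imputed")))
  if (anyDuplicated(kmer)) stop("duplicate k-mers in emission table")
  structure(list(kmer = as.character(kmer), mean = unname(as.numeric(mean)),
                 var = unname(as.numeric(var)),
                 provenance = unname(as.character(provenance)),
                 min_events = as.integer(min_events),
                 pooled = unname(pooled)),
            class = "emission_table")
}

#' @export
print.emission_table <- function(x, ...) {
  tab <- table(factor(x$provenance,
                      levels = c("learned", "default", "imputed")))
  cat("emission table: ", length(x$kmer), " k-mers (",
      paste(names(tab), tab, sep = " = ", collapse = ", "),
      "), min_events = ", x$min_events, "\n", sep = "")
  invisible(x)
}

## Gaussian parameters for specific k-mers, erroring on absences.
em_params <- function(em, kmers) {
  idx <- match(kmers, em$kmer)
  if (anyNA(idx))
    stop("missing emission entry for k-mer(s): ",
         paste(unique(kmers[is.na(idx)]), collapse = ", "))
  list(mean = em$mean[idx], var = em$var[idx],
       provenance = em$provenance[idx])
}

#' Train per-k-mer emission distributions from aligned events
#'
#' Events are grouped by their (methylation-marked) k-mer; a k-mer with at
#' least `min_events` events gets the sample mean and maximum-likelihood
#' sample variance (floored at a small positive constant) with provenance
#' `"learned"`.  Every other CpG-context k-mer receives the pooled default:
#' the moment-pooled Gaussian over all learned modified k-mers (falling back
#' to all learned k-mers when no modified one was learned), with provenance
#' `"default"`.  The alignment/update loop of event-level training is kept
#' as `n_iterations` (default 5); with fixed aligned events the alignment
#' step is a no-op, so iterations beyond the first do not change the result.
#'
#' If `site_labels` is given, events whose k-mer context overlaps a site not
#' confidently labelled (state `"ambiguous"`) are excluded from training.
#'
#' @param events Event table (`read_id`, `position`, `kmer`, `current`).
#' @param site_labels Optional output of [filter_confident_sites()].
#' @param min_events Support threshold for learning a k-mer (default 10).
#' @param n_iterations Alignment/update iterations (default 5; a no-op for
#'   fixed alignments).
#' @param k Context length (default 6).
#' @return An `emission_table` complete over all CpG-context 6-mers.
#' @export
train_emission_table <- function(events, site_labels = NULL,
                                 min_events = 10L, n_iterations = 5L,
                                 k = 6L) {
  if (!nrow(events)) stop("empty event set")
  if (!is.null(site_labels)) {
    amb <- site_labels$position[site_labels$state == "ambiguous"]
    if (length(amb)) {
      bad_starts <- unique(as.vector(outer(amb, 0:(k - 1L), `-`)))
      events <- events[!(events$position %in% bad_starts), , drop = FALSE]
      if (!nrow(events)) stop("no events left after ambiguous-site filter")
    }
  }
  # The alignment/update loop runs n_iterations times in event-level
  # training; with fixed aligned events the alignment step cannot change,
  # so the sufficient statistics are computed once.
  stopifnot(n_iterations >= 1L)
  n <- rowsum(rep(1, nrow(events)), events$kmer)
  s1 <- rowsum(events$current, events$kmer)
  s2 <- rowsum(events$current^2, events$kmer)
  kmer_obs <- rownames(n)
  mu <- s1[, 1L] / n[, 1L]
  sig2 <- pmax(s2[, 1L] / n[, 1L] - mu^2, VAR_FLOOR)
  learned <- n[, 1L] >= min_events

  # pooled default: moment-pooled over learned modified k-mers
  lm <- learned & grepl("M", kmer_obs, fixed = TRUE)
  if (!any(lm)) lm <- learned
  wts <- n[lm, 1L] / sum(n[lm, 1L])
  pooled_mu <- sum(wts * mu[lm])
  pooled_var <- max(sum(wts * (sig2[lm] + (mu[lm] - pooled_mu)^2)),
                    VAR_FLOOR)

  universe <- union(all_cpg_kmers_cache(), kmer_obs)
  idx <- match(universe, kmer_obs)
  use <- !is.na(idx) & learned[ifelse(is.na(idx), 1L, idx)]
  emission_table(
    kmer = universe,
    mean = ifelse(use, mu[idx], pooled_mu),
    var = ifelse(use, sig2[idx], pooled_var),
    provenance = ifelse(use, "learned", "default"),
    min_events = min_events,
    pooled = c(pooled_mu, pooled_var))
}

#' Restrict training events to an allowed modified-k-mer panel
#'
#' Drops every event whose k-mer contains an M and is not in `allowed_kmers`,
#' enforcing that emission parameters are never learned for modified k-mers
#' outside the selected panel.  Events on unmodified k-mers are untouched.
#'
#' @param events Event table.
#' @param allowed_kmers Character vector of allowed modified k-mers.
#' @return Filtered event table.
#' @export
restrict_training_events <- function(events, allowed_kmers) {
  modified <- grepl("M", events$kmer, fixed = TRUE)
  events[!modified | events$kmer %in% allowed_kmers, , drop = FALSE]
}

#' Transition parameters of the event HMM
#'
#' @param p_stay Probability of re-emitting the same k-mer.
#' @param p_skip Probability of skipping one k-mer.
#' @return A `transition_params` object; `p_step = 1 - p_stay - p_skip`.
#' @export
transition_params <- function(p_stay = 0, p_skip = 0) {
  stopifnot(p_stay >= 0, p_skip >= 0, p_stay <= 1, p_skip <= 1)
  if (p_stay + p_skip >= 1) stop("p_step = 1 - p_stay - p_skip must be > 0")
  structure(list(p_stay = p_stay, p_skip = p_skip,
                 p_step = 1 - p_stay - p_skip),
            class = "transition_params")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Forward-algorithm log-likelihood of an event sequence
#'
#' Hidden states are positions along `kmer_path`; each event is emitted from
#' its state's Gaussian, and transitions move by 0 (stay), 1 (step) or 2
#' (skip) positions.  Paths start at the first k-mer and must end at the
#' last.  With `p_stay = p_skip = 0` this reduces exactly to the factorized
#' sum of log Normal densities when the lengths match, and to `-Inf` when
#' they do not.
#'
#' @param currents Ordered numeric vector of observed currents.
#' @param kmer_path Ordered character vector of k-mers (all present in `em`).
#' @param em An `emission_table`.
#' @param tr A `transition_params` (default: no stays or skips).
#' @return Log-likelihood (may be `-Inf`).
#' @export
event_sequence_loglik <- function(currents, kmer_path, em,
                                  tr = transition_params()) {
  if (!length(currents) || !length(kmer_path))
    stop("currents and kmer_path must be non-empty")
  pars <- em_params(em, kmer_path)
  n <- length(kmer_path)
  TT <- length(currents)
  lemit <- outer(currents, seq_len(n),
                 function(x, j) stats::dnorm(x, pars$mean[j],
                                             sqrt(pars$var[j]), log = TRUE))
  ltr <- log(c(tr$p_stay, tr$p_step, tr$p_skip))
  alpha <- rep(-Inf, n)
  alpha[1L] <- lemit[1L, 1L]
  if (TT > 1L) for (t in 2:TT) {
    new <- rep(-Inf, n)
    for (j in seq_len(n)) {
      inc <- c(alpha[j] + ltr[1L],
               if (j >= 2L) alpha[j - 1L] + ltr[2L] else -Inf,
               if (j >= 3L) alpha[j - 2L] + ltr[3L] else -Inf)
      new[j] <- logsumexp(inc) + lemit[t, j]
    }
    alpha <- new
  }
  alpha[n]
}

#' Two-hypothesis site call
#'
#' For every read covering all `k` constituent positions of the site's
#' window, the read log-likelihood ratio is the forward log-likelihood of
#' its events under the methylated k-mer path (the window's decomposition)
#' minus that under the unmethylated path (M replaced by C).  The site LLR
#' is the sum over reads, and the site is called methylated iff LLR > 0.
#'
#' @param events Event table covering the site.
#' @param site 0-based position of the CpG's C.
#' @param window The site's methyl window (11-mer centred on M).
#' @param em An `emission_table`.
#' @param tr A `transition_params`.
#' @param k Context length (default 6).
#' @return An object of class `site_call`: list with `position`, `llr`,
#'   `call`, `read_llrs` (named by read id).
#' @export
call_site <- function(events, site, window, em, tr = transition_params(),
                      k = 6L) {
  meth_path <- decompose_window(window, k = k)
  unmeth_path <- unmethylate(meth_path)
  lo <- site - (k - 1L)
  ev <- events[events$position >= lo & events$position <= site, , drop = FALSE]
  ev <- ev[order(ev$read_id, ev$position), , drop = FALSE]
  strict <- tr$p_stay == 0 && tr$p_skip == 0
  read_llrs <- c()
  for (r in unique(ev$read_id)) {
    rows <- ev[ev$read_id == r, , drop = FALSE]
    covered <- if (strict) length(unique(rows$position)) == k
               else min(rows$position) <= lo && max(rows$position) >= site
    if (!covered) next
    llr <- event_sequence_loglik(rows$current, meth_path, em, tr) -
      event_sequence_loglik(rows$current, unmeth_path, em, tr)
    read_llrs[as.character(r)] <- llr
  }
  if (!length(read_llrs)) stop("no reads fully cover site ", site)
  llr <- sum(read_llrs)
  structure(list(position = site, llr = llr, call = llr > 0,
                 read_llrs = read_llrs),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat("site ", x$position, ": ",
      if (x$call) "methylated" else "unmethylated",
      " (llr ", format(x$llr, digits = 4), ", ",
      length(x$read_llrs), " reads)\n", sep = "")
  invisible(x)
}

#' Vectorized site calling in the aligned-event regime
#'
#' Fast path for `p_stay = p_skip = 0`: per read and site, the LLR is the
#' sum over the k covered positions of the pointwise Gaussian log-density
#' differences.  Only reads with an event at every one of the site's k
#' positions contribute.  Sites must be spaced so their k-mer windows do not
#' overlap (guaranteed by [generate_reference()]).
#'
#' @param events Event table.
#' @param sites 0-based site positions.
#' @param windows Methyl windows, parallel to `sites`.
#' @param em An `emission_table`.
#' @param k Context length (default 6).
#' @return List with `sites` (`data.frame`: `position`, `llr`, `call`,
#'   `coverage`, `meth_frac`) and `reads` (`data.frame`: `read_id`,
#'   `position`, `llr`, `call`), where `meth_frac` is the fraction of
#'   per-read calls that are methylated.
#' @export
call_sites <- function(events, sites, windows, em, k = 6L) {
  stopifnot(length(sites) == length(windows))
  ns <- length(sites)
  if (!ns) stop("no sites to call")
  # per (site, offset) hypothesis k-mers and their Gaussians
  meth_k <- t(vapply(windows, decompose_window, character(k), k = k))
  unmeth_k <- unmethylate(meth_k)
  pm <- em_params(em, as.vector(meth_k))
  pu <- em_params(em, as.vector(unmeth_k))
  key_pos <- as.vector(outer(sites, (k - 1L):0, `-`))  # column-major: offset
  site_ix <- rep(seq_len(ns), times = k)

  hit <- match(events$position, key_pos)
  use <- !is.na(hit)
  ev <- events[use, , drop = FALSE]
  fi <- hit[use]
  s_ix <- site_ix[fi]
  llr_row <- stats::dnorm(ev$current, pm$mean[fi], sqrt(pm$var[fi]),
                          log = TRUE) -
             stats::dnorm(ev$current, pu$mean[fi], sqrt(pu$var[fi]),
                          log = TRUE)
  gid <- (as.numeric(ev$read_id) - 1) * ns + s_ix
  cnt <- rowsum(rep(1L, length(gid)), gid)
  lsum <- rowsum(llr_row, gid)
  complete <- cnt[, 1L] == k
  gids <- as.numeric(rownames(cnt))[complete]
  read_df <- data.frame(read_id = floor((gids - 1) / ns) + 1,
                        position = sites[((gids - 1) %% ns) + 1],
                        llr = lsum[complete, 1L])
  read_df$call <- read_df$llr > 0
  ssum <- rowsum(read_df$llr, read_df$position)
  scov <- rowsum(rep(1L, nrow(read_df)), read_df$position)
  smeth <- rowsum(as.integer(read_df$call), read_df$position)
  pos_out <- as.numeric(rownames(ssum))
  site_df <- data.frame(position = pos_out,
                        llr = ssum[, 1L],
                        call = ssum[, 1L] > 0,
                        coverage = scov[, 1L],
                        meth_frac = smeth[, 1L] / scov[, 1L])
  rownames(site_df) <- NULL
  list(sites = site_df, reads = read_df)
}

#' Per-site methylation frequency from read-level calls
#'
#' @param read_calls `data.frame` with columns `position` and `call`
#'   (read-level methylated calls), e.g. the `reads` element of
#'   [call_sites()].
#' @return `data.frame` with `position` and `frequency`, the fraction of
#'   reads called methylated at each site.
#' @export
methylation_frequency <- function(read_calls) {
  stopifnot(all(c("position", "call") %in% colnames(read_calls)),
            nrow(read_calls) > 0)
  nm <- rowsum(as.integer(read_calls$call), read_calls$position)
  nn <- rowsum(rep(1L, nrow(read_calls)), read_calls$position)
  data.frame(position = as.numeric(rownames(nm)),
             frequency = nm[, 1L] / nn[, 1L])
}
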