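# Independent oracles and small generators used across tests.

# Exhaustive-path log-likelihood oracle: enumerates every hidden state
# sequence (increments 0 = stay, 1 = step, 2 = skip) that starts at state 1
# and ends at state n, summing path probabilities directly.
enum_path_loglik <- function(currents, kmer_path, em, tr) {
  idx <- match(kmer_path, em$kmer)
  stopifnot(!anyNA(idx))
  mu <- em$mean[idx]; sd <- sqrt(em$var[idx])
  n <- length(kmer_path); TT <- length(currents)
  pr <- c(tr$p_stay, tr$p_step, tr$p_skip)
  total <- 0
  recurse <- function(t, j, p) {
    p <- p * stats::dnorm(currents[t], mu[j], sd[j])
    if (t == TT) {
      if (j == n) total <<- total + p
      return(invisible())
    }
    for (inc in 0:2)
      if (pr[inc + 1] > 0 && j + inc <= n)
        recurse(t + 1, j + inc, p * pr[inc + 1])
  }
  recurse(1, 1, 1)
  log(total)
}

# Random valid methyl window (11-mer, centre M, centre+1 G, single M).
random_window <- function() {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE),
               collapse = "")
    substr(s, 6, 6) <- "M"
    substr(s, 7, 7) <- "G"
    if (is_valid_window(s)) return(s)
  }
}

# Small emission table over explicit k-mers with given parameters.
toy_emissions <- function(kmers, means, vars,
                          provenance = rep("learned", length(kmers))) {
  emission_table(kmers, means, vars, provenance, min_events = 1L)
}

# Tiny end-to-end fixture: reference + model + events.
tiny_simulation <- function(seed = 11, length = 3000, n_reads = 12,
                            methylated_fraction = 0.5, ...) {
  ref <- generate_reference(seed = seed, length = length,
                            cpg_density = 0.03,
                            methylated_fraction = methylated_fraction)
  model <- generate_pore_model(seed = seed + 1, ...)
  events <- simulate_events(ref, model, n_reads = n_reads, seed = seed + 2)
  list(ref = ref, model = model, events = events)
}

# Confident labels for a simulated reference, reusing its reads as the
# labelling assay (per-read call = true site state).
confident_labels <- function(ref, events) {
  truth <- stats::setNames(ref$methylated, ref$cpg_sites)
  cov <- events[events$position %in% ref$cpg_sites,
                c("read_id", "position")]
  filter_confident_sites(data.frame(
    position = cov$position, read_id = cov$read_id,
    call = truth[as.character(cov$position)]))
}

# Hypothesis windows (M at centre) for given site positions of a reference.
hypothesis_windows <- function(ref, positions) {
  w <- substring(ref$seq, positions - 4L, positions + 6L)
  substr(w, 6L, 6L) <- "M"
  w
}
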