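## Synthetic ground-truth pore models, references and aligned event tables.
## The generator emulates the statistical structure the caller consumes:
## per-k-mer Gaussian current levels that vary smoothly with k-mer
## composition (additive per-position letter effects + adjacent-pair effects
## + an i.i.d. residual), site-consistent methylation states, per-event
## Gaussian noise, and enough coverage for the >= 5-read confident-label
## filter.

#' Generate a ground-truth pore model
#'
#' Mean current for each CpG-context 6-mer (all 4096 unmodified plus the
#' 2669 modified ones) is a baseline plus additive per-position letter
#' effects, adjacent-dinucleotide effects, and an i.i.d. residual; the event
#' noise variance is drawn uniformly from `noise_var_range`.  Because 5mC is
#' chemically a perturbation of cytosine, the M letter does not get an
#' independent effect: its additive effect at each position equals the C
#' effect plus a methyl shift of scale `methyl_shift_scale`, and M-containing
#' dinucleotide effects equal their C-substituted counterparts plus
#' half-`pairwise_effect_scale` shifts (so with pairwise effects and residual
#' switched off, the means are exactly linear in the mononucleotide
#' features).  This makes methylation detection a genuine signal-discrimination
#' problem (the methylated and unmethylated hypotheses differ by a couple of
#' pA per affected position against ~1 pA event noise) rather than a trivial
#' one.  The
#' additive and pairwise terms make the means partially predictable from the
#' binary k-mer featurization (the amortization target), while the residual
#' bounds the accuracy any feature-based imputation can reach.
#'
#' @param seed Integer seed.
#' @param additive_effect_scale SD (pA) of per-position letter effects
#'   (default 4, giving a ~10 pA spread of k-mer levels).
#' @param pairwise_effect_scale SD (pA) of adjacent-pair effects (default 0.5;
#'   deviations from position additivity are a secondary effect in real
#'   pore tables).
#' @param methyl_shift_scale SD (pA) of the per-position mean shift of M
#'   relative to C (default 1.75, within the range of bisulfite-validated CpG
#'   level shifts in R9-era pore models).
#' @param residual_scale SD (pA) of the per-k-mer residual (default 0.5).
#' @param noise_var_range Range (pA^2) of per-k-mer event-noise variances
#'   (default c(1, 2)).
#' @param baseline Mean current level (pA), default 90.
#' @param k Context length; only 6 is supported by the featurization.
#' @return An object of class `pore_model`: a list with `kmer`, `mean`,
#'   `var` (aligned vectors over all CpG-context 6-mers) and the generator
#'   settings.
#' @export
generate_pore_model <- function(seed = 1L,
                                additive_effect_scale = 4,
                                pairwise_effect_scale = 0.5,
                                methyl_shift_scale = 1.75,
                                residual_scale = 0.5,
                                noise_var_range = c(1, 2),
                                baseline = 90,
                                k = 6L) {
  stopifnot(additive_effect_scale >= 0, pairwise_effect_scale >= 0,
            methyl_shift_scale >= 0, residual_scale >= 0,
            length(noise_var_range) == 2L, all(noise_var_range > 0))
  kmers <- enumerate_kmers(mod_alphabet(k = k), cpg_only = TRUE)
  with_seed(seed, {
    feats <- featurize_kmers(kmers)
    # per-position letter effects, order A C G T M within each position;
    # M = C + methyl shift
    bm <- matrix(rnorm(k * 4L, 0, additive_effect_scale), k, 4L)
    beta_mono <- as.vector(t(cbind(
      bm, bm[, 2L] + rnorm(k, 0, methyl_shift_scale))))
    # adjacent-pair effects over the 21-symbol CpG-context vocabulary;
    # M-containing pairs = their C-substituted counterpart + half shift
    pure <- DI_VOCAB[!grepl("M", DI_VOCAB)]
    bd <- matrix(0, k - 1L, length(DI_VOCAB))
    bd[, match(pure, DI_VOCAB)] <-
      rnorm((k - 1L) * length(pure), 0, pairwise_effect_scale)
    mpairs <- which(grepl("M", DI_VOCAB))
    for (j in mpairs)
      bd[, j] <- bd[, match(gsub("M", "C", DI_VOCAB[j]), DI_VOCAB)] +
        rnorm(k - 1L, 0, pairwise_effect_scale / 2)
    beta_di <- as.vector(t(bd))
    resid <- rnorm(length(kmers), 0, residual_scale)
    means <- baseline + feats[, 1:30, drop = FALSE] %*% beta_mono +
      feats[, 31:135, drop = FALSE] %*% beta_di + resid
    vars <- runif(length(kmers), noise_var_range[1L], noise_var_range[2L])
  })
  structure(list(kmer = kmers, mean = as.numeric(means), var = vars,
                 seed = seed, k = as.integer(k),
                 settings = list(additive_effect_scale = additive_effect_scale,
                                 pairwise_effect_scale = pairwise_effect_scale,
                                 methyl_shift_scale = methyl_shift_scale,
                                 residual_scale = residual_scale,
                                 noise_var_range = noise_var_range,
                                 baseline = baseline)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat("ground-truth pore model: ", length(x$kmer), " k-mers, mean current ",
      format(mean(x$mean), digits = 5), " pA\n", sep = "")
  invisible(x)
}

#' Generate a synthetic reference with planted CpG sites
#'
#' A random A/C/G/T sequence carrying `CG` dinucleotides only at planted,
#' mutually spaced positions (no two CpGs within `min_spacing` bases, so
#' every methylated site yields a valid single-M 11-mer window and no 6-mer
#' ever holds two M's).  Each site is independently methylated with
#' probability `methylated_fraction`; the state is a property of the site,
#' shared by all reads.
#'
#' @param seed Integer seed.
#' @param length Reference length in bases.
#' @param cpg_density Target CpG sites per base (default 0.04).
#' @param methylated_fraction Probability a site is methylated (default 0.5).
#' @param min_spacing Minimum distance between the C's of adjacent CpGs
#'   (default 6).
#' @return An object of class `synthetic_reference`: list with `seq`
#'   (string), `cpg_sites` (0-based positions of the C), `methylated`
#'   (logical per site).
#' @export
generate_reference <- function(seed = 1L, length = 20000L,
                               cpg_density = 0.04,
                               methylated_fraction = 0.5,
                               min_spacing = 6L) {
  stopifnot(cpg_density >= 0, cpg_density <= 1,
            methylated_fraction >= 0, methylated_fraction <= 1)
  L <- as.integer(length)
  k <- 6L
  n_sites <- as.integer(round(cpg_density * L))
  lo <- k                        # 0-based C position range keeping the
  hi <- L - k - 1L               # 11-mer window and its k-mers in bounds
  if (n_sites > 0 && (hi < lo ||
      (hi - lo) < (n_sites - 1L) * min_spacing))
    stop("cpg_density ", cpg_density, " infeasible at length ", L,
         " with min_spacing ", min_spacing)
  with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # remove accidental CG dinucleotides so planted sites are the only CpGs
    repeat {
      cg <- which(base[-L] == "C" & base[-1L] == "G")
      if (!base::length(cg)) break
      base[cg + 1L] <- sample(c("A", "C", "T"), base::length(cg),
                              replace = TRUE)
    }
    sites <- integer(0)
    if (n_sites > 0) {
      # spaced positions: order statistics of a uniform draw, pushed apart
      slack <- (hi - lo) - (n_sites - 1L) * min_spacing
      offs <- sort(sample.int(slack + 1L, n_sites, replace = TRUE)) - 1L
      sites <- lo + offs + (seq_len(n_sites) - 1L) * min_spacing
      base[sites + 1L] <- "C"
      base[sites + 2L] <- "G"
    }
    methylated <- runif(base::length(sites)) < methylated_fraction
  })
  structure(list(seq = paste(base, collapse = ""), cpg_sites = sites,
                 methylated = methylated, seed = seed),
            class = "synthetic_reference")
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("synthetic reference: ", nchar(x$seq), " bp, ",
      length(x$cpg_sites), " CpG sites (",
      sum(x$methylated), " methylated)\n", sep = "")
  invisible(x)
}

#' Methylated-site windows of a reference
#'
#' The 11-mer centred on each methylated CpG, written with M at the centre.
#'
#' @param ref A `synthetic_reference`.
#' @return Named character vector of windows, names = 0-based site positions.
#' @export
site_windows <- function(ref) {
  sites <- ref$cpg_sites[ref$methylated]
  if (!length(sites)) return(setNames(character(0), character(0)))
  w <- substring(ref$seq, sites - 4L, sites + 6L)  # 1-based: site+1 is the C
  substr(w, 6L, 6L) <- "M"
  setNames(w, sites)
}

#' Reference k-mer at given start positions, with methylation marks
#'
#' @param ref A `synthetic_reference`.
#' @param starts 0-based k-mer start positions.
#' @param k Context length (default 6).
#' @return Character vector of (possibly modified) k-mers.
#' @export
ref_kmers <- function(ref, starts, k = 6L) {
  kmers <- substring(ref$seq, starts + 1L, starts + k)
  msites <- ref$cpg_sites[ref$methylated]
  if (length(msites)) {
    # substitute M at any methylated C inside the k-mer
    for (off in 0:(k - 1L)) {
      hit <- (starts + off) %in% msites
      if (any(hit)) substr(kmers[hit], off + 1L, off + 1L) <- "M"
    }
  }
  kmers
}

#' Simulate aligned nanopore events
#'
#' Reads are contiguous intervals of the reference with uniform random
#' starts; each read emits one event per k-mer start position it covers
#' (aligned-event regime), with current drawn from the ground-truth Gaussian
#' of the (methylation-marked) reference k-mer.  Optional stay/skip
#' augmentation re-emits a k-mer (geometric stay count with probability
#' `p_stay`) or drops one (probability `p_skip`), for exercising the
#' forward-algorithm caller.
#'
#' @param ref A `synthetic_reference`.
#' @param model A `pore_model` covering every k-mer the reference induces.
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (default: full reference).
#' @param seed Integer seed.
#' @param p_stay,p_skip Stay/skip probabilities (default 0: one event per
#'   covered position).
#' @return A `data.frame` (event table) with columns `read_id` (integer),
#'   `position` (0-based k-mer start), `kmer`, `current`.
#' @export
simulate_events <- function(ref, model, n_reads, read_length = NULL,
                            seed = 1L, p_stay = 0, p_skip = 0) {
  stopifnot(inherits(ref, "synthetic_reference"),
            inherits(model, "pore_model"),
            p_stay >= 0, p_skip >= 0, p_stay + p_skip < 1)
  L <- nchar(ref$seq)
  k <- model$k
  if (is.null(read_length)) read_length <- L
  read_length <- min(as.integer(read_length), L)
  if (read_length < k) stop("read_length must be >= k")
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
    rows <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      pos <- starts[r]:(starts[r] + read_length - k)
      if (p_skip > 0)
        pos <- pos[runif(length(pos)) >= p_skip]
      if (p_stay > 0 && length(pos))
        pos <- rep(pos, times = 1L + stats::rgeom(length(pos), 1 - p_stay))
      pos <- sort(pos)
      rows[[r]] <- data.frame(read_id = r, position = pos)
    }
    ev <- do.call(rbind, rows)
    ev$kmer <- ref_kmers(ref, ev$position, k = k)
    idx <- match(ev$kmer, model$kmer)
    if (anyNA(idx))
      stop("k-mer missing from pore model: ",
           paste(unique(ev$kmer[is.na(idx)]), collapse = ", "))
    ev$current <- rnorm(nrow(ev), model$mean[idx], sqrt(model$var[idx]))
  })
  ev
}

#' Confident-label filter for CpG sites
#'
#' Keeps only sites that are (i) covered by at least `min_coverage` reads and
#' (ii) called consistently (methylated or unmethylated) across every read;
#' all other sites are marked ambiguous and excluded from training and
#' evaluation.
#'
#' @param labels_per_read `data.frame` with columns `position`, `read_id`,
#'   `call` (logical or 0/1; TRUE = methylated).
#' @param min_coverage Minimum read count (default 5).
#' @return `data.frame` with columns `position`, `coverage`, `state`
#'   (`"methylated"`, `"unmethylated"` or `"ambiguous"`), one row per
#'   position, sorted by position.
#' @export
filter_confident_sites <- function(labels_per_read, min_coverage = 5L) {
  stopifnot(all(c("position", "read_id", "call") %in%
                  colnames(labels_per_read)))
  call <- as.logical(labels_per_read$call)
  pos <- labels_per_read$position
  cov <- rowsum(rep(1L, length(pos)), pos)
  nmeth <- rowsum(as.integer(call), pos)
  position <- as.numeric(rownames(cov))
  unanimous <- nmeth[, 1L] == 0L | nmeth[, 1L] == cov[, 1L]
  state <- ifelse(cov[, 1L] >= min_coverage & unanimous,
                  ifelse(nmeth[, 1L] > 0L, "methylated", "unmethylated"),
                  "ambiguous")
  out <- data.frame(position = position, coverage = cov[, 1L], state = state)
  out[order(out$position), , drop = FALSE]
}

#' Number of reads needed for a target mean coverage
#'
#' @param length Reference length.
#' @param read_length Read length.
#' @param coverage Target mean per-base coverage.
#' @return Integer read count.
#' @export
reads_for_coverage <- function(length, read_length, coverage) {
  as.integer(ceiling(coverage * length / read_length))
}
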