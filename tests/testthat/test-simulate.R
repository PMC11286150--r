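test_that("pore-model generation is seed-deterministic and complete", {
  m1 <- generate_pore_model(seed = 5)
  m2 <- generate_pore_model(seed = 5)
  m3 <- generate_pore_model(seed = 6)
  expect_identical(m1$mean, m2$mean)
  expect_identical(m1$var, m2$var)
  expect_false(identical(m1$mean, m3$mean))
  expect_length(m1$kmer, 6765)
  expect_true(all(m1$var > 0))
  expect_setequal(setdiff(m1$kmer[grepl("M", m1$kmer)], all_modified_kmers()),
                  character(0))
})

test_that("with no pairwise effects and no residual the means are affine in
           mononucleotide features", {
  m <- generate_pore_model(seed = 2, pairwise_effect_scale = 0,
                           residual_scale = 0)
  X <- featurize_kmers(m$kmer)[, 1:30]
  fit <- lm.fit(cbind(1, X), m$mean)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("degenerate effect scales give constant means", {
  m <- generate_pore_model(seed = 3, additive_effect_scale = 0,
                           pairwise_effect_scale = 0,
                           methyl_shift_scale = 0, residual_scale = 0)
  expect_lt(diff(range(m$mean)), 1e-12)
})

test_that("methylated k-mers differ from their unmethylated counterparts", {
  m <- generate_pore_model(seed = 4)
  mk <- sample(all_modified_kmers(), 200)
  dm <- m$mean[match(mk, m$kmer)] - m$mean[match(unmethylate(mk), m$kmer)]
  expect_gt(mean(abs(dm) > 1e-8), 0.99)
  # the shift is a perturbation, not an independent redraw
  expect_lt(sd(dm), 5)
})

test_that("reference generation respects methylation fraction and spacing", {
  r0 <- generate_reference(seed = 1, length = 5000, cpg_density = 0.03,
                           methylated_fraction = 0)
  expect_false(any(r0$methylated))
  r1 <- generate_reference(seed = 1, length = 5000, cpg_density = 0.03,
                           methylated_fraction = 1)
  expect_true(all(r1$methylated))
  for (s in 1:200) {
    r <- generate_reference(seed = s, length = 2000, cpg_density = 0.04,
                            methylated_fraction = 0.5)
    # planted CpGs are the only CG dinucleotides, pairwise spacing >= 6
    cg <- gregexpr("CG", r$seq, fixed = TRUE)[[1]] - 1L
    expect_identical(as.integer(cg), as.integer(r$cpg_sites))
    if (length(r$cpg_sites) > 1)
      expect_true(all(diff(r$cpg_sites) >= 6))
  }
  expect_error(generate_reference(seed = 1, length = 100, cpg_density = 0.9),
               "infeasible")
})

test_that("methylated sites yield valid single-M windows and k-mers", {
  r <- generate_reference(seed = 8, length = 4000, cpg_density = 0.04,
                          methylated_fraction = 0.6)
  sw <- site_windows(r)
  expect_true(all(is_valid_window(sw)))
  # window decomposition matches the reference k-mers at the site
  for (i in seq_len(min(10, length(sw)))) {
    pos <- as.integer(names(sw)[i])
    expect_identical(ref_kmers(r, (pos - 5L):pos), decompose_window(sw[i]))
  }
})

test_that("events follow the ground-truth Gaussians", {
  r <- generate_reference(seed = 9, length = 300, cpg_density = 0.03,
                          methylated_fraction = 1)
  # near-zero noise: currents equal the model mean
  m0 <- generate_pore_model(seed = 10, noise_var_range = c(1e-12, 2e-12))
  ev0 <- simulate_events(r, m0, n_reads = 3, seed = 11)
  expect_lt(max(abs(ev0$current - m0$mean[match(ev0$kmer, m0$kmer)])), 1e-4)
  # one event per covered position per read
  expect_identical(nrow(ev0), 3L * (300L - 5L))
  # sampling distribution: per-k-mer mean within 4 SE over many events
  m <- generate_pore_model(seed = 10)
  ev <- simulate_events(r, m, n_reads = 40, seed = 12)
  km <- names(sort(table(ev$kmer), decreasing = TRUE))[1]
  x <- ev$current[ev$kmer == km]
  i <- match(km, m$kmer)
  expect_lt(abs(mean(x) - m$mean[i]), 4 * sqrt(m$var[i] / length(x)))
  # methylated CpGs contribute exactly k M-containing events per full read
  ms <- r$cpg_sites[r$methylated][2]
  one_read <- ev[ev$read_id == 1 & ev$position %in% (ms - 5L):ms, ]
  expect_identical(nrow(one_read), 6L)
  expect_true(all(grepl("M", one_read$kmer)))
})

test_that("event tables reconstruct the site window by overlap-merge", {
  sim <- tiny_simulation(seed = 20)
  ms <- sim$ref$cpg_sites[sim$ref$methylated][1]
  rows <- sim$events[sim$events$read_id == 2 &
                     sim$events$position %in% (ms - 5L):ms, ]
  rows <- rows[order(rows$position), ]
  merged <- paste0(rows$kmer[1],
                   paste(substr(rows$kmer[-1], 6, 6), collapse = ""))
  expect_identical(merged, site_windows(sim$ref)[as.character(ms)][[1]])
})

test_that("stay/skip augmentation changes event counts as configured", {
  r <- generate_reference(seed = 30, length = 500, cpg_density = 0.02)
  m <- generate_pore_model(seed = 31)
  base <- simulate_events(r, m, n_reads = 20, seed = 32)
  stays <- simulate_events(r, m, n_reads = 20, seed = 32, p_stay = 0.3)
  skips <- simulate_events(r, m, n_reads = 20, seed = 32, p_skip = 0.3)
  expect_gt(nrow(stays), nrow(base))
  expect_lt(nrow(skips), nrow(base))
})

test_that("the confident-label filter applies both printed rules", {
  lab <- data.frame(
    position = c(rep(10, 5), rep(20, 4), rep(30, 6)),
    read_id = c(1:5, 1:4, 1:6),
    call = c(rep(TRUE, 5), rep(TRUE, 4), c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                           TRUE)))
  out <- filter_confident_sites(lab)
  expect_identical(out$state[out$position == 10], "methylated")  # cov 5 ok
  expect_identical(out$state[out$position == 20], "ambiguous")   # cov 4
  expect_identical(out$state[out$position == 30], "ambiguous")   # discordant
  expect_identical(sum(out$state != "ambiguous"), 1L)
  # unanimity overrides any coverage
  lab2 <- data.frame(position = 1, read_id = 1:100,
                     call = c(rep(FALSE, 99), TRUE))
  expect_identical(filter_confident_sites(lab2)$state, "ambiguous")
  lab3 <- data.frame(position = 1, read_id = 1:100, call = FALSE)
  expect_identical(filter_confident_sites(lab3)$state, "unmethylated")
})

test_that("confident fraction approaches one at adequate coverage", {
  sim <- tiny_simulation(seed = 40, n_reads = 12)
  lab <- confident_labels(sim$ref, sim$events)
  expect_gt(mean(lab$state != "ambiguous"), 0.95)
})
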