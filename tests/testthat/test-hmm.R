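test_that("emission training computes the per-k-mer MLE", {
  ev <- data.frame(read_id = 1:3, position = 0L, kmer = "AAAAAM",
                   current = c(1, 2, 3))
  em <- train_emission_table(ev, min_events = 3)
  i <- match("AAAAAM", em$kmer)
  expect_equal(em$mean[i], 2)
  expect_equal(em$var[i], 2 / 3)           # ML variance, not n-1
  expect_identical(em$provenance[i], "learned")
  # below support: pooled default
  em2 <- train_emission_table(ev, min_events = 10)
  i2 <- match("AAAAAM", em2$kmer)
  expect_identical(em2$provenance[i2], "default")
  expect_error(train_emission_table(ev[0, ]), "empty")
})

test_that("trained emissions recover the generating parameters", {
  r <- generate_reference(seed = 50, length = 400, cpg_density = 0.02,
                          methylated_fraction = 1)
  m <- generate_pore_model(seed = 51)
  ev <- simulate_events(r, m, n_reads = 400, seed = 52)
  em <- train_emission_table(ev, min_events = 50)
  learned <- which(em$provenance == "learned")
  i <- match(em$kmer[learned], m$kmer)
  n_ev <- table(ev$kmer)[em$kmer[learned]]
  z <- abs(em$mean[learned] - m$mean[i]) /
    sqrt(m$var[i] / as.numeric(n_ev))
  expect_gt(mean(z < 5), 0.99)
})

test_that("ambiguous sites are excluded from training", {
  sim <- tiny_simulation(seed = 55)
  lab <- confident_labels(sim$ref, sim$events)
  lab$state[1] <- "ambiguous"
  amb <- lab$position[1]
  em <- train_emission_table(sim$events, site_labels = lab, min_events = 3)
  # k-mers only observable at the ambiguous site cannot be learned
  touching <- unique(ref_kmers(sim$ref, (amb - 5L):amb))
  elsewhere <- unique(sim$events$kmer[!(sim$events$position %in%
                                          (amb - 5L):amb)])
  only_there <- setdiff(touching, elsewhere)
  if (length(only_there))
    expect_true(all(em$provenance[match(only_there, em$kmer)] == "default"))
})

test_that("panel restriction drops exactly the disallowed modified k-mers", {
  ev <- data.frame(read_id = 1, position = 0:3,
                   kmer = c("GATTTM", "ATTTMG", "ACGTAC", "GATTTM"),
                   current = 1:4)
  expect_identical(restrict_training_events(ev, c("GATTTM", "ATTTMG")), ev)
  none <- restrict_training_events(ev, character(0))
  expect_false(any(grepl("M", none$kmer)))
  expect_identical(nrow(none), 1L)
  one <- restrict_training_events(ev, "GATTTM")
  expect_setequal(one$kmer, c("GATTTM", "ACGTAC"))
  expect_identical(sum(one$kmer == "GATTTM"), 2L)
})

test_that("forward log-likelihood reduces to the factorized sum", {
  path <- c("AAAAAM", "AAAAMG", "AAAMGA")
  em <- toy_emissions(path, c(80, 90, 100), c(1, 2, 4))
  tr <- transition_params()
  x <- c(80.5, 89, 101)
  expect_equal(event_sequence_loglik(x, path, em, tr),
               sum(stats::dnorm(x, c(80, 90, 100), sqrt(c(1, 2, 4)),
                                log = TRUE)))
  # single event, single k-mer
  expect_equal(event_sequence_loglik(2, "AAAAAM",
                                     toy_emissions("AAAAAM", 1, 4), tr),
               stats::dnorm(2, 1, 2, log = TRUE))
  # length mismatch without stays/skips is impossible
  expect_identical(event_sequence_loglik(c(1, 2), path, em, tr), -Inf)
  expect_error(event_sequence_loglik(1, "TTTTTT", em, tr), "TTTTTT")
})

test_that("forward matches exhaustive path enumeration with stays and skips", {
  set.seed(60)
  kmers <- enumerate_kmers(mod_alphabet(), 6, cpg_only = TRUE)[1:6]
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    TT <- sample(1:6, 1)
    em <- toy_emissions(kmers[1:n], rnorm(n, 90, 5), runif(n, 0.5, 2))
    tr <- transition_params(p_stay = runif(1, 0, 0.3),
                            p_skip = runif(1, 0, 0.3))
    x <- rnorm(TT, 90, 5)
    got <- event_sequence_loglik(x, kmers[1:n], em, tr)
    want <- enum_path_loglik(x, kmers[1:n], em, tr)
    if (is.finite(want)) expect_equal(got, want, tolerance = 1e-9)
    else expect_identical(got, -Inf)
  }
})

test_that("site calls follow the two-hypothesis log-likelihood ratio", {
  # single read, one informative position: means 0 (C) and 1 (M), unit
  # variances, observed current 1 -> llr = 0.5
  w <- "AAAAAMGAAAA"
  meth <- decompose_window(w)
  unmeth <- unmethylate(meth)
  mu <- c(setNames(rep(0, 6), unmeth), setNames(rep(0, 6), meth))
  mu[meth[1]] <- 1
  em <- toy_emissions(names(mu), unname(mu), rep(1, 12))
  ev <- data.frame(read_id = 1, position = 0:5,
                   kmer = meth, current = c(1, 0, 0, 0, 0, 0))
  sc <- call_site(ev, site = 5L, window = w, em = em)
  expect_equal(sc$llr, 0.5)
  expect_true(sc$call)
  # indistinguishable hypotheses give llr exactly zero
  em0 <- toy_emissions(names(mu), rep(0, 12), rep(1, 12))
  sc0 <- call_site(ev, site = 5L, window = w, em = em0)
  expect_equal(sc0$llr, 0)
  expect_error(call_site(ev[1:3, ], site = 5L, window = w, em = em),
               "cover")
})

test_that("well-separated emissions give confident methylated calls", {
  set.seed(61)
  w <- "AAAAAMGAAAA"
  meth <- decompose_window(w)
  unmeth <- unmethylate(meth)
  em <- toy_emissions(c(unmeth, meth), c(rep(85, 6), rep(95, 6)),
                      rep(1, 12))
  hits <- 0
  for (rep in 1:50) {
    ev <- data.frame(read_id = rep(1:5, each = 6),
                     position = rep(0:5, 5), kmer = rep(meth, 5),
                     current = rnorm(30, 95, 1))
    if (call_site(ev, 5L, w, em)$call) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.99)
})

test_that("vectorized calling agrees with the per-site caller", {
  sim <- tiny_simulation(seed = 70)
  lab <- confident_labels(sim$ref, sim$events)
  conf <- lab[lab$state != "ambiguous", ]
  win <- hypothesis_windows(sim$ref, conf$position)
  em <- train_emission_table(sim$events, min_events = 3)
  fast <- call_sites(sim$events, conf$position, win, em)
  for (i in sample(seq_along(win), 5)) {
    slow <- call_site(sim$events, conf$position[i], win[i], em)
    j <- match(conf$position[i], fast$sites$position)
    expect_equal(fast$sites$llr[j], slow$llr, tolerance = 1e-9)
  }
  # calling accuracy on complete training data is near-perfect
  truth <- conf$state == "methylated"
  expect_lt(mean(fast$sites$call != truth), 0.02)
})

test_that("call accuracy grows with the methyl mean separation", {
  set.seed(62)
  w <- "AAAAAMGAAAA"
  meth <- decompose_window(w)
  unmeth <- unmethylate(meth)
  errs <- vapply(c(0.2, 0.8, 2), function(sep) {
    em <- toy_emissions(c(unmeth, meth), c(rep(90, 6), rep(90 + sep, 6)),
                        rep(1, 12))
    wrong <- 0
    for (rep in 1:60) {
      truth <- rep %% 2 == 0
      cur <- rnorm(12, if (truth) 90 + sep else 90, 1)
      ev <- data.frame(read_id = rep(1:2, each = 6),
                       position = rep(0:5, 2), kmer = rep(meth, 2),
                       current = cur)
      if (call_site(ev, 5L, w, em)$call != truth) wrong <- wrong + 1
    }
    wrong / 60
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 0.05)
})

test_that("methylation frequency counts read-level calls per site", {
  rc <- data.frame(position = c(1, 1, 1, 1, 2, 2),
                   call = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  mf <- methylation_frequency(rc)
  expect_equal(mf$frequency[mf$position == 1], 0.75)
  expect_equal(mf$frequency[mf$position == 2], 1)
  # invariant to read order
  perm <- rc[sample(nrow(rc)), ]
  expect_equal(methylation_frequency(perm), mf)
})
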