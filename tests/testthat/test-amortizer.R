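test_that("symmetrized KL has its closed-form values and properties", {
  expect_equal(sym_kl(c(0, 1), c(0, 1)), 0)
  expect_equal(sym_kl(c(0, 1), c(1, 1)), 1)
  expect_equal(sym_kl(c(0, 1), c(0, 4)), 1.125)
  expect_error(sym_kl(c(0, 0), c(0, 1)), "positive")
  set.seed(1)
  for (i in 1:50) {
    p <- c(rnorm(1), runif(1, 0.1, 5))
    q <- c(rnorm(1), runif(1, 0.1, 5))
    expect_equal(sym_kl(p, q), sym_kl(q, p))
    expect_gte(sym_kl(p, q), 0)
    # equal unit variances: reduces exactly to the squared mean difference
    expect_equal(sym_kl(c(p[1], 1), c(q[1], 1)), (p[1] - q[1])^2)
  }
})

test_that("training pairs keep only learned modified rows", {
  kmers <- c(all_modified_kmers()[1:10], "ACGTAC", "TTTTTT",
             all_modified_kmers()[11:15])
  prov <- c(rep("learned", 10), "learned", "learned", rep("default", 5))
  em <- emission_table(kmers, seq_along(kmers) + 80, rep(1.5, 17), prov)
  pairs <- build_training_pairs(em)
  expect_length(pairs$mean, 10)
  expect_identical(ncol(pairs$features), 141L)
  # round trip: targets equal stored parameters exactly
  expect_identical(pairs$mean, em$mean[match(pairs$kmer, em$kmer)])
  expect_identical(pairs$var, em$var[match(pairs$kmer, em$kmer)])
  em_bad <- emission_table("ACGTAC", 90, 1, "learned")
  expect_error(build_training_pairs(em_bad), "no learned modified")
})

test_that("the amortizer fits constant targets to near-zero loss", {
  kmers <- all_modified_kmers()[1:100]
  em <- emission_table(kmers, rep(91.5, 100), rep(1.2, 100),
                       rep("learned", 100))
  pairs <- build_training_pairs(em)
  fit <- fit_amortizer(pairs, amortizer_config(epochs = 300, seed = 3))
  expect_lt(fit$history$train[nrow(fit$history)], 1e-3)
  pred <- predict(fit, kmers[1:5])
  expect_equal(pred$mean, rep(91.5, 5), tolerance = 0.05)
  expect_equal(pred$var, rep(1.2, 5), tolerance = 0.05)
})

test_that("fitting is deterministic given the seed", {
  set.seed(10)
  kmers <- sample(all_modified_kmers(), 120)
  em <- emission_table(kmers, rnorm(120, 90, 5), runif(120, 1, 2),
                       rep("learned", 120))
  pairs <- build_training_pairs(em)
  f1 <- fit_amortizer(pairs, amortizer_config(epochs = 50, seed = 7))
  f2 <- fit_amortizer(pairs, amortizer_config(epochs = 50, seed = 7))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$W, f2$W)
})

test_that("amortization recovers feature-linear emission parameters and
           beats the pooled default by a wide margin", {
  model <- generate_pore_model(seed = 3, residual_scale = 0)
  mk <- all_modified_kmers()
  prov <- rep("learned", length(model$kmer))
  em <- emission_table(model$kmer, model$mean, model$var, prov)
  hold <- with_seed(1, sample(seq_along(mk), 500))
  em$provenance[match(mk[hold], em$kmer)] <- "default"
  pairs <- build_training_pairs(em)
  fit <- fit_amortizer(pairs, amortizer_config(epochs = 1000, seed = 1))
  pred <- predict(fit, mk[hold])
  i <- match(mk[hold], model$kmer)
  heldout <- mean(sym_kl_vec(model$mean[i], model$var[i],
                             pred$mean, pred$var))
  pooled_mu <- mean(pairs$mean)
  pooled_var <- mean(pairs$var) + stats::var(pairs$mean)
  baseline <- mean(sym_kl_vec(model$mean[i], model$var[i],
                              pooled_mu, pooled_var))
  expect_lt(heldout, baseline / 5)
})

test_that("imputation fills defaults and never touches learned rows", {
  set.seed(20)
  kmers <- all_modified_kmers()
  means <- rnorm(length(kmers), 90, 5)
  vars <- runif(length(kmers), 1, 2)
  prov <- rep("learned", length(kmers))
  prov[sample(length(kmers), 2000)] <- "default"
  em <- emission_table(c(kmers, "ACGTAC"), c(means, 88), c(vars, 1.4),
                       c(prov, "default"))
  pairs <- build_training_pairs(em)
  fit <- fit_amortizer(pairs, amortizer_config(epochs = 60, seed = 2))
  imp <- impute_emission_table(em, fit)
  was_learned <- em$provenance == "learned"
  expect_identical(imp$mean[was_learned], em$mean[was_learned])
  expect_identical(imp$var[was_learned], em$var[was_learned])
  expect_true(all(imp$provenance[em$provenance == "default" &
                                   grepl("M", em$kmer)] == "imputed"))
  # unmodified defaults untouched
  expect_identical(imp$provenance[match("ACGTAC", imp$kmer)], "default")
  # a table with no modified defaults is returned unchanged
  em_full <- emission_table(kmers, means, vars,
                            rep("learned", length(kmers)))
  expect_identical(impute_emission_table(em_full, fit), em_full)
  # override replaces every modified row
  ov <- override_all_emissions(em, fit)
  expect_true(all(ov$provenance[grepl("M", ov$kmer)] == "imputed"))
  expect_false(identical(ov$mean[was_learned], em$mean[was_learned]))
})

test_that("the combined policy routes by training membership", {
  w <- "GATTTMGCAAC"
  seen_caller <- function(window, ...) "seen"
  unseen_caller <- function(window, ...) "unseen"
  expect_identical(
    combined_policy_call(seen_caller, unseen_caller,
                         decompose_window(w), w), "seen")
  expect_identical(
    combined_policy_call(seen_caller, unseen_caller,
                         decompose_window(w)[-1], w), "unseen")
  expect_identical(
    combined_policy_call(seen_caller, unseen_caller, character(0), w),
    "unseen")
})

test_that("serialization round-trips predictions exactly", {
  set.seed(30)
  kmers <- sample(all_modified_kmers(), 80)
  em <- emission_table(kmers, rnorm(80, 90, 4), runif(80, 1, 2),
                       rep("learned", 80))
  fit <- fit_amortizer(build_training_pairs(em),
                       amortizer_config(epochs = 40, seed = 4))
  path <- tempfile(fileext = ".json")
  write_amortizer(fit, path)
  back <- read_amortizer(path)
  p1 <- predict(fit, kmers[1:10])
  p2 <- predict(back, kmers[1:10])
  expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  expect_equal(p1$var, p2$var, tolerance = 1e-12)
})
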