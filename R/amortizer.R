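## Emission amortization: a small feedforward network maps the 141-bit k-mer
## featurization to Gaussian emission parameters, so that emission
## distributions for modified k-mers absent from training can be imputed
## instead of falling back to a pooled default.  The loss is the symmetrized
## KL divergence between Gaussians, which measures discrepancy between
## distributions rather than between raw parameter values.

#' Symmetrized KL divergence between two Gaussians
#'
#' `sym_kl(p, q) = KL(p || q) + KL(q || p)` with the closed forms
#' `KL(p || q) = log(sd_q/sd_p) + (var_p + (mu_p - mu_q)^2) / (2 var_q) - 1/2`.
#' Symmetric, non-negative, and zero iff the parameters coincide.  In the
#' equal-unit-variance limit it reduces to the squared mean difference.
#'
#' @param p,q Gaussian parameters as length-2 numeric vectors `c(mean, var)`.
#' @return Non-negative number.
#' @examples
#' sym_kl(c(0, 1), c(1, 1))  # 1
#' sym_kl(c(0, 1), c(0, 4))  # 1.125
#' @export
sym_kl <- function(p, q) {
  stopifnot(length(p) == 2L, length(q) == 2L)
  drop(sym_kl_vec(p[1L], p[2L], q[1L], q[2L]))
}

#' @rdname sym_kl
#' @param mean_p,var_p,mean_q,var_q Vectorized Gaussian parameters.
#' @return `sym_kl_vec` returns a numeric vector of divergences.
#' @export
sym_kl_vec <- function(mean_p, var_p, mean_q, var_q) {
  if (any(var_p <= 0) || any(var_q <= 0))
    stop("variances must be positive")
  d2 <- (mean_p - mean_q)^2
  (var_p + d2) / (2 * var_q) + (var_q + d2) / (2 * var_p) - 1
}

#' Amortizer configuration
#'
#' @param d Number of hidden layers, one of 3, 4, 5, 6.
#' @param h Hidden width, one of 16, 32, 64, 128.
#' @param lr Peak learning rate of the Adam-style optimizer (default 4e-2);
#'   the rate follows a cosine decay from `lr` to zero over the epochs.
#' @param epochs Full-batch epochs (default 1000).
#' @param seed Integer seed for the split and weight initialization.
#' @param val_fraction Held-out validation fraction in (0, 1), default 0.2
#'   (an 80/20 random split).
#' @param weight_decay Decoupled L2 weight decay (default 1e-3), which
#'   stabilizes generalization when few k-mers are available for training.
#' @return An `amortizer_config`.
#' @export
amortizer_config <- function(d = 3L, h = 64L, lr = 4e-2, epochs = 1000L,
                             seed = 1L, val_fraction = 0.2,
                             weight_decay = 1e-3) {
  if (!d %in% 3:6) stop("d must be in {3, 4, 5, 6}")
  if (!h %in% c(16L, 32L, 64L, 128L)) stop("h must be in {16, 32, 64, 128}")
  stopifnot(lr > 0, epochs >= 1, val_fraction > 0, val_fraction < 1,
            weight_decay >= 0)
  structure(list(d = as.integer(d), h = as.integer(h), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_fraction = val_fraction, weight_decay = weight_decay),
            class = "amortizer_config")
}

#' Training pairs from a learned emission table
#'
#' One (feature vector, Gaussian parameters) pair per modified k-mer whose
#' emission was learned from data; default and imputed rows, and unmodified
#' k-mers, are excluded.
#'
#' @param em An `emission_table`.
#' @return A `training_pairs` object: list with `kmer`, `features`
#'   (n x 141 binary matrix), `mean`, `var`.
#' @export
build_training_pairs <- function(em) {
  keep <- em$provenance == "learned" & grepl("M", em$kmer, fixed = TRUE)
  if (!any(keep)) stop("no learned modified-k-mer rows in emission table")
  structure(list(kmer = em$kmer[keep],
                 features = featurize_kmers(em$kmer[keep]),
                 mean = em$mean[keep],
                 var = em$var[keep]),
            class = "training_pairs")
}

relu <- function(x) (x > 0) * x

amortizer_forward <- function(net, X) {
  A <- X
  acts <- vector("list", net$d)
  for (l in seq_len(net$d)) {
    A <- relu(sweep(A %*% net$W[[l]], 2L, net$b[[l]], `+`))
    acts[[l]] <- A
  }
  O <- sweep(A %*% net$W[[net$d + 1L]], 2L, net$b[[net$d + 1L]], `+`)
  if (!is.null(net$Ws)) O <- O + X %*% net$Ws   # linear shortcut
  list(out = O, acts = acts)
}

## mean sym_kl loss and its gradient w.r.t. the output head (a, log vhat)
symkl_loss_grad <- function(out, mu, v) {
  a <- out[, 1L]
  b <- pmin(pmax(out[, 2L], -15), 15)
  vhat <- exp(b)
  d2 <- (mu - a)^2
  f <- (v + d2) / (2 * vhat) + (vhat + d2) / (2 * v) - 1
  n <- length(f)
  da <- (a - mu) * (1 / vhat + 1 / v) / n
  db <- (-(v + d2) / (2 * vhat) + vhat / (2 * v)) / n
  list(loss = mean(f), grad = cbind(da, db))
}

#' Fit the emission amortizer
#'
#' Trains a feedforward network (ReLU hidden layers, linear output head
#' predicting the mean and the log variance, so the variance is positive by
#' construction, plus a linear shortcut from the features to the output that
#' captures the dominant position-additive structure of pore models — the
#' hidden stack only has to model what additivity misses) to map k-mer
#' features to Gaussian emission parameters, minimizing the mean symmetrized
#' KL divergence by full-batch Adam-style gradient descent.  Target means are standardized to zero mean and unit
#' variance during training (variances scaled accordingly); the symmetrized
#' KL is invariant under this common affine map, and predictions are
#' de-standardized on output.  An 80/20 (by default) random split tracks a
#' held-out validation loss per epoch.
#'
#' @param pairs A `training_pairs` object (at least 2 pairs).
#' @param cfg An `amortizer_config`.
#' @return An object of class `amortizer` holding the weights, the
#'   standardization constants, the config and the loss `history`.
#' @export
fit_amortizer <- function(pairs, cfg = amortizer_config()) {
  stopifnot(inherits(pairs, "training_pairs"),
            inherits(cfg, "amortizer_config"))
  n <- length(pairs$mean)
  if (n < 2L) stop("need at least 2 training pairs")
  ctr <- mean(pairs$mean)
  scl <- sd(pairs$mean)
  if (!is.finite(scl) || scl == 0) scl <- 1
  X <- pairs$features
  mu <- (pairs$mean - ctr) / scl
  v <- pairs$var / scl^2

  nin <- ncol(X)
  sizes <- c(nin, rep(cfg$h, cfg$d), 2L)
  net <- with_seed(cfg$seed, {
    n_val <- max(1L, round(cfg$val_fraction * n))
    val <- sample.int(n, n_val)
    W <- b <- list()
    for (l in seq_len(cfg$d + 1L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                             sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    # zero-init the output layer: the model starts as the linear shortcut
    # and the hidden stack only contributes what additivity cannot explain
    W[[cfg$d + 1L]] <- W[[cfg$d + 1L]] * 0
    list(W = W, b = b, Ws = matrix(0, nin, 2L), d = cfg$d, val = val)
  })
  tr <- if (length(net$val) < n) setdiff(seq_len(n), net$val) else seq_len(n)

  # Adam state
  mW <- vW <- lapply(net$W, function(w) w * 0)
  mB <- vB <- lapply(net$b, function(x) x * 0)
  mS <- vS <- net$Ws * 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), train = numeric(),
                        val = numeric())
  Xtr <- X[tr, , drop = FALSE]
  Xval <- X[net$val, , drop = FALSE]

  for (ep in seq_len(cfg$epochs)) {
    fw <- amortizer_forward(net, Xtr)
    lg <- symkl_loss_grad(fw$out, mu[tr], v[tr])
    if (!is.finite(lg$loss))
      stop("amortizer training diverged at epoch ", ep,
           " (loss not finite); try a smaller learning rate")
    # backprop
    dO <- lg$grad
    gS <- crossprod(Xtr, dO)
    gW <- gB <- vector("list", net$d + 1L)
    A_prev <- if (net$d) fw$acts[[net$d]] else Xtr
    gW[[net$d + 1L]] <- crossprod(A_prev, dO)
    gB[[net$d + 1L]] <- colSums(dO)
    dA <- tcrossprod(dO, net$W[[net$d + 1L]])
    for (l in rev(seq_len(net$d))) {
      dZ <- dA * (fw$acts[[l]] > 0)
      A_prev <- if (l > 1L) fw$acts[[l - 1L]] else Xtr
      gW[[l]] <- crossprod(A_prev, dZ)
      gB[[l]] <- colSums(dZ)
      if (l > 1L) dA <- tcrossprod(dZ, net$W[[l]])
    }
    corr1 <- 1 - beta1^ep
    corr2 <- 1 - beta2^ep
    lr_ep <- cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
    for (l in seq_len(net$d + 1L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      net$W[[l]] <- net$W[[l]] - lr_ep * ((mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps) + cfg$weight_decay * net$W[[l]])
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
      net$b[[l]] <- net$b[[l]] - lr_ep * (mB[[l]] / corr1) /
        (sqrt(vB[[l]] / corr2) + eps)
    }
    mS <- beta1 * mS + (1 - beta1) * gS
    vS <- beta2 * vS + (1 - beta2) * gS^2
    net$Ws <- net$Ws - lr_ep * ((mS / corr1) / (sqrt(vS / corr2) + eps) +
                                  cfg$weight_decay * net$Ws)
    if (ep %% 25L == 0L || ep == cfg$epochs) {
      vloss <- if (nrow(Xval)) {
        fv <- amortizer_forward(net, Xval)
        symkl_loss_grad(fv$out, mu[net$val], v[net$val])$loss
      } else NA_real_
      history <- rbind(history,
                       data.frame(epoch = ep, train = lg$loss, val = vloss))
    }
  }
  structure(list(W = net$W, b = net$b, Ws = net$Ws, d = cfg$d, h = cfg$h,
                 mu_center = ctr, mu_scale = scl,
                 history = history, cfg = cfg,
                 feature_version = "mono30.di105.cm6"),
            class = "amortizer")
}

#' @export
print.amortizer <- function(x, ...) {
  hist_last <- x$history[nrow(x$history), ]
  cat("emission amortizer: d = ", x$d, ", h = ", x$h,
      ", final train/val sym-KL = ",
      format(hist_last$train, digits = 4), " / ",
      format(hist_last$val, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict emission parameters for k-mers
#'
#' @param object A fitted `amortizer`.
#' @param kmers Character vector of modified k-mers (or a precomputed
#'   feature matrix).
#' @param ... Unused.
#' @return `data.frame` with `kmer` (if given), `mean`, `var`.
#' @export
predict.amortizer <- function(object, kmers, ...) {
  X <- if (is.matrix(kmers)) kmers else featurize_kmers(kmers)
  O <- amortizer_forward(object, X)$out
  b <- pmin(pmax(O[, 2L], -15), 15)
  out <- data.frame(mean = object$mu_center + object$mu_scale * O[, 1L],
                    var = object$mu_scale^2 * exp(b))
  if (!is.matrix(kmers)) out <- cbind(data.frame(kmer = kmers), out)
  out
}

#' Impute missing emission distributions
#'
#' Every modified CpG-context k-mer whose emission is a pooled default (i.e.
#' was not learned from data) is replaced by the amortizer's prediction,
#' with provenance `"imputed"`.  Learned rows are never overridden — using
#' network emissions where data-derived ones exist degrades calling — and
#' unmodified k-mers are untouched.  The result is complete over all
#' modified CpG-context k-mers.
#'
#' @param em An `emission_table`.
#' @param predictor A fitted `amortizer`.
#' @return The imputed `emission_table`.
#' @export
impute_emission_table <- function(em, predictor) {
  target <- em$provenance == "default" & grepl("M", em$kmer, fixed = TRUE)
  if (!any(target)) return(em)
  pred <- predict.amortizer(predictor, em$kmer[target])
  em$mean[target] <- pred$mean
  em$var[target] <- pmax(pred$var, VAR_FLOOR)
  em$provenance[target] <- "imputed"
  em
}

#' Override all modified-k-mer emissions with network predictions
#'
#' Ablation baseline: every modified k-mer's emission (learned or not) is
#' replaced by the amortizer's prediction.  Expected to call worse than
#' imputation-only, which preserves data-derived emissions.
#'
#' @inheritParams impute_emission_table
#' @return The overridden `emission_table`.
#' @export
override_all_emissions <- function(em, predictor) {
  target <- grepl("M", em$kmer, fixed = TRUE)
  pred <- predict.amortizer(predictor, em$kmer[target])
  em$mean[target] <- pred$mean
  em$var[target] <- pmax(pred$var, VAR_FLOOR)
  em$provenance[target] <- "imputed"
  em
}

#' Route a site to a seen- or unseen-k-mer caller
#'
#' A site whose window decomposes entirely into modified k-mers present in
#' the training panel is routed to `seen_caller`; any other site goes to
#' `unseen_caller`.  This realizes the combined-calling policy where one
#' model handles sensor generalization and another handles k-mer
#' generalization.
#'
#' @param seen_caller,unseen_caller Functions taking (window, ...) and
#'   returning a `site_call`.
#' @param training_kmers Character vector of modified k-mers in training.
#' @param site_window The site's methyl window.
#' @param ... Passed through to the chosen caller.
#' @return The chosen caller's `site_call`.
#' @export
combined_policy_call <- function(seen_caller, unseen_caller, training_kmers,
                                 site_window, ...) {
  seen <- all(decompose_window(site_window) %in% training_kmers)
  if (seen) seen_caller(site_window, ...) else unseen_caller(site_window, ...)
}

#' Grid search over amortizer architectures
#'
#' Fits one amortizer per (d, h) combination and reports the final
#' validation symmetrized-KL loss; intended to be run once on k-mer complete
#' data, with the chosen architecture then frozen for all completeness
#' levels.
#'
#' @param pairs A `training_pairs` object.
#' @param d_grid,h_grid Architecture grids (defaults 3:6 and
#'   c(16, 32, 64, 128)).
#' @param ... Further arguments to [amortizer_config()].
#' @return `data.frame` with columns `d`, `h`, `val_loss`, sorted by
#'   `val_loss`; the best row first.
#' @export
grid_search_amortizer <- function(pairs, d_grid = 3:6,
                                  h_grid = c(16L, 32L, 64L, 128L), ...) {
  grid <- expand.grid(d = d_grid, h = h_grid)
  grid$val_loss <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_amortizer(pairs,
                         amortizer_config(d = grid$d[i], h = grid$h[i], ...))
    fit$history$val[nrow(fit$history)]
  }, numeric(1))
  grid[order(grid$val_loss), , drop = FALSE]
}
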