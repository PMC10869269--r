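# Score calibration: per-query Gumbel parameters fitted on alignments
# against a shuffled database, a small feed-forward net predicting those
# parameters from sequence composition and length, the E-value formula with
# its power correction, and the two-gamma mixture posterior probability that
# a match is a true positive.

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and scale `lam` of the Gumbel (extreme value)
#' distribution `F(x) = exp(-exp(-lam (x - mu)))` by damped Newton iteration
#' on the profile equation for `lam`; `mu` follows in closed form.
#'
#' @param scores Numeric vector (at least 30 values, non-degenerate).
#' @return List of class `fs_gumbel` with `mu`, `lam`.
#' @export
fit_gumbel <- function(scores) {
  x <- scores[is.finite(scores)]
  if (length(x) < 30) stop("need at least 30 scores")
  s <- stats::sd(x)
  if (s < 1e-12) stop("degenerate-fit error: all scores equal")
  xbar <- mean(x)
  lam <- pi / (s * sqrt(6))  # moment start
  # profile equation: g(lam) = 1/lam - xbar + sum(x w)/sum(w), w = exp(-lam x)
  g <- function(l) {
    z <- -l * (x - max(x))
    w <- exp(z)
    1 / l - xbar + sum(x * w) / sum(w)
  }
  gp <- function(l) {
    z <- -l * (x - max(x))
    w <- exp(z)
    sw <- sum(w)
    sxw <- sum(x * w)
    sxxw <- sum(x^2 * w)
    -1 / l^2 + (sxw^2 - sxxw * sw) / sw^2
  }
  for (it in 1:200) {
    gv <- g(lam)
    if (abs(gv) < 1e-8) break
    step <- gv / gp(lam)
    new <- lam - step
    damp <- 1
    while (new <= 0 && damp > 1e-6) {
      damp <- damp / 2
      new <- lam - damp * step
    }
    lam <- new
  }
  if (abs(g(lam)) > 1e-6) stop("Gumbel fit did not converge")
  # ML closed form: exp(-lam mu) = mean(exp(-lam x)), computed with a shift
  mx <- max(x)
  mu <- mx - log(mean(exp(-lam * (x - mx)))) / lam
  structure(list(mu = mu, lam = lam), class = "fs_gumbel")
}

#' Sample from a Gumbel distribution
#' @param n Sample size.
#' @param mu,lam Location and scale.
#' @export
rgumbel <- function(n, mu, lam) mu - log(-log(stats::runif(n))) / lam

#' Query features for the E-value model
#'
#' The 22 inputs: the 20 structural-state composition fractions of the
#' query, its length, and `log(length + 1)`.
#'
#' @param entry An [fs_entry].
#' @param use_aa Use the amino-acid composition instead of the
#'   structural-state composition.
#' @export
evalue_features <- function(entry, use_aa = FALSE) {
  s <- seq_chars(if (use_aa) entry$aa_seq else entry$tdi_seq)
  letters <- if (use_aa) strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]] else
    STATE_LETTERS
  s <- s[s != "X"]
  L <- nchar(entry$aa_seq)
  comp <- as.vector(table(factor(s, levels = letters))) /
    max(1, length(s))
  c(comp, L, log(L + 1))
}

#' Build the per-query Gumbel calibration table
#'
#' Shuffles each target's structural-state and amino-acid sequences with the
#' same seeded permutation, aligns every query (without reverse correction)
#' against `n_align` shuffled targets and fits a Gumbel distribution to the
#' resulting bit scores.
#'
#' @param queries,target_db Lists of [fs_entry].
#' @param matrices `list(tdi = , aa = )` of `fs_submat`.
#' @param n_align Alignments per query (>= 30).
#' @param seed Integer seed.
#' @param aln_params An [alignment_params].
#' @return List of class `fs_caltable`: `features` (matrix, one row per
#'   query), `mu`, `lam`, `scores` (list of per-query bit-score vectors).
#' @export
build_calibration_table <- function(queries, target_db, matrices,
                                    n_align = 1000, seed = 1,
                                    aln_params = alignment_params()) {
  if (n_align < 30) stop("config error: n_align must be at least 30")
  if (!length(target_db)) stop("empty target database")
  aln_params$use_reverse_correction <- FALSE
  feats <- NULL
  mus <- lams <- numeric(0)
  scores_all <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    set.seed(seed + qi)
    bits <- numeric(n_align)
    for (a in seq_len(n_align)) {
      t <- target_db[[(a - 1) %% length(target_db) + 1]]
      bits[a] <- align_local(q, shuffle_entry(t), matrices, aln_params)$bit_score
    }
    fit <- fit_gumbel(bits)
    feats <- rbind(feats, evalue_features(q))
    mus <- c(mus, fit$mu)
    lams <- c(lams, fit$lam)
    scores_all[[q$entry_id]] <- bits
  }
  structure(list(features = feats, mu = mus, lam = lams,
                 scores = scores_all),
            class = "fs_caltable")
}

# shuffle both sequences of an entry with one permutation (uses the current
# RNG state); coordinates follow the permutation so lengths stay consistent
shuffle_entry <- function(entry) {
  L <- nchar(entry$aa_seq)
  perm <- sample.int(L)
  fs_entry(paste0(entry$entry_id, "_shuf"),
           paste(seq_chars(entry$aa_seq)[perm], collapse = ""),
           paste(seq_chars(entry$tdi_seq)[perm], collapse = ""),
           entry$ca[perm, , drop = FALSE])
}

#' Train the E-value prediction network
#'
#' Feed-forward net (22 inputs, two hidden layers of 32 ReLU units, two
#' linear outputs) regressing the per-query Gumbel `mu` and `lam` on the
#' query features; mean-squared-error loss, Adam with learning rate 0.001,
#' 90/10 train/validation split with early stopping. Inputs and targets are
#' standardized internally (statistics stored in the model).
#'
#' @param table An `fs_caltable`.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs).
#' @param training_seed Seed controlling initialization and shuffling.
#' @param correction_exponent Exponent applied to raw E-values (default
#'   0.32).
#' @param correction_scale Multiplier applied after the exponent (default 1;
#'   re-estimable together with the exponent via
#'   [calibrate_evalue_correction]).
#' @return An object of class `fs_evalue_model`.
#' @export
train_evalue_net <- function(table, epochs = 300, batch_size = 32,
                             patience = 30, training_seed = 1,
                             correction_exponent = 0.32,
                             correction_scale = 1) {
  X <- as.matrix(table$features)
  Yt <- cbind(table$mu, table$lam)
  if (nrow(X) < 10) stop("too few calibration rows")
  if (any(!is.finite(Yt)))
    stop("non-finite targets in rows: ",
         paste(which(!stats::complete.cases(Yt)), collapse = ", "))
  set.seed(training_seed)
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs < 1e-8] <- 1
  ym <- colMeans(Yt); ys <- apply(Yt, 2, stats::sd); ys[ys < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Ys <- sweep(sweep(Yt, 2, ym), 2, ys, "/")
  n <- nrow(Xs)
  ord <- sample.int(n)
  n_val <- max(1, floor(n / 10))
  val <- ord[seq_len(n_val)]
  tr <- setdiff(ord, val)
  net <- list(nn_linear(ncol(X), 32), nn_relu(), nn_linear(32, 32), nn_relu(),
              nn_linear(32, 2))
  opt <- adam_init()
  best_val <- Inf; best_net <- net; wait <- 0
  for (ep in seq_len(epochs)) {
    ridx <- tr[sample.int(length(tr))]
    for (start in seq(1, length(ridx), by = batch_size)) {
      idx <- ridx[start:min(length(ridx), start + batch_size - 1)]
      fw <- nn_forward(net, Xs[idx, , drop = FALSE], train = TRUE)
      net <- fw$net
      resid <- fw$out - Ys[idx, , drop = FALSE]
      dY <- 2 * resid / length(idx) / 2
      bw <- nn_backward(net, fw$caches, dY)
      st <- adam_step(nn_get_params(net), nn_grads_as_params(net, bw$grads),
                      opt, 0.001)
      net <- nn_set_params(net, st$params)
      opt <- st$state
    }
    pv <- nn_forward(net, Xs[val, , drop = FALSE], train = FALSE)$out
    vloss <- mean((pv - Ys[val, , drop = FALSE])^2)
    if (vloss < best_val - 1e-10) {
      best_val <- vloss; best_net <- net; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  structure(list(net = best_net, x_mean = xm, x_sd = xs, y_mean = ym,
                 y_sd = ys, correction_exponent = correction_exponent,
                 correction_scale = correction_scale,
                 training_seed = training_seed, val_loss = best_val),
            class = "fs_evalue_model")
}

#' Predict per-query Gumbel parameters
#'
#' @param model An `fs_evalue_model`.
#' @param query_features 22-vector (or matrix of rows) from
#'   [evalue_features].
#' @return data.frame with `mu` and `lam` (`lam` clamped positive).
#' @export
predict_gumbel <- function(model, query_features) {
  X <- if (is.matrix(query_features)) query_features else
    matrix(query_features, nrow = 1)
  Xs <- sweep(sweep(X, 2, model$x_mean), 2, model$x_sd, "/")
  out <- nn_forward(model$net, Xs, train = FALSE)$out
  out <- sweep(sweep(out, 2, model$y_sd, "*"), 2, model$y_mean, "+")
  data.frame(mu = out[, 1], lam = pmax(out[, 2], 1e-3))
}

#' E-value of a hit
#'
#' `E_raw = db_size * exp(-lam (s - mu))` with the per-query Gumbel
#' parameters predicted from the query features, corrected as
#' `scale * E_raw^exponent` (searches against scrambled sequences show the
#' mean false-positive count to depend on the raw E-value through a power
#' law; the correction makes the reported E-value match that count).
#'
#' @param model An `fs_evalue_model`.
#' @param query_features Feature vector of the query.
#' @param bit_score Alignment bit score(s).
#' @param db_size Number of target entries.
#' @export
evalue <- function(model, query_features, bit_score, db_size) {
  p <- predict_gumbel(model, query_features)
  e_raw <- db_size * exp(-p$lam[1] * (bit_score - p$mu[1]))
  model$correction_scale * e_raw^model$correction_exponent
}

#' Estimate the E-value correction from a scrambled search
#'
#' Regresses the log of the mean number of hits per query at raw E-value at
#' most x on log x. The fitted slope is the correction exponent and the
#' fitted intercept the correction scale: with
#' `E = scale * E_raw^exponent`, the mean number of scrambled-search hits
#' with E below x matches x.
#'
#' @param raw_evalues Raw E-values of hits from searches with scrambled
#'   queries.
#' @param n_queries Number of queries searched.
#' @param grid E-value thresholds to regress over.
#' @return List with `exponent` and `scale`.
#' @export
calibrate_evalue_correction <- function(raw_evalues, n_queries,
                                        grid = 10^seq(-2, 1, by = 0.5)) {
  counts <- vapply(grid, function(x) sum(raw_evalues <= x), 0) / n_queries
  ok <- counts > 0
  if (sum(ok) < 2) stop("too few hits to estimate the correction")
  co <- stats::coef(stats::lm(log(counts[ok]) ~ log(grid[ok])))
  list(exponent = co[[2]], scale = exp(co[[1]]))
}

# raw E-values of scrambled versions of `queries` searched against the full
# target set (prefilter bypassed, no reverse correction): the input to the
# correction regression
scrambled_raw_evalues <- function(queries, targets, matrices, net, seed,
                                  aln_params = alignment_params()) {
  aln_params$use_reverse_correction <- FALSE
  set.seed(seed)
  out <- numeric(0)
  for (q0 in queries) {
    q <- shuffle_entry(q0)
    p <- predict_gumbel(net, evalue_features(q))
    cbc <- query_cbc(q, matrices, aln_params)
    for (t in targets) {
      b <- align_local(q, t, matrices, aln_params, cbc = cbc)$bit_score
      out <- c(out, length(targets) * exp(-p$lam[1] * (b - p$mu[1])))
    }
  }
  out
}

#' Fit a complete E-value model for a database
#'
#' Convenience driver: builds the shuffled-database Gumbel calibration table
#' for every entry, trains the prediction net, and (optionally) estimates
#' the E-value correction from an independent scrambled search so that
#' reported E-values match observed false-positive counts.
#'
#' @param db List of [fs_entry] (used as both queries and targets).
#' @param matrices `list(tdi = , aa = )` of `fs_submat`.
#' @param n_align Shuffled alignments per query for the Gumbel fits.
#' @param seed Integer seed.
#' @param fit_correction Estimate `correction_exponent` / `correction_scale`
#'   from a scrambled search (otherwise the defaults are kept).
#' @return An `fs_evalue_model`.
#' @export
calibrate_evalue_model <- function(db, matrices, n_align = 150, seed = 1,
                                   fit_correction = TRUE) {
  tab <- build_calibration_table(db, db, matrices, n_align = n_align,
                                 seed = seed)
  net <- train_evalue_net(tab, training_seed = seed)
  if (fit_correction) {
    raw <- scrambled_raw_evalues(db, db, matrices, net, seed = seed + 1000)
    corr <- calibrate_evalue_correction(raw, length(db))
    net$correction_exponent <- corr$exponent
    net$correction_scale <- corr$scale
  }
  net
}

# ---------------------------------------------------------------------------
# two-gamma mixtures and the TP posterior

#' Fit a two-component gamma mixture by EM
#'
#' @param x Positive scores.
#' @param n_restarts Seeded restarts (best log-likelihood kept).
#' @param max_iter,tol EM stopping rule.
#' @param seed Base seed.
#' @return List: `weight` (of component 1), `shape1`, `rate1`, `shape2`,
#'   `rate2`, `loglik`, `trace` (log-likelihood per iteration).
#' @export
fit_gamma_mixture <- function(x, n_restarts = 5, max_iter = 500, tol = 1e-8,
                              seed = 1) {
  if (any(x <= 0)) stop("scores must be positive")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    fit <- tryCatch(gamma_mix_em(x, max_iter, tol), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("gamma mixture EM failed")
  best
}

gamma_mix_em <- function(x, max_iter, tol) {
  n <- length(x)
  # random split initialization around a quantile
  qsplit <- stats::quantile(x, stats::runif(1, 0.3, 0.7))
  lab <- x > qsplit
  w <- mean(lab)
  p1 <- gamma_mle(x[!lab], rep(1, sum(!lab)))
  p2 <- gamma_mle(x[lab], rep(1, sum(lab)))
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- (1 - w) * stats::dgamma(x, p1$shape, p1$rate)
    d2 <- w * stats::dgamma(x, p2$shape, p2$rate)
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    r2 <- d2 / tot
    w <- mean(r2)
    p1 <- gamma_mle(x, 1 - r2)
    p2 <- gamma_mle(x, r2)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weight = 1 - w, shape1 = p1$shape, rate1 = p1$rate,
       shape2 = p2$shape, rate2 = p2$rate, loglik = ll, trace = trace)
}

# weighted gamma MLE: Newton on log(k) - digamma(k) = log(wmean) - wmeanlog
gamma_mle <- function(x, w) {
  sw <- sum(w)
  if (sw < 1e-8) return(list(shape = 1, rate = 1))
  m <- sum(w * x) / sw
  ml <- sum(w * log(x)) / sw
  s <- log(m) - ml
  if (s < 1e-10) s <- 1e-10
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # standard start
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    knew <- k - step
    if (knew <= 0) knew <- k / 2
    if (abs(knew - k) < 1e-12) { k <- knew; break }
    k <- knew
  }
  list(shape = k, rate = k / m)
}

#' Fit the TP / FP score mixtures
#'
#' Fits a two-gamma mixture to the structural bit scores of true-positive
#' and of false-positive matches (non-positive scores are excluded).
#'
#' @param scores_tp,scores_fp Score vectors.
#' @param prior_tp Prior probability of a TP match.
#' @param ... Passed to [fit_gamma_mixture].
#' @return List of class `fs_gamma_pair`: `tp_mix`, `fp_mix`, `prior_tp`.
#' @export
fit_tp_fp_mixtures <- function(scores_tp, scores_fp, prior_tp = 0.5, ...) {
  if (!length(scores_tp) || !length(scores_fp)) stop("empty score list")
  structure(list(tp_mix = fit_gamma_mixture(scores_tp[scores_tp > 0], ...),
                 fp_mix = fit_gamma_mixture(scores_fp[scores_fp > 0], ...),
                 prior_tp = prior_tp),
            class = "fs_gamma_pair")
}

gamma_mix_density <- function(x, mix) {
  mix$weight * stats::dgamma(x, mix$shape1, mix$rate1) +
    (1 - mix$weight) * stats::dgamma(x, mix$shape2, mix$rate2)
}

#' Posterior probability that a match is a true positive
#'
#' Bayes rule over the fitted class-conditional score densities:
#' `p(TP | s) = p(s | TP) p(TP) / (p(s | TP) p(TP) + p(s | FP) p(FP))`,
#' clipped to `[0, 1]`. Where the prior-weighted class densities are equal
#' the probability is 0.5.
#'
#' @param score Structural bit score(s).
#' @param mixtures An `fs_gamma_pair`.
#' @export
p_tp <- function(score, mixtures) {
  dtp <- gamma_mix_density(score, mixtures$tp_mix) * mixtures$prior_tp
  dfp <- gamma_mix_density(score, mixtures$fp_mix) * (1 - mixtures$prior_tp)
  out <- ifelse(dtp + dfp <= 0,
                as.numeric(score > 0) * mixtures$prior_tp, dtp / (dtp + dfp))
  # far above both supports the TP tail dominates; resolve 0/0 overflow there
  hi <- score > max(stats::qgamma(1 - 1e-12, mixtures$fp_mix$shape1,
                                  mixtures$fp_mix$rate1),
                    stats::qgamma(1 - 1e-12, mixtures$fp_mix$shape2,
                                  mixtures$fp_mix$rate2))
  out[hi & mixtures$prior_tp > 0] <- 1
  out[mixtures$prior_tp == 0] <- 0
  pmin(1, pmax(0, out))
}
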