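# Learning the 20-state structural alphabet: a vector-quantized autoencoder
# trained on descriptor pairs from structurally aligned residues, so that the
# discrete states are maximally conserved between homologs. The encoder embeds
# the 10-feature descriptor into a 2D latent space that is discretized by the
# nearest of 20 centroids; the decoder predicts a diagonal Gaussian over the
# aligned partner's descriptor.

#' VQ-VAE training configuration
#'
#' @param n_states Alphabet size.
#' @param latent_dim Continuous latent dimension.
#' @param hidden_dim,hidden_layers Encoder/decoder hidden architecture.
#' @param commitment_cost Weight of the commitment term.
#' @param batch_size,learning_rate,epochs Optimization settings (Adam).
#' @param n_restarts Number of differently-initialized training runs used by
#'   [train_alphabet].
#' @param warmup_epochs Epochs trained without quantization (continuous
#'   latent) before the centroids are initialized by k-means on the encoder
#'   embeddings; stabilizes the codebook at small training-set sizes.
#' @param seed Integer seed; training is deterministic given the seed.
#' @export
vqvae_config <- function(n_states = 20, latent_dim = 2, hidden_dim = 10,
                         hidden_layers = 2, commitment_cost = 0.25,
                         batch_size = 512, learning_rate = 1e-3, epochs = 4,
                         n_restarts = 100, warmup_epochs = 1, seed = 1) {
  structure(list(n_states = n_states, latent_dim = latent_dim,
                 hidden_dim = hidden_dim, hidden_layers = hidden_layers,
                 commitment_cost = commitment_cost, batch_size = batch_size,
                 learning_rate = learning_rate, epochs = epochs,
                 n_restarts = n_restarts, warmup_epochs = warmup_epochs,
                 seed = seed),
            class = "fs_vqvae_config")
}

#' Training-pair filters
#'
#' Alignments below `min_tm` TM-score and aligned residue pairs further than
#' `max_ca_dist` Angstrom apart after superposition are excluded from
#' alphabet training.
#' @param min_tm,max_ca_dist See description.
#' @export
pair_filter_params <- function(min_tm = 0.6, max_ca_dist = 5) {
  stopifnot(min_tm > 0, min_tm <= 1)
  structure(list(min_tm = min_tm, max_ca_dist = max_ca_dist),
            class = "fs_pair_filter")
}

#' Build descriptor training pairs from structurally aligned chains
#'
#' Applies the TM-score and Calpha-distance filters, requires a valid
#' descriptor on both sides, and emits each surviving pair symmetrized:
#' both (x, y) and (y, x).
#'
#' @param alignments List of `list(query, target, pairs, tm)` where `query` /
#'   `target` are [fs_chain] objects or names into `chains`, `pairs` a
#'   2-column matrix of aligned residue indices and `tm` the alignment
#'   TM-score.
#' @param chains Optional named list of [fs_chain] used to resolve names.
#' @param filters A [pair_filter_params].
#' @param vc_params A [virtual_center_params].
#' @return List with matrices `x` and `y` (rows are 10-feature descriptors).
#' @export
build_training_pairs <- function(alignments, chains = NULL,
                                 filters = pair_filter_params(),
                                 vc_params = virtual_center_params()) {
  desc_cache <- new.env(hash = TRUE, parent = emptyenv())
  get_desc <- function(ch) {
    key <- ch$chain_id
    d <- desc_cache[[key]]
    if (is.null(d)) {
      d <- chain_descriptors(reconstruct_cbeta(ch), vc_params)$desc
      desc_cache[[key]] <- d
    }
    d
  }
  xs <- ys <- list()
  for (al in alignments) {
    if (is.null(al$tm) || al$tm < filters$min_tm) next
    q <- if (is.character(al$query)) chains[[al$query]] else al$query
    t <- if (is.character(al$target)) chains[[al$target]] else al$target
    prs <- as.matrix(al$pairs)
    # superpose target onto query over the alignment, then distance-filter
    rt <- kabsch(t$ca[prs[, 2], , drop = FALSE], q$ca[prs[, 1], , drop = FALSE])
    tsup <- apply_rigid(t$ca[prs[, 2], , drop = FALSE], rt)
    dd <- sqrt(rowSums((q$ca[prs[, 1], , drop = FALSE] - tsup)^2))
    prs <- prs[dd <= filters$max_ca_dist, , drop = FALSE]
    if (!nrow(prs)) next
    dq <- get_desc(q)
    dt <- get_desc(t)
    ok <- !is.na(dq[prs[, 1], 1]) & !is.na(dt[prs[, 2], 1])
    prs <- prs[ok, , drop = FALSE]
    if (!nrow(prs)) next
    xs[[length(xs) + 1]] <- dq[prs[, 1], , drop = FALSE]
    ys[[length(ys) + 1]] <- dt[prs[, 2], , drop = FALSE]
    # symmetrize
    xs[[length(xs) + 1]] <- dt[prs[, 2], , drop = FALSE]
    ys[[length(ys) + 1]] <- dq[prs[, 1], , drop = FALSE]
  }
  if (!length(xs)) return(list(x = matrix(0, 0, 10), y = matrix(0, 0, 10)))
  list(x = do.call(rbind, xs), y = do.call(rbind, ys))
}

build_encoder <- function(cfg) {
  net <- list()
  nin <- 10
  for (h in seq_len(cfg$hidden_layers)) {
    net <- c(net, list(nn_linear(nin, cfg$hidden_dim)),
             list(nn_bn(cfg$hidden_dim)), list(nn_relu()))
    nin <- cfg$hidden_dim
  }
  c(net, list(nn_linear(nin, cfg$latent_dim)))
}

build_decoder <- function(cfg) {
  net <- list()
  nin <- cfg$latent_dim
  for (h in seq_len(cfg$hidden_layers)) {
    net <- c(net, list(nn_linear(nin, cfg$hidden_dim)),
             list(nn_bn(cfg$hidden_dim)), list(nn_relu()))
    nin <- cfg$hidden_dim
  }
  c(net, list(nn_linear(nin, 20)))  # mu (10) and log sigma^2 (10)
}

nearest_centroid <- function(latent, centroids) {
  # squared distances via the expansion trick; rows -> centroid index
  d2 <- outer(rowSums(latent^2), rowSums(centroids^2), "+") -
    2 * latent %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Train the vector-quantized autoencoder
#'
#' One training run with the configured seed: descriptors are z-scored per
#' feature (statistics stored in the result and applied at inference),
#' centroids are initialized from encoder outputs of random training
#' descriptors, and the network minimizes the Gaussian negative
#' log-likelihood of the partner descriptor plus the codebook term and
#' `commitment_cost` times the commitment term, with straight-through
#' gradients through the quantization. Centroids unused for a full epoch are
#' re-initialized to a random encoder output.
#'
#' @param pairs List with matrices `x`, `y` from [build_training_pairs].
#' @param config A [vqvae_config].
#' @return An object of class `fs_alphabet`: encoder net, centroids (one row
#'   per state), state letters, feature standardization, decoder net, config
#'   and per-epoch training log.
#' @export
train_vqvae <- function(pairs, config = vqvae_config()) {
  X <- as.matrix(pairs$x)
  Y <- as.matrix(pairs$y)
  N <- nrow(X)
  if (N < config$batch_size)
    stop("config error: fewer pairs (", N, ") than batch_size")
  if (config$n_states > 26) stop("at most 26 states supported")
  set.seed(config$seed)
  fm <- colMeans(X)
  fs <- apply(X, 2, stats::sd)
  fs[fs < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, fm), 2, fs, "/")
  Ys <- sweep(sweep(Y, 2, fm), 2, fs, "/")
  enc <- build_encoder(config)
  dec <- build_decoder(config)
  cent <- NULL
  params <- list(enc = nn_get_params(enc), dec = nn_get_params(dec))
  opt <- adam_init()
  beta <- config$commitment_cost
  log_ <- data.frame(epoch = integer(0), loss = numeric(0),
                     nll = numeric(0), perplexity = numeric(0))
  warmup <- min(config$warmup_epochs, config$epochs - 1)
  for (epoch in seq_len(config$epochs)) {
    quantize <- epoch > warmup
    if (quantize && is.null(cent)) {
      # k-means on the warmed-up embeddings spreads the initial codes over
      # the occupied latent region
      iidx <- sample.int(N, min(N, 4096))
      zi <- nn_forward(enc, Xs[iidx, , drop = FALSE], train = TRUE)$out
      km <- suppressWarnings(stats::kmeans(zi, config$n_states,
                                           nstart = 5, iter.max = 25))
      cent <- km$centers
      dimnames(cent) <- NULL
      params$cent <- cent
    }
    ord <- sample.int(N)
    used <- rep(FALSE, config$n_states)
    ep_loss <- ep_nll <- 0
    nb <- 0
    counts <- rep(0, config$n_states)
    for (start in seq(1, N, by = config$batch_size)) {
      idx <- ord[start:min(N, start + config$batch_size - 1)]
      if (length(idx) < 2) next
      xb <- Xs[idx, , drop = FALSE]
      yb <- Ys[idx, , drop = FALSE]
      fe <- nn_forward(enc, xb, train = TRUE)
      enc <- fe$net
      z_e <- fe$out
      if (quantize) {
        cent <- params$cent
        assign <- nearest_centroid(z_e, cent)
        used[unique(assign)] <- TRUE
        tb <- table(assign)
        counts[as.integer(names(tb))] <- counts[as.integer(names(tb))] +
          as.vector(tb)
        z_q <- cent[assign, , drop = FALSE]
      } else {
        z_q <- z_e
      }
      fd <- nn_forward(dec, z_q, train = TRUE)
      dec <- fd$net
      mu <- fd$out[, 1:10, drop = FALSE]
      logvar <- pmin(pmax(fd$out[, 11:20, drop = FALSE], -10), 10)
      B <- nrow(xb)
      resid <- yb - mu
      nll <- mean(rowSums(0.5 * (logvar + resid^2 / exp(logvar) + log(2 * pi))))
      l_codebook <- if (quantize) mean(rowSums((z_q - z_e)^2)) else 0
      loss <- nll + l_codebook + beta * l_codebook
      # decoder gradients
      dmu <- -resid / exp(logvar) / B
      dlogvar <- 0.5 * (1 - resid^2 / exp(logvar)) / B
      bd <- nn_backward(dec, fd$caches, cbind(dmu, dlogvar))
      # straight-through: decoder input gradient flows to the encoder output;
      # commitment term adds beta * 2 (z_e - c) / B
      dz_e <- bd$dX
      if (quantize) dz_e <- dz_e + beta * 2 * (z_e - z_q) / B
      be <- nn_backward(enc, fe$caches, dz_e)
      # codebook gradient: 2 (c - z_e) / B per assigned sample
      dcent <- matrix(0, config$n_states, config$latent_dim)
      if (quantize) {
        dz <- 2 * (z_q - z_e) / B
        for (d_ in seq_len(config$latent_dim))
          dcent[, d_] <- tapply(dz[, d_],
                                factor(assign,
                                       levels = seq_len(config$n_states)),
                                sum, default = 0)
      }
      grads <- list(enc = nn_grads_as_params(enc, be$grads),
                    dec = nn_grads_as_params(dec, bd$grads),
                    cent = dcent)
      params <- list(enc = nn_get_params(enc), dec = nn_get_params(dec),
                     cent = if (is.null(params$cent))
                       matrix(0, config$n_states, config$latent_dim)
                     else params$cent)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params
      opt <- st$state
      if (!quantize) params$cent <- cent  # keep NULL until initialized
      enc <- nn_set_params(enc, params$enc)
      dec <- nn_set_params(dec, params$dec)
      ep_loss <- ep_loss + loss
      ep_nll <- ep_nll + nll
      nb <- nb + 1
      if (!is.finite(loss)) stop("divergence error: NaN loss in epoch ", epoch)
    }
    # reinitialize dead codes to a random encoder output
    if (quantize && any(!used)) {
      ridx <- sample.int(N, sum(!used))
      fe <- nn_forward(enc, Xs[ridx, , drop = FALSE], train = FALSE)
      params$cent[!used, ] <- fe$out
    }
    p <- counts / max(1, sum(counts))
    perp <- exp(-sum(ifelse(p > 0, p * log(p), 0)))
    log_ <- rbind(log_, data.frame(epoch = epoch, loss = ep_loss / nb,
                                   nll = ep_nll / nb, perplexity = perp))
  }
  structure(list(encoder = enc, centroids = params$cent,
                 state_letters = LETTERS[seq_len(config$n_states)],
                 feat_mean = fm, feat_sd = fs,
                 decoder = dec, config = config, log = log_),
            class = "fs_alphabet")
}

#' @export
print.fs_alphabet <- function(x, ...) {
  cat(sprintf("<fs_alphabet: %d states, final training loss %.3f>\n",
              nrow(x$centroids), utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' Number of inference-path parameters of an alphabet
#'
#' Fully connected encoder parameters (batch-normalization parameters
#' excluded) plus centroid coordinates; 242 + 40 = 282 for the default
#' architecture.
#' @param alphabet An `fs_alphabet`.
#' @export
alphabet_n_params <- function(alphabet) {
  c(encoder = nn_count_params(alphabet$encoder, include_bn = FALSE),
    centroids = length(alphabet$centroids))
}

# encode standardized descriptors to latent coordinates (inference mode)
encode_latent <- function(alphabet, desc) {
  Xs <- sweep(sweep(desc, 2, alphabet$feat_mean), 2, alphabet$feat_sd, "/")
  nn_forward(alphabet$encoder, Xs, train = FALSE)$out
}

# held-out VQ-VAE objective (inference mode), for monitoring
vqvae_eval_loss <- function(alphabet, X, Y) {
  Xs <- sweep(sweep(X, 2, alphabet$feat_mean), 2, alphabet$feat_sd, "/")
  Ys <- sweep(sweep(Y, 2, alphabet$feat_mean), 2, alphabet$feat_sd, "/")
  z_e <- nn_forward(alphabet$encoder, Xs, train = FALSE)$out
  assign <- nearest_centroid(z_e, alphabet$centroids)
  z_q <- alphabet$centroids[assign, , drop = FALSE]
  out <- nn_forward(alphabet$decoder, z_q, train = FALSE)$out
  mu <- out[, 1:10, drop = FALSE]
  logvar <- pmin(pmax(out[, 11:20, drop = FALSE], -10), 10)
  mean(rowSums(0.5 * (logvar + (Ys - mu)^2 / exp(logvar) + log(2 * pi))))
}

#' Encode a chain as a structural-state sequence
#'
#' Residues without a valid descriptor (chain termini, missing backbone
#' atoms, no partner) are encoded `"X"`; all others get the letter of the
#' centroid nearest to the encoder embedding of their descriptor. Encoding is
#' deterministic and rigid-motion invariant.
#'
#' @param chain An [fs_chain].
#' @param alphabet An `fs_alphabet`.
#' @param vc_params A [virtual_center_params].
#' @return The state string (same length as the chain).
#' @export
encode_structure <- function(chain, alphabet,
                             vc_params = virtual_center_params()) {
  chain <- reconstruct_cbeta(chain)
  cd <- chain_descriptors(chain, vc_params)
  L <- length(chain$aa)
  out <- rep("X", L)
  ok <- which(!is.na(cd$desc[, 1]))
  if (length(ok)) {
    z <- encode_latent(alphabet, cd$desc[ok, , drop = FALSE])
    out[ok] <- alphabet$state_letters[nearest_centroid(z, alphabet$centroids)]
  }
  paste(out, collapse = "")
}

#' Select the best alphabet by validation benchmark
#'
#' Returns the candidate maximizing the sum over the family, superfamily and
#' fold levels of the ratio between the candidate's ROC1 AUC and a reference
#' AUC; ties are broken by the lower candidate index.
#'
#' @param candidates List of `fs_alphabet`.
#' @param validation_benchmark List with `eval_fn(alphabet)` returning the
#'   three per-level AUCs and `reference`, the three reference AUCs (same
#'   order).
#' @return The winning `fs_alphabet`, with attribute `"criterion"`.
#' @export
select_best_alphabet <- function(candidates, validation_benchmark) {
  if (!length(candidates)) stop("empty candidate list")
  crit <- vapply(candidates, function(a) {
    auc <- validation_benchmark$eval_fn(a)
    sum(auc / validation_benchmark$reference)
  }, 0)
  best <- which.max(crit)  # which.max takes the first maximum
  out <- candidates[[best]]
  attr(out, "criterion") <- crit
  out
}

#' Train the alphabet with restarts
#'
#' Runs [train_vqvae] `n_restarts` times (seeds `seed`, `seed + 1`, ...) and
#' selects the winner with [select_best_alphabet] when a validation benchmark
#' is supplied, otherwise by lowest final training loss.
#'
#' @inheritParams train_vqvae
#' @param validation Optional validation benchmark (see
#'   [select_best_alphabet]).
#' @export
train_alphabet <- function(pairs, config = vqvae_config(), validation = NULL) {
  cands <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    cands[[r]] <- train_vqvae(pairs, cfg)
  }
  if (!is.null(validation)) return(select_best_alphabet(cands, validation))
  losses <- vapply(cands, function(a) utils::tail(a$log$loss, 1), 0)
  cands[[which.min(losses)]]
}

#' Save / load an alphabet as a self-describing JSON file
#'
#' @param alphabet An `fs_alphabet`.
#' @param path JSON file path.
#' @export
save_alphabet <- function(alphabet, path) {
  obj <- list(encoder = alphabet$encoder, decoder = alphabet$decoder,
              centroids = alphabet$centroids,
              state_letters = alphabet$state_letters,
              feat_mean = alphabet$feat_mean, feat_sd = alphabet$feat_sd,
              config = unclass(alphabet$config), log = alphabet$log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_alphabet
#' @export
load_alphabet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  fix_net <- function(net) lapply(net, function(l) {
    for (f in c("W")) if (!is.null(l[[f]])) l[[f]] <- as.matrix(l[[f]])
    l
  })
  structure(list(encoder = fix_net(obj$encoder), centroids = as.matrix(obj$centroids),
                 state_letters = obj$state_letters,
                 feat_mean = unlist(obj$feat_mean), feat_sd = unlist(obj$feat_sd),
                 decoder = fix_net(obj$decoder),
                 config = do.call(vqvae_config, obj$config[names(formals(vqvae_config))]),
                 log = obj$log),
            class = "fs_alphabet")
}
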