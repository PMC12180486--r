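#' InfoNCE contrastive loss over in-batch negatives
#'
#' For anchor/positive batches of L2-normalized vectors, computes
#' `mean_i -log( exp(cos(a_i, p_i)/tau) / sum_j exp(cos(a_i, p_j)/tau) )`,
#' i.e. each anchor's positive is contrasted against every other positive
#' in the batch. The symmetric variant averages the anchor-to-positive and
#' positive-to-anchor directions.
#'
#' @param anchors,positives B x D matrices with unit-norm rows, B >= 2
#' @param temperature softmax temperature tau > 0
#' @param symmetric average both softmax directions
#' @return scalar loss (always >= 0; equals `log(B)` under uniform logits)
#' @export
info_nce_loss <- function(anchors, positives, temperature = 0.07,
                          symmetric = FALSE) {
  anchors <- as.matrix(anchors); positives <- as.matrix(positives)
  if (!identical(dim(anchors), dim(positives)))
    stop("anchors and positives must have identical shape")
  if (nrow(anchors) < 2) stop("batch size must be >= 2")
  if (temperature <= 0) stop("temperature must be positive")
  check_unit_norms(anchors, what = "anchors")
  check_unit_norms(positives, what = "positives")
  S <- tcrossprod(anchors, positives) / temperature
  loss <- mean(row_logsumexp(S) - diag(S))
  if (symmetric)
    loss <- (loss + mean(row_logsumexp(t(S)) - diag(S))) / 2
  loss
}

## loss + analytic gradients through projection and row re-normalization.
## Za = Xa W (+ b); Ua = Za / |Za|; S = Ua Up' / tau.
proj_pair_loss_grad <- function(W, b, Xa, Xp, temperature, symmetric) {
  B <- nrow(Xa)
  Za <- Xa %*% W
  Zp <- Xp %*% W
  if (!is.null(b)) {
    Za <- sweep(Za, 2, b, "+")
    Zp <- sweep(Zp, 2, b, "+")
  }
  na <- sqrt(rowSums(Za^2))
  np <- sqrt(rowSums(Zp^2))
  if (any(na == 0) || any(np == 0)) stop("zero-norm projected vector")
  Ua <- Za / na
  Up <- Zp / np
  S <- tcrossprod(Ua, Up) / temperature
  loss <- mean(row_logsumexp(S) - diag(S))
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  dS <- (P - diag(B)) / B
  if (symmetric) {
    lossc <- mean(row_logsumexp(t(S)) - diag(S))
    Q <- exp(sweep(S, 2, apply(S, 2, max)))
    Q <- sweep(Q, 2, colSums(Q), "/")
    dS <- (dS + (Q - diag(B)) / B) / 2
    loss <- (loss + lossc) / 2
  }
  Ga <- (dS %*% Up) / temperature
  Gp <- (crossprod(dS, Ua)) / temperature
  dZa <- (Ga - Ua * rowSums(Ga * Ua)) / na
  dZp <- (Gp - Up * rowSums(Gp * Up)) / np
  dW <- crossprod(Xa, dZa) + crossprod(Xp, dZp)
  db <- if (!is.null(b)) colSums(dZa) + colSums(dZp) else NULL
  list(loss = loss, dW = dW, db = db, dZa = dZa, dZp = dZp)
}

#' Training configuration for contrastive projections
#'
#' Defaults are desk-scale: batch 256, 1000 steps, Adam learning rate 1e-2
#' with decoupled weight decay 0.1 and temperature 0.07. Cluster-scale
#' values (batch 32768, 30000 steps, learning rate 1e-4) are accepted
#' through the same fields.
#'
#' @param batch_size pairs per step (>= 2)
#' @param steps optimization steps
#' @param learning_rate Adam step size
#' @param weight_decay decoupled (AdamW-style) weight decay
#' @param temperature InfoNCE temperature
#' @param seed RNG seed controlling init and pair sampling
#' @param d_out output dimension (default `round(d_in / 2.5)`)
#' @param symmetric use the symmetric InfoNCE variant
#' @param bias learn an additive bias in the projection
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 256L, steps = 1000L,
                         learning_rate = 1e-2, weight_decay = 0.1,
                         temperature = 0.07, seed = 1L, d_out = NULL,
                         symmetric = FALSE, bias = FALSE) {
  if (batch_size < 2) stop("batch_size must be >= 2")
  if (steps < 1 || learning_rate <= 0 || temperature <= 0 ||
      weight_decay < 0)
    stop("invalid training configuration")
  structure(list(batch_size = as.integer(batch_size),
                 steps = as.integer(steps), learning_rate = learning_rate,
                 weight_decay = weight_decay, temperature = temperature,
                 seed = as.integer(seed), d_out = d_out,
                 symmetric = symmetric, bias = bias),
            class = "train_config")
}

new_projection_model <- function(W, b, temperature, loss_trace, config) {
  structure(list(weights = W, bias = b, temperature = temperature,
                 d_in = nrow(W), d_out = ncol(W), loss_trace = loss_trace,
                 config = config),
            class = "projection_model")
}

adam_state <- function(dims) list(m = array(0, dims), v = array(0, dims),
                                  t = 0L)

adam_update <- function(par, grad, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  par <- par - lr * (mhat / (sqrt(vhat) + eps) + wd * par)
  list(par = par, st = st)
}

sample_cluster_pairs <- function(groups, sizes, B) {
  cl <- sample.int(length(groups), B, replace = TRUE, prob = sizes)
  a <- character(B); p <- character(B)
  for (i in seq_len(B)) {
    pair <- sample(groups[[cl[i]]], 2L)
    a[i] <- pair[1]; p[i] <- pair[2]
  }
  list(anchors = a, positives = p)
}

#' Train a contrastive linear projection on cluster co-membership
#'
#' Trains a (bias-free by default) linear projection on frozen embeddings so
#' that proteins sharing a cluster label end up with high cosine similarity:
#' each step samples `batch_size` same-cluster (anchor, positive) pairs with
#' distinct members, projects and re-normalizes both batches, and minimizes
#' the InfoNCE loss over in-batch negatives with an Adam optimizer using
#' decoupled weight decay. Fully reproducible under a fixed seed.
#'
#' @param db an [embedding_db()] of frozen input representations
#' @param clusters named vector mapping ids to cluster labels; at least two
#'   clusters must have >= 2 members
#' @param config a [train_config()]
#' @return a `projection_model` (weights, temperature, per-step loss trace)
#' @export
train_projection <- function(db, clusters, config = train_config()) {
  ids <- intersect(db$ids, names(clusters))
  groups <- split(ids, as.character(clusters[ids]))
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 1)
    stop("no cluster with >= 2 members present in the database")
  sizes <- lengths(groups)
  d_in <- db$dim
  d_out <- as.integer(config$d_out %||% round(d_in / 2.5))
  if (d_out > d_in) stop("d_out must be <= d_in")
  set.seed(config$seed)
  W <- matrix(rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out)
  b <- if (config$bias) numeric(d_out) else NULL
  stW <- adam_state(dim(W))
  stb <- if (config$bias) adam_state(d_out) else NULL
  trace <- numeric(config$steps)
  for (step in seq_len(config$steps)) {
    pr <- sample_cluster_pairs(groups, sizes, config$batch_size)
    Xa <- db$matrix[pr$anchors, , drop = FALSE]
    Xp <- db$matrix[pr$positives, , drop = FALSE]
    g <- proj_pair_loss_grad(W, b, Xa, Xp, config$temperature,
                             config$symmetric)
    if (!is.finite(g$loss))
      stop("non-finite loss at step ", step)
    upd <- adam_update(W, g$dW, stW, config$learning_rate,
                       config$weight_decay)
    W <- upd$par; stW <- upd$st
    if (config$bias) {
      updb <- adam_update(b, g$db, stb, config$learning_rate, 0)
      b <- updb$par; stb <- updb$st
    }
    trace[step] <- g$loss
  }
  new_projection_model(W, b, config$temperature, trace, config)
}

#' Project an embedding database through a trained model
#'
#' Rows are mapped through the projection weights and re-normalized; ids
#' and metadata are preserved. The default output dimension at training
#' time is `round(d_in / 2.5)` (1280 in, 512 out).
#'
#' @param model a `projection_model`
#' @param db an `embedding_db` with `db$dim == model$d_in`
#' @return projected `embedding_db` of dimension `model$d_out`
#' @export
project <- function(model, db) {
  if (db$dim != model$d_in)
    stop("database dimension ", db$dim, " does not match projection input ",
         model$d_in)
  Z <- db$matrix %*% model$weights
  if (!is.null(model$bias)) Z <- sweep(Z, 2, model$bias, "+")
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm < 1e-12)) stop("degenerate projection: zero-norm output row")
  out <- Z / nrm
  embedding_db(db$ids, out, metadata = db$metadata, normalize = FALSE)
}

project_vector <- function(model, v) {
  if (length(v) != model$d_in)
    stop("vector dimension ", length(v), " does not match projection input ",
         model$d_in)
  z <- drop(v %*% model$weights)
  if (!is.null(model$bias)) z <- z + model$bias
  normalize_vec(z)
}

#' Hashed bag-of-words text featurizer
#'
#' Deterministic replacement for a trained text encoder: annotation strings
#' are lowercased, tokenized on non-alphanumeric boundaries, and each token
#' is feature-hashed into a signed bucket; vectors are L2-normalized.
#'
#' @param annotations named character vector (id -> free text)
#' @param dim feature dimension
#' @param seed hash seed
#' @return an `embedding_db` over the annotation ids
#' @export
text_featurize <- function(annotations, dim = 256L, seed = 1L) {
  if (is.null(names(annotations)))
    stop("annotations must be a named character vector")
  mat <- matrix(0, length(annotations), dim)
  for (i in seq_along(annotations)) {
    tok <- strsplit(tolower(annotations[[i]]), "[^a-z0-9]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) stop("annotation '", names(annotations)[i],
                           "' has no tokens")
    mat[i, ] <- .hash_tokens_cpp(tok, as.integer(dim), as.integer(seed))
  }
  embedding_db(names(annotations), normalize_rows(mat), normalize = FALSE)
}

#' Train a CLIP-style cross-modal aligner
#'
#' Learns two linear projections - one over protein embeddings, one over
#' text features - into a shared space, trained with the symmetric InfoNCE
#' objective over in-batch negatives on (protein, text) pairs. Both feature
#' sets stay frozen; only the projections are learned.
#'
#' @param protein_db an `embedding_db` of protein vectors
#' @param text_db an `embedding_db` of text feature vectors (e.g. from
#'   [text_featurize()])
#' @param pairs named character vector: protein id -> text id (>= 2 pairs)
#' @param config a [train_config()]; `d_out` defaults to
#'   `round(min(dims)/2.5)`
#' @return a `crossmodal_model`: list with `protein` and `text`
#'   projection models sharing an output space
#' @export
train_crossmodal <- function(protein_db, text_db, pairs,
                             config = train_config(symmetric = TRUE)) {
  if (length(pairs) < 2) stop("need at least 2 protein-text pairs")
  unknown_p <- setdiff(names(pairs), protein_db$ids)
  if (length(unknown_p)) stop("unknown protein id in pairs: ", unknown_p[1])
  unknown_t <- setdiff(unname(pairs), text_db$ids)
  if (length(unknown_t)) stop("unknown text id in pairs: ", unknown_t[1])
  dp <- protein_db$dim; dt <- text_db$dim
  d_out <- as.integer(config$d_out %||% round(min(dp, dt) / 2.5))
  set.seed(config$seed)
  Wp <- matrix(rnorm(dp * d_out, sd = 1 / sqrt(dp)), dp, d_out)
  Wt <- matrix(rnorm(dt * d_out, sd = 1 / sqrt(dt)), dt, d_out)
  stP <- adam_state(dim(Wp)); stT <- adam_state(dim(Wt))
  B <- min(config$batch_size, length(pairs))
  trace <- numeric(config$steps)
  for (step in seq_len(config$steps)) {
    take <- if (length(pairs) >= B) sample(seq_along(pairs), B)
            else sample(seq_along(pairs), B, replace = TRUE)
    Xa <- protein_db$matrix[names(pairs)[take], , drop = FALSE]
    Xt <- text_db$matrix[unname(pairs)[take], , drop = FALSE]
    ## forward both modalities through their own projections
    Za <- Xa %*% Wp; Zt <- Xt %*% Wt
    na <- sqrt(rowSums(Za^2)); nt <- sqrt(rowSums(Zt^2))
    if (any(na == 0) || any(nt == 0)) stop("zero-norm projected vector")
    Ua <- Za / na; Ut <- Zt / nt
    S <- tcrossprod(Ua, Ut) / config$temperature
    loss <- mean(row_logsumexp(S) - diag(S))
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    dS <- (P - diag(B)) / B
    if (config$symmetric) {
      loss <- (loss + mean(row_logsumexp(t(S)) - diag(S))) / 2
      Q <- exp(sweep(S, 2, apply(S, 2, max)))
      Q <- sweep(Q, 2, colSums(Q), "/")
      dS <- (dS + (Q - diag(B)) / B) / 2
    }
    Ga <- (dS %*% Ut) / config$temperature
    Gt <- crossprod(dS, Ua) / config$temperature
    dZa <- (Ga - Ua * rowSums(Ga * Ua)) / na
    dZt <- (Gt - Ut * rowSums(Gt * Ut)) / nt
    if (!is.finite(loss)) stop("non-finite loss at step ", step)
    up <- adam_update(Wp, crossprod(Xa, dZa), stP, config$learning_rate,
                      config$weight_decay)
    Wp <- up$par; stP <- up$st
    ut <- adam_update(Wt, crossprod(Xt, dZt), stT, config$learning_rate,
                      config$weight_decay)
    Wt <- ut$par; stT <- ut$st
    trace[step] <- loss
  }
  structure(list(protein = new_projection_model(Wp, NULL, config$temperature,
                                                trace, config),
                 text = new_projection_model(Wt, NULL, config$temperature,
                                             trace, config)),
            class = "crossmodal_model")
}

#' Save / load a projection model (JSON)
#' @param model a `projection_model`
#' @param path output path
#' @export
save_projection <- function(model, path) {
  obj <- list(weights = model$weights, bias = model$bias,
              temperature = model$temperature, d_in = model$d_in,
              d_out = model$d_out,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_projection
#' @export
load_projection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$weights
  if (!is.matrix(W)) W <- matrix(unlist(W), obj$d_in, obj$d_out, byrow = TRUE)
  b <- if (!is.null(obj$bias) && length(obj$bias)) as.numeric(obj$bias)
       else NULL
  new_projection_model(W, b, obj$temperature, NULL, obj$config)
}
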