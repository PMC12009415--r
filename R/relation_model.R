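#' Model configuration for the BiGRU + attention relation classifier
#'
#' Defaults follow the tuned operating point for this architecture family on
#' imbalanced clinical Q&A relation corpora: batch size 16, 40 epochs,
#' learning rate 5e-4, 32 hidden units per direction, dropout 0.2.
#'
#' @param hidden_units GRU hidden units per direction (`u`); the concatenated
#'   bidirectional representation has width `2u`.
#' @param n_labels Number of relation labels (4: DS, SFD, NSFD, UKN).
#' @param dropout Dropout rate applied to the BiGRU output `H` during
#'   training only.
#' @param learning_rate,batch_size,epochs Optimiser settings.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain mini-batch descent).
#' @param pooling `"attention"` (default) or `"mean"` (ablation: uniform
#'   weights over unmasked positions).
#' @param train_embeddings Whether the lookup-encoder embedding table is
#'   updated during training.
#' @param seed Seed for initialisation, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden_units = 32L, n_labels = 4L, dropout = 0.2,
                         learning_rate = 5e-4, batch_size = 16L,
                         epochs = 40L, optimizer = c("adam", "sgd"),
                         pooling = c("attention", "mean"),
                         train_embeddings = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  pooling <- match.arg(pooling)
  stopifnot(hidden_units >= 1, n_labels >= 2, dropout >= 0, dropout < 1,
            learning_rate >= 0, batch_size >= 1, epochs >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 n_labels = as.integer(n_labels), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 pooling = pooling, train_embeddings = train_embeddings,
                 seed = as.integer(seed)),
            class = "model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# A + bias row vector, column-major broadcast
addb <- function(A, b) A + rep(b, each = nrow(A))

init_gru_dir <- function(D, u) {
  w <- function(n, m) matrix(stats::rnorm(n * m, sd = 0.1), n, m)
  list(Wz = w(D, u), Wr = w(D, u), Wn = w(D, u),
       Uz = w(u, u), Ur = w(u, u), Un = w(u, u),
       bz = numeric(u), br = numeric(u), bn = numeric(u))
}

init_params <- function(D, u, n_labels, seed) {
  with_seed(seed, {
    list(f = init_gru_dir(D, u), b = init_gru_dir(D, u),
         omega = stats::rnorm(2 * u, sd = 0.1),
         Wout = matrix(stats::rnorm(n_labels * 2 * u, sd = 0.1),
                       n_labels, 2 * u),
         bout = numeric(n_labels))
  })
}

# One GRU direction over a batch. X is a list of B x D matrices per
# timestep (in slot order 1..L); `order` gives the traversal direction.
# Masked positions carry the previous state through and emit zero rows.
gru_dir_forward <- function(p, X, mask, order, keep_cache = TRUE) {
  B <- nrow(mask); u <- length(p$bz); L <- ncol(mask)
  h <- matrix(0, B, u)
  H <- vector("list", L)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (t in order) {
    m <- mask[, t]
    x <- X[[t]]
    z <- sigmoid(addb(x %*% p$Wz + h %*% p$Uz, p$bz))
    r <- sigmoid(addb(x %*% p$Wr + h %*% p$Ur, p$br))
    nn <- tanh(addb(x %*% p$Wn + (r * h) %*% p$Un, p$bn))
    hc <- (1 - z) * nn + z * h
    if (keep_cache) cache[[t]] <- list(x = x, z = z, r = r, nn = nn,
                                       h_prev = h)
    H[[t]] <- m * hc
    h <- m * hc + (1 - m) * h
  }
  list(H = H, cache = cache)
}

gru_dir_backward <- function(p, cache, dH, mask, order) {
  B <- nrow(mask); u <- length(p$bz)
  D <- ncol(cache[[order[1]]]$x)
  g <- list(Wz = matrix(0, D, u), Wr = matrix(0, D, u), Wn = matrix(0, D, u),
            Uz = matrix(0, u, u), Ur = matrix(0, u, u), Un = matrix(0, u, u),
            bz = numeric(u), br = numeric(u), bn = numeric(u))
  dh <- matrix(0, B, u)
  dX <- vector("list", length(cache))
  for (t in rev(order)) {
    cc <- cache[[t]]
    m <- mask[, t]
    d_hc <- m * (dh + dH[[t]])
    d_hprev <- (1 - m) * dh
    dz <- d_hc * (cc$h_prev - cc$nn)
    dnn <- d_hc * (1 - cc$z)
    d_hprev <- d_hprev + d_hc * cc$z
    dnn_pre <- dnn * (1 - cc$nn^2)
    g$Wn <- g$Wn + crossprod(cc$x, dnn_pre)
    g$Un <- g$Un + crossprod(cc$r * cc$h_prev, dnn_pre)
    g$bn <- g$bn + colSums(dnn_pre)
    d_rh <- dnn_pre %*% t(p$Un)
    dr <- d_rh * cc$h_prev
    d_hprev <- d_hprev + d_rh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    g$Wz <- g$Wz + crossprod(cc$x, dz_pre)
    g$Uz <- g$Uz + crossprod(cc$h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$Wr <- g$Wr + crossprod(cc$x, dr_pre)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    d_hprev <- d_hprev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
    dX[[t]] <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) +
      dnn_pre %*% t(p$Wn)
    dh <- d_hprev
  }
  list(grads = g, dX = dX)
}

#' Run the BiGRU over one encoded instance
#'
#' Forward and backward GRU passes over the unmasked positions, outputs
#' concatenated per position; masked (padding) positions produce zero rows.
#' With `u` hidden units per direction and sequence length `L`, the result
#' has shape `L x 2u` (e.g. 200 x 64 at the default `u = 32`).
#'
#' @param enc An `encoded_instance` from [encode()].
#' @param params Parameter list from the trained model (or [model_config()]
#'   defaults via internal initialisation).
#' @return Matrix `H` of shape `L x 2u`.
#' @export
bigru_forward <- function(enc, params) {
  L <- length(enc$mask); D <- ncol(enc$matrix)
  if (ncol(params$f$Wz) < 1 || nrow(params$f$Wz) != D)
    stop("config-error: encoder width does not match GRU input dimension")
  X <- lapply(seq_len(L), function(t) enc$matrix[t, , drop = FALSE])
  mask <- matrix(as.numeric(enc$mask), nrow = 1)
  Hf <- gru_dir_forward(params$f, X, mask, seq_len(L), keep_cache = FALSE)$H
  Hb <- gru_dir_forward(params$b, X, mask, rev(seq_len(L)),
                        keep_cache = FALSE)$H
  t(vapply(seq_len(L), function(t) c(Hf[[t]][1, ], Hb[[t]][1, ]),
           numeric(2 * length(params$f$bz))))
}

#' Attention pooling over recurrent states
#'
#' Computes `M = tanh(H)`, scores each position by the trainable vector
#' `omega`, masks padding positions (additive -1e9 before the softmax),
#' normalises with softmax, and returns the weighted sum of the rows of `H`.
#' The weights are a probability distribution over the unmasked positions,
#' so the sentence vector `c` is a convex combination of real-token states.
#'
#' @param H Matrix `L x 2u` of concatenated BiGRU outputs.
#' @param omega Numeric vector of length `2u`.
#' @param mask Logical (or 0/1) vector of length `L`.
#' @return List with `alpha` (length-`L` weights, zero on padding) and `c`
#'   (length-`2u` sentence vector).
#' @export
attention_pool <- function(H, omega, mask) {
  mask <- as.numeric(mask)
  if (sum(mask) == 0) stop("degenerate-input: all positions masked")
  scores <- as.vector(tanh(H) %*% omega)
  scores <- scores + (1 - mask) * -1e9
  scores <- scores - max(scores)
  e <- exp(scores)
  alpha <- e / sum(e)
  alpha[mask == 0] <- 0
  alpha <- alpha / sum(alpha)
  list(alpha = alpha, c = as.vector(crossprod(H, alpha)))
}

#' Softmax classification of a sentence vector
#'
#' @param c Sentence representation (length `2u`).
#' @param W Weight matrix `n_labels x 2u`.
#' @param b Bias vector of length `n_labels`.
#' @param labels Optional label names for the prediction.
#' @return List with `logits`, `probs` (sums to 1) and `predicted` (argmax,
#'   ties broken toward the lowest index).
#' @export
classify <- function(c, W, b, labels = RELATION_LABELS) {
  logits <- as.vector(W %*% c + b)
  if (any(!is.finite(logits))) stop("numeric-error: non-finite logits")
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  idx <- which.max(probs)  # which.max takes the first maximum
  list(logits = logits, probs = probs,
       predicted = if (is.null(labels)) idx else labels[idx])
}

# Batched forward pass; returns loss pieces and (optionally) everything the
# backward pass needs. ids: B x L integer (>=1; padding rows masked out),
# mask: B x L logical. E: vocabulary embedding matrix.
batch_forward <- function(params, E, ids, mask, config, y = NULL,
                          training = FALSE, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids); u <- length(params$f$bz)
  maskn <- mask * 1
  X <- lapply(seq_len(L), function(t) E[pmax(ids[, t], 1L), , drop = FALSE])
  fwd <- gru_dir_forward(params$f, X, maskn, seq_len(L), keep_cache)
  bwd <- gru_dir_forward(params$b, X, maskn, rev(seq_len(L)), keep_cache)
  H <- lapply(seq_len(L), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
  dmask <- NULL
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    dmask <- lapply(seq_len(L), function(t)
      matrix(stats::rbinom(B * 2 * u, 1, keep) / keep, B, 2 * u))
    H <- lapply(seq_len(L), function(t) H[[t]] * dmask[[t]])
  }
  # attention (or uniform mean-pool) over positions
  if (config$pooling == "attention") {
    S <- vapply(seq_len(L), function(t)
      as.vector(tanh(H[[t]]) %*% params$omega), numeric(B))
    S <- matrix(S, B, L)
    S <- S + (1 - maskn) * -1e9
    S <- S - apply(S, 1, max)
    Ez <- exp(S)
    alpha <- Ez / rowSums(Ez)
  } else {
    alpha <- maskn / rowSums(maskn)
  }
  cvec <- matrix(0, B, 2 * u)
  for (t in seq_len(L)) cvec <- cvec + alpha[, t] * H[[t]]
  logits <- addb(cvec %*% t(params$Wout), params$bout)
  lz <- logits - apply(logits, 1, max)
  probs <- exp(lz) / rowSums(exp(lz))
  loss <- NA_real_
  if (!is.null(y)) loss <- -mean(log(pmax(probs[cbind(seq_len(B), y)],
                                          1e-12)))
  list(probs = probs, loss = loss, H = H, alpha = alpha, cvec = cvec,
       X = X, fwd = fwd, bwd = bwd, dmask = dmask, maskn = maskn)
}

batch_backward <- function(params, E, ids, mask, config, y, fw) {
  B <- nrow(ids); L <- ncol(ids); u <- length(params$f$bz)
  Y <- matrix(0, B, config$n_labels)
  Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (fw$probs - Y) / B
  g <- list(Wout = crossprod(dlogits, fw$cvec), bout = colSums(dlogits),
            omega = numeric(2 * u))
  dc <- dlogits %*% params$Wout
  dalpha <- vapply(seq_len(L), function(t) rowSums(dc * fw$H[[t]]),
                   numeric(B))
  dalpha <- matrix(dalpha, B, L)
  dH <- vector("list", L)
  if (config$pooling == "attention") {
    ds <- fw$alpha * (dalpha - rowSums(fw$alpha * dalpha))
    for (t in seq_len(L)) {
      Mt <- tanh(fw$H[[t]])
      g$omega <- g$omega + colSums(Mt * ds[, t])
      dH[[t]] <- outer(ds[, t], params$omega) * (1 - Mt^2) +
        fw$alpha[, t] * dc
    }
  } else {
    for (t in seq_len(L)) dH[[t]] <- fw$alpha[, t] * dc
  }
  if (!is.null(fw$dmask))
    for (t in seq_len(L)) dH[[t]] <- dH[[t]] * fw$dmask[[t]]
  dHf <- lapply(dH, function(d) d[, seq_len(u), drop = FALSE])
  dHb <- lapply(dH, function(d) d[, u + seq_len(u), drop = FALSE])
  bf <- gru_dir_backward(params$f, fw$fwd$cache, dHf, fw$maskn, seq_len(L))
  bb <- gru_dir_backward(params$b, fw$bwd$cache, dHb, fw$maskn,
                         rev(seq_len(L)))
  g$f <- bf$grads
  g$b <- bb$grads
  if (config$train_embeddings) {
    dXall <- do.call(rbind, lapply(seq_len(L), function(t)
      bf$dX[[t]] + bb$dX[[t]]))
    idvec <- pmax(as.vector(ids), 1L)
    used <- as.vector(mask)
    dE <- matrix(0, nrow(E), ncol(E))
    if (any(used)) {
      agg <- rowsum(dXall[used, , drop = FALSE], group = idvec[used])
      dE[as.integer(rownames(agg)), ] <- agg
    }
    g$E <- dE
  }
  g
}

# Adam / SGD over a nested parameter list
make_optimizer <- function(config) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  step <- function(params, grads) {
    state$t <- state$t + 1L
    lr <- config$learning_rate
    walk <- function(p, g, path) {
      if (is.list(p)) {
        for (nm in names(p)) p[[nm]] <- walk(p[[nm]], g[[nm]],
                                             paste0(path, ".", nm))
        return(p)
      }
      if (is.null(g)) return(p)
      if (config$optimizer == "sgd") return(p - lr * g)
      key_m <- paste0(path, ".m"); key_v <- paste0(path, ".v")
      m <- get0(key_m, envir = state, ifnotfound = 0 * g)
      v <- get0(key_v, envir = state, ifnotfound = 0 * g)
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      assign(key_m, m, envir = state)
      assign(key_v, v, envir = state)
      mh <- m / (1 - 0.9^state$t)
      vh <- v / (1 - 0.999^state$t)
      p - lr * mh / (sqrt(vh) + 1e-8)
    }
    walk(params, grads, "p")
  }
  step
}

#' Train the BiGRU + attention relation classifier
#'
#' Minimises categorical cross-entropy by mini-batch gradient descent (Adam
#' by default) with the configured hyperparameters. Dropout is applied to
#' the BiGRU output during training only. The parameters of the epoch with
#' the best validation weighted F1 are returned.
#'
#' @param train_set,val_set Lists of `relation_instance` objects with labels.
#' @param encoder A [lookup_encoder()] built over the training tokens.
#' @param config A [model_config()].
#' @param verbose Print a one-line trace per epoch.
#' @return An object of class `relation_model`: `params`, `encoder`,
#'   `config`, `labels`, and `trace` (data.frame epoch, loss, val_P, val_R,
#'   val_F1).
#' @export
train_relation_model <- function(train_set, val_set, encoder,
                                 config = model_config(), verbose = FALSE) {
  if (length(train_set) == 0) stop("empty training set")
  labels <- RELATION_LABELS[seq_len(config$n_labels)]
  tr <- batch_ids(encoder, train_set)
  va <- batch_ids(encoder, val_set)
  keep <- rowSums(tr$mask) > 0 & tr$valid
  tr$ids <- tr$ids[keep, , drop = FALSE]
  tr$mask <- tr$mask[keep, , drop = FALSE]
  tr$labels <- tr$labels[keep]
  y_tr <- match(tr$labels, labels)
  y_va <- match(va$labels, labels)
  stopifnot(!anyNA(y_tr), !anyNA(y_va))
  params <- init_params(encoder$D, config$hidden_units, config$n_labels,
                        config$seed)
  if (config$train_embeddings) params$E <- encoder$E
  E_of <- function(p) if (config$train_embeddings) p$E else encoder$E
  opt <- make_optimizer(config)
  n <- nrow(tr$ids)
  best <- list(f1 = -Inf, params = params)
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      val_P = numeric(), val_R = numeric(),
                      val_F1 = numeric())
  eval_val <- function(p) {
    pr <- predict_batch(p, E_of(p), va$ids, va$mask, config)
    rep_ <- metric_report(labels[y_va], labels[pr$pred],
                          pr$probs, labels = labels)
    tot <- rep_[rep_$class == "Total", ]
    c(P = tot$precision, R = tot$recall, F1 = tot$f1)
  }
  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0; nb <- 0
    with_seed(derive_seed(config$seed, epoch), {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1, n)]
        ids_b <- tr$ids[bi, , drop = FALSE]
        mask_b <- tr$mask[bi, , drop = FALSE]
        Lmax <- max(which(colSums(mask_b) > 0))
        ids_b <- ids_b[, seq_len(Lmax), drop = FALSE]
        mask_b <- mask_b[, seq_len(Lmax), drop = FALSE]
        fw <- batch_forward(params, E_of(params), ids_b, mask_b, config,
                            y = y_tr[bi], training = TRUE,
                            keep_cache = TRUE)
        gr <- batch_backward(params, E_of(params), ids_b, mask_b, config,
                             y_tr[bi], fw)
        params <- opt(params, gr)
        epoch_loss <- epoch_loss + fw$loss; nb <- nb + 1
      }
    })
    vm <- eval_val(params)
    trace <- rbind(trace, data.frame(epoch = epoch, loss = epoch_loss / nb,
                                     val_P = vm["P"], val_R = vm["R"],
                                     val_F1 = vm["F1"]))
    if (vm["F1"] > best$f1) best <- list(f1 = vm["F1"], params = params)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val F1 %.4f", epoch,
                      epoch_loss / nb, vm["F1"]))
  }
  if (config$epochs == 0) best$params <- params
  rownames(trace) <- NULL
  final_enc <- encoder
  if (config$train_embeddings && !is.null(best$params$E))
    final_enc$E <- best$params$E
  structure(list(params = best$params, encoder = final_enc,
                 config = config, labels = labels, trace = trace),
            class = "relation_model")
}

predict_batch <- function(params, E, ids, mask, config) {
  B <- nrow(ids)
  pred <- integer(B)
  probs <- matrix(NA_real_, B, config$n_labels)
  ok <- rowSums(mask) > 0
  if (any(ok)) {
    fw <- batch_forward(params, E, ids[ok, , drop = FALSE],
                        mask[ok, , drop = FALSE], config,
                        training = FALSE, keep_cache = FALSE)
    probs[ok, ] <- fw$probs
    pred[ok] <- max.col(fw$probs, ties.method = "first")
  }
  pred[!ok] <- 1L
  list(pred = pred, probs = probs)
}

#' Predict relation labels for marked instances
#'
#' @param object A trained `relation_model`.
#' @param instances List of `relation_instance` objects (labels ignored).
#' @param ... Unused.
#' @return A list with `labels` (character), `probs` (matrix, one column per
#'   relation label).
#' @export
predict.relation_model <- function(object, instances, ...) {
  ba <- batch_ids(object$encoder, instances)
  pr <- predict_batch(object$params,
                      if (object$config$train_embeddings &&
                          !is.null(object$params$E)) object$params$E
                      else object$encoder$E,
                      ba$ids, ba$mask, object$config)
  colnames(pr$probs) <- object$labels
  list(labels = object$labels[pr$pred], probs = pr$probs)
}

#' Extract relation triples from Q&A records
#'
#' Enumerates all ordered (DIS, SYM) and (DIS, TRE) mention pairs per record,
#' classifies each marked instance, and emits one triple per pair. UKN
#' predictions are kept here and dropped when dictionaries are assembled.
#'
#' @param records List of [qa_record()] objects with mentions.
#' @param model A trained `relation_model`.
#' @return A data.frame with columns `record_id`, `entity1`, `entity2`,
#'   `relation`, `prob`.
#' @export
predict_triples <- function(records, model) {
  rows <- list()
  insts <- list()
  for (rec in records) {
    for (pair in candidate_pairs(rec)) {
      inst <- make_marked_instance(rec, pair$e1, pair$e2, "UKN",
                                   escape = TRUE)
      insts[[length(insts) + 1L]] <- inst
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rec$record_id, entity1 = pair$e1$surface,
        entity2 = pair$e2$surface, stringsAsFactors = FALSE)
    }
  }
  if (length(insts) == 0)
    return(data.frame(record_id = character(), entity1 = character(),
                      entity2 = character(), relation = character(),
                      prob = numeric(), stringsAsFactors = FALSE))
  pr <- predict(model, insts)
  out <- do.call(rbind, rows)
  out$relation <- pr$labels
  out$prob <- apply(pr$probs, 1, max)
  rownames(out) <- NULL
  out
}
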