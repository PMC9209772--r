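# Multi-stream CBAM-GRU gesture classifier.
#
# One independent branch per input stream (each retained sEMG channel is a
# stream; the 3-axis accelerometer is one extra stream). A branch is
# conv1d -> [BN] -> ReLU (x n blocks), with the 1-D CBAM inserted after the
# last ReLU, then a GRU consuming the attended feature map as a T-step
# sequence (last hidden state = stream vector). Without the GRU the stream
# vector is the global time-average of the conv features. Branch vectors
# are concatenated along the feature-channel axis and classified by a
# dropout fully-connected layer followed by a softmax fully-connected layer
# of size M.

#' Model configuration
#'
#' @param n_semg_streams number of single-channel sEMG branches (default 6,
#'   the retained electrodes after redundancy pruning).
#' @param use_acc add the 3-axis accelerometer as an extra branch?
#' @param input_mode `"raw_windows"` (each branch sees a `T x 1` filtered
#'   signal window) or `"feature_images"` (each branch sees a
#'   `n_sub x 4` window of sub-window features).
#' @param conv_blocks list of `c(out_channels, kernel, stride)` per block;
#'   kernels must be odd.
#' @param use_bn,use_cbam,use_gru component switches (the five ablation
#'   variants toggle exactly these).
#' @param cbam_r CBAM compression rate; the last conv width must be a
#'   multiple of it.
#' @param cbam_mlp_bias enable biases in the shared CBAM perceptron.
#' @param gru_hidden GRU hidden size.
#' @param fc_hidden width of the dropout fully-connected layer.
#' @param dropout_p dropout probability in `[0, 1)`.
#' @param n_classes number of gesture classes M.
#' @param seed integer; fixes every randomly drawn weight.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_semg_streams = 6, use_acc = TRUE,
                         input_mode = c("raw_windows", "feature_images"),
                         conv_blocks = list(c(32, 3, 1), c(64, 3, 1)),
                         use_bn = TRUE, use_cbam = TRUE, use_gru = TRUE,
                         cbam_r = 8, cbam_mlp_bias = FALSE,
                         gru_hidden = 64, fc_hidden = 64,
                         dropout_p = 0.5, n_classes = 52, seed = 1) {
  input_mode <- match.arg(input_mode)
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  for (b in conv_blocks)
    if (b[2] %% 2 == 0) stop("conv kernel sizes must be odd")
  cout <- conv_blocks[[length(conv_blocks)]][1]
  if (use_cbam && cout %% cbam_r != 0)
    stop("last conv width must be a multiple of cbam_r")
  structure(list(n_semg_streams = n_semg_streams, use_acc = use_acc,
                 input_mode = input_mode, conv_blocks = conv_blocks,
                 use_bn = use_bn, use_cbam = use_cbam, use_gru = use_gru,
                 cbam_r = cbam_r, cbam_mlp_bias = cbam_mlp_bias,
                 gru_hidden = gru_hidden, fc_hidden = fc_hidden,
                 dropout_p = dropout_p, n_classes = n_classes, seed = seed),
            class = "model_config")
}

stream_cin <- function(cfg) {
  per_semg <- if (cfg$input_mode == "raw_windows") 1L else 4L
  cins <- rep(per_semg, cfg$n_semg_streams)
  if (cfg$use_acc) cins <- c(cins, 3L)
  cins
}

init_stream <- function(cin, cfg) {
  blocks <- list()
  for (b in cfg$conv_blocks) {
    blk <- list(conv = conv1d_init(cin, b[1], b[2]), stride = b[3])
    if (cfg$use_bn) blk$bn <- bn_init(b[1])
    blocks[[length(blocks) + 1L]] <- blk
    cin <- b[1]
  }
  s <- list(blocks = blocks)
  if (cfg$use_cbam) s$cbam <- cbam_init(cin, cfg$cbam_r, cfg$cbam_mlp_bias)
  if (cfg$use_gru) s$gru <- gru_init(cin, cfg$gru_hidden)
  s
}

#' Build a multi-stream gesture recognition model
#'
#' Weight initialisation is fully determined by `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @return list of class `semg_model` with `streams`, `head`, `cfg`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  cins <- stream_cin(cfg)
  streams <- lapply(cins, init_stream, cfg = cfg)
  cout <- cfg$conv_blocks[[length(cfg$conv_blocks)]][1]
  stream_dim <- if (cfg$use_gru) cfg$gru_hidden else cout
  D <- stream_dim * length(cins)
  head <- list(fc1 = dense_init(D, cfg$fc_hidden),
               fc2 = dense_init(cfg$fc_hidden, cfg$n_classes))
  structure(list(streams = streams, head = head, cfg = cfg,
                 stream_dim = stream_dim), class = "semg_model")
}

#' @export
print.semg_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<semg_model> %d streams (%s%s), %s%s%s-> %d classes\n",
              length(x$streams), cfg$input_mode,
              if (cfg$use_acc) " + ACC" else "",
              if (cfg$use_bn) "BN " else "",
              if (cfg$use_cbam) "CBAM " else "",
              if (cfg$use_gru) "GRU " else "",
              cfg$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `semg_model`.
#' @return integer count over all weight matrices and bias vectors.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(x, nm) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (k in names(x)) walk(x[[k]], k)
  }
  for (s in model$streams)
    for (blk in s$blocks) { walk(blk$conv$W, "W"); walk(blk$conv$b, "b")
      if (!is.null(blk$bn)) { walk(blk$bn$gamma, "g"); walk(blk$bn$beta, "b") } }
  for (s in model$streams) {
    if (!is.null(s$cbam)) {
      walk(s$cbam$ch$W0, "W0"); walk(s$cbam$ch$W1, "W1")
      if (!is.null(s$cbam$ch$b0)) { walk(s$cbam$ch$b0, "b0"); walk(s$cbam$ch$b1, "b1") }
      walk(s$cbam$tmp$conv$W, "W"); walk(s$cbam$tmp$conv$b, "b")
    }
    if (!is.null(s$gru)) { walk(s$gru$W, "W"); walk(s$gru$U, "U")
      walk(s$gru$b, "b"); walk(s$gru$bhn, "bhn") }
  }
  walk(model$head$fc1$W, "W"); walk(model$head$fc1$b, "b")
  walk(model$head$fc2$W, "W"); walk(model$head$fc2$b, "b")
  n
}

#' Shapes of every trainable tensor, for structural comparison
#'
#' @param model a `semg_model`.
#' @return named character vector mapping parameter paths to dim strings.
#' @export
param_manifest <- function(model) {
  out <- character(0)
  emit <- function(x, path) {
    if (is.numeric(x)) {
      out[[path]] <<- paste(if (is.null(dim(x))) length(x) else dim(x),
                            collapse = "x")
    } else if (is.list(x)) {
      keys <- names(x)
      if (is.null(keys)) keys <- as.character(seq_along(x))
      for (k in keys)
        if (!k %in% c("k", "cin", "cout", "H", "r", "run_mean", "run_var",
                      "stride"))
          emit(x[[if (is.na(suppressWarnings(as.integer(k)))) k else
                    as.integer(k)]], paste(path, k, sep = "."))
    }
  }
  for (i in seq_along(model$streams))
    emit(model$streams[[i]], sprintf("stream%02d", i))
  emit(model$head, "head")
  out
}

## ---- forward / backward --------------------------------------------------

forward_stream_full <- function(X, s, cfg, training) {
  caches <- list()
  H <- X
  for (i in seq_along(s$blocks)) {
    blk <- s$blocks[[i]]
    cv <- conv1d_forward(H, blk$conv, blk$stride)
    H <- cv$out
    bn <- NULL
    if (!is.null(blk$bn)) {
      bn <- bn_forward(H, blk$bn, training)
      H <- bn$out
      s$blocks[[i]]$bn <- bn$par           # running stats update
    }
    rl <- relu_forward(H)
    H <- rl$out
    caches[[i]] <- list(cv = cv, bn = bn, rl = rl)
  }
  cb <- NULL
  if (!is.null(s$cbam)) {
    cb <- cbam_forward(H, s$cbam)
    H <- cb$out
  }
  if (!is.null(s$gru)) {
    gr <- gru_forward(H, s$gru)
    vec <- gr$out
  } else {
    gr <- NULL
    vec <- colMeans(aperm(H, c(2, 1, 3)))          # time-average -> [B, C]
  }
  list(vec = vec, stream = s,
       cache = list(blocks = caches, cb = cb, gr = gr, dims = dim(H)))
}

backward_stream_full <- function(dvec, s, cache) {
  grads <- list(blocks = vector("list", length(s$blocks)))
  if (!is.null(s$gru)) {
    gb <- gru_backward(dvec, cache$gr$cache)
    dH <- gb$dX
    grads$gru <- gb$grads
  } else {
    d <- cache$dims
    dH <- array(0, d)
    for (c in seq_len(d[3])) dH[, , c] <- dvec[, c] / d[2]
  }
  if (!is.null(s$cbam)) {
    cbb <- cbam_backward(dH, cache$cb$cache)
    dH <- cbb$dX
    grads$cbam <- cbb$grads
  }
  for (i in rev(seq_along(s$blocks))) {
    cc <- cache$blocks[[i]]
    dH <- relu_backward(dH, cc$rl$cache)
    gblk <- list()
    if (!is.null(cc$bn)) {
      bnb <- bn_backward(dH, cc$bn$cache)
      dH <- bnb$dX
      gblk$bn <- bnb$grads
    }
    cvb <- conv1d_backward(dH, cc$cv$cache)
    dH <- cvb$dX
    gblk$conv <- cvb$grads
    grads$blocks[[i]] <- gblk
  }
  list(grads = grads)
}

forward_model <- function(model, x, training = FALSE, return_cache = FALSE) {
  n_stream <- length(model$streams)
  vecs <- vector("list", n_stream)
  caches <- vector("list", n_stream)
  for (i in seq_len(n_stream)) {
    fs <- forward_stream_full(x[[i]], model$streams[[i]], model$cfg, training)
    vecs[[i]] <- fs$vec
    caches[[i]] <- fs$cache
    model$streams[[i]] <- fs$stream
  }
  Z <- do.call(cbind, vecs)
  f1 <- dense_forward(Z, model$head$fc1)
  r1 <- relu_forward(f1$out)
  dp <- dropout_forward(r1$out, model$cfg$dropout_p, training)
  f2 <- dense_forward(dp$out, model$head$fc2)
  res <- list(logits = f2$out, model = model)
  if (return_cache)
    res$cache <- list(stream = caches, Z = Z, f1 = f1, r1 = r1, dp = dp,
                      f2 = f2)
  res
}

backward_model <- function(model, dlogits, cache) {
  b2 <- dense_backward(dlogits, cache$f2$cache)
  dd <- dropout_backward(b2$dX, cache$dp$cache)
  dr <- relu_backward(dd, cache$r1$cache)
  b1 <- dense_backward(dr, cache$f1$cache)
  dZ <- b1$dX
  sd_ <- model$stream_dim
  grads <- list(streams = vector("list", length(model$streams)),
                head = list(fc1 = b1$grads, fc2 = b2$grads))
  for (i in seq_along(model$streams)) {
    dvec <- dZ[, ((i - 1) * sd_ + 1):(i * sd_), drop = FALSE]
    grads$streams[[i]] <-
      backward_stream_full(dvec, model$streams[[i]], cache$stream[[i]])$grads
  }
  grads
}

#' Forward one stream branch
#'
#' Runs a single branch of the model (conv blocks, optional BN, ReLU,
#' optional CBAM, optional GRU) in eval mode and returns the stream feature
#' vector(s).
#'
#' @param stream_input array `[B, T, cin]` or matrix `T x cin` (treated as
#'   batch of 1).
#' @param model a `semg_model`; @param which stream index.
#' @return matrix `[B, stream_dim]`.
#' @export
forward_stream <- function(stream_input, model, which = 1) {
  if (is.matrix(stream_input))
    stream_input <- array(stream_input, c(1L, dim(stream_input)))
  exp_cin <- stream_cin(model$cfg)[which]
  if (dim(stream_input)[3] != exp_cin)
    stop(sprintf("stream %d expects %d input channel(s), got %d",
                 which, exp_cin, dim(stream_input)[3]))
  forward_stream_full(stream_input, model$streams[[which]], model$cfg,
                      training = FALSE)$vec
}

#' Aggregate stream vectors and classify
#'
#' Concatenates the branch outputs along the feature-channel axis, applies
#' the fully-connected head, and returns the label vector `g`, the softmax
#' probabilities `p(m|g)` and the decision `m0 = argmax_m p(m|g)` (lowest
#' index on ties).
#'
#' @param stream_outputs list of numeric vectors (one per stream) or
#'   matrices `[B, dim]`.
#' @param model a `semg_model` providing the head weights.
#' @return list of class `class_scores`: `g`, `p`, `m0`.
#' @export
aggregate_and_classify <- function(stream_outputs, model) {
  if (!length(stream_outputs)) stop("empty stream output list")
  mats <- lapply(stream_outputs, function(v)
    if (is.matrix(v)) v else matrix(v, 1))
  Z <- do.call(cbind, mats)
  f1 <- dense_forward(Z, model$head$fc1)
  r1 <- relu_forward(f1$out)
  f2 <- dense_forward(r1$out, model$head$fc2)
  g <- f2$out
  p <- softmax_probs(g)
  structure(list(g = drop(g), p = drop(p), m0 = decide_class(p)),
            class = "class_scores")
}

## ---- training -------------------------------------------------------------

model_params <- function(model) list(streams = model$streams, head = model$head)

model_set_params <- function(model, params) {
  # merge trained tensors back, keeping non-numeric bookkeeping fields
  model$streams <- params$streams
  model$head <- params$head
  model
}

#' Train the gesture classifier
#'
#' Adam on the softmax cross-entropy, mini-batches reshuffled each epoch.
#' All randomness (shuffling, dropout) is driven by `opts$seed`, so two runs
#' with the same seed produce identical final weights.
#'
#' @param model a `semg_model` from [build_model()].
#' @param dataset list with `x` (list of per-stream arrays `[N, T, cin]`)
#'   and `y` (integer labels in 1..M).
#' @param opts list: `lr` (default 1e-3), `batch` (64), `epochs` (10),
#'   `seed` (1).
#' @return list with `model` (trained) and `history` (data.frame: epoch,
#'   loss, train_acc).
#' @export
train_model <- function(model, dataset, opts = list()) {
  o <- utils::modifyList(list(lr = 1e-3, batch = 64, epochs = 10, seed = 1,
                              verbose = FALSE), opts)
  y <- dataset$y
  if (!all(seq_len(model$cfg$n_classes) %in% y))
    stop("every class must appear in the training set")
  N <- length(y)
  set.seed(o$seed)
  astate <- list(t = 0L, m = tree_zeros(model_params(model)),
                 v = tree_zeros(model_params(model)))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0))
  for (ep in seq_len(o$epochs)) {
    idx <- sample.int(N)
    losses <- c(); correct <- 0L
    for (start in seq(1, N, by = o$batch)) {
      bi <- idx[start:min(start + o$batch - 1, N)]
      xb <- lapply(dataset$x, function(a) a[bi, , , drop = FALSE])
      fw <- forward_model(model, xb, training = TRUE, return_cache = TRUE)
      model <- fw$model
      sx <- softmax_xent(fw$logits, y[bi])
      losses <- c(losses, sx$loss)
      correct <- correct + sum(decide_class(sx$p) == y[bi])
      grads <- backward_model(model, sx$dlogits, fw$cache)
      upd <- adam_step(model_params(model),
                       list(streams = grads$streams, head = grads$head),
                       astate, lr = o$lr)
      model <- model_set_params(model, upd$params)
      astate <- upd$state
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   train_acc = correct / N))
    if (isTRUE(o$verbose))
      message(sprintf("epoch %d  loss %.4f  acc %.3f",
                      ep, mean(losses), correct / N))
  }
  list(model = model, history = hist)
}

#' Predict class labels for a window dataset
#'
#' @param model trained `semg_model`.
#' @param x list of per-stream arrays `[N, T, cin]`.
#' @param batch forward batch size.
#' @return list with `logits` `[N, M]`, `p`, `labels` (argmax, lowest index
#'   on ties).
#' @export
predict_model <- function(model, x, batch = 256) {
  N <- dim(x[[1]])[1]
  logits <- NULL
  for (start in seq(1, N, by = batch)) {
    bi <- start:min(start + batch - 1, N)
    xb <- lapply(x, function(a) a[bi, , , drop = FALSE])
    fw <- forward_model(model, xb, training = FALSE)
    logits <- rbind(logits, fw$logits)
  }
  p <- softmax_probs(logits)
  list(logits = logits, p = p, labels = decide_class(p))
}

#' Accuracy and confusion matrix on a test set
#'
#' Rows are actual labels, columns predicted; accuracy is the trace over
#' the total count.
#'
#' @param model trained `semg_model`.
#' @param x per-stream input arrays; @param y integer labels 1..M.
#' @return list with `accuracy` and `confusion` (M x M integer matrix).
#' @export
evaluate_confusion <- function(model, x, y) {
  M <- model$cfg$n_classes
  pred <- predict_model(model, x)$labels
  cm <- matrix(0L, M, M, dimnames = list(actual = 1:M, predicted = 1:M))
  for (i in seq_along(y)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1L
  list(accuracy = sum(diag(cm)) / length(y), confusion = cm)
}

## ---- ablation experiments --------------------------------------------------

#' Configuration for one of the five ablation variants
#'
#' The variants toggle only the stated components on a shared base
#' configuration: I multi-stream convolution; II +BN; III +BN+GRU;
#' IV +BN+CBAM; V +BN+CBAM+GRU.
#'
#' @param experiment integer 1..5 (or "I".."V").
#' @param base a [model_config()] supplying everything else.
#' @return a [model_config()].
#' @export
ablation_config <- function(experiment, base = model_config()) {
  if (is.character(experiment))
    experiment <- match(toupper(experiment), c("I", "II", "III", "IV", "V"))
  flags <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE))[[experiment]]
  base$use_bn <- flags[1]; base$use_cbam <- flags[2]; base$use_gru <- flags[3]
  base
}

ablation_labels <- c("multi-stream convolution", "+ BN", "+ BN + GRU",
                     "+ BN + 1D CBAM", "+ BN + 1D CBAM + GRU")

#' Run the five-variant ablation study
#'
#' Trains every variant on the same data and seeds and reports the mean
#' test accuracy per variant, one row per experiment in the fixed order.
#'
#' @param dataset list with `train` and `test`, each `list(x, y)`.
#' @param seeds integer vector; each variant is trained once per seed.
#' @param base a [model_config()]; per the study design the ablations run
#'   sEMG-only, so callers usually pass `use_acc = FALSE` data and config.
#' @param opts training options as in [train_model()].
#' @return data.frame: experiment, components, mean accuracy, one column
#'   per seed.
#' @export
run_ablation <- function(dataset, seeds = 1:5, base = model_config(),
                         opts = list()) {
  acc <- matrix(NA_real_, 5, length(seeds),
                dimnames = list(NULL, paste0("seed", seeds)))
  for (e in 1:5) {
    cfg <- ablation_config(e, base)
    for (j in seq_along(seeds)) {
      cfg$seed <- seeds[j]
      tr <- train_model(build_model(cfg), dataset$train,
                        utils::modifyList(opts, list(seed = seeds[j])))
      acc[e, j] <- evaluate_confusion(tr$model, dataset$test$x,
                                      dataset$test$y)$accuracy
    }
  }
  data.frame(experiment = c("I", "II", "III", "IV", "V"),
             components = ablation_labels,
             accuracy = rowMeans(acc), acc,
             row.names = NULL, check.names = FALSE)
}
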