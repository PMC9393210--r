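# Model specifications and the training protocol for the MLP branch, the
# CNN branch and the combined two-branch classifier.

#' MLP branch specification
#'
#' Layer widths 15 -> 500 -> 250 -> 150 -> 50 -> 2 with rectifier
#' activations on hidden layers and a 2-way softmax output. Dropout 0.4
#' follows hidden layers 1, 2 and 4; hidden layer 3 carries an L1 penalty
#' of 1e-5 and an L2 penalty of 1e-4.
#'
#' @param n_features Input width (default 15).
#' @param dropout Dropout probability after hidden layers 1, 2 and 4.
#' @param l1,l2 Regularization constants on hidden layer 3.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(n_features = 15, dropout = 0.4, l1 = 1e-5, l2 = 1e-4) {
  structure(list(kind = "mlp", n_features = n_features,
                 widths = c(n_features, 500, 250, 150, 50, 2),
                 dropout = dropout, l1 = l1, l2 = l2),
            class = "mlp_spec")
}

#' CNN branch specification
#'
#' Input 64 x 64 x n (n encoded images as channels); conv 16 filters 5x5
#' (no padding) + rectifier + batch norm; max-pool 2x2; conv 32 filters
#' 5x5 (no padding) + rectifier + batch norm; max-pool 2x2 + dropout 0.8;
#' flatten (13 * 13 * 32 = 5408); dense 64 + rectifier + batch norm +
#' dropout 0.8; dense 16 + rectifier; dense 2 softmax. The no-padding
#' spatial arithmetic is 64 -> 60 -> 30 -> 26 -> 13.
#'
#' @param n_channels Number of stacked input images n (default 3).
#' @param size Input side length (default 64).
#' @param dropout Dropout probability in the CNN head (default 0.8).
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(n_channels = 3, size = 64, dropout = 0.8) {
  structure(list(kind = "cnn", n_channels = n_channels, size = size,
                 dropout = dropout),
            class = "cnn_spec")
}

#' Combined two-branch specification
#'
#' The MLP and CNN branches run in parallel; their terminal outputs are
#' concatenated and passed through a dense fusion layer of 128 rectifier
#' units and a final 2-way softmax. With `fusion = "softmax"` (the
#' default, reading the branch concatenation literally) each branch
#' contributes its 2-unit softmax output, giving a 4-unit fusion input;
#' with `fusion = "penultimate"` the branches are truncated after their
#' last hidden representation (50 + 16 = 66 units).
#'
#' @param n_features MLP input width (default 15).
#' @param n_channels CNN input channels (default 3).
#' @param fusion `"softmax"` or `"penultimate"`.
#' @param size Image side length (default 64).
#' @return An object of class `combined_spec`.
#' @export
combined_spec <- function(n_features = 15, n_channels = 3,
                          fusion = c("softmax", "penultimate"), size = 64) {
  structure(list(kind = "combined", n_features = n_features,
                 n_channels = n_channels, fusion = match.arg(fusion),
                 size = size),
            class = "combined_spec")
}

.build_mlp_layers <- function(spec, keep_head = TRUE) {
  w <- spec$widths
  layers <- list(
    .layer_dense(w[1], w[2]), .layer_relu(), .layer_dropout(spec$dropout),
    .layer_dense(w[2], w[3]), .layer_relu(), .layer_dropout(spec$dropout),
    .layer_dense(w[3], w[4], l1 = spec$l1, l2 = spec$l2), .layer_relu(),
    .layer_dense(w[4], w[5]), .layer_relu(), .layer_dropout(spec$dropout))
  if (keep_head)
    layers <- c(layers, list(.layer_dense(w[5], w[6]), .layer_softmax()))
  layers
}

.build_cnn_layers <- function(spec, keep_head = TRUE) {
  s <- spec$size; C <- spec$n_channels
  s1 <- s - 4L                 # after conv 5x5 no padding
  s2 <- s1 %/% 2L              # after pool
  s3 <- s2 - 4L                # after conv 5x5
  s4 <- s3 %/% 2L              # after pool
  flat <- s4 * s4 * 32L
  layers <- list(
    .layer_conv2d(c(s, s, C), 16L, 5L), .layer_relu(),
    .layer_batchnorm(16L, spatial = TRUE, hw = s1 * s1),
    .layer_maxpool2(c(s1, s1, 16L)),
    .layer_conv2d(c(s2, s2, 16L), 32L, 5L), .layer_relu(),
    .layer_batchnorm(32L, spatial = TRUE, hw = s3 * s3),
    .layer_maxpool2(c(s3, s3, 32L)),
    .layer_dropout(spec$dropout),
    .layer_flatten(flat),
    .layer_dense(flat, 64L), .layer_relu(), .layer_batchnorm(64L),
    .layer_dropout(spec$dropout),
    .layer_dense(64L, 16L), .layer_relu())
  if (keep_head)
    layers <- c(layers, list(.layer_dense(16L, 2L), .layer_softmax()))
  layers
}

#' Build an untrained model from a specification
#'
#' Weight initialization (He-scaled normal draws) is reproducible under
#' the given seed.
#'
#' @param spec An [mlp_spec()], [cnn_spec()] or [combined_spec()].
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `fhr_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  set.seed(seed)
  model <- switch(spec$kind,
    mlp = list(kind = "mlp", spec = spec,
               layers = .build_mlp_layers(spec)),
    cnn = list(kind = "cnn", spec = spec,
               layers = .build_cnn_layers(spec)),
    combined = {
      keep <- spec$fusion == "softmax"
      mlp_layers <- .build_mlp_layers(mlp_spec(spec$n_features), keep_head = keep)
      cnn_layers <- .build_cnn_layers(cnn_spec(spec$n_channels, spec$size),
                                      keep_head = keep)
      fin <- if (keep) 4L else 66L
      list(kind = "combined", spec = spec,
           branches = list(mlp = mlp_layers, cnn = cnn_layers),
           head = list(.layer_dense(fin, 128L), .layer_relu(),
                       .layer_dense(128L, 2L), .layer_softmax()))
    },
    stop("unknown spec kind"))
  model$trained <- FALSE
  model$seed <- seed
  structure(model, class = "fhr_model")
}

#' Summarize a model's topology
#'
#' @param model An [build_model()] result.
#' @return A data.frame with one row per layer: branch, layer type and
#'   output shape (conv/pool layers) or width, and parameter count.
#' @export
model_summary <- function(model) {
  one <- function(layers, branch) {
    rows <- lapply(seq_along(layers), function(i) {
      ly <- layers[[i]]
      shape <- if (!is.null(ly$out_shape)) paste(ly$out_shape, collapse = "x")
               else if (ly$type == "dense") as.character(ly$n_out)
               else if (ly$type == "flatten") as.character(ly$n_out)
               else ""
      data.frame(branch = branch, layer = i, type = ly$type,
                 output = shape,
                 n_params = sum(vapply(ly$params, length, integer(1))))
    })
    do.call(rbind, rows)
  }
  if (model$kind == "combined")
    rbind(one(model$branches$mlp, "mlp"), one(model$branches$cnn, "cnn"),
          one(model$head, "head"))
  else one(model$layers, model$kind)
}

#' @export
print.fhr_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<fhr_model %s> %d layers, %d parameters, %s\n", x$kind,
              nrow(s), sum(s$n_params),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 1e-4 and a per-epoch decay parameter
#' of 1e-4/200 (applied as `lr_t = lr / (1 + decay * epoch)`), batch size
#' 32, binary cross-entropy on the 2-way softmax (categorical
#' cross-entropy on one-hot labels, mathematically identical for two
#' classes), early stopping with patience 2 on validation loss, a
#' stratified validation split of 10% of the training data, and
#' restoration of the best-validation-loss weights at the end.
#'
#' @param lr Initial learning rate.
#' @param decay Per-epoch learning-rate decay parameter.
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); `Inf` disables early stopping.
#' @param val_fraction Fraction of the training data held out (stratified)
#'   for validation; 0 disables validation and early stopping.
#' @param seed RNG seed governing the validation split, shuffling and
#'   dropout.
#' @param restore_best Restore the weights of the best validation epoch.
#' @return A list of class `training_config`.
#' @export
training_config <- function(lr = 1e-4, decay = 1e-4 / 200, max_epochs = 100,
                            batch_size = 32, patience = 2,
                            val_fraction = 0.1, seed = 1L,
                            restore_best = TRUE) {
  stopifnot(val_fraction >= 0, val_fraction < 1, patience >= 1)
  structure(list(lr = lr, decay = decay, max_epochs = max_epochs,
                 batch_size = batch_size, patience = patience,
                 val_fraction = val_fraction, seed = seed,
                 restore_best = restore_best),
            class = "training_config")
}

# Coerce user inputs into the internal (features x batch) matrices the
# engine consumes. Returns list(tab = ..., img = ...), either possibly NULL.
.prep_inputs <- function(model, x) {
  need_tab <- model$kind %in% c("mlp", "combined")
  need_img <- model$kind %in% c("cnn", "combined")
  if (model$kind != "combined") {
    if (is.list(x) && !is.data.frame(x))
      x <- if (need_tab) x$features else x$images
  }
  tab <- img <- NULL
  if (need_tab) {
    f <- if (is.list(x) && !is.data.frame(x)) x$features else x
    if (is.null(f)) stop("tabular features required for this model")
    f <- as.matrix(f)
    if (ncol(f) != model$spec$n_features %||% 15)
      stop("feature width mismatch: expected ",
           model$spec$n_features, ", got ", ncol(f))
    tab <- t(f)
  }
  if (need_img) {
    a <- if (is.list(x) && !is.data.frame(x)) x$images else x
    if (is.null(a)) stop("image stacks required for this model")
    d <- dim(a)
    spec_c <- if (model$kind == "cnn") model$spec$n_channels else model$spec$n_channels
    size <- model$spec$size %||% 64
    if (length(d) != 4 || d[1] != size || d[2] != size || d[3] != spec_c)
      stop(sprintf("image array must be %d x %d x %d x n", size, size, spec_c))
    img <- matrix(a, d[1] * d[2] * d[3], d[4])
  }
  n <- if (!is.null(tab)) ncol(tab) else ncol(img)
  if (!is.null(tab) && !is.null(img) && ncol(tab) != ncol(img))
    stop("feature rows and image stacks are not aligned")
  list(tab = tab, img = img, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward the full model on prepared inputs (columns = samples).
.model_forward <- function(model, inp, training = FALSE) {
  if (model$kind == "mlp") {
    r <- .fwd_chain(model$layers, inp$tab, training)
    list(prob = r$out, parts = list(main = r), model = {
      model$layers <- r$layers; model })
  } else if (model$kind == "cnn") {
    r <- .fwd_chain(model$layers, inp$img, training)
    list(prob = r$out, parts = list(main = r), model = {
      model$layers <- r$layers; model })
  } else {
    rm_ <- .fwd_chain(model$branches$mlp, inp$tab, training)
    rc <- .fwd_chain(model$branches$cnn, inp$img, training)
    conc <- rbind(rm_$out, rc$out)
    rh <- .fwd_chain(model$head, conc, training)
    model$branches$mlp <- rm_$layers
    model$branches$cnn <- rc$layers
    model$head <- rh$layers
    list(prob = rh$out,
         parts = list(mlp = rm_, cnn = rc, head = rh,
                      n_mlp_out = nrow(rm_$out)),
         model = model)
  }
}

# Gather all trainable layer lists of a model as a named list, so the
# optimizer can treat every model kind uniformly.
.layer_sets <- function(model) {
  if (model$kind == "combined")
    list(mlp = model$branches$mlp, cnn = model$branches$cnn,
         head = model$head)
  else list(main = model$layers)
}

.set_layer_sets <- function(model, sets) {
  if (model$kind == "combined") {
    model$branches$mlp <- sets$mlp
    model$branches$cnn <- sets$cnn
    model$head <- sets$head
  } else model$layers <- sets$main
  model
}

# Cross-entropy loss (plus regularization) and accuracy from probabilities.
.ce_loss <- function(prob, y01) {
  p <- prob[cbind(y01 + 1L, seq_along(y01))]
  -mean(log(pmax(p, 1e-12)))
}

.accuracy <- function(prob, y01) mean((prob[2, ] > prob[1, ]) == (y01 == 1))

#' Train a model
#'
#' Minibatch Adam optimization of the cross-entropy loss with a stratified
#' validation split, early stopping on validation loss, and per-epoch
#' history. With `max_epochs = 0` the model is returned unchanged.
#'
#' @param model An untrained (or previously trained) [build_model()]
#'   result.
#' @param x Model inputs: a numeric matrix/data.frame of features (MLP), a
#'   `64 x 64 x c x n` image array (CNN), or `list(features =, images =)`
#'   (combined).
#' @param y Binary labels (0 healthy / 1 pathological), length n.
#' @param config A [training_config()].
#' @return The trained model with a `history` data.frame
#'   (`epoch, train_loss, val_loss, train_acc, val_acc`) attached.
#' @export
train_model <- function(model, x, y, config = training_config()) {
  stopifnot(inherits(model, "fhr_model"))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  inp <- .prep_inputs(model, x)
  if (inp$n == 0) stop("empty training set")
  if (length(y) != inp$n) stop("labels and inputs are not aligned")
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (config$max_epochs == 0) {
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                val_loss = numeric(0), train_acc = numeric(0),
                                val_acc = numeric(0))
    return(model)
  }

  set.seed(config$seed)
  # stratified validation split
  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    for (cl in c(0L, 1L)) {
      cand <- which(y == cl)
      nv <- max(1L, round(length(cand) * config$val_fraction))
      val_idx <- c(val_idx, sample(cand, nv))
    }
  }
  tr_idx <- setdiff(seq_len(inp$n), val_idx)
  take <- function(i) list(
    tab = if (!is.null(inp$tab)) inp$tab[, i, drop = FALSE],
    img = if (!is.null(inp$img)) inp$img[, i, drop = FALSE], n = length(i))
  val <- if (length(val_idx)) take(val_idx) else NULL
  y_val <- y[val_idx]

  sets <- .layer_sets(model)
  opt <- lapply(sets, .adam_init)
  t_step <- 0L
  best <- list(loss = Inf, sets = sets, epoch = 0L)
  wait <- 0L
  hist <- NULL

  for (epoch in seq_len(config$max_epochs)) {
    lr_t <- config$lr / (1 + config$decay * (epoch - 1))
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0

    for (bi in batches) {
      b <- take(bi)
      yb <- y[bi]
      fw <- .model_forward(model, b, training = TRUE)
      model <- fw$model
      P <- fw$prob
      Bn <- length(bi)
      Y <- rbind(1 - yb, yb)
      reg <- sum(vapply(.layer_sets(model), .reg_loss, numeric(1)))
      ep_loss <- ep_loss + (.ce_loss(P, yb) + reg) * Bn
      ep_acc <- ep_acc + .accuracy(P, yb) * Bn
      ep_n <- ep_n + Bn
      dZ <- (P - Y) / Bn  # fused softmax + cross-entropy gradient

      sets <- .layer_sets(model)
      grads <- list()
      if (model$kind == "combined") {
        ph <- fw$parts$head
        bh <- .bwd_chain(sets$head, ph$caches, dZ,
                         from = length(sets$head) - 1L)
        grads$head <- bh$grads
        k <- fw$parts$n_mlp_out
        d_mlp <- bh$dX[seq_len(k), , drop = FALSE]
        d_cnn <- bh$dX[-seq_len(k), , drop = FALSE]
        bm <- .bwd_chain(sets$mlp, fw$parts$mlp$caches, d_mlp)
        bc <- .bwd_chain(sets$cnn, fw$parts$cnn$caches, d_cnn)
        grads$mlp <- bm$grads
        grads$cnn <- bc$grads
      } else {
        bm <- .bwd_chain(sets$main, fw$parts$main$caches, dZ,
                         from = length(sets$main) - 1L)
        grads$main <- bm$grads
      }
      t_step <- t_step + 1L
      for (nm in names(sets)) {
        u <- .adam_update(sets[[nm]], grads[[nm]], opt[[nm]], lr_t, t_step)
        sets[[nm]] <- u$layers; opt[[nm]] <- u$state
      }
      model <- .set_layer_sets(model, sets)
    }

    row <- data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                      val_loss = NA_real_, train_acc = ep_acc / ep_n,
                      val_acc = NA_real_)
    if (!is.null(val)) {
      pv <- .model_forward(model, val, training = FALSE)$prob
      row$val_loss <- .ce_loss(pv, y_val)
      row$val_acc <- .accuracy(pv, y_val)
      if (row$val_loss < best$loss) {
        best <- list(loss = row$val_loss, sets = .layer_sets(model),
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, row)
    if (!is.null(val) && wait >= config$patience) break
  }

  if (!is.null(val) && config$restore_best && is.finite(best$loss))
    model <- .set_layer_sets(model, best$sets)
  model$trained <- TRUE
  model$history <- hist
  model$config <- config
  model
}

#' Class probabilities for new inputs
#'
#' @param model A trained (or untrained) [build_model()] result.
#' @param x Inputs in the same form as for [train_model()].
#' @param batch_size Evaluation chunk size (default 256).
#' @return An `n x 2` matrix of probabilities with columns `healthy`
#'   (class 0) and `pathological` (class 1); rows sum to 1.
#' @export
predict_proba <- function(model, x, batch_size = 256) {
  inp <- .prep_inputs(model, x)
  out <- matrix(NA_real_, inp$n, 2,
                dimnames = list(NULL, c("healthy", "pathological")))
  i <- 1L
  while (i <= inp$n) {
    j <- min(i + batch_size - 1L, inp$n)
    b <- list(tab = if (!is.null(inp$tab)) inp$tab[, i:j, drop = FALSE],
              img = if (!is.null(inp$img)) inp$img[, i:j, drop = FALSE])
    out[i:j, ] <- t(.model_forward(model, b, training = FALSE)$prob)
    i <- j + 1L
  }
  out
}

#' Predicted class labels (argmax)
#'
#' @inheritParams predict_proba
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, x, batch_size = 256) {
  p <- predict_proba(model, x, batch_size)
  as.integer(p[, 2] > p[, 1])
}
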