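#' One point of the CNN hyperparameter grid
#'
#' The architecture is `[conv(filters, width) + ReLU + max-pool] x cl ->
#' flatten -> [dense(units) + ReLU + dropout] x hidden -> 1-unit sigmoid`,
#' trained with binary cross-entropy and Adam. Following the convention of the
#' grid-summary tables, `n_dense_layers` counts the output layer, so a model
#' with `dense_units = c(64, 128)` has three dense layers.
#'
#' @param conv_filters integer vector: filters of each convolutional layer;
#'   its length is the number of convolutional layers (cl).
#' @param conv_width kernel width, recycled across conv layers.
#' @param pool_width,pool_stride max-pooling window and stride, shared by all
#'   pooling layers.
#' @param dense_units integer vector: units of each *hidden* dense layer.
#' @param dropout_rate dropout after each hidden dense activation.
#' @param learning_rate Adam step size (default 0.0001).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 64).
#' @param warmup_epochs epochs over which the learning rate ramps linearly
#'   from zero (default 2). Adam's early steps are as large as the target
#'   rate regardless of gradient scale; without a ramp they can silence
#'   rectified units permanently when the rate is aggressive.
#' @return a `hyperparams` object.
#' @export
hyperparams <- function(conv_filters = 64L, conv_width = 4L,
                        pool_width = 4L, pool_stride = 4L,
                        dense_units = 64L, dropout_rate = 0.25,
                        learning_rate = 1e-4, epochs = 50L,
                        batch_size = 64L, warmup_epochs = 2L) {
  conv_filters <- as.integer(conv_filters)
  dense_units <- as.integer(dense_units)
  if (length(conv_filters) < 1L || any(conv_filters < 1L))
    stop("conv_filters must be positive, one per convolutional layer")
  if (any(c(conv_width, pool_width, pool_stride, dense_units,
            epochs, batch_size) < 1L))
    stop("all size hyperparameters must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(
    n_conv_layers = length(conv_filters),
    conv_filters = conv_filters,
    conv_width = as.integer(conv_width),
    pool_width = as.integer(pool_width),
    pool_stride = as.integer(pool_stride),
    dense_units = dense_units,
    n_dense_layers = length(dense_units) + 1L,  # output layer included
    dropout_rate = dropout_rate,
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    warmup_epochs = as.integer(warmup_epochs)
  ), class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("<hyperparams> conv:", paste(x$conv_filters, collapse = "/"),
      "filters, width", x$conv_width,
      "| pool", x$pool_width, "/", x$pool_stride,
      "| dense:", paste(x$dense_units, collapse = "/"),
      "(+ output) | dropout", x$dropout_rate,
      "| lr", x$learning_rate, "\n")
  invisible(x)
}

#' Build the hyperparameter grid
#'
#' Cartesian product of the supplied value lists. All convolutional layers of
#' one model share the filter count and all hidden dense layers share the
#' unit count, which keeps the grid the size a single-workstation screen can
#' afford; the per-layer vectors in [hyperparams()] remain available for
#' hand-built architectures.
#'
#' @param conv_layers,filters,conv_width,pool_width,pool_stride,dense_hidden,dense_units,dropout,learning_rate,epochs
#'   candidate values; see [hyperparams()].
#' @return list of `hyperparams` (class `hyper_grid`).
#' @export
hyper_grid <- function(conv_layers = c(1L, 2L, 3L), filters = c(64L, 128L),
                       conv_width = c(4L, 8L), pool_width = c(4L, 8L),
                       pool_stride = c(4L, 8L), dense_hidden = c(1L, 2L),
                       dense_units = c(64L, 128L), dropout = c(0.1, 0.25),
                       learning_rate = 1e-4, epochs = 50L) {
  g <- expand.grid(cl = conv_layers, fl = filters, cw = conv_width,
                   pw = pool_width, pl = pool_stride, dh = dense_hidden,
                   du = dense_units, dr = dropout, lr = learning_rate,
                   ep = epochs, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(g)), function(i)
    hyperparams(conv_filters = rep(g$fl[i], g$cl[i]), conv_width = g$cw[i],
                pool_width = g$pw[i], pool_stride = g$pl[i],
                dense_units = rep(g$du[i], g$dh[i]), dropout_rate = g$dr[i],
                learning_rate = g$lr[i], epochs = g$ep[i]))
  class(out) <- "hyper_grid"
  out
}

#' Build (initialise) a CNN for a given input length
#'
#' Validates that the convolution/pooling chain never collapses the feature
#' map to zero length, then He-initialises all weights.
#'
#' @param hp a [hyperparams()].
#' @param input_length window length L (3000 for both regions concatenated,
#'   2000 for upstream-only).
#' @param n_channels input channels (4: A, C, G, T).
#' @param seed seed for weight initialisation.
#' @return a `cnn_model`.
#' @export
build_model <- function(hp, input_length, n_channels = 4L, seed = 1L) {
  stopifnot(inherits(hp, "hyperparams"))
  if (hp$pool_stride > input_length)
    stop("pool_stride (", hp$pool_stride, ") exceeds the input length (",
         input_length, ")")
  widths <- rep_len(hp$conv_width, hp$n_conv_layers)
  L <- as.integer(input_length)
  conv_dims <- vector("list", hp$n_conv_layers)
  for (i in seq_len(hp$n_conv_layers)) {
    Lc <- L - widths[i] + 1L
    if (Lc < 1L)
      stop("convolutional layer ", i, ": kernel width ", widths[i],
           " exceeds its input length ", L)
    if (hp$pool_width > Lc)
      stop("pooling layer ", i, ": window ", hp$pool_width,
           " exceeds its input length ", Lc)
    Lq <- (Lc - hp$pool_width) %/% hp$pool_stride + 1L
    if (Lq < 1L)
      stop("pooling layer ", i, " reduces the feature map to zero length")
    conv_dims[[i]] <- c(conv = Lc, pooled = Lq)
    L <- Lq
  }
  set.seed(seed)
  params <- list()
  cin <- as.integer(n_channels)
  for (i in seq_len(hp$n_conv_layers)) {
    k <- widths[i]; fo <- hp$conv_filters[i]
    params[[paste0("c", i, ".W")]] <-
      array(rnorm(k * cin * fo, sd = sqrt(2 / (k * cin))), c(k, cin, fo))
    params[[paste0("c", i, ".b")]] <- numeric(fo)
    cin <- fo
  }
  din <- L * cin
  for (i in seq_along(hp$dense_units)) {
    u <- hp$dense_units[i]
    params[[paste0("d", i, ".W")]] <-
      matrix(rnorm(din * u, sd = sqrt(2 / din)), din, u)
    params[[paste0("d", i, ".b")]] <- numeric(u)
    din <- u
  }
  params$out.W <- matrix(rnorm(din, sd = sqrt(1 / din)), din, 1L)
  params$out.b <- 0
  structure(list(
    hp = hp, input_length = as.integer(input_length),
    n_channels = as.integer(n_channels),
    arch = list(n_conv = hp$n_conv_layers, conv_widths = widths,
                pool_width = hp$pool_width, pool_stride = hp$pool_stride,
                n_dense_hidden = length(hp$dense_units),
                dropout_rate = hp$dropout_rate),
    conv_dims = conv_dims, params = params
  ), class = "cnn_model")
}

#' Number of trainable parameters of a model
#' @param model a `cnn_model`.
#' @return integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> L =", x$input_length, "|",
      x$arch$n_conv, "conv +", x$arch$n_dense_hidden,
      "hidden dense + output |", n_params(x), "parameters\n")
  invisible(x)
}

#' Predicted probability of the non-DEG class (label 1)
#' @param model a trained or fresh `cnn_model`.
#' @param newdata a [labeled_set()] or an `N x L x 4` array.
#' @return numeric vector of `P(label = 1)`.
#' @export
predict_prob <- function(model, newdata) {
  X <- if (inherits(newdata, "labeled_set")) newdata$x else newdata
  if (dim(X)[2L] != model$input_length)
    stop("input length ", dim(X)[2L], " does not match the model (",
         model$input_length, ")")
  .cnn_predict_prob(model, X)
}

#' Evaluate a model on a test set
#'
#' Classes are predicted by a 0.5 threshold on the sigmoid output;
#' within-class accuracy is the number of correct predictions of a class
#' divided by that class's size. prAUC uses the DEG class (label 0) as
#' positive by default; the opposite polarity is also reported since scores
#' for one are one minus the other's.
#'
#' @param model a trained `cnn_model`.
#' @param test_set a [labeled_set()] retaining the original class ratio.
#' @return list: prauc_test, prauc_test_non (non-DEG positive),
#'   acc_class_deg, acc_class_non, class_diff.
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(test_set, "labeled_set"))
  y <- test_set$label
  if (length(unique(y)) < 2L)
    stop("test set must contain both classes")
  p <- predict_prob(model, test_set)        # P(label = 1) = P(non-DEG)
  pred <- as.integer(p >= 0.5)
  acc_deg <- mean(pred[y == 0L] == 0L)
  acc_non <- mean(pred[y == 1L] == 1L)
  list(prauc_test = pr_auc(1 - p, y == 0L),
       prauc_test_non = pr_auc(p, y == 1L),
       acc_class_deg = acc_deg, acc_class_non = acc_non,
       class_diff = class_accuracy_difference(acc_deg, acc_non))
}

.overfit_flag <- function(prauc_test) {
  if (is.na(prauc_test)) return(NA_character_)
  if (prauc_test > 0.8) "to_deg" else if (prauc_test < 0.2) "to_non" else "none"
}

#' Train a CNN with validation-prAUC model selection
#'
#' Runs minibatch Adam on binary cross-entropy; after every epoch the
#' validation prAUC (DEG positive) is computed and the weights of the best
#' epoch are the ones kept, so the returned record describes the saved model,
#' not the last epoch.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param train_set oversampled training [labeled_set()].
#' @param validation_set un-oversampled validation set.
#' @param test_set optional test set; if given, test metrics are filled in.
#' @param epochs number of epochs (default: the model's hyperparameters).
#' @param seed seed for shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return a `model_record`: hyperparams, loss, accuracy, prauc_train,
#'   prauc_validation, prauc_test, loss_validation, acc_class_deg,
#'   acc_class_non, class_diff, best_epoch, overfit_flag, and the trained
#'   `model`.
#' @export
train <- function(model, train_set, validation_set, test_set = NULL,
                  epochs = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(train_set, "labeled_set"),
            inherits(validation_set, "labeled_set"))
  if (is.null(epochs)) epochs <- model$hp$epochs
  if (epochs < 1L) stop("epochs must be >= 1")
  if (length(unique(train_set$label)) < 2L)
    stop("training set must contain both classes")
  if (!any(validation_set$label == 0L))
    stop("validation set has no DEG records; validation prAUC undefined")
  X <- train_set$x
  y <- train_set$label
  N <- length(y)
  bs <- model$hp$batch_size
  state <- .adam_init(model$params)
  best <- list(prauc = -Inf, epoch = NA_integer_, params = model$params)
  steps_per_epoch <- ceiling(N / bs)
  warmup_steps <- model$hp$warmup_epochs * steps_per_epoch
  step <- 0L
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(N)
    for (s in seq(1L, N, by = bs)) {
      b <- idx[s:min(s + bs - 1L, N)]
      fw <- .cnn_forward(model, X[b, , , drop = FALSE], train = TRUE,
                         keep_cache = TRUE)
      loss <- .bce(fw$p, y[b])
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep)
      grads <- .cnn_backward(model, fw, y[b])
      step <- step + 1L
      lr <- model$hp$learning_rate *
        if (warmup_steps > 0L) min(1, step / warmup_steps) else 1
      upd <- .adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    val_p <- .cnn_predict_prob(model, validation_set$x)
    val_prauc <- pr_auc(1 - val_p, validation_set$label == 0L)
    if (val_prauc > best$prauc) {
      best <- list(prauc = val_prauc, epoch = ep, params = model$params)
    }
    if (verbose)
      message(sprintf("epoch %d: val prAUC %.4f%s", ep, val_prauc,
                      if (best$epoch == ep) " *" else ""))
  }
  model$params <- best$params

  tr_p <- .cnn_predict_prob(model, X)
  val_p <- .cnn_predict_prob(model, validation_set$x)
  rec <- list(
    hyperparams = model$hp,
    loss = .bce(tr_p, y),
    accuracy = mean(as.integer(tr_p >= 0.5) == y),
    prauc_train = pr_auc(1 - tr_p, y == 0L),
    prauc_validation = best$prauc,
    loss_validation = .bce(val_p, validation_set$label),
    prauc_test = NA_real_, acc_class_deg = NA_real_,
    acc_class_non = NA_real_, class_diff = NA_real_,
    best_epoch = best$epoch, overfit_flag = NA_character_,
    model = model
  )
  if (!is.null(test_set)) {
    ev <- evaluate(model, test_set)
    rec$prauc_test <- ev$prauc_test
    rec$prauc_test_non <- ev$prauc_test_non
    rec$acc_class_deg <- ev$acc_class_deg
    rec$acc_class_non <- ev$acc_class_non
    rec$class_diff <- ev$class_diff
    rec$overfit_flag <- .overfit_flag(ev$prauc_test)
  }
  class(rec) <- "model_record"
  rec
}

#' @export
print.model_record <- function(x, ...) {
  cat("<model_record> best epoch", x$best_epoch,
      "| prAUC train/val/test:",
      paste(round(c(x$prauc_train, x$prauc_validation, x$prauc_test), 4),
            collapse = "/"),
      "| class_diff:", round(x$class_diff, 4),
      "| overfit:", x$overfit_flag, "\n")
  invisible(x)
}

.record_row <- function(rec, i) {
  hp <- rec$hyperparams
  data.frame(
    grid_index = i,
    cl = hp$n_conv_layers, fl = hp$conv_filters[1L],
    conv_width = hp$conv_width, pool_width = hp$pool_width,
    pl = hp$pool_stride, dl = hp$n_dense_layers,
    du = hp$dense_units[1L], dr = hp$dropout_rate,
    learning_rate = hp$learning_rate,
    loss = .nv(rec$loss), accuracy = .nv(rec$accuracy),
    prauc_train = .nv(rec$prauc_train),
    prauc_validation = .nv(rec$prauc_validation),
    prauc_test = .nv(rec$prauc_test),
    loss_validation = .nv(rec$loss_validation),
    acc_class_deg = .nv(rec$acc_class_deg),
    acc_class_non = .nv(rec$acc_class_non),
    class_diff = .nv(rec$class_diff),
    best_epoch = if (is.null(rec$best_epoch)) NA_integer_ else rec$best_epoch,
    overfit_flag = if (is.null(rec$overfit_flag)) NA_character_ else rec$overfit_flag,
    error = if (is.null(rec$error)) NA_character_ else rec$error,
    stringsAsFactors = FALSE)
}

.nv <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Grid search over CNN hyperparameters
#'
#' Trains one model per grid point on the same data and seed (so identical
#' grid points give identical metrics) and collects the full evaluation
#' record of each. Records are checkpointed as JSON per combination when
#' `checkpoint_dir` is given, and existing checkpoints are reused, making a
#' long search resumable. Failed combinations are recorded with their error
#' message rather than aborting the search.
#'
#' @param grid a [hyper_grid()] or list of [hyperparams()].
#' @param data list with `train` (oversampled), `validation`, `test`
#'   [labeled_set()]s.
#' @param seed seed applied to every combination.
#' @param checkpoint_dir optional directory for per-combination JSON records.
#' @param verbose print progress.
#' @return a `model_records` list; see [as.data.frame.model_records()] and
#'   [summary.model_records()].
#' @export
grid_search <- function(grid, data, seed = 1L, checkpoint_dir = NULL,
                        verbose = FALSE) {
  if (!length(grid)) stop("grid must be nonempty")
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  L <- dim(data$train$x)[2L]
  records <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("record_%04d.json", i)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      row <- jsonlite::read_json(ck, simplifyVector = TRUE)
      rec <- c(row, list(hyperparams = grid[[i]]))
      class(rec) <- "model_record"
      records[[i]] <- rec
      next
    }
    hp <- grid[[i]]
    rec <- tryCatch({
      model <- build_model(hp, L, seed = seed)
      train(model, data$train, data$validation, test_set = data$test,
            seed = seed)
    }, error = function(e) {
      structure(list(hyperparams = hp, error = conditionMessage(e)),
                class = "model_record")
    })
    rec$model <- NULL   # records stay light; retrain the selected one
    records[[i]] <- rec
    if (!is.null(ck)) {
      row <- .record_row(rec, i)
      jsonlite::write_json(as.list(row), ck, auto_unbox = TRUE, digits = NA)
    }
    if (verbose)
      message(sprintf("[%d/%d] prAUC test %.4f", i, length(grid),
                      .nv(rec$prauc_test)))
  }
  class(records) <- "model_records"
  records
}

#' @export
as.data.frame.model_records <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x), function(i) .record_row(x[[i]], i)))
}

#' Summary of a grid search
#'
#' @param object a `model_records` list.
#' @param ... unused.
#' @return list with median/mean train and test prAUC and the overfit
#'   fraction (share of models with test prAUC above 0.8 plus share below
#'   0.2).
#' @export
summary.model_records <- function(object, ...) {
  df <- as.data.frame(object)
  pt <- df$prauc_test[!is.na(df$prauc_test)]
  list(n = nrow(df), n_failed = sum(!is.na(df$error)),
       median_prauc_train = stats::median(df$prauc_train, na.rm = TRUE),
       mean_prauc_train = mean(df$prauc_train, na.rm = TRUE),
       median_prauc_test = stats::median(pt), mean_prauc_test = mean(pt),
       overfit_fraction = mean(pt > 0.8) + mean(pt < 0.2))
}

#' Select the best model record
#'
#' Among records whose test prAUC is at least `prauc_min`, returns the one
#' with the smallest class-accuracy difference; ties are broken by larger
#' test prAUC, then by grid order. Returns `NULL` (with a message) when no
#' record passes the filter.
#'
#' @param records a `model_records` list (or list of `model_record`s).
#' @param prauc_min test prAUC threshold (default 0.7).
#' @return a `model_record` or `NULL`.
#' @export
select_best <- function(records, prauc_min = 0.7) {
  if (!length(records)) stop("records must be nonempty")
  df <- as.data.frame.model_records(records)
  ok <- which(is.na(df$error) & !is.na(df$prauc_test) &
                df$prauc_test >= prauc_min)
  if (!length(ok)) {
    message("no model reached test prAUC >= ", prauc_min)
    return(NULL)
  }
  ord <- ok[order(df$class_diff[ok], -df$prauc_test[ok], ok)]
  records[[ord[1L]]]
}

#' Label-permutation significance of a selected architecture
#'
#' Re-trains the selected architecture `n_perm` times with the training and
#' validation labels jointly shuffled (test labels untouched; the training
#' half is re-oversampled after each shuffle) and reports
#' `p = #(permuted runs with test prAUC >= observed AND class_diff <=
#' observed) / n_perm`.
#'
#' @param hp the selected [hyperparams()].
#' @param data list with `train` (NOT oversampled), `validation`, `test`
#'   [labeled_set()]s.
#' @param n_perm number of permutations (default 100).
#' @param seed seed.
#' @param observed optional `model_record` with the observed metrics; if
#'   `NULL` the observed model is trained first from the same data.
#' @param epochs optional override of `hp$epochs`.
#' @return a `perm_significance` list: p_value, observed, perm_prauc,
#'   perm_diff.
#' @export
permutation_significance <- function(hp, data, n_perm = 100L, seed = 1L,
                                     observed = NULL, epochs = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  L <- dim(data$train$x)[2L]
  if (is.null(observed)) {
    model <- build_model(hp, L, seed = seed)
    observed <- train(model, oversample(data$train, seed = seed),
                      data$validation, test_set = data$test,
                      epochs = epochs, seed = seed)
  }
  obs_prauc <- observed$prauc_test
  obs_diff <- observed$class_diff
  if (is.na(obs_prauc) || is.na(obs_diff))
    stop("observed record carries no test metrics")
  n_train <- length(data$train$label)
  pool <- c(data$train$label, data$validation$label)
  perm_prauc <- perm_diff <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pseed <- seed + i
    set.seed(pseed)
    repeat {
      shuffled <- sample(pool)
      if (length(unique(shuffled[seq_len(n_train)])) == 2L &&
          any(shuffled[-seq_len(n_train)] == 0L)) break
    }
    tr <- data$train
    tr$label <- shuffled[seq_len(n_train)]
    va <- data$validation
    va$label <- shuffled[-seq_len(n_train)]
    rec <- train(build_model(hp, L, seed = pseed),
                 oversample(tr, seed = pseed), va,
                 test_set = data$test, epochs = epochs, seed = pseed)
    perm_prauc[i] <- rec$prauc_test
    perm_diff[i] <- rec$class_diff
  }
  structure(list(
    p_value = mean(perm_prauc >= obs_prauc & perm_diff <= obs_diff),
    observed = observed, perm_prauc = perm_prauc, perm_diff = perm_diff
  ), class = "perm_significance")
}

#' @export
print.perm_significance <- function(x, ...) {
  cat("<perm_significance> p =", x$p_value, "over",
      length(x$perm_prauc), "label permutations\n")
  invisible(x)
}
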