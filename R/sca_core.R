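#' Build a connectivity mask from a relationship table
#'
#' The mask is the binary metafeature x feature matrix that sparsifies the
#' autoencoder: \code{mask[k, j] = 1} iff feature j belongs to metafeature
#' k's target set. Metafeatures whose target sets do not intersect
#' \code{feature_ids} are dropped; with \code{drop_unconnected}, features
#' connected to no surviving metafeature are removed as well, so the model
#' never sees inputs it cannot reconstruct through the hidden layer.
#'
#' @param rel a [relationship_table()].
#' @param feature_ids features available in the expression matrix.
#' @param drop_unconnected drop all-zero feature columns (default TRUE).
#' @return binary matrix with metafeature rownames and feature colnames.
#' @export
build_mask <- function(rel, feature_ids, drop_unconnected = TRUE) {
  rel <- relationship_table(rel)
  feature_ids <- as.character(feature_ids)
  if (!length(feature_ids)) stop("'feature_ids' is empty")
  mask <- vapply(rel, function(targets) feature_ids %in% targets,
                 logical(length(feature_ids)))
  mask <- t(matrix(as.numeric(mask), nrow = length(feature_ids),
                   dimnames = list(feature_ids, names(rel))))
  keep_rows <- rowSums(mask) > 0
  if (!any(keep_rows))
    stop("no metafeature has targets among the supplied features")
  mask <- mask[keep_rows, , drop = FALSE]
  if (drop_unconnected) {
    keep_cols <- colSums(mask) > 0
    mask <- mask[, keep_cols, drop = FALSE]
  }
  mask
}

#' SCA training configuration
#'
#' @param n_epochs training epochs per run (no early stopping; the
#'   reference setting is 1000).
#' @param learning_rate Adam step size.
#' @param hidden_activation "relu" (default; nonnegative activations let
#'   hidden values be treated as pseudo-counts) or "sigmoid".
#' @param batch_size mini-batch size, or NULL for automatic mode:
#'   full-batch when the sample count is at most \code{full_batch_limit},
#'   else mini-batches of 128 with per-epoch shuffling.
#' @param full_batch_limit sample count up to which full-batch training is
#'   used in automatic mode.
#' @param base_seed seed of run 0; run r of [run_permutations()] uses
#'   \code{base_seed + r}.
#' @param scale_input when TRUE (default), training data are transformed
#'   by \code{log1p} and min-max scaled to \[0, 1\] per feature before
#'   entering the model; set FALSE for inputs that are already normalized.
#' @return a list of class \code{sca_config}.
#' @export
sca_config <- function(n_epochs = 1000, learning_rate = 1e-3,
                       hidden_activation = c("relu", "sigmoid"),
                       batch_size = NULL, full_batch_limit = 2048,
                       base_seed = 111, scale_input = TRUE) {
  hidden_activation <- match.arg(hidden_activation)
  stopifnot(n_epochs >= 1, learning_rate > 0,
            is.null(batch_size) || batch_size >= 1)
  structure(list(n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate,
                 hidden_activation = hidden_activation,
                 batch_size = batch_size,
                 full_batch_limit = full_batch_limit,
                 base_seed = as.integer(base_seed),
                 scale_input = scale_input),
            class = "sca_config")
}

# log1p + per-feature (column) min-max scaling to [0, 1]; constant columns
# map to 0 so they carry no gradient signal.
scale_for_sca <- function(x) {
  x <- log1p(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(x, 2, lo, `-`), 2, span, `/`)
}

#' Train a sparsely connected autoencoder
#'
#' The model is a single-hidden-layer autoencoder whose weights are zeroed
#' outside the metafeature-target relationships: the encoder computes
#' \code{h = act((M * We) x + be)} and the linear decoder
#' \code{xhat = (M' * Wd) h + bd}, where \code{M} is the connectivity mask
#' and \code{*} the elementwise product. Masking is enforced by
#' multiplying the weights by the mask in the forward pass, so gradients
#' flow only through unmasked entries and masked positions stay exactly
#' zero after every update. Training minimizes mean squared reconstruction
#' error with Adam; weights start from a nonnegative half-Glorot draw (see
#' the package vignette for why the sign symmetry must be broken).
#'
#' @param data samples x features matrix; columns must match the mask's
#'   feature columns (aligned by name when both are named). With
#'   \code{config$scale_input} the data are log1p/min-max scaled first.
#' @param mask binary metafeature x feature matrix from [build_mask()].
#' @param config an [sca_config()].
#' @param seed integer RNG seed for weight initialization and shuffling.
#' @return a list of class \code{sca_model}: \code{hidden} (samples x
#'   metafeatures activations after training), \code{encoder_weights},
#'   \code{decoder_weights}, biases, \code{mask}, \code{loss_trace}
#'   (initial and per-epoch MSE), \code{seed} and \code{config}.
#' @export
train_sca <- function(data, mask, config = sca_config(),
                      seed = config$base_seed) {
  stopifnot(is.matrix(data), is.matrix(mask))
  if (!is.null(colnames(mask)) && !is.null(colnames(data))) {
    missing <- setdiff(colnames(mask), colnames(data))
    if (length(missing))
      stop("data lacks mask feature(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    data <- data[, colnames(mask), drop = FALSE]
  } else if (ncol(data) != ncol(mask)) {
    stop("data has ", ncol(data), " features but mask has ", ncol(mask))
  }
  if (config$scale_input) data <- scale_for_sca(data)

  n <- nrow(data); p <- ncol(data); k <- nrow(mask)
  M <- unname(mask != 0) * 1
  x_all <- unname(data)
  act <- config$hidden_activation

  set.seed(seed)
  # Nonnegative half-Glorot initialization: with nonnegative inputs and
  # relu hidden units, a symmetric init admits sign-flipped solutions in
  # which activations anticorrelate with the aggregate expression they
  # summarize; starting in the nonnegative orthant selects the
  # interpretable basin without constraining training.
  lim_e <- sqrt(6 / (p + k))
  lim_d <- sqrt(6 / (k + p))
  We <- matrix(stats::runif(k * p, 0, lim_e), k, p) * M
  Wd <- matrix(stats::runif(p * k, 0, lim_d), p, k) * t(M)
  be <- numeric(k)
  bd <- numeric(p)

  adam <- function(dim) list(m = array(0, dim), v = array(0, dim))
  st <- list(We = adam(dim(We)), Wd = adam(dim(Wd)),
             be = adam(k), bd = adam(p))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  t_step <- 0

  forward <- function(x) {
    z <- x %*% t(We) + rep(be, each = nrow(x))
    h <- if (act == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
    xhat <- h %*% t(Wd) + rep(bd, each = nrow(x))
    list(z = z, h = h, xhat = xhat)
  }
  mse <- function(x) { f <- forward(x); mean((f$xhat - x)^2) }

  batch_size <- config$batch_size
  if (is.null(batch_size))
    batch_size <- if (n <= config$full_batch_limit) n else 128L
  batch_size <- min(batch_size, n)

  loss_trace <- numeric(config$n_epochs + 1)
  loss_trace[1] <- mse(x_all)

  for (epoch in seq_len(config$n_epochs)) {
    order_idx <- if (batch_size < n) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- order_idx[s:min(s + batch_size - 1, n)]
      x <- x_all[idx, , drop = FALSE]
      nb <- nrow(x)
      f <- forward(x)
      err <- f$xhat - x
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * nb
      g_out <- err * (2 / (nb * p))
      gWd <- crossprod(g_out, f$h) * t(M)
      gbd <- colSums(g_out)
      dh <- g_out %*% Wd
      dz <- if (act == "relu") dh * (f$z > 0) else dh * f$h * (1 - f$h)
      gWe <- crossprod(dz, x) * M
      gbe <- colSums(dz)

      t_step <- t_step + 1
      upd <- function(par, g, s) {
        s$m <- b1 * s$m + (1 - b1) * g
        s$v <- b2 * s$v + (1 - b2) * g^2
        mhat <- s$m / (1 - b1^t_step)
        vhat <- s$v / (1 - b2^t_step)
        list(par = par - lr * mhat / (sqrt(vhat) + eps), s = s)
      }
      r <- upd(We, gWe, st$We); We <- r$par * M; st$We <- r$s
      r <- upd(Wd, gWd, st$Wd); Wd <- r$par * t(M); st$Wd <- r$s
      r <- upd(be, gbe, st$be); be <- r$par; st$be <- r$s
      r <- upd(bd, gbd, st$bd); bd <- r$par; st$bd <- r$s
    }
    loss_trace[epoch + 1] <- epoch_loss / n
  }

  hidden <- forward(x_all)$h
  dimnames(hidden) <- list(rownames(data), rownames(mask))
  structure(list(hidden = hidden,
                 encoder_weights = We, encoder_bias = be,
                 decoder_weights = Wd, decoder_bias = bd,
                 mask = mask, loss_trace = loss_trace,
                 seed = seed, config = config),
            class = "sca_model")
}

#' @method print sca_model
#' @export
print.sca_model <- function(x, ...) {
  cat("Sparsely connected autoencoder\n",
      "  ", ncol(x$mask), " features -> ", nrow(x$mask), " metafeatures\n",
      "  seed ", x$seed, ", ", x$config$n_epochs, " epochs; MSE ",
      signif(x$loss_trace[1], 4), " -> ",
      signif(x$loss_trace[length(x$loss_trace)], 4), "\n", sep = "")
  invisible(x)
}

#' Hidden activations for new data under a trained model
#' @param object an \code{sca_model}.
#' @param newdata samples x features matrix aligned to the model's mask
#'   (already on the scale the model was trained on).
#' @param ... unused.
#' @return samples x metafeatures activation matrix.
#' @export
predict.sca_model <- function(object, newdata, ...) {
  if (!is.null(colnames(object$mask)) && !is.null(colnames(newdata)))
    newdata <- newdata[, colnames(object$mask), drop = FALSE]
  z <- newdata %*% t(object$encoder_weights) +
    rep(object$encoder_bias, each = nrow(newdata))
  h <- if (object$config$hidden_activation == "relu") pmax(z, 0)
       else 1 / (1 + exp(-z))
  dimnames(h) <- list(rownames(newdata), rownames(object$mask))
  h
}

#' Repeated independent SCA runs ("permutations")
#'
#' Each run retrains the model from a fresh weight initialization: run r
#' uses seed \code{base_seed + r}, so runs are order-independent and the
#' whole sequence is reproducible. The reference settings are 20 runs for
#' pseudo-bulk generation and 100 runs for metagene accumulation.
#'
#' @param data samples x features matrix.
#' @param mask binary metafeature x feature matrix.
#' @param config an [sca_config()].
#' @param n_runs number of independent runs.
#' @param keep_models keep the full \code{sca_model} objects (default
#'   FALSE: only hidden matrices are retained).
#' @return list of hidden matrices (samples x metafeatures), each with
#'   attribute \code{run_index} in \code{0:(n_runs - 1)}; when
#'   \code{keep_models}, attribute \code{models} holds the fitted models.
#' @export
run_permutations <- function(data, mask, config = sca_config(), n_runs,
                             keep_models = FALSE) {
  stopifnot(n_runs >= 1)
  models <- vector("list", n_runs)
  hiddens <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      train_sca(data, mask, config, seed = config$base_seed + r - 1L),
      error = function(e) stop("run ", r - 1L, ": ", conditionMessage(e)))
    h <- fit$hidden
    attr(h, "run_index") <- r - 1L
    hiddens[[r]] <- h
    if (keep_models) models[[r]] <- fit
  }
  if (keep_models) attr(hiddens, "models") <- models
  hiddens
}
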