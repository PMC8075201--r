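# ---- deep belief network ----------------------------------------------------

#' Training configuration for the deep belief network
#'
#' Defaults reproduce the study schedule: 40 epochs of 120 mini-batch
#' learning events each, i.e. 4,800 cycles per layer. The learning rate,
#' momentum schedule (0.5 for the first `momentum_switch` epochs, then
#' `momentum`), weight decay and Gaussian weight initialization follow
#' common practice for this architecture family.
#'
#' @param epochs Training epochs per layer (default 40).
#' @param batches_per_epoch Mini-batch learning events per epoch
#'   (default 120).
#' @param learning_rate CD-1 learning rate (default 0.05).
#' @param momentum Momentum applied after the switch epoch (default 0:
#'   plain stochastic CD-1; momentum inflates cycle-to-cycle churn and
#'   with it the apparent dimensionality of the recorded dynamics).
#' @param momentum_switch Epoch after which `momentum` replaces the
#'   initial 0.5 (default 0, i.e. `momentum` from the start).
#' @param weight_decay L2 weight decay on the weights (default 2e-4).
#' @param init_sd SD of the Gaussian weight initialization (default 0.01).
#' @param seed Integer seed fixing initialization, sampling and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batches_per_epoch = 120L,
                         learning_rate = 0.05, momentum = 0,
                         momentum_switch = 0L, weight_decay = 2e-4,
                         init_sd = 0.01, seed = 1L) {
  stopifnot(epochs >= 1L, batches_per_epoch >= 1L, learning_rate >= 0,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 learning_rate = learning_rate, momentum = momentum,
                 momentum_switch = as.integer(momentum_switch),
                 weight_decay = weight_decay, init_sd = init_sd,
                 seed = as.integer(seed)),
            class = "train_config")
}

# train one RBM layer; calls `recorder` (if any) after every mini-batch update
.train_layer <- function(layer, x, config, recorder = NULL) {
  n <- nrow(x)
  if (config$batches_per_epoch > n) {
    stop("batches_per_epoch (", config$batches_per_epoch,
         ") exceeds the dataset size (", n, ")")
  }
  if (!is.double(x)) storage.mode(x) <- "double"
  st <- .layer_state(layer)
  mse <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    mom <- if (epoch <= config$momentum_switch) 0.5 else config$momentum
    batches <- .partition_batches(sample.int(n), config$batches_per_epoch)
    errs <- numeric(config$batches_per_epoch)
    for (b in seq_along(batches)) {
      errs[b] <- .cpp_cd1_inplace(st$w, st$vbias, st$hbias, st$w_inc,
                                  st$vbias_inc, st$hbias_inc,
                                  x[batches[[b]], , drop = FALSE],
                                  config$learning_rate, mom,
                                  config$weight_decay)
      if (!is.null(recorder)) recorder(st$w, st$hbias)
    }
    mse[epoch] <- mean(errs)
  }
  layer[names(st)] <- st
  attr(layer, "epoch_mse") <- mse
  layer
}

#' Fit a two-layer deep belief network by greedy layer-wise CD-1
#'
#' Trains the 900-400-800 generative stack: layer 1 (input to 400 hidden
#' units) for the configured schedule, then layer 2 (400 to 800) on the
#' deterministic mean-field outputs of the frozen layer 1. The dataset is
#' reshuffled every epoch with the seeded random stream and split into
#' `batches_per_epoch` near-equal mini-batches, so each epoch contributes
#' exactly `batches_per_epoch` learning events (cycles); 40 x 120 = 4,800
#' cycles at the defaults. An optional recorder (see [icd_recorder()]) is
#' invoked after every layer-2 update to capture the internal
#' computational dynamics. The run is bitwise reproducible given
#' `config$seed`.
#'
#' @param x A `stimulus_set` or a numeric matrix whose rows are input
#'   vectors in [0, 1].
#' @param config A [train_config()].
#' @param recorder Optional [icd_recorder()]; its probes are presented to
#'   the network after every layer-2 mini-batch update.
#' @param sizes Hidden layer sizes (default `c(400, 800)`).
#' @return An object of class `dbn` with elements `layer1`, `layer2`,
#'   `config`, `sizes` and `recon_error` (data frame epoch/layer/mse).
#' @seealso [predict.dbn()], [train_readout()]
#' @export
train_dbn <- function(x, config = train_config(), recorder = NULL,
                      sizes = c(400L, 800L)) {
  if (inherits(x, "stimulus_set")) x <- x$x
  stopifnot(is.matrix(x), all(x >= 0), all(x <= 1))
  set.seed(config$seed)

  l1 <- rbm_layer(ncol(x), sizes[1], config$init_sd)
  l2 <- rbm_layer(sizes[1], sizes[2], config$init_sd)

  l1 <- .train_layer(l1, x, config)
  h1 <- .rbm_hidden(l1, x)

  rec_fun <- NULL
  if (!is.null(recorder)) {
    probe_h1 <- .rbm_hidden(l1, recorder$probes)   # layer 1 is frozen now
    rec_fun <- function(w, hbias) {
      a <- probe_h1 %*% w
      a <- 1 / (1 + exp(-(a + rep(hbias, each = nrow(a)))))
      recorder$record(a)
    }
  }
  l2 <- .train_layer(l2, h1, config, rec_fun)

  structure(
    list(layer1 = l1, layer2 = l2, config = config, sizes = sizes,
         recon_error = data.frame(
           epoch = rep(seq_len(config$epochs), 2L),
           layer = rep(1:2, each = config$epochs),
           mse = c(attr(l1, "epoch_mse"), attr(l2, "epoch_mse"))
         )),
    class = "dbn"
  )
}

#' @export
print.dbn <- function(x, ...) {
  cat(sprintf("<dbn> %d-%d-%d, %d epochs x %d batches (seed %d)\n",
              nrow(x$layer1$w), x$sizes[1], x$sizes[2],
              x$config$epochs, x$config$batches_per_epoch, x$config$seed))
  last <- subset(x$recon_error, x$recon_error$epoch == x$config$epochs)
  cat(sprintf("  final reconstruction mse: layer1 %.5f, layer2 %.5f\n",
              last$mse[1], last$mse[2]))
  invisible(x)
}

#' @export
summary.dbn <- function(object, ...) {
  print(object)
  cat("reconstruction error by epoch (layer 2):\n")
  print(utils::head(subset(object$recon_error, object$recon_error$layer == 2), 5))
  invisible(object)
}

#' Deterministic mean-field activations of a fitted network
#'
#' Propagates inputs through the generative stack with logistic
#' mean-field units (no sampling), so identical inputs always yield
#' identical activations strictly inside (0, 1).
#'
#' @param object A fitted `dbn`.
#' @param newdata A `stimulus_set`, a single `stimulus_image`, or a
#'   matrix/vector of length-900 inputs.
#' @param layer `"h2"` (default, the 800-unit layer feeding the read-out),
#'   `"h1"`, or `"both"`.
#' @param ... Unused.
#' @return Activation matrix (rows = inputs), or a list of both layers.
#' @export
predict.dbn <- function(object, newdata, layer = c("h2", "h1", "both"), ...) {
  layer <- match.arg(layer)
  v <- forward_input_matrix(newdata)
  h1 <- .rbm_hidden(object$layer1, v)
  if (layer == "h1") return(h1)
  h2 <- .rbm_hidden(object$layer2, h1)
  if (layer == "h2") h2 else list(h1 = h1, h2 = h2)
}

#' Per-layer activations for a single stimulus
#'
#' @param net A fitted `dbn`.
#' @param image A `stimulus_image` or length-900 numeric vector.
#' @return List with vectors `h1` (400) and `h2` (800).
#' @export
forward_activation <- function(net, image) {
  a <- predict(net, image, layer = "both")
  list(h1 = drop(a$h1), h2 = drop(a$h2))
}

# accept stimulus_set / stimulus_image / matrix / vector as network input
forward_input_matrix <- function(newdata) {
  if (inherits(newdata, "stimulus_set")) return(newdata$x)
  if (inherits(newdata, "stimulus_image")) return(matrix(newdata$vector, 1L))
  if (is.vector(newdata) && is.numeric(newdata)) return(matrix(newdata, 1L))
  stopifnot(is.matrix(newdata))
  newdata
}

#' Save / load a network checkpoint
#'
#' Checkpoints are plain RDS files containing the fitted object (weights,
#' biases, configuration and seed).
#'
#' @param net A `dbn` (or any fitted object from this package).
#' @param path File path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the object.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
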