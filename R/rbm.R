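# ---- restricted Boltzmann machine layer ------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a restricted Boltzmann machine layer
#'
#' Initializes a visible-to-hidden weight matrix with small Gaussian
#' weights (standard deviation `init_sd`) and zero biases, drawing from
#' R's current random stream.
#'
#' @param n_visible,n_hidden Layer sizes.
#' @param init_sd Standard deviation of the Gaussian weight
#'   initialization (default 0.01).
#' @return An object of class `rbm_layer`: list with `w`
#'   (`n_visible` x `n_hidden`), `vbias`, `hbias`, and momentum buffers.
#' @export
rbm_layer <- function(n_visible, n_hidden, init_sd = 0.01) {
  structure(
    list(
      w = matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                 n_visible, n_hidden),
      vbias = numeric(n_visible),
      hbias = numeric(n_hidden),
      w_inc = matrix(0, n_visible, n_hidden),
      vbias_inc = numeric(n_visible),
      hbias_inc = numeric(n_hidden)
    ),
    class = "rbm_layer"
  )
}

#' @export
print.rbm_layer <- function(x, ...) {
  cat(sprintf("<rbm_layer> %d visible -> %d hidden\n", nrow(x$w), ncol(x$w)))
  invisible(x)
}

# mean-field hidden activation
.rbm_hidden <- function(layer, v) {
  .sigmoid(sweep(v %*% layer$w, 2, layer$hbias, `+`))
}

#' One contrastive-divergence (CD-1) update
#'
#' Performs a single CD-1 step on a mini-batch: positive-phase hidden
#' probabilities from the data, a binary hidden sample, one Gibbs
#' reconstruction of the visibles (mean-field), negative-phase hidden
#' probabilities, then a Hebbian difference update with momentum and
#' weight decay (decay applies to the weights only). Visible values are
#' treated as probabilities in [0, 1]. The binary sampling consumes R's
#' random stream, so fix the seed for reproducible updates.
#'
#' @param layer An `rbm_layer`.
#' @param batch Numeric matrix, rows = cases, columns = visible units,
#'   values in [0, 1].
#' @param learning_rate,momentum,weight_decay Update hyperparameters.
#' @return The updated `rbm_layer`, with the mini-batch mean squared
#'   reconstruction error in attribute `"mse"`.
#' @export
cd1_update <- function(layer, batch, learning_rate = 0.05,
                       momentum = 0.5, weight_decay = 2e-4) {
  stopifnot(inherits(layer, "rbm_layer"), is.matrix(batch))
  if (!is.double(batch)) storage.mode(batch) <- "double"
  st <- .layer_state(layer)
  mse <- .cpp_cd1_inplace(st$w, st$vbias, st$hbias, st$w_inc, st$vbias_inc,
                          st$hbias_inc, batch, learning_rate, momentum,
                          weight_decay)
  layer[names(st)] <- st
  attr(layer, "mse") <- mse
  layer
}

# deep copies of the parameter arrays; the compiled kernel updates these
# in place, so the trainer owns one state for a whole schedule
.layer_state <- function(layer) {
  list(w = layer$w + 0, vbias = layer$vbias + 0, hbias = layer$hbias + 0,
       w_inc = layer$w_inc + 0, vbias_inc = layer$vbias_inc + 0,
       hbias_inc = layer$hbias_inc + 0)
}

# near-equal partition of shuffled indices into n_batches mini-batches
.partition_batches <- function(idx, n_batches) {
  n <- length(idx)
  base <- n %/% n_batches
  sizes <- rep(base, n_batches)
  extra <- n %% n_batches
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  split(idx, rep(seq_len(n_batches), times = sizes))
}
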