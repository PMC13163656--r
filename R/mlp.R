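#' Hidden-layer size by the geometric pyramid rule
#'
#' For a three-layer network with `n` inputs and `k` outputs the hidden
#' layer gets `round(sqrt(n * k))` neurons (at least 1).
#'
#' @param n,k Positive integers: input and output counts.
#' @return Integer hidden-layer size.
#' @examples
#' hidden_size(100, 4)    # 20
#' hidden_size(4465, 31)  # 372
#' @export
hidden_size <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 1, k >= 1)
  max(1L, as.integer(round(sqrt(as.numeric(n) * as.numeric(k)))))
}

#' Training configuration for one network
#'
#' Defaults follow the recognition protocol: learning rate and momentum
#' 0.07/0.07 for concatenated-image networks and 0.3/0.1 for single-gene
#' networks (see [teach_ensemble()]); training stops when the root mean
#' squared error over all samples and outputs reaches `target_rmse`
#' (default 0.01, the "SMTP" stopping criterion).
#'
#' @param n_inputs,n_outputs Layer sizes.
#' @param n_hidden Hidden-layer size; default [hidden_size()].
#' @param learning_rate,momentum Online backpropagation parameters.
#' @param target_rmse Stopping RMSE in `(0, 1)`.
#' @param max_epochs Epoch cap; exceeding it raises a non-convergence error
#'   in [train_online()].
#' @param seed Integer seed controlling weight initialisation and per-epoch
#'   sample shuffling.
#' @param shuffle Reshuffle presentation order each epoch (default `TRUE`);
#'   set `FALSE` for a strictly sequential presentation.
#' @return Object of class `mlp_config`.
#' @export
mlp_config <- function(n_inputs, n_outputs,
                       n_hidden = hidden_size(n_inputs, n_outputs),
                       learning_rate = 0.07, momentum = 0.07,
                       target_rmse = 0.01, max_epochs = 50000L,
                       seed = 1L, shuffle = TRUE) {
  stopifnot(n_inputs >= 1, n_outputs >= 1, n_hidden >= 1,
            learning_rate >= 0, momentum >= 0,
            target_rmse > 0, target_rmse < 1, max_epochs >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate, momentum = momentum,
                 target_rmse = target_rmse,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "mlp_config")
}

#' Initialise a network
#'
#' Weights (including hidden and output biases) are drawn uniformly from
#' `[-0.5, 0.5]` using a generator seeded from `config$seed`, so the same
#' seed always yields identical weights.
#'
#' @param config An [mlp_config()].
#' @param label_order Character vector of organism identifiers, one per
#'   output neuron.
#' @return Object of class `mlp_model`: `config`, `hidden_weights`
#'   (`n_hidden x (n_inputs + 1)`, last column the bias), `output_weights`
#'   (`n_outputs x (n_hidden + 1)`), `label_order`.
#' @export
init_mlp <- function(config, label_order = NULL) {
  if (is.null(label_order))
    label_order <- sprintf("output_%d", seq_len(config$n_outputs))
  stopifnot(length(label_order) == config$n_outputs)
  w <- cpp_mlp_init(config$n_inputs, config$n_hidden, config$n_outputs,
                    config$seed)
  structure(list(config = config, hidden_weights = w$W1,
                 output_weights = w$W2, label_order = label_order),
            class = "mlp_model")
}

as_sample_matrix <- function(samples, n_inputs) {
  if (is.list(samples))
    samples <- do.call(rbind, lapply(samples, as.numeric))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  if (ncol(samples) != n_inputs)
    stop(sprintf("sample length %d does not match n_inputs %d",
                 ncol(samples), n_inputs), call. = FALSE)
  samples
}

#' Forward pass
#'
#' Sigmoid activations layer by layer; every output lies strictly in
#' `(0, 1)`.
#'
#' @param model An [init_mlp()] (possibly trained) model.
#' @param input Bit vector of length `n_inputs`, a `genetic_image`, or a
#'   matrix with one sample per row.
#' @return Named activation vector (one sample) or matrix (several).
#' @export
mlp_forward <- function(model, input) {
  if (inherits(input, "genetic_image")) input <- input$bits
  X <- as_sample_matrix(input, model$config$n_inputs)
  Y <- cpp_mlp_forward(model$hidden_weights, model$output_weights, X)
  colnames(Y) <- model$label_order
  if (nrow(Y) == 1L) Y[1L, ] else Y
}

#' Root mean squared error of a model on a sample set
#'
#' `sqrt(mean((outputs - targets)^2))` over all samples and output units —
#' the quantity the stopping rule compares with `target_rmse`.
#'
#' @param model An `mlp_model`.
#' @param samples Matrix or list of input vectors.
#' @param targets Matrix or list of target vectors.
#' @return Non-negative scalar.
#' @export
mlp_rmse <- function(model, samples, targets) {
  X <- as_sample_matrix(samples, model$config$n_inputs)
  T <- as_sample_matrix(targets, model$config$n_outputs)
  if (nrow(X) == 0L) stop("empty sample list", call. = FALSE)
  if (nrow(X) != nrow(T)) stop("sample/target counts differ", call. = FALSE)
  Y <- cpp_mlp_forward(model$hidden_weights, model$output_weights, X)
  sqrt(mean((Y - T)^2))
}

#' One-hot target matrix for a teaching set
#'
#' @param labels Labels of the training samples, in sample order.
#' @param label_order Output-neuron order.
#' @return `length(labels) x length(label_order)` 0/1 matrix.
#' @export
one_hot_targets <- function(labels, label_order) {
  stopifnot(all(labels %in% label_order), !anyDuplicated(labels))
  T <- matrix(0, length(labels), length(label_order),
              dimnames = list(labels, label_order))
  T[cbind(seq_along(labels), match(labels, label_order))] <- 1
  T
}

#' Train a network by online backpropagation with momentum
#'
#' One weight update per presented sample
#' (`dw <- -lr * gradient + momentum * dw_prev`); epochs repeat until the
#' epoch-end RMSE over all samples and outputs reaches
#' `config$target_rmse` or `max_epochs` is hit, in which case a
#' `genimage_nonconvergence` error is raised.
#'
#' @param model An [init_mlp()] model.
#' @param samples Matrix (or list) of training inputs, one per row.
#' @param targets One-hot target matrix; each sample's hot index must be
#'   unique (one organism per output neuron).
#' @return The trained `mlp_model` with attributes `rmse_log` (per-epoch
#'   RMSE) and `epochs`.
#' @export
train_online <- function(model, samples, targets) {
  cfg <- model$config
  X <- as_sample_matrix(samples, cfg$n_inputs)
  T <- as_sample_matrix(targets, cfg$n_outputs)
  stopifnot(nrow(X) == nrow(T))
  fit <- cpp_mlp_train(model$hidden_weights, model$output_weights, X, T,
                       cfg$learning_rate, cfg$momentum, cfg$target_rmse,
                       cfg$max_epochs, cfg$seed, cfg$shuffle)
  if (!fit$converged && cfg$learning_rate > 0) {
    stop(structure(class = c("genimage_nonconvergence", "error", "condition"),
                   list(message = sprintf(
                     "training did not reach RMSE %.4g in %d epochs (final %.4g, seed %d)",
                     cfg$target_rmse, cfg$max_epochs,
                     utils::tail(fit$rmse_log, 1L), cfg$seed),
                     call = sys.call(-1))))
  }
  model$hidden_weights <- fit$W1
  model$output_weights <- fit$W2
  attr(model, "rmse_log") <- fit$rmse_log
  attr(model, "epochs") <- fit$epochs
  model
}

#' Per-sample loss gradient (for verification)
#'
#' Backpropagation gradient of `0.5 * sum((output - target)^2)` with respect
#' to all weights, exposed so it can be checked against central finite
#' differences.
#'
#' @param model An `mlp_model`.
#' @param input,target Single sample and target vectors.
#' @return List with matrices `G1` (hidden) and `G2` (output).
#' @export
mlp_gradient <- function(model, input, target) {
  cpp_mlp_grad(model$hidden_weights, model$output_weights,
               as.numeric(input), as.numeric(target))
}

#' Save / load a model as JSON
#'
#' Versioned plain-text serialisation; [load_mlp()] restores an exact
#' round-trip (weights at full double precision).
#'
#' @param model An `mlp_model`.
#' @param path JSON file path.
#' @return `path` invisibly; for [load_mlp()], the restored model.
#' @export
save_mlp <- function(model, path) {
  obj <- list(format = "genimage-mlp/1",
              config = unclass(model$config),
              label_order = model$label_order,
              hidden_weights = model$hidden_weights,
              output_weights = model$output_weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "genimage-mlp/1"))
    stop("not a genimage MLP file", call. = FALSE)
  cfg <- do.call(mlp_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(config = cfg,
                 hidden_weights = obj$hidden_weights,
                 output_weights = obj$output_weights,
                 label_order = obj$label_order),
            class = "mlp_model")
}
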