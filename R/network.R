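#' Architecture of the feedforward classifier
#'
#' A fully connected multilayer perceptron: Tanh hidden layers followed by
#' a SoftMax output layer. The default hidden layout 2000/500/120/30/10
#' funnels the spectrum down to ten "deep features" in the last hidden
#' layer, which are the interpretable representation of each sample.
#'
#' @param input_dim Spectrum length (gene-set collection size).
#' @param n_classes Number of subtype classes (>= 2).
#' @param hidden_dims Integer vector of hidden layer widths.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(input_dim, n_classes,
                              hidden_dims = c(2000L, 500L, 120L, 30L, 10L)) {
  input_dim <- as.integer(input_dim)
  n_classes <- as.integer(n_classes)
  hidden_dims <- as.integer(hidden_dims)
  stopifnot(input_dim >= 1L, n_classes >= 2L,
            length(hidden_dims) >= 1L, all(hidden_dims >= 1L))
  structure(list(input_dim = input_dim, hidden_dims = hidden_dims,
                 n_classes = n_classes, hidden_activation = "tanh"),
            class = "architecture_spec")
}

#' Training configuration
#'
#' Mini-batch training of the multiclass cross-entropy loss with either
#' SGD with momentum (default learning rate 0.01, momentum 0.9) or
#' AdaDelta (rho = 0.95, epsilon = 1e-6, its conventional defaults).
#' Training is single-threaded and fully seeded: the same seed, data and
#' configuration reproduce bit-identical parameters.
#'
#' @param optimizer `"sgd"` or `"adadelta"`.
#' @param learning_rate Positive step size (SGD only).
#' @param momentum Momentum coefficient in `[0, 1)` (SGD only).
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param rho,epsilon AdaDelta decay and stabilizer.
#' @return A `training_config`.
#' @export
training_config <- function(optimizer = c("sgd", "adadelta"),
                            learning_rate = 0.01, momentum = 0.9,
                            epochs = 500L, batch_size = 64L, seed = 1L,
                            rho = 0.95, epsilon = 1e-6) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            epochs >= 1L, batch_size >= 1L)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 rho = rho, epsilon = epsilon, loss = "cross_entropy"),
            class = "training_config")
}

layer_dims <- function(arch) {
  c(arch$input_dim, arch$hidden_dims, arch$n_classes)
}

#' Xavier/Glorot initialization
#'
#' Weights are drawn uniformly from
#' `[-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out))]` (the uniform
#' Glorot variant, matched to Tanh activations); biases start at zero.
#' The same seed yields bit-identical parameters.
#'
#' @param arch An `architecture_spec`.
#' @param seed Integer seed.
#' @return A `network_parameters` list of per-layer `W` (out x in) and `b`.
#' @export
init_parameters <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  set.seed(as.integer(seed))
  dims <- layer_dims(arch)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    fan_out <- dims[l + 1L]
    bound <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_out * fan_in, -bound, bound),
                 nrow = fan_out, ncol = fan_in),
      b = numeric(fan_out))
  }
  structure(list(layers = layers, arch = arch), class = "network_parameters")
}

softmax_rows <- function(logits) {
  # log-sum-exp stabilized so rows sum to 1 for arbitrary finite logits
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Forward pass
#'
#' Applies each hidden layer's affine map followed by Tanh, then the output
#' layer's affine map followed by SoftMax. Posterior rows sum to 1.
#'
#' @param params `network_parameters`.
#' @param spectra Numeric matrix, samples x input_dim (a spectra matrix).
#' @return List with `posteriors` (samples x classes) and `activations`
#'   (one samples x width matrix per hidden layer).
#' @export
net_forward <- function(params, spectra) {
  stopifnot(inherits(params, "network_parameters"), is.matrix(spectra))
  arch <- params$arch
  if (ncol(spectra) != arch$input_dim)
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(spectra), arch$input_dim))
  n_hidden <- length(arch$hidden_dims)
  a <- spectra
  activations <- vector("list", n_hidden)
  for (l in seq_len(n_hidden)) {
    lay <- params$layers[[l]]
    a <- tanh(sweep(a %*% t(lay$W), 2L, lay$b, `+`))
    activations[[l]] <- a
  }
  out <- params$layers[[n_hidden + 1L]]
  logits <- sweep(a %*% t(out$W), 2L, out$b, `+`)
  posteriors <- softmax_rows(logits)
  rownames(posteriors) <- rownames(spectra)
  list(posteriors = posteriors, activations = activations)
}

# Mean cross-entropy loss and analytic gradients for one (mini-)batch.
# Y is the n x K one-hot indicator. Returns loss plus per-layer dW/db.
net_loss_gradients <- function(params, X, Y) {
  fwd <- net_forward(params, X)
  P <- fwd$posteriors
  n <- nrow(X)
  loss <- -sum(Y * log(pmax(P, 1e-300))) / n
  n_layers <- length(params$layers)
  grads <- vector("list", n_layers)
  delta <- (P - Y) / n                       # d loss / d logits
  acts <- c(list(X), fwd$activations)        # inputs to each layer
  for (l in rev(seq_len(n_layers))) {
    a_prev <- acts[[l]]
    grads[[l]] <- list(dW = t(delta) %*% a_prev, db = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% params$layers[[l]]$W) * (1 - acts[[l]]^2)
    }
  }
  list(loss = loss, grads = grads)
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, nrow = length(labels), ncol = length(classes),
              dimnames = list(names(labels), classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

#' Train the network on labelled spectra
#'
#' Mini-batch gradient descent on the multiclass cross-entropy; batches are
#' reshuffled every epoch from the seeded RNG stream. Classes present in
#' the vocabulary but absent from the data trigger a warning; a NaN loss
#' aborts with a diagnostic.
#'
#' @param spectra Numeric matrix, samples x sets.
#' @param labels Named factor of class labels covering every spectra row.
#' @param arch An `architecture_spec`; its `n_classes` must equal the
#'   vocabulary size.
#' @param config A `training_config`.
#' @return List with `params` (`network_parameters`), `loss_trace`
#'   (mean loss per epoch, length `epochs`) and `classes`.
#' @export
net_train <- function(spectra, labels, arch, config = training_config()) {
  stopifnot(inherits(arch, "architecture_spec"),
            inherits(config, "training_config"))
  if (is.null(names(labels)) || !all(rownames(spectra) %in% names(labels)))
    stop("every spectra sample must have a label")
  labels <- labels[rownames(spectra)]
  classes <- if (is.factor(labels)) levels(labels) else unique(labels)
  if (length(classes) < 2L) stop("need >= 2 classes")
  if (length(classes) != arch$n_classes)
    stop(sprintf("architecture expects %d classes, labels have %d",
                 arch$n_classes, length(classes)))
  absent <- setdiff(classes, as.character(labels))
  if (length(absent) > 0L)
    warning("class(es) with no training samples: ",
            paste(absent, collapse = ", "))
  params <- init_parameters(arch, config$seed)
  Y <- one_hot(labels, classes)
  n <- nrow(spectra)
  n_layers <- length(params$layers)
  state <- lapply(params$layers, function(l)
    list(vW = l$W * 0, vb = l$b * 0, uW = l$W * 0, ub = l$b * 0))
  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      lg <- net_loss_gradients(params, spectra[idx, , drop = FALSE],
                               Y[idx, , drop = FALSE])
      batch_losses[bi] <- lg$loss
      for (l in seq_len(n_layers)) {
        g <- lg$grads[[l]]
        if (config$optimizer == "sgd") {
          state[[l]]$vW <- config$momentum * state[[l]]$vW -
            config$learning_rate * g$dW
          state[[l]]$vb <- config$momentum * state[[l]]$vb -
            config$learning_rate * g$db
          params$layers[[l]]$W <- params$layers[[l]]$W + state[[l]]$vW
          params$layers[[l]]$b <- params$layers[[l]]$b + state[[l]]$vb
        } else {  # adadelta
          st <- state[[l]]
          st$vW <- config$rho * st$vW + (1 - config$rho) * g$dW^2
          st$vb <- config$rho * st$vb + (1 - config$rho) * g$db^2
          dW <- -sqrt(st$uW + config$epsilon) / sqrt(st$vW + config$epsilon) *
            g$dW
          db <- -sqrt(st$ub + config$epsilon) / sqrt(st$vb + config$epsilon) *
            g$db
          st$uW <- config$rho * st$uW + (1 - config$rho) * dW^2
          st$ub <- config$rho * st$ub + (1 - config$rho) * db^2
          params$layers[[l]]$W <- params$layers[[l]]$W + dW
          params$layers[[l]]$b <- params$layers[[l]]$b + db
          state[[l]] <- st
        }
      }
    }
    loss_trace[epoch] <- mean(batch_losses)
    if (!is.finite(loss_trace[epoch]))
      stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                   epoch))
  }
  list(params = params, loss_trace = loss_trace, classes = classes)
}

#' Deep features: the last hidden layer's activations
#'
#' The compressed representation (10 values per sample by default) used for
#' interpretation -- correlating learned features with gene-set scores and
#' measuring within-subtype compactness.
#'
#' @param params `network_parameters` (trained).
#' @param spectra Numeric matrix, samples x input_dim.
#' @return Numeric matrix, samples x last hidden width.
#' @export
deep_features <- function(params, spectra) {
  acts <- net_forward(params, spectra)$activations
  f <- acts[[length(acts)]]
  colnames(f) <- paste0("DF", seq_len(ncol(f)))
  f
}

#' Hidden-layer activations at a chosen depth
#'
#' @param params `network_parameters`.
#' @param spectra Numeric matrix, samples x input_dim.
#' @param layer_index 1-based hidden layer index.
#' @return Activations (after Tanh) at that depth, samples x width.
#' @export
hidden_layer_activations <- function(params, spectra, layer_index) {
  n_hidden <- length(params$arch$hidden_dims)
  if (layer_index < 1L || layer_index > n_hidden)
    stop(sprintf("layer_index must be in 1..%d", n_hidden))
  net_forward(params, spectra)$activations[[layer_index]]
}
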