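# Two-layer dropout MLP binary classifier.
#
# Topology: input -> dropout(0.5) -> dense(n_in -> n_hidden) -> relu
#           -> dropout(0.5) -> dense(n_hidden -> 2) -> softmax
# with n_hidden fixed by the nearest-integer rule n_in/10, Glorot-uniform
# weight initialization (biases zero), an L2 penalty on weights only, and
# full-batch Adam for a fixed number of epochs. Dropout is inverted
# (activations rescaled by 1/(1-p) at train time) and disabled at inference.
# Written directly in matrix algebra: the cohorts involved are tiny
# (<= a few hundred rows, <= 806 features), so BLAS-backed full-batch
# steps are both fast and exactly reproducible.

POSITIVE_CLASS <- "group1_osteo"
NEGATIVE_CLASS <- "group2_healthy"

#' Hidden-layer width from the input width
#'
#' Nearest integer to `n_in / 10`, ties rounding away from zero. The rule is
#' intended for feature vectors of 201 to 806 entries; outside that range it
#' still applies but a warning is emitted.
#'
#' @param n_in Number of input features (>= 1).
#' @return Integer hidden width.
#' @examples
#' hidden_width(402) # 40
#' @export
hidden_width <- function(n_in) {
  if (!is.numeric(n_in) || length(n_in) != 1L || n_in < 1 ||
      n_in != round(n_in)) {
    stop_wristrf("n_in must be a single integer >= 1")
  }
  if (n_in < 201 || n_in > 806) {
    warning(sprintf("hidden_width: n_in = %d is outside the intended 201-806 range",
                    as.integer(n_in)), call. = FALSE)
  }
  as.integer(floor(n_in / 10 + 0.5))
}

#' Classifier configuration
#'
#' @param n_in Input feature count.
#' @param n_hidden Hidden width; default from [hidden_width()].
#' @param dropout_rate Dropout probability in `[0, 1)` for both dropout
#'   layers (default 0.5).
#' @param epochs Training epochs (default 1000).
#' @param l2_weights L2 penalty coefficient on dense-layer weights; biases
#'   are never penalized (default 1e-4).
#' @param learn_rate Adam step size (default 1e-3).
#' @param seed Seed for the single RNG stream driving initialization and all
#'   dropout masks.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(n_in, n_hidden = NULL, dropout_rate = 0.5,
                       epochs = 1000L, l2_weights = 1e-4, learn_rate = 1e-3,
                       seed = 1L) {
  check_scalar_number(n_in, "n_in", positive = TRUE)
  if (is.null(n_hidden)) {
    n_hidden <- suppressWarnings(hidden_width(n_in))
  }
  if (n_hidden < 1L) {
    stop_wristrf("derived hidden width is %d; n_in = %d is too small for the sizing rule",
                 n_hidden, n_in)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_wristrf("dropout_rate must lie in [0, 1)")
  }
  if (epochs < 1L) stop_wristrf("epochs must be >= 1")
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 l2_weights = l2_weights, learn_rate = learn_rate,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build an untrained classifier
#'
#' Glorot-uniform weights and zero biases, drawn from `config$seed`.
#' Identical configs yield identical initial parameters.
#'
#' @param config An [mlp_config()].
#' @return An `rf_mlp` with `params` (`W1`, `b1`, `W2`, `b2`), `config`, and
#'   `trained = FALSE`.
#' @export
mlp_build <- function(config) {
  if (!inherits(config, "mlp_config")) stop_wristrf("not an mlp_config")
  params <- with_seed(config$seed, mlp_init_params(config))
  structure(list(params = params, config = config, trained = FALSE,
                 classes = c(POSITIVE_CLASS, NEGATIVE_CLASS)),
            class = "rf_mlp")
}

mlp_init_params <- function(config) {
  list(W1 = glorot_uniform(config$n_in, config$n_hidden),
       b1 = numeric(config$n_hidden),
       W2 = glorot_uniform(config$n_hidden, 2L),
       b2 = numeric(2L))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward + analytic gradient for one full batch. `mask_in`/`mask_h` are
# inverted-dropout multipliers (already scaled by 1/(1-p)); pass NULL to
# disable dropout. Y is the n x 2 one-hot matrix. Loss is mean cross-entropy
# plus l2 * (||W1||^2 + ||W2||^2).
mlp_loss_grad <- function(params, x, y_onehot, l2, mask_in = NULL,
                          mask_h = NULL) {
  n <- nrow(x)
  xd <- if (is.null(mask_in)) x else x * mask_in
  z1 <- xd %*% params$W1
  z1 <- sweep(z1, 2L, params$b1, `+`)
  h <- pmax(z1, 0)
  hd <- if (is.null(mask_h)) h else h * mask_h
  z2 <- hd %*% params$W2
  z2 <- sweep(z2, 2L, params$b2, `+`)
  p <- softmax_rows(z2)
  loss <- -mean(rowSums(y_onehot * log(pmax(p, 1e-300)))) +
    l2 * (sum(params$W1^2) + sum(params$W2^2))
  dz2 <- (p - y_onehot) / n
  gW2 <- crossprod(hd, dz2) + 2 * l2 * params$W2
  gb2 <- colSums(dz2)
  dhd <- tcrossprod(dz2, params$W2)
  dh <- if (is.null(mask_h)) dhd else dhd * mask_h
  dz1 <- dh * (z1 > 0)
  gW1 <- crossprod(xd, dz1) + 2 * l2 * params$W1
  gb1 <- colSums(dz1)
  list(loss = loss,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       prob = p)
}

#' Train the classifier
#'
#' Full-batch Adam on softmax cross-entropy with the weight-only L2 penalty,
#' for a fixed `config$epochs` epochs (no early stopping). A single RNG
#' stream seeded by `config$seed` drives initialization (when `model` is
#' `NULL`) and every dropout mask, so training is fully reproducible.
#'
#' @param x Numeric matrix, one instance per row, `config$n_in` columns.
#' @param y Labels, `"group1_osteo"` / `"group2_healthy"`, one per row; both
#'   classes must be present.
#' @param config An [mlp_config()]; defaults to the sizing rule on
#'   `ncol(x)`.
#' @param model Optional prebuilt [mlp_build()] model to start from.
#' @return A trained `rf_mlp`.
#' @export
mlp_train <- function(x, y, config = mlp_config(ncol(x)), model = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    stop_wristrf("features contain NaN/Inf; refusing to train")
  }
  if (ncol(x) != config$n_in) {
    stop_wristrf("x has %d columns but config$n_in = %d", ncol(x), config$n_in)
  }
  y <- as.character(y)
  if (length(y) != nrow(x)) stop_wristrf("length(y) != nrow(x)")
  if (!all(y %in% c(POSITIVE_CLASS, NEGATIVE_CLASS))) {
    stop_wristrf("labels must be '%s' or '%s'", POSITIVE_CLASS, NEGATIVE_CLASS)
  }
  if (length(unique(y)) < 2L) {
    stop_wristrf("both classes must be present in the training labels")
  }
  y_onehot <- cbind(as.numeric(y == POSITIVE_CLASS),
                    as.numeric(y == NEGATIVE_CLASS))
  n <- nrow(x)
  rate <- config$dropout_rate
  keep <- 1 - rate
  params <- with_seed(config$seed, {
    params <- if (is.null(model)) mlp_init_params(config) else model$params
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (t in seq_len(config$epochs)) {
      mask_in <- mask_h <- NULL
      if (rate > 0) {
        mask_in <- matrix((stats::runif(n * config$n_in) >= rate) / keep,
                          n, config$n_in)
        mask_h <- matrix((stats::runif(n * config$n_hidden) >= rate) / keep,
                         n, config$n_hidden)
      }
      lg <- mlp_loss_grad(params, x, y_onehot, config$l2_weights,
                          mask_in, mask_h)
      for (nm in names(params)) {
        g <- lg$grad[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        mhat <- m[[nm]] / (1 - b1^t)
        vhat <- v[[nm]] / (1 - b2^t)
        params[[nm]] <- params[[nm]] -
          config$learn_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    params
  })
  structure(list(params = params, config = config, trained = TRUE,
                 classes = c(POSITIVE_CLASS, NEGATIVE_CLASS)),
            class = "rf_mlp")
}

#' Predict group membership
#'
#' Dropout is disabled; inference is deterministic. A softmax tie
#' (p = 0.5) is resolved to `"group1_osteo"` — screening-conservative, since
#' a false alarm costs a confirmatory scan while a miss costs a diagnosis.
#'
#' @param object A trained `rf_mlp`.
#' @param x Numeric matrix (or single vector) of feature rows of width
#'   `config$n_in`.
#' @param ... Unused.
#' @return A list with `label` (character vector) and `prob` (matrix with
#'   columns `group1_osteo`, `group2_healthy`, rows summing to 1).
#' @export
predict.rf_mlp <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != object$config$n_in) {
    stop_wristrf("x has %d columns but the model expects %d",
                 ncol(x), object$config$n_in)
  }
  z1 <- sweep(x %*% object$params$W1, 2L, object$params$b1, `+`)
  h <- pmax(z1, 0)
  z2 <- sweep(h %*% object$params$W2, 2L, object$params$b2, `+`)
  p <- softmax_rows(z2)
  colnames(p) <- object$classes
  label <- ifelse(p[, POSITIVE_CLASS] >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS)
  list(label = unname(label), prob = p)
}

#' Save / load a trained classifier
#'
#' JSON bundle carrying the exact config (echoed verbatim for audit) and all
#' parameter arrays in full precision.
#'
#' @param model An `rf_mlp`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `load_mlp` returns the restored `rf_mlp`.
#' @export
save_mlp <- function(model, path) {
  if (!inherits(model, "rf_mlp")) stop_wristrf("not an rf_mlp")
  bundle <- list(
    config = unclass(model$config),
    trained = model$trained,
    classes = model$classes,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    }))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mlp_config, bundle$config[c("n_in", "n_hidden",
                                             "dropout_rate", "epochs",
                                             "l2_weights", "learn_rate",
                                             "seed")])
  params <- lapply(bundle$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = cfg, trained = bundle$trained,
                 classes = bundle$classes),
            class = "rf_mlp")
}
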