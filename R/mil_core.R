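#' Training configuration for the attention-MIL model
#'
#' Defaults follow the protocol used for the response-prediction study:
#' plain SGD at learning rate 1e-4 with weight decay 1e-3, one bag per
#' optimization step, up to 1024 epochs with early stopping once the
#' validation loss has not improved for 50 epochs. Momentum 0.9 and the
#' attention hidden size L = 256 are conventional choices.
#'
#' @param learning_rate SGD learning rate.
#' @param weight_decay L2 penalty coefficient applied to V, w and the head
#'   weights (not the bias).
#' @param momentum SGD momentum.
#' @param batch_size Bags per optimization step (the protocol uses 1).
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement.
#' @param L Attention hidden size.
#' @param seed Seed governing parameter initialization and bag shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-3,
                         momentum = 0.9, batch_size = 1L,
                         max_epochs = 1024L, patience = 50L,
                         L = 256L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, momentum >= 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1, L >= 1)
  if (patience > max_epochs)
    stop("`patience` must not exceed `max_epochs`", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), L = as.integer(L),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Gated-free tanh attention weights
#'
#' Computes the normalized attention weight of each patch,
#' `alpha_k = exp(w' tanh(V h_k)) / sum_j exp(w' tanh(V h_j))`,
#' with max-subtraction inside the softmax for numerical stability. The
#' weights are nonnegative and sum to one for any parameter values.
#'
#' @param H Numeric `N x d` matrix of patch features (rows are patches).
#' @param params Model parameter list with `V` (`L x d`) and `w` (length
#'   `L`), e.g. from [mil_init()].
#' @return Numeric vector of `N` attention weights summing to 1.
#' @export
attention_weights <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(H) != ncol(params$V))
    stop("feature dimension of H does not match params$V", call. = FALSE)
  scores <- attention_scores(H, params)
  softmax(scores)
}

attention_scores <- function(H, params) {
  as.vector(tanh(H %*% t(params$V)) %*% params$w)
}

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Attention-weighted bag aggregation
#'
#' The slide-level embedding is the attention-weighted sum of patch
#' features, `z = sum_k alpha_k h_k`.
#'
#' @param H Numeric `N x d` feature matrix.
#' @param alpha Attention weights of length `N`, summing to 1 (within 1e-6).
#' @return Numeric vector of length `d`.
#' @export
aggregate_bag <- function(H, alpha) {
  H <- as.matrix(H)
  if (length(alpha) != nrow(H))
    stop("`alpha` must have one weight per row of H", call. = FALSE)
  if (abs(sum(alpha) - 1) > 1e-6)
    stop("`alpha` must sum to 1", call. = FALSE)
  as.vector(crossprod(H, alpha))
}

#' Slide-level classification head
#'
#' A single linear layer followed by a sigmoid, mapping the slide embedding
#' to the predicted probability of pathologic complete response.
#'
#' @param z Slide embedding of length `d`.
#' @param params Parameter list with head weights `u` (length `d`) and
#'   scalar bias `b`.
#' @return Probability in `(0, 1)`.
#' @export
classify_slide <- function(z, params) {
  if (length(z) != length(params$u))
    stop("embedding length does not match head weights", call. = FALSE)
  stats::plogis(sum(params$u * z) + params$b)
}

#' Inverse-frequency class weights
#'
#' For a cohort with `n_pcr` responders and `n_non_pcr` non-responders the
#' class weights are `w_pCR = N / (2 n_pCR)` and
#' `w_nonpCR = N / (2 n_nonpCR)` with `N = n_pCR + n_nonpCR`, so the
#' count-weighted mean weight is exactly 1 and the minority class receives
#' the larger penalty.
#'
#' @param n_pcr,n_non_pcr Class counts, both at least 1.
#' @return An object of class `class_weights` with fields `w_pcr`,
#'   `w_non_pcr`, `n_pcr`, `n_non_pcr`, `n`.
#' @export
class_weights <- function(n_pcr, n_non_pcr) {
  if (n_pcr < 1 || n_non_pcr < 1)
    stop("degenerate cohort: both classes must be present", call. = FALSE)
  n <- n_pcr + n_non_pcr
  structure(list(w_pcr = n / (2 * n_pcr), w_non_pcr = n / (2 * n_non_pcr),
                 n_pcr = as.integer(n_pcr), n_non_pcr = as.integer(n_non_pcr),
                 n = as.integer(n)),
            class = "class_weights")
}

#' Class-weighted binary cross-entropy
#'
#' `L = -(1/B) sum_k [ w_pCR y_k log p_k + w_nonpCR (1 - y_k) log(1 - p_k) ]`.
#' Probabilities are clamped to `[eps, 1 - eps]` before the logarithm. With
#' unit weights this is the ordinary binary cross-entropy.
#'
#' @param y Binary labels (0/1) of length `B`.
#' @param p Predicted probabilities of length `B`.
#' @param cw Optional [class_weights()]; `NULL` means unit weights.
#' @param eps Clamping constant.
#' @return Nonnegative scalar loss.
#' @export
weighted_bce <- function(y, p, cw = NULL, eps = 1e-7) {
  if (length(y) != length(p))
    stop("`y` and `p` must have equal length", call. = FALSE)
  if (length(y) < 1L) stop("empty batch", call. = FALSE)
  w1 <- if (is.null(cw)) 1 else cw$w_pcr
  w0 <- if (is.null(cw)) 1 else cw$w_non_pcr
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(w1 * y * log(p) + w0 * (1 - y) * log(1 - p))
}

#' Initialize attention-MIL parameters
#'
#' V and w use scaled Gaussian initialization (sd `1/sqrt(fan_in)`); the
#' head starts near zero so early training is driven by the embedding.
#'
#' @param d Feature dimensionality.
#' @param L Attention hidden size.
#' @param seed Seed for the draws.
#' @return List with `V` (`L x d`), `w` (`L`), `u` (`d`), `b` (scalar).
#' @export
mil_init <- function(d, L = 256L, seed = 1L) {
  with_seed(seed, list(
    V = matrix(stats::rnorm(L * d, sd = 1 / sqrt(d)), nrow = L),
    w = stats::rnorm(L, sd = 1 / sqrt(L)),
    u = stats::rnorm(d, sd = 0.01),
    b = 0
  ))
}

# Forward pass + analytic gradients of the class-weighted BCE for one bag.
# Returns loss, p and gradients w.r.t. V, w, u, b (without weight decay).
mil_grad <- function(H, y, params, cw, eps = 1e-7) {
  Tm <- tanh(H %*% t(params$V))              # N x L
  s <- as.vector(Tm %*% params$w)
  alpha <- softmax(s)
  z <- as.vector(crossprod(H, alpha))
  logit <- sum(params$u * z) + params$b
  p <- stats::plogis(logit)
  pc <- min(max(p, eps), 1 - eps)
  loss <- -(cw$w_pcr * y * log(pc) + cw$w_non_pcr * (1 - y) * log(1 - pc))
  dlogit <- -cw$w_pcr * y * (1 - p) + cw$w_non_pcr * (1 - y) * p
  du <- dlogit * z
  db <- dlogit
  dz <- dlogit * params$u
  g <- as.vector(H %*% dz)                   # dL/dalpha
  ds <- alpha * (g - sum(alpha * g))         # softmax backward
  dw <- as.vector(crossprod(Tm, ds))
  dpre <- (ds %o% params$w) * (1 - Tm^2)     # N x L
  dV <- crossprod(dpre, H)                   # L x d
  list(loss = loss, p = p,
       grads = list(V = dV, w = dw, u = du, b = db))
}

#' Train the attention-MIL model
#'
#' Optimizes the attention parameters and classifier head jointly by SGD
#' with momentum on the class-weighted binary cross-entropy, one bag per
#' step, shuffling the training bags every epoch. Class weights are
#' computed from the training split only. Early stopping keeps the
#' parameters from the epoch with minimum validation loss; training halts
#' when that loss has not improved for `patience` epochs or at
#' `max_epochs`. The whole run is a deterministic function of the bags and
#' `config$seed`.
#'
#' @param train_bags,val_bags Non-empty lists of labelled [feature_bag()]s;
#'   the training split must contain both classes.
#' @param config A [train_config()].
#' @return An object of class `mil_model`: best-epoch parameters, the
#'   training log (`epoch`, `train_loss`, `val_loss`), the best epoch
#'   index, the class weights used, and the configuration.
#' @export
train_mil <- function(train_bags, val_bags, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_bags) == 0L || length(val_bags) == 0L)
    stop("both training and validation splits must be non-empty", call. = FALSE)
  y_train <- vapply(train_bags, function(b) b$label, integer(1))
  if (anyNA(y_train)) stop("all training bags must be labelled", call. = FALSE)
  if (length(unique(y_train)) < 2L)
    stop("degenerate cohort: training split contains a single class", call. = FALSE)
  d <- train_bags[[1]]$d
  cw <- class_weights(sum(y_train == 1L), sum(y_train == 0L))

  with_seed(config$seed, {
    params <- list(
      V = matrix(stats::rnorm(config$L * d, sd = 1 / sqrt(d)), nrow = config$L),
      w = stats::rnorm(config$L, sd = 1 / sqrt(config$L)),
      u = stats::rnorm(d, sd = 0.01),
      b = 0
    )
    vel <- list(V = params$V * 0, w = params$w * 0, u = params$u * 0, b = 0)
    lr <- config$learning_rate; wd <- config$weight_decay; mom <- config$momentum

    best_val <- Inf; best_params <- params; best_epoch <- 0L
    stall <- 0L
    log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(train_bags))
      step_losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        b <- train_bags[[ord[ii]]]
        fb <- mil_grad(b$features, b$label, params, cw)
        step_losses[ii] <- fb$loss
        for (nm in c("V", "w", "u")) {
          g <- fb$grads[[nm]] + wd * params[[nm]]
          vel[[nm]] <- mom * vel[[nm]] + g
          params[[nm]] <- params[[nm]] - lr * vel[[nm]]
        }
        vel$b <- mom * vel$b + fb$grads$b
        params$b <- params$b - lr * vel$b
      }
      val_loss <- mean(vapply(val_bags, function(b) {
        p <- classify_slide(aggregate_bag(b$features,
                                          attention_weights(b$features, params)),
                            params)
        weighted_bce(b$label, p, cw)
      }, numeric(1)))
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, mean(step_losses))
      log_val <- c(log_val, val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params
        best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }

    structure(list(params = best_params, d = d, L = config$L,
                   class_weights = cw, config = config,
                   best_epoch = best_epoch, best_val_loss = best_val,
                   log = data.frame(epoch = log_epoch,
                                    train_loss = log_train,
                                    val_loss = log_val)),
              class = "mil_model")
  })
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> d = %d, L = %d; %d epochs trained, best epoch %d (val loss %.4f)\n",
              x$d, x$L, nrow(x$log), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict the response probability for one bag
#'
#' Runs the attention forward pass: per-patch attention weights, the
#' attention-weighted slide embedding, and the sigmoid head. The bag
#' function is permutation invariant — reordering patches permutes `alpha`
#' identically and leaves `z` and `p` unchanged.
#'
#' @param object A fitted `mil_model`.
#' @param bag A [feature_bag()] with matching feature dimensionality.
#' @param ... Unused.
#' @return An object of class `attention_result`: `alpha` (length `N`,
#'   sums to 1), `z` (length `d`), `p` (probability), `slide_id`.
#' @export
predict.mil_model <- function(object, bag, ...) {
  stopifnot(inherits(bag, "feature_bag"))
  if (bag$d != object$d)
    stop(sprintf("bag has d = %d but the model expects d = %d",
                 bag$d, object$d), call. = FALSE)
  alpha <- attention_weights(bag$features, object$params)
  z <- aggregate_bag(bag$features, alpha)
  p <- classify_slide(z, object$params)
  structure(list(alpha = alpha, z = z, p = p, slide_id = bag$slide_id),
            class = "attention_result")
}

#' @export
print.attention_result <- function(x, ...) {
  cat(sprintf("<attention_result> %s: N = %d patches, p(pCR) = %.4f, max alpha = %.4f\n",
              x$slide_id, length(x$alpha), x$p, max(x$alpha)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a keyed container holding all parameters, the
#' dimensionalities, the class weights, the training log and the full
#' configuration (including the seed), sufficient to reproduce predictions
#' exactly.
#'
#' @param model A fitted `mil_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_checkpoint` returns the `mil_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mil_model"))
  saveRDS(c(list(format = "milpath_ckpt", version = 1L), unclass(model)),
          path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "milpath_ckpt"))
    stop("not a milpath checkpoint: ", path, call. = FALSE)
  obj$format <- NULL; obj$version <- NULL
  structure(obj, class = "mil_model")
}
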