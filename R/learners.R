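# The five classifier families behind a single fit/predict interface.
#
# Each learner is fit through `fit_learner(algorithm, x, y, param, seed)`
# and scored through `predict_prob(fit, newx)`; `param` is the one tuned
# hyperparameter of that family:
#
#   glm  elastic-net-regularized logistic regression; tunes the mixing
#        parameter alpha (glmnet backend, fixed small lambda)
#   knn  k-nearest neighbours; tunes k; probability = positive fraction
#        among the k nearest training rows (FNN backend)
#   svm  RBF-kernel SVM trained by SMO; tunes log2(C); probability by
#        Platt scaling of the decision values
#   ann  single-hidden-layer perceptron (logistic activations, fixed 5
#        hidden units) fit by BFGS on the penalized cross-entropy; tunes
#        the weight decay
#   rf   random forest, 500 trees; tunes mtry; probability = fraction of
#        trees voting positive
#
# Features are standardized with train-set mean/SD for glm/knn/svm/ann
# (constant columns get SD 1 so they standardize to zero) and left raw
# for rf. The standardization is stored in the fit and re-applied at
# prediction time.

ALGORITHMS <- c("glm", "knn", "svm", "ann", "rf")

default_grid <- function(algorithm, p) {
  switch(algorithm,
    glm = c(0, 0.25, 0.5, 0.75, 1),
    knn = seq(3, 21, by = 2),
    svm = -2:6,                             # log2(C)
    ann = seq(0.1, 0.9, by = 0.1),          # weight decay
    rf  = unique(sort(c(round(sqrt(p)), 100, 149))),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Fit one classifier family
#'
#' @param algorithm One of `"glm"`, `"knn"`, `"svm"`, `"ann"`, `"rf"`.
#' @param x Numeric feature matrix (rows = pairs).
#' @param y 0/1 labels.
#' @param param The family's tuned hyperparameter (see the file header);
#'   `NULL` picks a sensible default.
#' @param seed Integer seed for the stochastic learners (rf bootstrap,
#'   ann initialization); deterministic learners ignore it.
#' @param ntree Number of random-forest trees (default 500).
#' @return Object of class `smireg_learner`.
#' @export
fit_learner <- function(algorithm, x, y, param = NULL, seed = 1L,
                        ntree = 500L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- check_binary_labels(y)
  if (is.null(param)) {
    param <- switch(algorithm, glm = 1, knn = 7, svm = 2, ann = 0.5,
                    rf = round(sqrt(ncol(x))))
  }
  fit <- switch(algorithm,
    glm = {
      std <- standardize_fit(x)
      xs <- standardize_apply(x, std)
      m <- glmnet::glmnet(xs, factor(y, levels = c(0L, 1L)),
                          family = "binomial", alpha = param,
                          lambda = c(0.1, 0.01, 0.001))
      list(model = m, std = std, lambda = 0.001)
    },
    knn = {
      std <- standardize_fit(x)
      list(x = standardize_apply(x, std), y = y, k = as.integer(param),
           std = std)
    },
    svm = {
      std <- standardize_fit(x)
      xs <- standardize_apply(x, std)
      m <- .svm_train_cpp(xs, ifelse(y == 1L, 1, -1), C = 2^param,
                          gamma = 1 / ncol(x), tol = 1e-3,
                          max_passes = 3L, seed = as.integer(seed))
      dec <- .svm_decision_cpp(m, xs)
      list(model = m, std = std, platt = platt_fit(dec, y))
    },
    ann = {
      std <- standardize_fit(x)
      list(model = mlp_fit(standardize_apply(x, std), y, size = 5L,
                           decay = param, seed = seed),
           std = std)
    },
    rf = {
      mtry <- max(1L, min(ncol(x), as.integer(round(param))))
      list(model = .rf_train_cpp(x, y, ntree = as.integer(ntree),
                                 mtry = mtry, min_node = 1L,
                                 max_depth = 30L,
                                 seed = as.integer(seed)))
    })
  structure(c(fit, list(algorithm = algorithm, param = param, seed = seed,
                        p = ncol(x))),
            class = "smireg_learner")
}

#' Predicted probability of the positive class
#'
#' @param fit A `smireg_learner` from [fit_learner()].
#' @param newx Numeric feature matrix with the same columns as training.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(fit, newx) {
  stopifnot(inherits(fit, "smireg_learner"), is.matrix(newx))
  if (ncol(newx) != fit$p) {
    stop(sprintf("expected %d features, got %d", fit$p, ncol(newx)),
         call. = FALSE)
  }
  switch(fit$algorithm,
    glm = {
      xs <- standardize_apply(newx, fit$std)
      as.vector(stats::predict(fit$model, xs, s = fit$lambda,
                               type = "response"))
    },
    knn = {
      xs <- standardize_apply(newx, fit$std)
      nn <- FNN::get.knnx(fit$x, xs, k = fit$k)$nn.index
      rowMeans(matrix(fit$y[nn], nrow = nrow(xs)))
    },
    svm = {
      dec <- .svm_decision_cpp(fit$model, standardize_apply(newx, fit$std))
      platt_apply(fit$platt, dec)
    },
    ann = mlp_predict(fit$model, standardize_apply(newx, fit$std)),
    rf = as.vector(.rf_predict_cpp(fit$model, newx)))
}

# ---- Platt scaling --------------------------------------------------------

# Sigmoid calibration of SVM decision values: fits P(y=1|f) =
# 1/(1+exp(A f + B)) by penalized maximum likelihood with Platt's
# smoothed targets.
platt_fit <- function(decision, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  t <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1L] * decision + par[2L]
    # stable log(1+exp(z)) and cross-entropy in t
    lse <- pmax(z, 0) + log1p(exp(-abs(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  list(A = fit$par[1L], B = fit$par[2L])
}

platt_apply <- function(platt, decision) {
  1 / (1 + exp(platt$A * decision + platt$B))
}

# ---- single-hidden-layer perceptron ---------------------------------------

# Logistic hidden and output activations, cross-entropy loss with an L2
# weight-decay penalty, analytic gradients, BFGS optimization. Weight
# initialization is seeded uniform(-0.5, 0.5).
mlp_fit <- function(x, y, size = 5L, decay = 0.1, maxit = 200L, seed = 1L) {
  p <- ncol(x)
  n_par <- (p + 1L) * size + size + 1L
  unpack <- function(w) {
    list(W1 = matrix(w[seq_len((p + 1L) * size)], p + 1L, size),
         W2 = w[(p + 1L) * size + seq_len(size + 1L)])
  }
  xb <- cbind(1, x)
  sigmoid <- function(z) 1 / (1 + exp(-z))
  obj <- function(w) {
    par <- unpack(w)
    h <- sigmoid(xb %*% par$W1)
    z <- drop(cbind(1, h) %*% par$W2)
    eps <- 1e-12
    pr <- pmin(pmax(sigmoid(z), eps), 1 - eps)
    -sum(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(w^2)
  }
  grad <- function(w) {
    par <- unpack(w)
    h <- sigmoid(xb %*% par$W1)
    hb <- cbind(1, h)
    pr <- drop(sigmoid(hb %*% par$W2))
    d_out <- pr - y                                   # n
    g_W2 <- drop(crossprod(hb, d_out))                # size+1
    d_hid <- (d_out %o% par$W2[-1L]) * h * (1 - h)    # n x size
    g_W1 <- crossprod(xb, d_hid)                      # (p+1) x size
    c(as.vector(g_W1), g_W2) + 2 * decay * w
  }
  w0 <- local_seed(seed, stats::runif(n_par, -0.5, 0.5))
  fit <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit))
  list(w = fit$par, size = size, p = p, decay = decay)
}

mlp_predict <- function(model, x) {
  par <- list(
    W1 = matrix(model$w[seq_len((model$p + 1L) * model$size)],
                model$p + 1L, model$size),
    W2 = model$w[(model$p + 1L) * model$size + seq_len(model$size + 1L)])
  sigmoid <- function(z) 1 / (1 + exp(-z))
  h <- sigmoid(cbind(1, x) %*% par$W1)
  drop(sigmoid(cbind(1, h) %*% par$W2))
}
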