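# Small two-hidden-layer feed-forward regression network trained by error
# back-propagation. Written in-package because the installed neural-network
# tooling is limited to a single hidden layer; this implementation follows
# the standard MLP regressor design: choice of activation (identity,
# logistic, tanh, relu), choice of solver (lbfgs, sgd with momentum, adam),
# squared-error loss, inputs and targets standardized internally.

activations <- list(
  identity = list(f = function(z) z,            df = function(a) 1),
  logistic = list(f = function(z) 1 / (1 + exp(-z)), df = function(a) a * (1 - a)),
  tanh     = list(f = tanh,                     df = function(a) 1 - a^2),
  relu     = list(f = function(z) pmax(z, 0),   df = function(a) (a > 0) * 1))

mlp_init <- function(p, h1, h2, seed) {
  with_seed(seed, {
    gl <- function(nin, nout)
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
    list(W1 = gl(p, h1), b1 = rep(0, h1),
         W2 = gl(h1, h2), b2 = rep(0, h2),
         W3 = gl(h2, 1),  b3 = 0)
  })
}

mlp_unroll <- function(th) unlist(th, use.names = FALSE)

mlp_roll <- function(v, p, h1, h2) {
  i <- 0
  take <- function(k) { out <- v[(i + 1):(i + k)]; i <<- i + k; out }
  list(W1 = matrix(take(p * h1), p, h1), b1 = take(h1),
       W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
       W3 = matrix(take(h2), h2, 1), b3 = take(1))
}

mlp_forward <- function(th, X, act) {
  A1 <- act$f(sweep(X %*% th$W1, 2, th$b1, "+"))
  A2 <- act$f(sweep(A1 %*% th$W2, 2, th$b2, "+"))
  yhat <- as.numeric(A2 %*% th$W3 + th$b3)
  list(A1 = A1, A2 = A2, yhat = yhat)
}

mlp_grad <- function(th, X, y, act) {
  n <- nrow(X)
  fw <- mlp_forward(th, X, act)
  d3 <- matrix((fw$yhat - y) / n, ncol = 1)          # dL/dyhat, L = mean sq/2
  gW3 <- t(fw$A2) %*% d3; gb3 <- sum(d3)
  d2 <- (d3 %*% t(th$W3)) * act$df(fw$A2)
  gW2 <- t(fw$A1) %*% d2; gb2 <- colSums(d2)
  d1 <- (d2 %*% t(th$W2)) * act$df(fw$A1)
  gW1 <- t(X) %*% d1; gb1 <- colSums(d1)
  list(loss = mean((fw$yhat - y)^2) / 2,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3))
}

#' Fit a two-hidden-layer neural-network regressor
#'
#' @param x feature matrix or data frame.
#' @param y numeric response.
#' @param hidden integer vector of the two hidden-layer sizes.
#' @param activation one of "identity", "logistic", "tanh", "relu".
#' @param solver one of "lbfgs", "sgd", "adam".
#' @param max_iter iteration cap (optimizer iterations for lbfgs, epochs
#'   for sgd/adam).
#' @param learning_rate step size for sgd/adam.
#' @param seed integer seed for weight initialization (and batch order).
#' @return A list of class \code{mlp_model}; a warning is raised if the
#'   optimizer stopped without converging and the partial fit is returned.
#' @export
mlp_fit <- function(x, y, hidden = c(16, 8), activation = "tanh",
                    solver = "lbfgs", max_iter = 10000,
                    learning_rate = 0.01, seed = 1) {
  X <- as.matrix(as.data.frame(x))
  stopifnot(length(hidden) == 2, nrow(X) == length(y))
  activation <- match.arg(activation, names(activations))
  act <- activations[[activation]]
  solver <- match.arg(solver, c("lbfgs", "sgd", "adam"))
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y); ys <- stats::sd(y); if (!isTRUE(ys > 0)) ys <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yss <- (y - yc) / ys
  p <- ncol(X); h1 <- hidden[1]; h2 <- hidden[2]
  th <- mlp_init(p, h1, h2, seed)
  converged <- TRUE
  if (solver == "lbfgs") {
    fn <- function(v) mlp_grad(mlp_roll(v, p, h1, h2), Xs, yss, act)$loss
    gr <- function(v) mlp_unroll(mlp_grad(mlp_roll(v, p, h1, h2),
                                          Xs, yss, act)$grad)
    opt <- stats::optim(mlp_unroll(th), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter))
    th <- mlp_roll(opt$par, p, h1, h2)
    converged <- opt$convergence == 0
  } else {
    m <- lapply(th, function(w) w * 0)   # momentum / first moment
    v2 <- lapply(th, function(w) w * 0)  # adam second moment
    b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8
    with_seed(seed, {
      for (it in seq_len(max_iter)) {
        g <- mlp_grad(th, Xs, yss, act)$grad
        if (solver == "sgd") {
          for (k in names(th)) {
            m[[k]] <- 0.9 * m[[k]] - learning_rate * g[[k]]
            th[[k]] <- th[[k]] + m[[k]]
          }
        } else {
          for (k in names(th)) {
            m[[k]] <- b1a * m[[k]] + (1 - b1a) * g[[k]]
            v2[[k]] <- b2a * v2[[k]] + (1 - b2a) * g[[k]]^2
            mh <- m[[k]] / (1 - b1a^it)
            vh <- v2[[k]] / (1 - b2a^it)
            th[[k]] <- th[[k]] - learning_rate * mh / (sqrt(vh) + epsa)
          }
        }
        if (max(abs(unlist(g))) < 1e-7) break
      }
    })
    converged <- TRUE
  }
  if (!converged)
    warning("MLP optimizer stopped before convergence; returning partial fit")
  structure(list(theta = th, activation = activation, solver = solver,
                 xc = xc, xs = xs, yc = yc, ys = ys,
                 feature_names = colnames(X)),
            class = "mlp_model")
}

#' Predict from a fitted MLP
#'
#' @param model an \code{mlp_model}.
#' @param x new data.
#' @return Numeric predictions on the original response scale.
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as.matrix(as.data.frame(x))
  Xs <- sweep(sweep(X, 2, model$xc), 2, model$xs, "/")
  act <- activations[[model$activation]]
  mlp_forward(model$theta, Xs, act)$yhat * model$ys + model$yc
}
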