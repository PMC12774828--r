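## Minimal vectorized neural-network primitives for the genotype encoder.
## Tensors are base-R arrays: batches of one-hot genotypes are (B, D, C)
## arrays, dense activations are (B, units) matrices. All heavy operations
## reduce to BLAS matrix multiplications.

.silu <- function(x) .siluCpp(x)

.siluGrad <- function(x) .siluGradCpp(x)

## 1D convolution over the marker axis, kernel size 3, stride 1, zero padding
## ("same"). kernel: list of three Cin x Cout matrices (offsets -1, 0, +1);
## bias: length Cout. The im2col matrix (B*D x 3*Cin) built in the forward
## pass is cached and reused by the backward pass.
.im2col <- function(x) {
    d <- dim(x)
    .im2colCpp(x, d[1], d[2], d[3])
}

.convForward <- function(x, kernel, bias, cache = FALSE) {
    d <- dim(x); B <- d[1]; D <- d[2]; Cin <- d[3]
    Cout <- ncol(kernel[[1]])
    xc <- .im2col(x)
    K <- rbind(kernel[[1]], kernel[[2]], kernel[[3]])
    out <- xc %*% K
    out <- out + rep(bias, each = B * D)
    dim(out) <- c(B, D, Cout)
    if (cache) list(y = out, xc = xc) else list(y = out)
}

.convBackward <- function(xc, kernel, dOut, needDX = TRUE) {
    d <- dim(dOut); B <- d[1]; D <- d[2]; Cout <- d[3]
    Cin <- nrow(kernel[[1]])
    dOutM <- dOut; dim(dOutM) <- c(B * D, Cout)
    dKbig <- crossprod(xc, dOutM)                   # (3*Cin) x Cout
    dK <- list(dKbig[seq_len(Cin), , drop = FALSE],
               dKbig[Cin + seq_len(Cin), , drop = FALSE],
               dKbig[2L * Cin + seq_len(Cin), , drop = FALSE])
    if (!needDX)
        return(list(dK = dK, dBias = colSums(dOutM), dX = NULL))
    K <- rbind(kernel[[1]], kernel[[2]], kernel[[3]])
    dXc <- tcrossprod(dOutM, K)                     # (B*D) x (3*Cin)
    list(dK = dK, dBias = colSums(dOutM), dX = .col2imCpp(dXc, B, D, Cin))
}

## batch normalization over features (columns). Returns forward cache needed
## for the backward pass; updates running statistics when training.
.bnForward <- function(x, gamma, beta, runMean, runVar, training,
                       momentum = 0.1, eps = 1e-5) {
    if (training && nrow(x) > 1) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        runMean <- (1 - momentum) * runMean + momentum * mu
        runVar <- (1 - momentum) * runVar + momentum * v
    } else {
        mu <- runMean
        v <- runVar
        xc <- sweep(x, 2, mu)
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, istd, `*`)
    y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    list(y = y, xhat = xhat, istd = istd, runMean = runMean, runVar = runVar)
}

.bnBackward <- function(dY, cache, gamma) {
    m <- nrow(dY)
    dGamma <- colSums(dY * cache$xhat)
    dBeta <- colSums(dY)
    dXhat <- sweep(dY, 2, gamma, `*`)
    dX <- sweep(dXhat - matrix(colMeans(dXhat), m, ncol(dY), byrow = TRUE) -
                cache$xhat * matrix(colMeans(dXhat * cache$xhat), m,
                                    ncol(dY), byrow = TRUE),
                2, cache$istd, `*`)
    list(dX = dX, dGamma = dGamma, dBeta = dBeta)
}

## L2 normalization of matrix rows; backward maps gradients onto the sphere's
## tangent space.
.l2Forward <- function(x, eps = 1e-12) {
    nrm <- pmax(sqrt(rowSums(x^2)), eps)
    list(y = x / nrm, nrm = nrm)
}

.l2Backward <- function(dY, cache) {
    y <- cache$y
    (dY - y * rowSums(dY * y)) / cache$nrm
}

## Kaiming-uniform initialization (fan_in scaling), matching common practice
## for conv/dense layers with piecewise-linear-ish activations.
.initMat <- function(nin, nout) {
    bound <- sqrt(6 / nin)
    matrix(stats::runif(nin * nout, -bound, bound), nin, nout)
}

.adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

## fused in-place update: params and the moment buffers in `state` are
## modified by reference (the training loop owns them exclusively)
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    .adamStepInplace(params, grads[names(params)], state$m, state$v,
                     lr, beta1, beta2,
                     1 - beta1^state$t, 1 - beta2^state$t, eps)
    list(params = params, state = state)
}
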