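# Temporal convolutional network: dilated causal convolutions in residual
# blocks with a dense linear head. Implemented directly on BLAS matrix
# multiplies: window signals are stacked into a (T*N) x C matrix (row
# t + (i-1)*T) and a causal convolution becomes a sum over kernel taps of
# time-shifted GEMMs. Backpropagation is derived by hand below; the
# training loop lives in train.R.

#' TCN architecture configuration
#'
#' @param filters convolution filters per layer (default 64).
#' @param n_dilations number of exponentially dilated convolution layers
#'   (default 5; dilations `dilation_base^(0 .. n-1)`).
#' @param kernel convolution kernel size in samples (default 3).
#' @param residual_blocks number of residual blocks the dilated layers are
#'   distributed over (default 2); with an odd layer count earlier blocks
#'   take the extra layer (5 layers split 3 + 2).
#' @param dilation_base base of the exponential dilation schedule
#'   (default 2).
#' @return a `tcn_config` list.
#' @export
tcn_config <- function(filters = 64L, n_dilations = 5L, kernel = 3L,
                       residual_blocks = 2L, dilation_base = 2L) {
  assert_scalar_number(filters, "filters", lo = 1)
  assert_scalar_number(n_dilations, "n_dilations", lo = 1)
  assert_scalar_number(kernel, "kernel", lo = 1)
  assert_scalar_number(residual_blocks, "residual_blocks", lo = 1)
  assert_scalar_number(dilation_base, "dilation_base", lo = 2)
  if (residual_blocks > n_dilations)
    stop("cannot have more residual blocks than dilated layers", call. = FALSE)
  structure(list(filters = as.integer(filters),
                 n_dilations = as.integer(n_dilations),
                 kernel = as.integer(kernel),
                 residual_blocks = as.integer(residual_blocks),
                 dilation_base = as.integer(dilation_base)),
            class = "tcn_config")
}

#' Receptive field of the dilated causal stack
#'
#' With kernel size `k` and `n` exponentially dilated layers (base 2) the
#' causal receptive field is `1 + (k - 1) * (2^n - 1)`; for a general
#' dilation base it is one plus `(k - 1)` times the sum of the dilations.
#'
#' @param kernel kernel size (samples), at least 1.
#' @param n_dilations number of dilated layers, at least 1.
#' @param dilation_base dilation base (default 2).
#' @return the receptive field in samples.
#' @examples
#' receptive_field(3, 5)  # 63
#' receptive_field(1, 8)  # 1
#' @export
receptive_field <- function(kernel, n_dilations, dilation_base = 2) {
  assert_scalar_number(kernel, "kernel", lo = 1)
  assert_scalar_number(n_dilations, "n_dilations", lo = 1)
  1 + (kernel - 1) * sum(dilation_base^(0:(n_dilations - 1)))
}

# Split n_dilations consecutive layers over n_blocks, earlier blocks taking
# the extra layers: 5 over 2 -> c(3, 2).
dilation_allocation <- function(n_dilations, n_blocks) {
  base <- n_dilations %/% n_blocks
  sizes <- rep(base, n_blocks)
  extra <- n_dilations %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  sizes
}

#' Build an untrained TCN
#'
#' Assembles the residual-block architecture: dilated causal convolutions
#' (ReLU) distributed over the blocks, an identity skip connection when the
#' channel counts match and a 1x1 convolution otherwise (only the first
#' block changes the channel count), ReLU after each residual addition, and
#' a dense linear head on the features of the last time step producing one
#' scalar per window. Weights use He initialization.
#'
#' @param config a [tcn_config()].
#' @param in_channels input channels (default 4, the RMP distances).
#' @param seed integer seed for the weight initialization.
#' @return a `tcn_model` with `$config`, `$arch` (dilations per block,
#'   skip types) and `$params` (weight tensors).
#' @export
build_tcn <- function(config = tcn_config(), in_channels = 4L, seed = NULL) {
  stopifnot(inherits(config, "tcn_config"))
  K <- config$kernel
  Fn <- config$filters
  dil <- config$dilation_base^(0:(config$n_dilations - 1L))
  sizes <- dilation_allocation(config$n_dilations, config$residual_blocks)
  params <- with_local_seed(seed, {
    he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                     nin, nout)
    blocks <- list()
    c_in <- in_channels
    di <- 1L
    arch <- list()
    for (bi in seq_along(sizes)) {
      convs <- list()
      dils <- integer(0)
      block_in <- c_in
      for (j in seq_len(sizes[bi])) {
        # He fan-in counts all K taps of the c_in input channels
        convs[[j]] <- list(
          W = lapply(seq_len(K), function(k)
            matrix(rnorm(c_in * Fn, 0, sqrt(2 / (c_in * K))), c_in, Fn)),
          b = numeric(Fn))
        dils <- c(dils, dil[di])
        di <- di + 1L
        c_in <- Fn
      }
      skip <- if (block_in != Fn)
        list(W = he(block_in, Fn), b = numeric(Fn)) else NULL
      blocks[[bi]] <- list(convs = convs, skip = skip)
      arch[[bi]] <- list(dilations = dils, has_skip = block_in != Fn)
    }
    list(blocks = blocks,
         head = list(W = matrix(rnorm(Fn, 0, sqrt(1 / Fn)), Fn, 1), b = 0),
         arch = arch)
  })
  arch <- params$arch
  params$arch <- NULL
  structure(list(config = config, in_channels = as.integer(in_channels),
                 arch = arch, params = params),
            class = "tcn_model")
}

#' @export
print.tcn_model <- function(x, ...) {
  cat(sprintf("<tcn_model> %d filters, %d dilated layers in %d residual block(s), kernel %d, receptive field %d\n",
              x$config$filters, x$config$n_dilations,
              x$config$residual_blocks, x$config$kernel,
              receptive_field(x$config$kernel, x$config$n_dilations,
                              x$config$dilation_base)))
  invisible(x)
}

# Zero-padded causal time shift by `o` samples within each length-T block of
# rows: out[t] = m[t - o] for t > o, else 0.
shift_fwd <- function(m, o, T_len) {
  if (o == 0L) return(m)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  tt <- rep_len(seq_len(T_len), n)
  sel <- which(tt > o)
  out[sel, ] <- m[sel - o, , drop = FALSE]
  out
}

# Adjoint of shift_fwd: out[t] = m[t + o] for t <= T - o, else 0.
shift_adj <- function(m, o, T_len) {
  if (o == 0L) return(m)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  tt <- rep_len(seq_len(T_len), n)
  sel <- which(tt <= T_len - o)
  out[sel, ] <- m[sel + o, , drop = FALSE]
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass. x: (T*N) x C matrix. Returns N predictions; with
# cache = TRUE also every intermediate needed by tcn_backward().
tcn_forward <- function(model, x, T_len, cache = FALSE) {
  K <- model$config$kernel
  n <- nrow(x) %/% T_len
  H <- x
  bcaches <- if (cache) vector("list", length(model$params$blocks)) else NULL
  for (bi in seq_along(model$params$blocks)) {
    blk <- model$params$blocks[[bi]]
    dils <- model$arch[[bi]]$dilations
    binput <- H
    G <- H
    ccaches <- if (cache) vector("list", length(blk$convs)) else NULL
    for (j in seq_along(blk$convs)) {
      cv <- blk$convs[[j]]
      d <- dils[j]
      Z <- matrix(cv$b, nrow(G), length(cv$b), byrow = TRUE)
      for (k in seq_len(K))
        Z <- Z + shift_fwd(G, (K - k) * d, T_len) %*% cv$W[[k]]
      if (cache) ccaches[[j]] <- list(input = G, Z = Z)
      G <- relu(Z)
    }
    S <- if (model$arch[[bi]]$has_skip)
      sweep(binput %*% blk$skip$W, 2, blk$skip$b, "+") else binput
    R <- G + S
    H <- relu(R)
    if (cache) bcaches[[bi]] <- list(binput = binput, convs = ccaches, R = R)
  }
  idx_last <- seq.int(T_len, by = T_len, length.out = n)
  feats <- H[idx_last, , drop = FALSE]
  pred <- drop(feats %*% model$params$head$W) + model$params$head$b
  if (!cache) return(list(pred = pred))
  list(pred = pred, feats = feats, idx_last = idx_last, bcaches = bcaches,
       n = n)
}

# Backward pass: gradient of sum_i dpred[i] * pred[i] with respect to every
# parameter (dpred is the loss gradient at the output). Returns a structure
# parallel to model$params.
tcn_backward <- function(model, fw, dpred, T_len) {
  K <- model$config$kernel
  gblocks <- vector("list", length(model$params$blocks))
  dW_head <- crossprod(fw$feats, dpred)
  db_head <- sum(dpred)
  dH <- matrix(0, T_len * fw$n, ncol(fw$feats))
  dH[fw$idx_last, ] <- dpred %o% drop(model$params$head$W)
  for (bi in rev(seq_along(model$params$blocks))) {
    blk <- model$params$blocks[[bi]]
    bc <- fw$bcaches[[bi]]
    dils <- model$arch[[bi]]$dilations
    dR <- dH * (bc$R > 0)
    dS <- dR
    if (model$arch[[bi]]$has_skip) {
      gskip <- list(W = crossprod(bc$binput, dS), b = colSums(dS))
      dbinput_skip <- tcrossprod(dS, blk$skip$W)
    } else {
      gskip <- NULL
      dbinput_skip <- dS
    }
    dG <- dR
    gconvs <- vector("list", length(blk$convs))
    for (j in rev(seq_along(blk$convs))) {
      cv <- blk$convs[[j]]
      cc <- bc$convs[[j]]
      d <- dils[j]
      dZ <- dG * (cc$Z > 0)
      gW <- vector("list", K)
      dInput <- matrix(0, nrow(dZ), ncol(cc$input))
      for (k in seq_len(K)) {
        o <- (K - k) * d
        gW[[k]] <- crossprod(shift_fwd(cc$input, o, T_len), dZ)
        dInput <- dInput + shift_adj(dZ %*% t(cv$W[[k]]), o, T_len)
      }
      gconvs[[j]] <- list(W = gW, b = colSums(dZ))
      dG <- dInput
    }
    dH <- dG + dbinput_skip
    gblocks[[bi]] <- list(convs = gconvs, skip = gskip)
  }
  list(blocks = gblocks, head = list(W = dW_head, b = db_head))
}
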