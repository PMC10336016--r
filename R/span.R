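# Stacked polynomial attention network (SPAN).
#
# One polynomial attention sub-network maps a batch Z (samples x d_in) to an
# attended representation of width d_out:
#
#   X_1 = Z W' + b_Z                       (affine projection)
#   X_k = X_{k-1} . X_1   (k = 2..n)       (elementwise monomials, X_k = X_1^k)
#   M_A = softmax_features( sum_k X_k w_k' + b )
#   Zhat = act( X_1 . M_A )
#
# "." is the Hadamard product: all operands share the width d_out, and the
# monomial recurrence builds componentwise powers of the projected input.
# The softmax runs over the feature axis, one attention distribution per
# sample.  A SPAN stack chains two sub-networks, the first with identity
# activation and the second with SELU.

#' Parameters of one polynomial attention sub-network
#'
#' @param W_Z projection matrix (d_out x d_in).
#' @param b_Z projection bias (length d_out).
#' @param w list of n per-degree attention weight matrices (d_out x d_out).
#' @param b attention bias (length d_out).
#' @return object of class \code{poly_attention_params}.
#' @export
poly_attention_params <- function(W_Z, b_Z, w, b) {
  W_Z <- as.matrix(W_Z)
  d_out <- nrow(W_Z)
  stopifnot(length(b_Z) == d_out, length(b) == d_out, length(w) >= 1L)
  for (wk in w) {
    wk <- as.matrix(wk)
    if (!all(dim(wk) == c(d_out, d_out))) {
      stop("attention weight matrices must be d_out x d_out", call. = FALSE)
    }
  }
  structure(list(W_Z = W_Z, b_Z = as.numeric(b_Z),
                 w = lapply(w, as.matrix), b = as.numeric(b)),
            class = "poly_attention_params")
}

#' Parameters of a two-sub-network SPAN stack
#'
#' @param subnet1,subnet2 [poly_attention_params()]; the second consumes the
#'   first's output and applies SELU.
#' @export
span_stack_params <- function(subnet1, subnet2) {
  if (ncol(subnet2$W_Z) != nrow(subnet1$W_Z)) {
    stop("subnet2 input width must equal subnet1 output width", call. = FALSE)
  }
  structure(list(subnet1 = subnet1, subnet2 = subnet2), class = "span_stack_params")
}

#' Affine projection of a feature batch
#'
#' @param Z batch matrix (samples x d_in).
#' @param W_Z projection matrix (d_out x d_in).
#' @param b_Z bias (length d_out).
#' @return X_1 = Z W_Z' + b_Z, samples x d_out.
#' @export
affine_project <- function(Z, W_Z, b_Z) {
  Z <- rbind_matrix(Z)
  if (ncol(Z) != ncol(W_Z)) {
    stop(sprintf("shape mismatch: input width %d, projection expects %d",
                 ncol(Z), ncol(W_Z)), call. = FALSE)
  }
  sweep(Z %*% t(W_Z), 2L, b_Z, `+`)
}

rbind_matrix <- function(Z) {
  if (is.matrix(Z)) Z else matrix(Z, nrow = 1L)
}

#' Elementwise polynomial expansion
#'
#' Builds the monomial ladder X_k = X_{k-1} . X_1, so that X_k equals the
#' componentwise k-th power of X_1.
#'
#' @param X_1 batch matrix.
#' @param n polynomial degree (>= 1).
#' @return list of n matrices, X_1 .. X_n.
#' @export
polynomial_expand <- function(X_1, n) {
  if (n < 1) stop("polynomial degree must be >= 1", call. = FALSE)
  X_1 <- rbind_matrix(X_1)
  out <- vector("list", n)
  out[[1L]] <- X_1
  for (k in seq_len(n)[-1L]) out[[k]] <- out[[k - 1L]] * X_1
  out
}

#' Attention map over feature channels
#'
#' Logits are the bias plus the sum of the per-degree linear maps of the
#' monomials; the softmax runs over the feature axis so that each sample
#' carries one attention distribution across its channels.
#'
#' @param X_list list of monomial matrices from [polynomial_expand()].
#' @param w list of attention weight matrices, one per degree.
#' @param b attention bias.
#' @return attention map, rows summing to 1.
#' @export
attention_map <- function(X_list, w, b) {
  if (length(X_list) != length(w)) {
    stop("need one attention weight matrix per polynomial degree", call. = FALSE)
  }
  logits <- matrix(rep(b, each = nrow(X_list[[1L]])), nrow = nrow(X_list[[1L]]))
  for (k in seq_along(w)) logits <- logits + X_list[[k]] %*% t(w[[k]])
  softmax_rows(logits)
}

#' Forward pass of one polynomial attention sub-network
#'
#' @param Z batch matrix.
#' @param params [poly_attention_params()].
#' @param degree polynomial degree n.
#' @param activation "identity" or "selu".
#' @param keep_cache keep intermediates for backpropagation.
#' @return attended batch, or (with \code{keep_cache}) a list
#'   \code{(out, cache)}.
#' @export
span_subnet_forward <- function(Z, params, degree = length(params$w),
                                activation = c("identity", "selu"),
                                keep_cache = FALSE) {
  activation <- match.arg(activation)
  Z <- rbind_matrix(Z)
  X1 <- affine_project(Z, params$W_Z, params$b_Z)
  X_list <- polynomial_expand(X1, degree)
  M <- attention_map(X_list, params$w, params$b)
  pre <- X1 * M
  out <- if (activation == "selu") selu(pre) else pre
  if (!keep_cache) return(out)
  list(out = out, cache = list(Z = Z, X_list = X_list, M = M, pre = pre,
                               activation = activation))
}

#' Forward pass of a SPAN stack (two sub-networks)
#'
#' The first sub-network uses the identity activation; the second applies
#' SELU to its attended output.
#'
#' @param Z batch matrix.
#' @param stack [span_stack_params()].
#' @param keep_cache keep intermediates for backpropagation.
#' @export
span_forward <- function(Z, stack, keep_cache = FALSE) {
  s1 <- span_subnet_forward(Z, stack$subnet1, activation = "identity",
                            keep_cache = keep_cache)
  h <- if (keep_cache) s1$out else s1
  s2 <- span_subnet_forward(h, stack$subnet2, activation = "selu",
                            keep_cache = keep_cache)
  if (!keep_cache) return(s2)
  list(out = s2$out, cache = list(s1 = s1$cache, s2 = s2$cache))
}

#' Forward pass of a SPAN block (SPAN stacks with dropout between them)
#'
#' Dropout uses the inverted convention (activations rescaled by
#' 1/(1-rate) at training time), so evaluation is deterministic with no
#' rescaling.
#'
#' @param Z batch matrix.
#' @param blocks list of [span_stack_params()].
#' @param dropout_rate dropout probability in \[0, 1).
#' @param training apply dropout (TRUE) or run deterministically (FALSE).
#' @param seed seed for the dropout masks.
#' @param keep_cache keep intermediates for backpropagation.
#' @export
span_block_forward <- function(Z, blocks, dropout_rate = 0, training = FALSE,
                               seed = 1L, keep_cache = FALSE) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  Z <- rbind_matrix(Z)
  caches <- vector("list", length(blocks))
  masks <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    s <- span_forward(Z, blocks[[i]], keep_cache = keep_cache)
    Z <- if (keep_cache) s$out else s
    if (keep_cache) caches[[i]] <- s$cache
    if (training && dropout_rate > 0) {
      mask <- with_seed(derive_seed(seed, paste0("dropout", i)), {
        matrix(stats::rbinom(length(Z), 1L, 1 - dropout_rate), nrow(Z), ncol(Z))
      }) / (1 - dropout_rate)
      Z <- Z * mask
      masks[[i]] <- mask
    }
  }
  if (!keep_cache) return(Z)
  list(out = Z, cache = list(stacks = caches, masks = masks))
}
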