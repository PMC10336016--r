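# Reverse-mode gradients, derived by hand layer by layer.
#
# Gradient objects mirror the parameter tree; every backward function takes
# the adjoint of its output and returns the adjoint of its input plus the
# parameter gradients for its own weights.

# One polynomial attention sub-network.
# Adjoint chain: activation -> Hadamard attention product -> softmax ->
# per-degree linear maps -> monomial ladder -> affine projection.
subnet_backward <- function(params, cache, d_out) {
  n <- length(params$w)
  X <- cache$X_list
  X1 <- X[[1L]]
  M <- cache$M

  d_pre <- if (cache$activation == "selu") d_out * selu_grad(cache$pre) else d_out
  dX1 <- d_pre * M
  dM <- d_pre * X1

  # softmax over the feature axis
  d_logits <- M * (dM - rowSums(dM * M))

  db <- colSums(d_logits)
  dw <- vector("list", n)
  a <- vector("list", n)  # adjoints of the monomials from the attention map
  for (k in seq_len(n)) {
    dw[[k]] <- t(d_logits) %*% X[[k]]
    a[[k]] <- d_logits %*% params$w[[k]]
  }
  # monomial ladder X_k = X_{k-1} . X_1
  if (n >= 2L) {
    for (k in n:2L) {
      a[[k - 1L]] <- a[[k - 1L]] + a[[k]] * X1
      dX1 <- dX1 + a[[k]] * X[[k - 1L]]
    }
  }
  dX1 <- dX1 + a[[1L]]

  dW_Z <- t(dX1) %*% cache$Z
  db_Z <- colSums(dX1)
  dZ <- dX1 %*% params$W_Z

  list(grads = list(W_Z = dW_Z, b_Z = db_Z, w = dw, b = db), dZ = dZ)
}

stack_backward <- function(stack, cache, d_out) {
  s2 <- subnet_backward(stack$subnet2, cache$s2, d_out)
  s1 <- subnet_backward(stack$subnet1, cache$s1, s2$dZ)
  list(grads = list(subnet1 = s1$grads, subnet2 = s2$grads), dZ = s1$dZ)
}

span_block_backward <- function(blocks, cache, d_out) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    if (!is.null(cache$masks[[i]])) d_out <- d_out * cache$masks[[i]]
    s <- stack_backward(blocks[[i]], cache$stacks[[i]], d_out)
    grads[[i]] <- s$grads
    d_out <- s$dZ
  }
  list(grads = grads, dZ = d_out)
}

mlp_block_backward <- function(blocks, cache, d_out) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    if (!is.null(cache$masks[[i]])) d_out <- d_out * cache$masks[[i]]
    A <- cache$layers[[i]]$A
    dA <- d_out * selu_grad(A)
    grads[[i]] <- list(W = t(dA) %*% cache$layers[[i]]$Z, b = colSums(dA))
    d_out <- dA %*% blocks[[i]]$W
  }
  list(grads = grads, dZ = d_out)
}

branch_backward <- function(blocks, cache, d_out, config) {
  if (config$encoder == "span") span_block_backward(blocks, cache, d_out)
  else mlp_block_backward(blocks, cache, d_out)
}

# AED gate: tau_i = G[i, argmax_i]; only the pooled unit receives gradient.
aed_backward <- function(params, cache, d_tau) {
  G <- cache$G
  if (cache$per_feature) {
    dG <- d_tau
  } else {
    dG <- matrix(0, nrow(G), ncol(G))
    dG[cbind(seq_len(nrow(G)), cache$argmax)] <- d_tau
  }
  dA <- dG * G * (1 - G)
  dW <- t(dA) %*% cache$Hd
  db <- colSums(dA)
  dHd <- dA %*% params$W
  dHr <- -dHd * cache$Hd           # Hd = exp(-Hr)
  dH1 <- dHr * (cache$H1 > 0)      # rectifier
  dU <- t(dH1) %*% cache$I
  dI <- dH1 %*% params$U
  list(grads = list(U = dU, W = dW, b = db), dI = dI)
}

#' Gradients of the two heads' pre-activations w.r.t. all parameters
#'
#' Backpropagates the adjoints of the classification logit and of the
#' hazard score through the head, the fully connected stack, the fusion
#' step and both encoder branches.
#'
#' @param params model parameters.
#' @param cache cache from \code{model_forward(..., keep_cache = TRUE)}.
#' @param d_logit adjoint of the classification logit (length n).
#' @param d_risk adjoint of the hazard score (length n).
#' @return gradient tree mirroring \code{params}.
#' @keywords internal
model_backward <- function(params, cache, d_logit, d_risk) {
  config <- params$config
  H <- cache$H
  d_logit <- matrix(d_logit, ncol = 1L)
  d_risk <- matrix(d_risk, ncol = 1L)

  g <- list(config = NULL)
  g$W_cl <- t(d_logit) %*% H
  g$b_cl <- sum(d_logit)
  g$W_hr <- t(d_risk) %*% H
  g$b_hr <- sum(d_risk)
  dH <- d_logit %*% params$W_cl + d_risk %*% params$W_hr

  g$fc <- vector("list", length(params$fc))
  for (i in rev(seq_along(params$fc))) {
    A <- cache$fc[[i]]$A
    dA <- dH * selu_grad(A)
    g$fc[[i]] <- list(W = t(dA) %*% cache$fc[[i]]$H_in, b = colSums(dA))
    dH <- dA %*% params$fc[[i]]$W
  }
  d_fused <- dH

  dI_c <- NULL; dI_r <- NULL
  if (config$fusion == "aed") {
    tau <- if (config$per_feature_tau) cache$gate$G else
      cache$gate$G[cbind(seq_len(nrow(cache$gate$G)), cache$gate$argmax)]
    if (config$per_feature_tau) {
      dI_c <- d_fused * tau
      dI_r <- d_fused * (1 - tau)
      d_tau <- d_fused * (cache$I_c - cache$I_r)
    } else {
      dI_c <- d_fused * tau
      dI_r <- d_fused * (1 - tau)
      d_tau <- rowSums(d_fused * (cache$I_c - cache$I_r))
    }
    gb <- aed_backward(params$aed, cache$gate, d_tau)
    g$aed <- gb$grads
    dI_c <- dI_c + gb$dI
  } else if (config$fusion == "concat") {
    d_c <- ncol(cache$I_c)
    dI_c <- d_fused[, seq_len(d_c), drop = FALSE]
    dI_r <- d_fused[, -seq_len(d_c), drop = FALSE]
  } else if (config$fusion == "clinical_only") {
    dI_c <- d_fused
  } else {
    dI_r <- d_fused
  }

  if (!is.null(dI_c)) {
    g$clinical_blocks <- branch_backward(params$clinical_blocks, cache$enc_c,
                                         dI_c, config)$grads
  }
  if (!is.null(dI_r)) {
    g$radiomics_blocks <- branch_backward(params$radiomics_blocks, cache$enc_r,
                                          dI_r, config)$grads
  }
  g
}

# ---- parameter tree <-> flat vector ------------------------------------

numeric_leaves <- function(x) {
  if (is.numeric(x)) return(list(x))
  if (is.list(x)) {
    out <- list()
    for (nm in setdiff(names(x) %||% seq_along(x), "config")) {
      if (is.null(x[[nm]])) next
      out <- c(out, numeric_leaves(x[[nm]]))
    }
    return(out)
  }
  list()
}

params_to_vec <- function(params) {
  unlist(lapply(numeric_leaves(params), as.numeric), use.names = FALSE)
}

vec_to_params <- function(vec, template) {
  i <- 0L
  fill <- function(x) {
    if (is.numeric(x)) {
      k <- length(x)
      out <- vec[(i + 1L):(i + k)]
      i <<- i + k
      if (is.matrix(x)) dim(out) <- dim(x)
      return(out)
    }
    if (is.list(x)) {
      for (nm in setdiff(names(x) %||% seq_along(x), "config")) {
        if (is.null(x[[nm]])) next
        x[[nm]] <- fill(x[[nm]])
      }
      return(x)
    }
    x
  }
  out <- fill(template)
  stopifnot(i == length(vec))
  out
}

# Mask vector zeroing off-diagonal attention-weight gradients when the
# diagonal-only variant is configured.
grad_mask_vec <- function(params) {
  if (!isTRUE(params$config$diag_attention) || params$config$encoder != "span") {
    return(NULL)
  }
  mask <- params
  one_like <- function(x) {
    if (is.numeric(x)) { x[] <- 1; return(x) }
    x
  }
  mask_subnet <- function(sn) {
    sn$W_Z[] <- 1; sn$b_Z[] <- 1; sn$b[] <- 1
    sn$w <- lapply(sn$w, function(m) diag(nrow(m)))
    sn
  }
  walk <- function(x) {
    if (inherits(x, "poly_attention_params")) return(mask_subnet(x))
    if (is.list(x)) {
      for (nm in setdiff(names(x) %||% seq_along(x), "config")) {
        if (is.null(x[[nm]])) next
        x[[nm]] <- walk(x[[nm]])
      }
      return(x)
    }
    one_like(x)
  }
  params_to_vec(walk(mask))
}
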