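# Full two-branch forward pass.

mlp_block_forward <- function(Z, blocks, dropout_rate = 0, training = FALSE,
                              seed = 1L, keep_cache = FALSE) {
  Z <- rbind_matrix(Z)
  caches <- vector("list", length(blocks))
  masks <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    A <- affine_project(Z, blocks[[i]]$W, blocks[[i]]$b)
    H <- selu(A)
    if (keep_cache) caches[[i]] <- list(Z = Z, A = A)
    Z <- H
    if (training && dropout_rate > 0) {
      mask <- with_seed(derive_seed(seed, paste0("dropout", i)), {
        matrix(stats::rbinom(length(Z), 1L, 1 - dropout_rate), nrow(Z), ncol(Z))
      }) / (1 - dropout_rate)
      Z <- Z * mask
      masks[[i]] <- mask
    }
  }
  if (!keep_cache) return(Z)
  list(out = Z, cache = list(layers = caches, masks = masks))
}

branch_forward <- function(Z, blocks, config, training, seed, keep_cache) {
  if (config$encoder == "span") {
    span_block_forward(Z, blocks, dropout_rate = config$dropout,
                       training = training, seed = seed, keep_cache = keep_cache)
  } else {
    mlp_block_forward(Z, blocks, dropout_rate = config$dropout,
                      training = training, seed = seed, keep_cache = keep_cache)
  }
}

#' Forward pass of the multimodal multitask model
#'
#' Encodes each modality with its branch, fuses the encodings according to
#' the configured fusion mode, passes the fused representation through the
#' fully connected head, and emits both task outputs from that shared
#' representation: the lMCI probability (sigmoid head) and the unbounded
#' log-relative hazard (linear head).
#'
#' @param clinical,radiomics design matrices (equal row counts); a branch
#'   unused by a unimodal configuration may be \code{NULL}.
#' @param params [init_params()] output.
#' @param training apply dropout.
#' @param seed dropout seed.
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with \code{p_lmci}, \code{risk}, \code{tau} (NULL unless
#'   AED fusion) and, when requested, \code{cache}.
#' @export
model_forward <- function(clinical, radiomics, params, training = FALSE,
                          seed = 1L, keep_cache = FALSE) {
  config <- params$config
  use_c <- config$fusion != "radiomics_only"
  use_r <- config$fusion != "clinical_only"
  if (use_c && use_r) {
    nc <- nrow(rbind_matrix(clinical)); nr <- nrow(rbind_matrix(radiomics))
    if (nc != nr) stop("clinical and radiomics row counts differ", call. = FALSE)
  }

  enc_c <- if (use_c) branch_forward(clinical, params$clinical_blocks, config,
                                     training, derive_seed(seed, "branch_c"), keep_cache)
  enc_r <- if (use_r) branch_forward(radiomics, params$radiomics_blocks, config,
                                     training, derive_seed(seed, "branch_r"), keep_cache)
  I_c <- if (use_c) { if (keep_cache) enc_c$out else enc_c }
  I_r <- if (use_r) { if (keep_cache) enc_r$out else enc_r }

  tau <- NULL; gate_cache <- NULL
  fused <- switch(config$fusion,
    aed = {
      g <- aed_factor(I_c, params$aed, per_feature = config$per_feature_tau,
                      keep_cache = TRUE)
      tau <- g$tau
      gate_cache <- g$cache
      if (config$per_feature_tau) tau * I_c + (1 - tau) * I_r
      else I_c * tau + I_r * (1 - tau)
    },
    concat = concat_fuse(I_c, I_r),
    clinical_only = I_c,
    radiomics_only = I_r
  )

  H <- fused
  fc_cache <- vector("list", length(params$fc))
  for (i in seq_along(params$fc)) {
    A <- affine_project(H, params$fc[[i]]$W, params$fc[[i]]$b)
    if (keep_cache) fc_cache[[i]] <- list(H_in = H, A = A)
    H <- selu(A)
  }
  logit_cl <- drop(affine_project(H, params$W_cl, params$b_cl))
  risk <- drop(affine_project(H, params$W_hr, params$b_hr))
  p <- sigmoid(logit_cl)

  out <- list(p_lmci = p, risk = risk, tau = tau)
  if (keep_cache) {
    out$cache <- list(enc_c = if (use_c) enc_c$cache, enc_r = if (use_r) enc_r$cache,
                      I_c = I_c, I_r = I_r, gate = gate_cache, fused = fused,
                      fc = fc_cache, H = H, logit_cl = logit_cl)
  }
  out
}
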