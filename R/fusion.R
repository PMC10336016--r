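# Two-branch multimodal multitask model.
#
# Each modality is encoded by a SPAN block (or a plain-MLP baseline for
# ablations), the encodings are mixed -- by the learned AED gate, by
# concatenation, or bypassed in unimodal configurations -- and a stack of
# fully connected SELU layers feeds two heads that share the fused
# representation: a sigmoid stage classifier and a linear log-relative
# hazard score.

#' Model configuration
#'
#' @param fusion one of "aed", "concat", "clinical_only", "radiomics_only".
#' @param encoder "span" or "mlp" (a plain multilayer perceptron baseline
#'   used for encoder ablations).
#' @param degree polynomial degree n of each SPAN sub-network.
#' @param widths encoder widths, one per SPAN block in a branch.
#' @param widths_clinical,widths_radiomics optional per-branch overrides.
#' @param dropout dropout rate between blocks, in \[0, 1).
#' @param fc_widths widths of the fully connected head layers.
#' @param gate_hidden hidden width of the AED gate; default the branch
#'   output width.
#' @param per_feature_tau if TRUE the gate skips max-pooling and yields one
#'   mixing factor per feature channel (non-default variant).
#' @param diag_attention constrain the per-degree attention weight matrices
#'   to be diagonal.
#' @return list of class \code{model_config}.
#' @export
model_config <- function(fusion = c("aed", "concat", "clinical_only", "radiomics_only"),
                         encoder = c("span", "mlp"),
                         degree = 3L,
                         widths = c(16L, 16L),
                         widths_clinical = NULL,
                         widths_radiomics = NULL,
                         dropout = 0.5,
                         fc_widths = c(16L, 8L),
                         gate_hidden = NULL,
                         per_feature_tau = FALSE,
                         diag_attention = FALSE) {
  fusion <- match.arg(fusion)
  encoder <- match.arg(encoder)
  if (degree < 1L) stop_config("degree", "must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_config("dropout", "must lie in [0, 1)")
  wc <- widths_clinical %||% widths
  wr <- widths_radiomics %||% widths
  if (fusion == "aed" && utils::tail(wc, 1L) != utils::tail(wr, 1L)) {
    stop_config("widths", "AED fusion requires equal branch output widths")
  }
  structure(list(
    fusion = fusion, encoder = encoder, degree = as.integer(degree),
    widths_clinical = as.integer(wc), widths_radiomics = as.integer(wr),
    dropout = dropout, fc_widths = as.integer(fc_widths),
    gate_hidden = gate_hidden, per_feature_tau = per_feature_tau,
    diag_attention = diag_attention
  ), class = "model_config")
}

# Variance-preserving initialization.  `in_scale` is the expected
# per-channel magnitude of the matrix input; the uniform limit is chosen
# so the pre-activations come out at unit-order magnitude regardless of
# how much the preceding layers attenuated the signal.
X1_TARGET <- 1 / sqrt(3)  # sd of U(-1/sqrt(f), 1/sqrt(f)) x unit input

init_mat <- function(nr, nc, in_scale = 1) {
  lim <- 1 / (in_scale * sqrt(nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Attention weights start at zero so the initial map is exactly uniform
# (softmax of zeros) and each sub-network begins as a well-scaled linear
# projection; attention structure is then learned from data.  A random
# attention init concentrates the softmax on few channels and gates most
# of the representation away before training starts.  The attended
# product X1 . M attenuates the representation by the uniform-map factor
# 1/d_out, which the next layer's init gain undoes.
init_subnet <- function(d_in, d_out, degree, diag_attention, in_scale = 1) {
  w <- lapply(seq_len(degree), function(k) matrix(0, d_out, d_out))
  poly_attention_params(W_Z = init_mat(d_out, d_in, in_scale),
                        b_Z = numeric(d_out),
                        w = w, b = numeric(d_out))
}

subnet_out_scale <- function(d_out) X1_TARGET / d_out

init_branch <- function(d_in, widths, config) {
  blocks <- vector("list", length(widths))
  d <- d_in
  sc <- 1
  for (i in seq_along(widths)) {
    if (config$encoder == "span") {
      blocks[[i]] <- span_stack_params(
        init_subnet(d, widths[i], config$degree, config$diag_attention, sc),
        init_subnet(widths[i], widths[i], config$degree, config$diag_attention,
                    subnet_out_scale(widths[i]))
      )
      sc <- subnet_out_scale(widths[i])
    } else {
      blocks[[i]] <- structure(list(W = init_mat(widths[i], d, sc), b = numeric(widths[i])),
                               class = "mlp_layer_params")
      sc <- 1
    }
    d <- widths[i]
  }
  attr(blocks, "out_scale") <- sc
  blocks
}

#' Initialize model parameters
#'
#' Scaled uniform fan-in initialization; the same seed yields identical
#' parameters.
#'
#' @param config a [model_config()].
#' @param d_clinical,d_radiomics input widths of the two feature blocks.
#' @param seed integer seed.
#' @return object of class \code{model_params}.
#' @export
init_params <- function(config, d_clinical, d_radiomics, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(derive_seed(seed, "init"), {
    use_c <- config$fusion != "radiomics_only"
    use_r <- config$fusion != "clinical_only"
    clinical_blocks <- if (use_c) init_branch(d_clinical, config$widths_clinical, config)
    radiomics_blocks <- if (use_r) init_branch(d_radiomics, config$widths_radiomics, config)
    d_c <- utils::tail(config$widths_clinical, 1L)
    d_r <- utils::tail(config$widths_radiomics, 1L)
    fused_width <- switch(config$fusion,
      aed = d_c, concat = d_c + d_r, clinical_only = d_c, radiomics_only = d_r
    )
    enc_scale <- if (use_c) attr(clinical_blocks, "out_scale")
                 else attr(radiomics_blocks, "out_scale")
    aed <- NULL
    if (config$fusion == "aed") {
      g <- config$gate_hidden %||% d_c
      g_out <- if (config$per_feature_tau) d_c else g
      aed <- structure(list(U = init_mat(g, d_c, enc_scale),
                            W = init_mat(g_out, g), b = numeric(g_out)),
                       class = "aed_params")
    }
    fc <- list()
    d <- fused_width
    sc <- enc_scale
    for (i in seq_along(config$fc_widths)) {
      fc[[i]] <- list(W = init_mat(config$fc_widths[i], d, sc),
                      b = numeric(config$fc_widths[i]))
      d <- config$fc_widths[i]
      sc <- 1
    }
    structure(list(
      config = config,
      clinical_blocks = clinical_blocks,
      radiomics_blocks = radiomics_blocks,
      aed = aed, fc = fc,
      W_cl = init_mat(1L, d, sc), b_cl = 0,
      W_hr = init_mat(1L, d, sc), b_hr = 0
    ), class = "model_params")
  })
}

#' Adaptive exponential decay gate
#'
#' Computes the per-sample mixing factor
#' \eqn{\tau = \mathrm{maxpool}(S(W_\tau e^{-\max(0, U_\tau I_c)} + b_\tau))}
#' from the encoded clinical batch: a rectifier, an exponential decay (so
#' the hidden units lie in (0, 1]), an affine map, a sigmoid, and a max
#' over gate units giving one scalar per sample, strictly inside (0, 1).
#'
#' @param I_clinical encoded clinical batch (samples x width).
#' @param params AED parameters (\code{U}, \code{W}, \code{b}).
#' @param per_feature skip pooling and return one factor per channel.
#' @param keep_cache keep intermediates for backpropagation.
#' @return numeric vector of gate values (or matrix when
#'   \code{per_feature}).
#' @export
aed_factor <- function(I_clinical, params, per_feature = FALSE, keep_cache = FALSE) {
  I_clinical <- rbind_matrix(I_clinical)
  if (ncol(I_clinical) != ncol(params$U)) {
    stop("AED gate width mismatch", call. = FALSE)
  }
  H1 <- I_clinical %*% t(params$U)          # pre-rectifier
  Hr <- pmax(H1, 0)
  Hd <- exp(-Hr)                            # in (0, 1]
  G <- sigmoid(sweep(Hd %*% t(params$W), 2L, params$b, `+`))
  if (per_feature) {
    tau <- G
    argmax <- NULL
  } else {
    argmax <- max.col(G, ties.method = "first")
    tau <- G[cbind(seq_len(nrow(G)), argmax)]
  }
  if (!keep_cache) return(tau)
  list(tau = tau, cache = list(I = I_clinical, H1 = H1, Hd = Hd, G = G,
                               argmax = argmax, per_feature = per_feature))
}

#' Fuse two modality encodings with the AED gate
#'
#' Per-sample convex combination
#' \eqn{I_{fused} = \tau I_{clinical} + (1 - \tau) I_{radiomic}}; each
#' fused coordinate therefore lies between the two branch values.
#'
#' @param I_clinical,I_radiomic encoded batches of equal width.
#' @param params AED parameters.
#' @param per_feature use a per-channel gate.
#' @return list with \code{fused} and \code{tau}.
#' @export
aed_fuse <- function(I_clinical, I_radiomic, params, per_feature = FALSE) {
  I_clinical <- rbind_matrix(I_clinical)
  I_radiomic <- rbind_matrix(I_radiomic)
  if (!all(dim(I_clinical) == dim(I_radiomic))) {
    stop("AED fusion requires equal branch widths", call. = FALSE)
  }
  tau <- aed_factor(I_clinical, params, per_feature = per_feature)
  fused <- if (per_feature) tau * I_clinical + (1 - tau) * I_radiomic
           else I_clinical * tau + I_radiomic * (1 - tau)
  list(fused = fused, tau = tau)
}

#' Concatenation fusion (ablation)
#'
#' @param I_clinical,I_radiomic encoded batches; widths add, clinical
#'   first.
#' @export
concat_fuse <- function(I_clinical, I_radiomic) {
  cbind(rbind_matrix(I_clinical), rbind_matrix(I_radiomic))
}
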