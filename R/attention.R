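# Forward-pass attention operators on feature maps.
#
# Feature maps are 4-D numeric arrays with dimensions
# (batch, channels, height, width). All operators are shape-preserving.
# Learned weights are plain numeric lists created by seeded initializers,
# so forwards are deterministic and inspectable without any deep-learning
# runtime.

check_feature_map <- function(x) {
  if (!(is.array(x) && length(dim(x)) == 4L))
    stop_bovi("feature map must be a 4-D (batch, channels, height, width) array",
              class = "attention_error")
  if (any(!is.finite(x)))
    stop_bovi("feature map contains non-finite values", class = "attention_error")
  invisible(dim(x))
}

#' Count learned parameters in a weight list
#'
#' @param weights Possibly nested list of numeric arrays (or NULL).
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(weights) {
  if (is.null(weights)) return(0L)
  sum(vapply(rapply(weights, length, how = "unlist"), identity, numeric(1)))
}

#' Attention block configuration
#'
#' @param channels Number of feature channels.
#' @param num_heads Attention heads (channels must be divisible by it).
#' @param lambda SimAM energy regularizer (> 0).
#' @param reduction Channel reduction for coordinate attention.
#' @param insertion_point Where the block sits in a detector: "backbone"
#'   (CASimAM), "p3_head_layer15" (DRAMiTransformer after the C2f block on
#'   the P3 map at layer 15), or "pre_detect_head" (MHSA-C2f).
#' @param seed Seed for weight initialization.
#' @return List of class `block_config`.
#' @export
block_config <- function(channels = 64L, num_heads = 4L, lambda = 1e-4,
                         reduction = 8L,
                         insertion_point = c("backbone", "p3_head_layer15",
                                             "pre_detect_head"),
                         seed = 1L) {
  insertion_point <- match.arg(insertion_point)
  if (lambda <= 0) stop_bovi("lambda must be positive", class = "attention_error")
  if (channels %% num_heads != 0L)
    stop_bovi("channels must be divisible by num_heads", class = "attention_error")
  if (reduction > channels)
    stop_bovi("reduction cannot exceed the channel count", class = "attention_error")
  structure(list(channels = as.integer(channels), num_heads = as.integer(num_heads),
                 lambda = lambda, reduction = as.integer(reduction),
                 insertion_point = insertion_point, seed = as.integer(seed)),
            class = "block_config")
}

rand_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' SimAM: parameter-free pixel saliency gating
#'
#' For each channel, every pixel gets a closed-form energy from the channel
#' mean and variance; low-energy (more discriminative) pixels receive
#' higher gates through a sigmoid. With the minimal energy
#' e* = 4 (var + lambda) / ((x - mu)^2 + 2 var + 2 lambda), the gate is
#' sigmoid(1 / e*) = sigmoid((x - mu)^2 / (4 (var + lambda)) + 1/2) and the
#' output is x * gate. The operator introduces no learned parameters.
#'
#' @param x Feature map array (batch, channels, height, width) with
#'   height * width >= 2.
#' @param lambda Positive variance regularizer.
#' @return Gated feature map, same shape as `x`.
#' @export
simam_forward <- function(x, lambda = 1e-4) {
  dm <- check_feature_map(x)
  if (lambda <= 0) stop_bovi("lambda must be positive", class = "attention_error")
  if (dm[3] * dm[4] < 2L)
    stop_bovi("SimAM needs at least 2 spatial positions", class = "attention_error")
  n <- dm[3] * dm[4]
  out <- x
  for (b in seq_len(dm[1])) for (ch in seq_len(dm[2])) {
    v <- x[b, ch, , ]
    mu <- mean(v)
    var_ <- sum((v - mu)^2) / (n - 1)
    inv_energy <- (v - mu)^2 / (4 * (var_ + lambda)) + 0.5
    out[b, ch, , ] <- v * sigmoid(inv_energy)
  }
  out
}

#' Initialize coordinate-attention weights
#'
#' @param channels,reduction Channel count and reduction factor.
#' @param seed Initialization seed.
#' @return Weight list (shared squeeze projection plus per-direction
#'   expansion projections, all with biases).
#' @export
init_coord_attention <- function(channels, reduction = 8L, seed = 1L) {
  cr <- max(1L, channels %/% reduction)
  with_local_seed(seed, list(
    w1 = rand_mat(cr, channels), b1 = numeric(cr),
    wh = rand_mat(channels, cr), bh = numeric(channels),
    ww = rand_mat(channels, cr), bw = numeric(channels)))
}

#' Coordinate attention: direction-decomposed positional gating
#'
#' Features are average-pooled separately along the height and width axes,
#' squeezed through a shared projection, then expanded into per-row and
#' per-column sigmoid gates in (0, 1) that multiply the input. Encoding the
#' two directions separately lets the gate carry positional structure.
#'
#' @param x Feature map array (batch, channels, height, width).
#' @param reduction Channel reduction factor (<= channels).
#' @param weights Optional weights from [init_coord_attention()].
#' @param seed Seed used when `weights` is NULL.
#' @return Gated feature map, same shape as `x`.
#' @export
coord_attention_forward <- function(x, reduction = 8L, weights = NULL, seed = 1L) {
  dm <- check_feature_map(x)
  C <- dm[2]
  if (reduction > C)
    stop_bovi("reduction cannot exceed the channel count", class = "attention_error")
  if (is.null(weights)) weights <- init_coord_attention(C, reduction, seed)
  relu <- function(z) pmax(z, 0)
  out <- x
  for (b in seq_len(dm[1])) {
    xb <- x[b, , , , drop = FALSE]
    dim(xb) <- dm[2:4]
    pool_h <- apply(xb, c(1, 2), mean)  # C x H (pooled over width)
    pool_w <- apply(xb, c(1, 3), mean)  # C x W (pooled over height)
    sq_h <- relu(weights$w1 %*% pool_h + weights$b1)  # cr x H
    sq_w <- relu(weights$w1 %*% pool_w + weights$b1)  # cr x W
    gate_h <- sigmoid(weights$wh %*% sq_h + weights$bh)  # C x H
    gate_w <- sigmoid(weights$ww %*% sq_w + weights$bw)  # C x W
    for (ch in seq_len(C))
      out[b, ch, , ] <- xb[ch, , ] * outer(gate_h[ch, ], gate_w[ch, ])
  }
  out
}

#' CASimAM: SimAM followed by coordinate attention
#'
#' Composition in that order: SimAM first enhances per-pixel saliency
#' within each channel, then coordinate attention adds direction-decomposed
#' spatial structure. Intended insertion point: the detector backbone.
#'
#' @param x Feature map array.
#' @param config `block_config` (uses lambda, reduction, seed).
#' @param weights Optional coordinate-attention weights.
#' @return Feature map, same shape as `x`.
#' @export
casimam_forward <- function(x, config = block_config(), weights = NULL) {
  coord_attention_forward(simam_forward(x, config$lambda),
                          reduction = config$reduction,
                          weights = weights, seed = config$seed)
}

#' Initialize multi-head self-attention weights
#'
#' @param channels Feature channels.
#' @param num_heads Attention heads.
#' @param seed Initialization seed.
#' @return Weight list with Q/K/V projections and the output fusion.
#' @export
init_mhsa <- function(channels, num_heads = 4L, seed = 1L) {
  if (channels %% num_heads != 0L)
    stop_bovi("channels must be divisible by num_heads", class = "attention_error")
  with_local_seed(seed, list(
    wq = rand_mat(channels, channels), wk = rand_mat(channels, channels),
    wv = rand_mat(channels, channels), wo = rand_mat(channels, channels),
    bo = numeric(channels)))
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

#' Multi-head self-attention over spatial positions
#'
#' Spatial positions are flattened into a sequence; three linear
#' projections produce queries, keys and values, split across heads. Each
#' head applies scaled dot-product attention (rows of the attention matrix
#' sum to 1), head outputs are concatenated and fused by a final linear
#' transformation. Intended insertion point: before the detection head
#' (as the attention stage of an MHSA-C2f block).
#'
#' @param x Feature map array (batch, channels, height, width).
#' @param num_heads Number of heads (divides channels).
#' @param weights Optional weights from [init_mhsa()].
#' @param seed Seed used when `weights` is NULL.
#' @param return_attention If TRUE, also return the per-batch, per-head
#'   attention matrices.
#' @return Feature map of the input shape, or a list (out, attention).
#' @export
mhsa_forward <- function(x, num_heads = 4L, weights = NULL, seed = 1L,
                         return_attention = FALSE) {
  dm <- check_feature_map(x)
  C <- dm[2]; N <- dm[3] * dm[4]
  if (C %% num_heads != 0L)
    stop_bovi("channels must be divisible by num_heads", class = "attention_error")
  if (is.null(weights)) weights <- init_mhsa(C, num_heads, seed)
  dh <- C %/% num_heads
  out <- x
  attn_all <- list()
  for (b in seq_len(dm[1])) {
    X <- t(matrix(x[b, , , ], C, N))  # N x C
    Q <- X %*% weights$wq; K <- X %*% weights$wk; V <- X %*% weights$wv
    O <- matrix(0, N, C)
    attn_b <- list()
    for (h in seq_len(num_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh))
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      attn_b[[h]] <- A
    }
    Y <- O %*% weights$wo + matrix(weights$bo, N, C, byrow = TRUE)
    out[b, , , ] <- array(t(Y), dm[2:4])
    attn_all[[b]] <- attn_b
  }
  if (return_attention) list(out = out, attention = attn_all) else out
}

#' Initialize dual-branch reciprocal transformer weights
#'
#' @param channels Feature channels.
#' @param seed Initialization seed.
#' @return Weight list: spatial-attention branch, channel-attention branch,
#'   per-channel mixing gate logits, and a two-layer FFN.
#' @export
init_dramit <- function(channels, seed = 1L) {
  with_local_seed(seed, list(
    spatial = list(wq = rand_mat(channels, channels),
                   wk = rand_mat(channels, channels),
                   wv = rand_mat(channels, channels)),
    channel = list(wq = rand_mat(channels, channels),
                   wk = rand_mat(channels, channels),
                   wv = rand_mat(channels, channels)),
    gate_logit = numeric(channels),  # sigmoid(0) = 0.5: even mix at init
    ffn = list(w1 = rand_mat(2L * channels, channels), b1 = numeric(2L * channels),
               w2 = rand_mat(channels, 2L * channels), b2 = numeric(channels))))
}

#' Dual-branch reciprocal transformer block
#'
#' Two attention branches run in parallel on the input: a spatial branch
#' (scaled dot-product attention over flattened positions, approximating
#' global spatial modeling) and a channel branch (attention over the
#' channel dimension, capturing inter-channel dependencies). A learned
#' per-channel sigmoid gate mixes the branches, and a two-layer
#' feed-forward network with a residual connection produces the output.
#' Intended insertion point: layer 15, immediately after the C2f block on
#' the P3 feature map.
#'
#' @param x Feature map array (batch, channels, height, width).
#' @param config `block_config` (uses channels for validation and seed).
#' @param weights Optional weights from [init_dramit()]; set
#'   `weights$gate_logit` to large +/- values to force one branch.
#' @return Feature map, same shape as `x`.
#' @export
dramit_forward <- function(x, config = block_config(), weights = NULL) {
  dm <- check_feature_map(x)
  C <- dm[2]; N <- dm[3] * dm[4]
  if (is.null(weights)) weights <- init_dramit(C, config$seed)
  relu <- function(z) pmax(z, 0)
  g <- sigmoid(weights$gate_logit)  # length C
  out <- x
  for (b in seq_len(dm[1])) {
    X <- t(matrix(x[b, , , ], C, N))  # N x C
    # spatial branch: attention across positions
    Qs <- X %*% weights$spatial$wq; Ks <- X %*% weights$spatial$wk
    Vs <- X %*% weights$spatial$wv
    Ys <- softmax_rows(Qs %*% t(Ks) / sqrt(C)) %*% Vs
    # channel branch: attention across channels (transposed attention)
    Qc <- X %*% weights$channel$wq; Kc <- X %*% weights$channel$wk
    Vc <- X %*% weights$channel$wv
    Ac <- softmax_rows(t(Qc) %*% Kc / sqrt(N))  # C x C
    Yc <- Vc %*% t(Ac)
    M <- sweep(Ys, 2, g, `*`) + sweep(Yc, 2, 1 - g, `*`)
    FFN <- relu(M %*% t(weights$ffn$w1) +
                  matrix(weights$ffn$b1, N, 2L * C, byrow = TRUE)) %*%
      t(weights$ffn$w2) + matrix(weights$ffn$b2, N, C, byrow = TRUE)
    out[b, , , ] <- array(t(M + FFN), dm[2:4])
  }
  out
}

#' Detector insertion points for the three attention blocks
#'
#' @return Named list mapping block name to its insertion point in a
#'   YOLO-style pose detector.
#' @export
insertion_points <- function() {
  list(casimam = "backbone",
       dramit_transformer = "p3_head_layer15",
       mhsa_c2f = "pre_detect_head")
}

#' Export block configurations as a YAML fragment
#'
#' Writes the three blocks with their insertion points and default
#' hyperparameters in a form consumable by a detector-framework model file.
#'
#' @param path Output YAML path.
#' @param channels,num_heads,lambda,reduction Defaults recorded per block.
#' @return Invisibly, the configuration list.
#' @export
write_block_config <- function(path, channels = 64L, num_heads = 4L,
                               lambda = 1e-4, reduction = 8L) {
  cfg <- list(
    casimam = list(insertion_point = "backbone", channels = channels,
                   lambda = lambda, reduction = reduction),
    dramit_transformer = list(insertion_point = "p3_head_layer15",
                              channels = channels),
    mhsa_c2f = list(insertion_point = "pre_detect_head", channels = channels,
                    num_heads = num_heads))
  yaml::write_yaml(cfg, path)
  invisible(cfg)
}
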