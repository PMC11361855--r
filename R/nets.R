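# The three sub-models and the fusion head, in plain R matrix arithmetic.
#
# Forward passes keep the intermediate tensors needed by the hand-derived
# backward passes; parameters live in one flat named list so that the Adam
# update and the finite-difference gradient checks can treat every tensor
# uniformly.  The atom branch is a structure-enhanced transformer whose
# per-head attention probabilities are attenuated element-wise by the
# Strength matrices; the monomer branch is a stack of (optionally circular)
# 1D convolutions over the residue axis; the peptide branch is a pair of
# MLPs over descriptors and fingerprint bits.

LN_EPS <- 1e-5

#' Model configuration
#'
#' Collects every tunable dimension and rate of the three sub-models, the
#' fusion head, the auxiliary-loss weights and the optimizer.  Defaults are
#' desk-scale; all are overridable.
#'
#' @param d_model Atom-branch embedding width (divisible by `heads`).
#' @param heads Attention heads.
#' @param layers_per_block Encoder layers in each of the graph/conf blocks.
#' @param lambda_g Blend weight in `[0, 1]` applied to the graph block
#'   (the conf block gets `1 - lambda_g`).
#' @param ffn_width Feed-forward width inside each encoder layer.
#' @param dropout Dropout rate on hidden activations during training.
#' @param n_max Atom padding size (maximum heavy atoms, default 128).
#' @param conv_kind `"plain"` (zero-padded) or `"cyclic"` (circular over
#'   the occupied span) monomer convolution.
#' @param channels Output channels per monomer conv layer; all equal so
#'   per-layer outputs can be averaged for the layer loss.
#' @param kernel Odd convolution width.
#' @param max_len Monomer frame length (>= longest peptide).
#' @param desc_hidden,fp_hidden Hidden widths of the peptide-branch MLPs.
#' @param latent Width of each branch's output latent vector.
#' @param fusion_hidden Hidden width of the shared fusion layer.
#' @param gamma_sub,gamma_layer Auxiliary-loss weights (defaults 0.10 and
#'   0.05).
#' @param lr,batch,epochs,patience Adam learning rate, minibatch size,
#'   epoch budget and early-stopping patience (epochs without validation
#'   MAE improvement).
#' @return Object of class `pepperm_config`.
#' @export
pepperm_config <- function(d_model = 64, heads = 4, layers_per_block = 2,
                           lambda_g = 0.5, ffn_width = 128, dropout = 0,
                           n_max = 128, conv_kind = c("plain", "cyclic"),
                           channels = c(32, 32), kernel = 3, max_len = 16,
                           desc_hidden = 32, fp_hidden = 64, latent = 32,
                           fusion_hidden = 32, gamma_sub = 0.10,
                           gamma_layer = 0.05, lr = 1e-3, batch = 32,
                           epochs = 100, patience = 10) {
  conv_kind <- match.arg(conv_kind)
  if (d_model %% heads != 0) input_error("d_model must be divisible by heads")
  if (lambda_g < 0 || lambda_g > 1) input_error("lambda_g must lie in [0, 1]")
  if (kernel %% 2 != 1) input_error("kernel must be odd")
  if (length(channels) < 1) input_error("at least one conv layer required")
  if (length(unique(channels)) != 1) {
    input_error("conv channels must be equal across layers (layer loss averages them)")
  }
  if (dropout < 0 || dropout >= 1) input_error("dropout must lie in [0, 1)")
  structure(
    list(d_model = d_model, heads = heads,
         layers_per_block = layers_per_block, lambda_g = lambda_g,
         ffn_width = ffn_width, dropout = dropout, n_max = n_max,
         conv_kind = conv_kind, channels = channels, kernel = kernel,
         max_len = max_len, desc_hidden = desc_hidden, fp_hidden = fp_hidden,
         latent = latent, fusion_hidden = fusion_hidden,
         gamma_sub = gamma_sub, gamma_layer = gamma_layer, lr = lr,
         batch = batch, epochs = epochs, patience = patience),
    class = "pepperm_config"
  )
}

#' @export
print.pepperm_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<pepperm_config: atom d=%d h=%d %dx2 layers lambda_g=%.2f | ",
    "monomer %s conv %s k=%d | latent %d>\n"),
    x$d_model, x$heads, x$layers_per_block, x$lambda_g, x$conv_kind,
    paste(x$channels, collapse = "-"), x$kernel, x$latent))
  invisible(x)
}

# --- parameter initialisation ----------------------------------------------

glorot <- function(rng, nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix((rng$runif(nin * nout) * 2 - 1) * lim, nin, nout)
}

#' Initialise model parameters
#'
#' Glorot-uniform weights and zero biases in one flat named list; layer
#' norms start at gain 1, bias 0.
#'
#' @param config A [pepperm_config()].
#' @param seed Integer seed.
#' @return Named list of numeric matrices/vectors, class `pepperm_params`.
#' @export
init_pepperm_params <- function(config, seed = 1) {
  cf <- config
  rng <- local_rng(stable_hash(seed, "init") %% 2147483647)
  d <- cf$d_model
  p <- list()
  p[["atom.W_node"]] <- glorot(rng, NODE_FEATURE_WIDTH, d)
  p[["atom.W_bond"]] <- glorot(rng, cf$n_max, d)
  for (blk in c("graph", "conf")) {
    for (l in seq_len(cf$layers_per_block)) {
      key <- function(nm) sprintf("atom.%s.l%d.%s", blk, l, nm)
      p[[key("Wq")]] <- glorot(rng, d, d); p[[key("bq")]] <- numeric(d)
      p[[key("Wk")]] <- glorot(rng, d, d); p[[key("bk")]] <- numeric(d)
      p[[key("Wv")]] <- glorot(rng, d, d); p[[key("bv")]] <- numeric(d)
      p[[key("Wo")]] <- glorot(rng, d, d); p[[key("bo")]] <- numeric(d)
      p[[key("ln1g")]] <- rep(1, d); p[[key("ln1b")]] <- numeric(d)
      p[[key("W1")]] <- glorot(rng, d, cf$ffn_width)
      p[[key("b1")]] <- numeric(cf$ffn_width)
      p[[key("W2")]] <- glorot(rng, cf$ffn_width, d)
      p[[key("b2")]] <- numeric(d)
      p[[key("ln2g")]] <- rep(1, d); p[[key("ln2b")]] <- numeric(d)
    }
  }
  p[["atom.W_out"]] <- glorot(rng, 2 * d, cf$latent)
  p[["atom.b_out"]] <- numeric(cf$latent)
  p[["atom.head_w"]] <- glorot(rng, cf$latent, 1)
  p[["atom.head_b"]] <- 0
  p[["atom.layer_w"]] <- glorot(rng, d, 1)
  p[["atom.layer_b"]] <- 0

  cin <- 16L
  for (l in seq_along(cf$channels)) {
    p[[sprintf("mono.l%d.W", l)]] <- glorot(rng, cf$kernel * cin, cf$channels[l])
    p[[sprintf("mono.l%d.b", l)]] <- numeric(cf$channels[l])
    cin <- cf$channels[l]
  }
  p[["mono.W_out"]] <- glorot(rng, cin, cf$latent)
  p[["mono.b_out"]] <- numeric(cf$latent)
  p[["mono.head_w"]] <- glorot(rng, cf$latent, 1)
  p[["mono.head_b"]] <- 0
  p[["mono.layer_w"]] <- glorot(rng, cf$channels[1], 1)
  p[["mono.layer_b"]] <- 0

  p[["pep.D1"]] <- glorot(rng, 16, cf$desc_hidden)
  p[["pep.bd1"]] <- numeric(cf$desc_hidden)
  p[["pep.D2"]] <- glorot(rng, cf$desc_hidden, cf$latent)
  p[["pep.bd2"]] <- numeric(cf$latent)
  p[["pep.F1"]] <- glorot(rng, 2048, cf$fp_hidden)
  p[["pep.bf1"]] <- numeric(cf$fp_hidden)
  p[["pep.F2"]] <- glorot(rng, cf$fp_hidden, cf$latent)
  p[["pep.bf2"]] <- numeric(cf$latent)
  p[["pep.W_out"]] <- glorot(rng, 2 * cf$latent, cf$latent)
  p[["pep.b_out"]] <- numeric(cf$latent)
  p[["pep.head_w"]] <- glorot(rng, cf$latent, 1)
  p[["pep.head_b"]] <- 0
  p[["pep.layer_w"]] <- glorot(rng, cf$latent, 1)
  p[["pep.layer_b"]] <- 0

  p[["fus.S1"]] <- glorot(rng, 3 * cf$latent, cf$fusion_hidden)
  p[["fus.bs1"]] <- numeric(cf$fusion_hidden)
  p[["fus.S2"]] <- glorot(rng, cf$fusion_hidden, 1)
  p[["fus.bs2"]] <- 0
  structure(p, class = "pepperm_params")
}

# --- primitive layers -------------------------------------------------------

layer_norm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + LN_EPS)
  xhat <- xc / s
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, s = s)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$s
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(a) {
  rowmax <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  e <- exp(a - rowmax)
  e / rowSums(e)
}

#' Embed node and bond features
#'
#' `x = (Node W_node + Bond W_bond) / sqrt(d_model)`: the bond matrix acts
#' as a learnt relative positional encoding added to the node embedding.
#'
#' @param node N x 30 node feature matrix.
#' @param bond N x n_max bond weight matrix (columns padded to the bond
#'   embedding size).
#' @param W_node,W_bond Embedding weights (30 x d and n_max x d).
#' @return N x d embedding matrix.
#' @export
atom_embed <- function(node, bond, W_node, W_bond) {
  d <- ncol(W_node)
  if (ncol(node) != nrow(W_node)) input_error("node width mismatch")
  if (ncol(bond) != nrow(W_bond)) input_error("bond width mismatch")
  (node %*% W_node + bond %*% W_bond) / sqrt(d)
}

# one encoder layer of the structure-enhanced transformer
encoder_layer_fwd <- function(x, strength, lp, cf, drop_mask = NULL) {
  d <- cf$d_model
  dh <- d / cf$heads
  n <- nrow(x)
  Q <- x %*% lp$Wq + rep(lp$bq, each = n)
  K <- x %*% lp$Wk + rep(lp$bk, each = n)
  V <- x %*% lp$Wv + rep(lp$bv, each = n)
  H <- matrix(0, n, d)
  P_list <- vector("list", cf$heads)
  for (h in seq_len(cf$heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(d)
    P <- softmax_rows(A)
    P_list[[h]] <- P
    H[, cols] <- (P * strength) %*% V[, cols, drop = FALSE]
  }
  focus <- H %*% lp$Wo + rep(lp$bo, each = n)
  ln1 <- layer_norm_fwd(x + focus, lp$ln1g, lp$ln1b)
  r <- ln1$y
  pre <- r %*% lp$W1 + rep(lp$b1, each = n)
  hrelu <- pmax(pre, 0)
  hdrop <- if (is.null(drop_mask)) hrelu else hrelu * drop_mask
  f <- hdrop %*% lp$W2 + rep(lp$b2, each = n)
  ln2 <- layer_norm_fwd(r + f, lp$ln2g, lp$ln2b)
  list(y = ln2$y, x = x, Q = Q, K = K, V = V, H = H, P = P_list,
       ln1 = ln1, r = r, pre = pre, hdrop = hdrop, drop_mask = drop_mask,
       ln2 = ln2)
}

encoder_layer_bwd <- function(dy, cache, strength, lp, cf, acc, key) {
  d <- cf$d_model
  dh <- d / cf$heads
  n <- nrow(dy)
  l2 <- layer_norm_bwd(dy, cache$ln2, lp$ln2g)
  acc_add(acc, key("ln2g"), l2$dg); acc_add(acc, key("ln2b"), l2$db)
  drf <- l2$dx                     # gradient on (r + f)
  df <- drf
  dhdrop <- tcrossprod(df, lp$W2)
  acc_add(acc, key("W2"), crossprod(cache$hdrop, df))
  acc_add(acc, key("b2"), colSums(df))
  dhrelu <- if (is.null(cache$drop_mask)) dhdrop else dhdrop * cache$drop_mask
  dpre <- dhrelu * (cache$pre > 0)
  acc_add(acc, key("W1"), crossprod(cache$r, dpre))
  acc_add(acc, key("b1"), colSums(dpre))
  dr <- drf + tcrossprod(dpre, lp$W1)
  l1 <- layer_norm_bwd(dr, cache$ln1, lp$ln1g)
  acc_add(acc, key("ln1g"), l1$dg); acc_add(acc, key("ln1b"), l1$db)
  dxf <- l1$dx                     # gradient on (x + focus)
  dfocus <- dxf
  dH <- tcrossprod(dfocus, lp$Wo)
  acc_add(acc, key("Wo"), crossprod(cache$H, dfocus))
  acc_add(acc, key("bo"), colSums(dfocus))
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (h in seq_len(cf$heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$P[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dFh <- dH[, cols, drop = FALSE]
    PS <- P * strength
    dV[, cols] <- crossprod(PS, dFh)
    dP <- tcrossprod(dFh, Vh) * strength
    dA <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- (dA %*% cache$K[, cols, drop = FALSE]) / sqrt(d)
    dK[, cols] <- crossprod(dA, cache$Q[, cols, drop = FALSE]) / sqrt(d)
  }
  acc_add(acc, key("Wq"), crossprod(cache$x, dQ)); acc_add(acc, key("bq"), colSums(dQ))
  acc_add(acc, key("Wk"), crossprod(cache$x, dK)); acc_add(acc, key("bk"), colSums(dK))
  acc_add(acc, key("Wv"), crossprod(cache$x, dV)); acc_add(acc, key("bv"), colSums(dV))
  dxf + tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) + tcrossprod(dV, lp$Wv)
}

layer_params <- function(params, blk, l) {
  pre <- sprintf("atom.%s.l%d.", blk, l)
  nm <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "ln1g", "ln1b",
          "W1", "b1", "W2", "b2", "ln2g", "ln2b")
  stats::setNames(lapply(nm, function(x) params[[paste0(pre, x)]]), nm)
}

#' Run one focused-attention encoder block
#'
#' A stack of encoder layers in which each head's attention probabilities
#' are multiplied element-wise by the Strength matrix before being applied
#' to the values (no renormalization), then residual + layer norm, a ReLU
#' feed-forward sublayer, and a second residual + layer norm.  With an
#' all-ones Strength this reduces to standard multi-head attention; with an
#' identity Strength every atom attends only to itself.
#'
#' @param x N x d input (real atoms only).
#' @param strength N x N attenuation matrix in `[0, 1]`.
#' @param params A `pepperm_params` list.
#' @param config The matching [pepperm_config()].
#' @param block `"graph"` or `"conf"` (selects the parameter block).
#' @param return_attention Also return each layer's per-head attention
#'   probability matrices (before strength masking).
#' @return List with `x` (N x d output), `pooled` (per-layer mean-pooled
#'   vectors) and optionally `attention`.
#' @export
focused_block <- function(x, strength, params, config, block = "graph",
                          return_attention = FALSE) {
  pooled <- list()
  attn <- list()
  for (l in seq_len(config$layers_per_block)) {
    cache <- encoder_layer_fwd(x, strength, layer_params(params, block, l), config)
    x <- cache$y
    pooled[[l]] <- colMeans(x)
    if (return_attention) attn[[l]] <- cache$P
  }
  out <- list(x = x, pooled = pooled)
  if (return_attention) out$attention <- attn
  out
}

# --- atom branch ------------------------------------------------------------

atom_fwd <- function(sm, params, cf, train = FALSE, rng = NULL) {
  d <- cf$d_model
  n <- nrow(sm$node)
  x0 <- atom_embed(sm$node, sm$bond, params[["atom.W_node"]], params[["atom.W_bond"]])
  blocks <- list()
  pooled_all <- list()
  for (blk in c("graph", "conf")) {
    S <- if (blk == "graph") sm$sg else sm$sc
    x <- x0
    caches <- vector("list", cf$layers_per_block)
    for (l in seq_len(cf$layers_per_block)) {
      dm <- NULL
      if (train && cf$dropout > 0) {
        dm <- matrix((rng$runif(n * cf$ffn_width) >= cf$dropout) / (1 - cf$dropout),
                     n, cf$ffn_width)
      }
      caches[[l]] <- encoder_layer_fwd(x, S, layer_params(params, blk, l), cf, dm)
      x <- caches[[l]]$y
      pooled_all[[length(pooled_all) + 1]] <- colMeans(x)
    }
    blocks[[blk]] <- list(caches = caches, out = x, pooled = colMeans(x))
  }
  zcat <- c(cf$lambda_g * blocks$graph$pooled,
            (1 - cf$lambda_g) * blocks$conf$pooled)
  out <- drop(zcat %*% params[["atom.W_out"]]) + params[["atom.b_out"]]
  layer_feat <- Reduce(`+`, pooled_all) / length(pooled_all)
  list(out = out, layer_feat = layer_feat, x0 = x0, blocks = blocks,
       zcat = zcat, n = n)
}

atom_bwd <- function(dout, dlayer, fw, sm, params, cf, acc) {
  d <- cf$d_model
  n <- fw$n
  acc_add(acc, "atom.W_out", outer(fw$zcat, dout))
  acc_add(acc, "atom.b_out", dout)
  dzcat <- drop(params[["atom.W_out"]] %*% dout)
  dpool <- list(graph = cf$lambda_g * dzcat[1:d],
                conf = (1 - cf$lambda_g) * dzcat[d + (1:d)])
  n_pooled <- 2 * cf$layers_per_block
  dx0 <- matrix(0, n, d)
  idx <- 0
  for (blk in c("graph", "conf")) {
    S <- if (blk == "graph") sm$sg else sm$sc
    bc <- fw$blocks[[blk]]
    # gradients flowing into each layer's output via the pooled vectors
    dlayer_out <- vector("list", cf$layers_per_block)
    for (l in seq_len(cf$layers_per_block)) {
      g <- dlayer / n_pooled
      if (l == cf$layers_per_block) g <- g + dpool[[blk]]
      dlayer_out[[l]] <- matrix(g / n, n, d, byrow = TRUE)
    }
    dx <- matrix(0, n, d)
    for (l in rev(seq_len(cf$layers_per_block))) {
      dx <- dx + dlayer_out[[l]]
      key <- local({
        blk_l <- blk; l_l <- l
        function(nm) sprintf("atom.%s.l%d.%s", blk_l, l_l, nm)
      })
      dx <- encoder_layer_bwd(dx, bc$caches[[l]], S,
                              layer_params(params, blk, l), cf, acc, key)
    }
    dx0 <- dx0 + dx
  }
  sq <- sqrt(d)
  acc_add(acc, "atom.W_node", crossprod(sm$node, dx0) / sq)
  acc_add(acc, "atom.W_bond", crossprod(sm$bond, dx0) / sq)
  invisible(NULL)
}

#' Atom-branch forward pass
#'
#' Embeds node and bond features, runs the graph- and conf-strength
#' encoder blocks in parallel from the shared embedding, mean-pools each
#' block over real atoms, blends the two pooled vectors with `lambda_g`
#' and maps the concatenation to the branch latent.  Per-layer pooled
#' outputs are averaged into `layer_feat` for the layer auxiliary loss.
#'
#' @param features An `atom_feature_set` (padded) or a list with trimmed
#'   `node`, `bond`, `sg`, `sc` matrices.
#' @param params,config Model parameters and configuration.
#' @return List with `out` (latent vector) and `layer_feat`.
#' @export
atom_forward <- function(features, params, config) {
  sm <- as_atom_sample(features, config)
  fw <- atom_fwd(sm, params, config)
  list(out = fw$out, layer_feat = fw$layer_feat)
}

as_atom_sample <- function(features, cf) {
  if (inherits(features, "atom_feature_set")) {
    n <- features$n_real
    list(node = features$node[1:n, , drop = FALSE],
         bond = features$bond[1:n, , drop = FALSE],
         sg = features$strength_graph[1:n, 1:n, drop = FALSE],
         sc = features$strength_conf[1:n, 1:n, drop = FALSE])
  } else {
    stopifnot(is.matrix(features$node))
    if (ncol(features$bond) < cf$n_max) {
      pad <- matrix(0, nrow(features$bond), cf$n_max - ncol(features$bond))
      features$bond <- cbind(features$bond, pad)
    }
    features
  }
}

# --- monomer branch ---------------------------------------------------------

# gather index table: rows = frame positions, cols = kernel taps; 0 = zero row
conv_gather_idx <- function(max_len, kernel, kind, offset, L) {
  hw <- (kernel - 1) / 2
  idx <- matrix(0L, max_len, kernel)
  for (p in seq_len(max_len)) {
    for (t in seq_len(kernel)) {
      delta <- t - 1 - hw
      if (kind == "cyclic") {
        rel <- p - offset          # 1..L inside the span
        if (rel >= 1 && rel <= L) {
          idx[p, t] <- offset + ((rel - 1 + delta) %% L) + 1L
        }
      } else {
        q <- p + delta
        if (q >= 1 && q <= max_len) idx[p, t] <- as.integer(q)
      }
    }
  }
  idx
}

conv_layer_fwd <- function(X, W, b, idx, kind, span_rows) {
  max_len <- nrow(X)
  k <- ncol(idx)
  cin <- ncol(X)
  Xg <- matrix(0, max_len, k * cin)
  for (t in seq_len(k)) {
    rows <- idx[, t]
    ok <- rows > 0
    Xg[ok, ((t - 1) * cin + 1):(t * cin)] <- X[rows[ok], , drop = FALSE]
  }
  pre <- Xg %*% W + rep(b, each = max_len)
  out <- pmax(pre, 0)
  if (kind == "cyclic") out[-span_rows, ] <- 0
  list(out = out, pre = pre, Xg = Xg)
}

conv_layer_bwd <- function(dout, cache, W, idx, kind, span_rows, acc, key) {
  max_len <- nrow(dout)
  k <- ncol(idx)
  if (kind == "cyclic") {
    keep <- rep(FALSE, max_len); keep[span_rows] <- TRUE
    dout[!keep, ] <- 0
  }
  dpre <- dout * (cache$pre > 0)
  acc_add(acc, key("W"), crossprod(cache$Xg, dpre))
  acc_add(acc, key("b"), colSums(dpre))
  dXg <- tcrossprod(dpre, W)
  cin <- ncol(dXg) / k
  dX <- matrix(0, max_len, cin)
  for (t in seq_len(k)) {
    rows <- idx[, t]
    ok <- which(rows > 0)
    for (p in ok) dX[rows[p], ] <- dX[rows[p], ] + dXg[p, ((t - 1) * cin + 1):(t * cin)]
  }
  dX
}

mono_fwd <- function(sm, params, cf) {
  X <- sm$mono
  offset <- sm$span_offset          # 0-based
  L <- sm$span_len
  span_rows <- offset + seq_len(L)
  n_layers <- length(cf$channels)
  caches <- vector("list", n_layers)
  idxs <- vector("list", n_layers)
  pooled <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    idxs[[l]] <- conv_gather_idx(cf$max_len, cf$kernel, cf$conv_kind, offset, L)
    caches[[l]] <- conv_layer_fwd(X, params[[sprintf("mono.l%d.W", l)]],
                                  params[[sprintf("mono.l%d.b", l)]],
                                  idxs[[l]], cf$conv_kind, span_rows)
    X <- caches[[l]]$out
    pooled[[l]] <- colMeans(X[span_rows, , drop = FALSE])
  }
  out <- drop(pooled[[n_layers]] %*% params[["mono.W_out"]]) + params[["mono.b_out"]]
  layer_feat <- Reduce(`+`, pooled) / n_layers
  list(out = out, layer_feat = layer_feat, caches = caches, idxs = idxs,
       pooled = pooled, span_rows = span_rows)
}

mono_bwd <- function(dout, dlayer, fw, sm, params, cf, acc) {
  n_layers <- length(cf$channels)
  span_rows <- fw$span_rows
  L <- length(span_rows)
  acc_add(acc, "mono.W_out", outer(fw$pooled[[n_layers]], dout))
  acc_add(acc, "mono.b_out", dout)
  dpool_last <- drop(params[["mono.W_out"]] %*% dout)
  dX <- NULL
  for (l in rev(seq_len(n_layers))) {
    dp <- dlayer / n_layers
    if (l == n_layers) dp <- dp + dpool_last
    dZ <- matrix(0, cf$max_len, cf$channels[l])
    dZ[span_rows, ] <- matrix(dp / L, L, cf$channels[l], byrow = TRUE)
    if (!is.null(dX)) dZ <- dZ + dX
    key <- local({
      l_l <- l
      function(nm) sprintf("mono.l%d.%s", l_l, nm)
    })
    dX <- conv_layer_bwd(dZ, fw$caches[[l]], params[[sprintf("mono.l%d.W", l)]],
                         fw$idxs[[l]], cf$conv_kind, span_rows, acc, key)
  }
  invisible(NULL)
}

#' Monomer-branch forward pass
#'
#' Stacked 1D convolutions over the residue axis of a zero-padded
#' `max_len` x 16 frame.  With `conv_kind = "cyclic"` the convolution
#' wraps circularly over the occupied span, treating the sequence as a
#' closed loop; with `"plain"` the frame is zero-padded.  Pooling is the
#' masked mean over the occupied rows; per-layer pooled outputs feed the
#' layer auxiliary loss.
#'
#' @param matrix max_len x 16 standardized, arranged monomer matrix.
#' @param span Occupied span as `c(offset, length)` (offset 0-based).
#' @param params,config Model parameters and configuration.
#' @return List with `out` (latent vector) and `layer_feat`.
#' @export
monomer_forward <- function(matrix, span, params, config) {
  if (nrow(matrix) != config$max_len) {
    size_error("monomer matrix rows must equal config$max_len")
  }
  sm <- list(mono = matrix, span_offset = as.integer(span[1]),
             span_len = as.integer(span[2]))
  fw <- mono_fwd(sm, params, config)
  list(out = fw$out, layer_feat = fw$layer_feat)
}

# --- peptide branch ---------------------------------------------------------

pep_fwd <- function(sm, params, cf, train = FALSE, rng = NULL) {
  dmask <- fmask <- NULL
  if (train && cf$dropout > 0) {
    dmask <- (rng$runif(cf$desc_hidden) >= cf$dropout) / (1 - cf$dropout)
    fmask <- (rng$runif(cf$fp_hidden) >= cf$dropout) / (1 - cf$dropout)
  }
  pre_d <- drop(sm$desc %*% params[["pep.D1"]]) + params[["pep.bd1"]]
  h_d <- pmax(pre_d, 0)
  if (!is.null(dmask)) h_d <- h_d * dmask
  x_desc <- drop(h_d %*% params[["pep.D2"]]) + params[["pep.bd2"]]
  pre_f <- drop(sm$fp %*% params[["pep.F1"]]) + params[["pep.bf1"]]
  h_f <- pmax(pre_f, 0)
  if (!is.null(fmask)) h_f <- h_f * fmask
  x_fp <- drop(h_f %*% params[["pep.F2"]]) + params[["pep.bf2"]]
  zcat <- c(x_desc, x_fp)
  out <- drop(zcat %*% params[["pep.W_out"]]) + params[["pep.b_out"]]
  layer_feat <- (x_desc + x_fp) / 2
  list(out = out, layer_feat = layer_feat, pre_d = pre_d, h_d = h_d,
       pre_f = pre_f, h_f = h_f, zcat = zcat, dmask = dmask, fmask = fmask)
}

pep_bwd <- function(dout, dlayer, fw, sm, params, cf, acc) {
  lat <- cf$latent
  acc_add(acc, "pep.W_out", outer(fw$zcat, dout))
  acc_add(acc, "pep.b_out", dout)
  dzcat <- drop(params[["pep.W_out"]] %*% dout)
  dx_desc <- dzcat[1:lat] + dlayer / 2
  dx_fp <- dzcat[lat + (1:lat)] + dlayer / 2
  acc_add(acc, "pep.D2", outer(fw$h_d, dx_desc))
  acc_add(acc, "pep.bd2", dx_desc)
  dh_d <- drop(params[["pep.D2"]] %*% dx_desc)
  if (!is.null(fw$dmask)) dh_d <- dh_d * fw$dmask
  dpre_d <- dh_d * (fw$pre_d > 0)
  acc_add(acc, "pep.D1", outer(sm$desc, dpre_d))
  acc_add(acc, "pep.bd1", dpre_d)
  acc_add(acc, "pep.F2", outer(fw$h_f, dx_fp))
  acc_add(acc, "pep.bf2", dx_fp)
  dh_f <- drop(params[["pep.F2"]] %*% dx_fp)
  if (!is.null(fw$fmask)) dh_f <- dh_f * fw$fmask
  dpre_f <- dh_f * (fw$pre_f > 0)
  acc_add(acc, "pep.F1", outer(sm$fp, dpre_f))
  acc_add(acc, "pep.bf1", dpre_f)
  invisible(NULL)
}

#' Peptide-branch forward pass
#'
#' Two separate MLPs over the standardized 16-descriptor vector and the
#' 2048-bit Morgan fingerprint; the branch latents are concatenated and
#' mapped linearly to the peptide latent.  The mean of the two branch
#' outputs feeds the layer auxiliary loss.
#'
#' @param desc Standardized descriptor vector (length 16).
#' @param fp Fingerprint 0/1 vector (length 2048).
#' @param params,config Model parameters and configuration.
#' @return List with `out` (latent vector) and `layer_feat`.
#' @export
peptide_forward <- function(desc, fp, params, config) {
  fw <- pep_fwd(list(desc = desc, fp = fp), params, config)
  list(out = fw$out, layer_feat = fw$layer_feat)
}

# --- fusion -----------------------------------------------------------------

fus_fwd <- function(latents, params, cf, train = FALSE, rng = NULL) {
  z <- c(latents$atom, latents$monomer, latents$peptide)
  pre <- drop(z %*% params[["fus.S1"]]) + params[["fus.bs1"]]
  h <- pmax(pre, 0)
  mask <- NULL
  if (train && cf$dropout > 0) {
    mask <- (rng$runif(cf$fusion_hidden) >= cf$dropout) / (1 - cf$dropout)
    h <- h * mask
  }
  out <- drop(h %*% params[["fus.S2"]]) + params[["fus.bs2"]]
  list(out = out, z = z, pre = pre, h = h, mask = mask)
}

fus_bwd <- function(dout, fw, params, cf, acc) {
  acc_add(acc, "fus.S2", matrix(fw$h * dout, ncol = 1))
  acc_add(acc, "fus.bs2", dout)
  dh <- drop(params[["fus.S2"]]) * dout
  if (!is.null(fw$mask)) dh <- dh * fw$mask
  dpre <- dh * (fw$pre > 0)
  acc_add(acc, "fus.S1", outer(fw$z, dpre))
  acc_add(acc, "fus.bs1", dpre)
  lat <- cf$latent
  dz <- drop(params[["fus.S1"]] %*% dpre)
  list(atom = dz[1:lat], monomer = dz[lat + (1:lat)],
       peptide = dz[2 * lat + (1:lat)])
}

#' Fusion forward pass
#'
#' Concatenates the three branch latents and passes them through the
#' shared layer to the scalar permeability prediction.  Only this output
#' is used at inference time.
#'
#' @param latents List with `atom`, `monomer`, `peptide` latent vectors.
#' @param params,config Model parameters and configuration.
#' @return Scalar prediction (log10 cm/s).
#' @export
fusion_forward <- function(latents, params, config) {
  if (any(vapply(c("atom", "monomer", "peptide"),
                 function(nm) is.null(latents[[nm]]), logical(1)))) {
    input_error("all three branch latents are required")
  }
  fus_fwd(latents, params, config)$out
}

# --- losses -----------------------------------------------------------------

#' Combine the seven training losses
#'
#' `total = L_fusion + gamma_sub (L_atom + L_monomer + L_peptide) +
#' gamma_layer (L_layer_a + L_layer_m + L_layer_p)`.
#'
#' @param losses Named list/vector with elements `fusion`, `atom`,
#'   `monomer`, `peptide`, `layer_a`, `layer_m`, `layer_p` (mean squared
#'   errors).
#' @param gamma_sub,gamma_layer Auxiliary weights (defaults 0.10, 0.05).
#' @return Object of class `loss_breakdown` with the seven components, the
#'   weights and `total`.
#' @export
total_loss <- function(losses, gamma_sub = 0.10, gamma_layer = 0.05) {
  losses <- as.list(losses)
  need <- c("fusion", "atom", "monomer", "peptide",
            "layer_a", "layer_m", "layer_p")
  if (!all(need %in% names(losses))) {
    input_error(sprintf("missing loss component(s): %s",
                        paste(setdiff(need, names(losses)), collapse = ", ")))
  }
  l <- lapply(losses[need], as.numeric)
  total <- l$fusion + gamma_sub * (l$atom + l$monomer + l$peptide) +
    gamma_layer * (l$layer_a + l$layer_m + l$layer_p)
  structure(c(l, list(gamma_sub = gamma_sub, gamma_layer = gamma_layer,
                      total = total)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown: total %.4f = fusion %.4f + %.2f*(sub %.4f) + %.2f*(layer %.4f)>\n",
    x$total, x$fusion, x$gamma_sub, x$atom + x$monomer + x$peptide,
    x$gamma_layer, x$layer_a + x$layer_m + x$layer_p))
  invisible(x)
}

# --- whole-network forward / backward per sample ----------------------------

forward_sample <- function(sm, params, cf, train = FALSE, rng = NULL) {
  fa <- atom_fwd(sm, params, cf, train, rng)
  fm <- mono_fwd(sm, params, cf)
  fp <- pep_fwd(sm, params, cf, train, rng)
  ff <- fus_fwd(list(atom = fa$out, monomer = fm$out, peptide = fp$out),
                params, cf, train, rng)
  preds <- c(
    fusion = ff$out,
    atom = drop(fa$out %*% params[["atom.head_w"]]) + params[["atom.head_b"]],
    monomer = drop(fm$out %*% params[["mono.head_w"]]) + params[["mono.head_b"]],
    peptide = drop(fp$out %*% params[["pep.head_w"]]) + params[["pep.head_b"]],
    layer_a = drop(fa$layer_feat %*% params[["atom.layer_w"]]) + params[["atom.layer_b"]],
    layer_m = drop(fm$layer_feat %*% params[["mono.layer_w"]]) + params[["mono.layer_b"]],
    layer_p = drop(fp$layer_feat %*% params[["pep.layer_w"]]) + params[["pep.layer_b"]]
  )
  list(preds = preds, fa = fa, fm = fm, fp = fp, ff = ff)
}

sample_losses <- function(preds, y) {
  list(fusion = (preds[["fusion"]] - y)^2,
       atom = (preds[["atom"]] - y)^2,
       monomer = (preds[["monomer"]] - y)^2,
       peptide = (preds[["peptide"]] - y)^2,
       layer_a = (preds[["layer_a"]] - y)^2,
       layer_m = (preds[["layer_m"]] - y)^2,
       layer_p = (preds[["layer_p"]] - y)^2)
}

backward_sample <- function(fw, sm, y, params, cf, acc, scale = 1) {
  pr <- fw$preds
  g <- function(nm, w) 2 * w * (pr[[nm]] - y) * scale
  dfus <- g("fusion", 1)
  dlat <- fus_bwd(dfus, fw$ff, params, cf, acc)

  d_atom_head <- g("atom", cf$gamma_sub)
  acc_add(acc, "atom.head_w", matrix(fw$fa$out * d_atom_head, ncol = 1))
  acc_add(acc, "atom.head_b", d_atom_head)
  d_out_a <- dlat$atom + drop(params[["atom.head_w"]]) * d_atom_head
  d_la <- g("layer_a", cf$gamma_layer)
  acc_add(acc, "atom.layer_w", matrix(fw$fa$layer_feat * d_la, ncol = 1))
  acc_add(acc, "atom.layer_b", d_la)
  atom_bwd(d_out_a, drop(params[["atom.layer_w"]]) * d_la, fw$fa, sm, params, cf, acc)

  d_mono_head <- g("monomer", cf$gamma_sub)
  acc_add(acc, "mono.head_w", matrix(fw$fm$out * d_mono_head, ncol = 1))
  acc_add(acc, "mono.head_b", d_mono_head)
  d_out_m <- dlat$monomer + drop(params[["mono.head_w"]]) * d_mono_head
  d_lm <- g("layer_m", cf$gamma_layer)
  acc_add(acc, "mono.layer_w", matrix(fw$fm$layer_feat * d_lm, ncol = 1))
  acc_add(acc, "mono.layer_b", d_lm)
  mono_bwd(d_out_m, drop(params[["mono.layer_w"]]) * d_lm, fw$fm, sm, params, cf, acc)

  d_pep_head <- g("peptide", cf$gamma_sub)
  acc_add(acc, "pep.head_w", matrix(fw$fp$out * d_pep_head, ncol = 1))
  acc_add(acc, "pep.head_b", d_pep_head)
  d_out_p <- dlat$peptide + drop(params[["pep.head_w"]]) * d_pep_head
  d_lp <- g("layer_p", cf$gamma_layer)
  acc_add(acc, "pep.layer_w", matrix(fw$fp$layer_feat * d_lp, ncol = 1))
  acc_add(acc, "pep.layer_b", d_lp)
  pep_bwd(d_out_p, drop(params[["pep.layer_w"]]) * d_lp, fw$fp, sm, params, cf, acc)
  invisible(NULL)
}

# --- gradient accumulator and Adam -----------------------------------------

acc_new <- function() new.env(parent = emptyenv())

acc_add <- function(acc, name, delta) {
  cur <- acc[[name]]
  acc[[name]] <- if (is.null(cur)) delta else cur + delta
  invisible(NULL)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, acc, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- acc[[nm]]
    if (is.null(g)) next
    if (!is.null(dim(params[[nm]])) && is.null(dim(g))) dim(g) <- dim(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
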