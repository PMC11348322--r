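#' Network configuration
#'
#' Builds the hyperparameter list describing the pair-representation
#' transformer: feature channel counts of the AlphaFold2-style inputs,
#' node/edge dimensions of the internal residue graph, attention geometry,
#' stack depth and dropout rates.
#'
#' Defaults follow the reference architecture: single/structure
#' representations of 384 channels, pair representation of 128 channels,
#' node dimension 256, edge dimension 32 (31 learned channels plus one
#' reserved binary same-chain/different-chain indicator), 8 attention heads
#' and 8 transformer layers, transition expansion factor 4.
#'
#' @param c_msa,c_pair,c_struc Channel counts of the input single, pair and
#'   structure representations.
#' @param c_n Node channel count; must be divisible by `n_head`.
#' @param c_e Edge channel count (includes the reserved indicator channel).
#' @param n_head Number of attention heads.
#' @param n_layers Number of transformer layers in the stack.
#' @param n_expand Transition-block expansion factor.
#' @param edge_mlp_hidden Hidden width of the attention block's edge-update
#'   MLP (its width is not pinned down by the architecture; the edge channel
#'   count is used by default).
#' @param head_res_hidden,head_res_out Widths of the per-residue projection
#'   in the prediction head.
#' @param head_hidden Integer vector of the two hidden widths of the pooled
#'   output MLP.
#' @param drop_attention,drop_transition,drop_affinity Dropout rates applied
#'   after the attention block, after the transition blocks, and inside the
#'   prediction head.
#' @param symmetrize Logical; average the scores of the two chain orders
#'   when predicting (a co-condensation propensity is order-free).
#' @return A list of class `codroplet_config`.
#' @export
net_config <- function(c_msa = 384L, c_pair = 128L, c_struc = 384L,
                       c_n = 256L, c_e = 32L, n_head = 8L, n_layers = 8L,
                       n_expand = 4L, edge_mlp_hidden = c_e,
                       head_res_hidden = c_n, head_res_out = c_n,
                       head_hidden = c(64L, 32L),
                       drop_attention = 0.1, drop_transition = 0.1,
                       drop_affinity = 0.1, symmetrize = TRUE) {
  if (c_n %% n_head != 0L) {
    stop("node dimension c_n must be divisible by n_head", call. = FALSE)
  }
  if (c_e < 2L) stop("c_e must be at least 2 (one learned channel plus the chain indicator)",
                     call. = FALSE)
  cfg <- list(
    c_msa = as.integer(c_msa), c_pair = as.integer(c_pair),
    c_struc = as.integer(c_struc), c_n = as.integer(c_n),
    c_e = as.integer(c_e), n_head = as.integer(n_head),
    n_layers = as.integer(n_layers), n_expand = as.integer(n_expand),
    edge_mlp_hidden = as.integer(edge_mlp_hidden),
    head_res_hidden = as.integer(head_res_hidden),
    head_res_out = as.integer(head_res_out),
    head_hidden = as.integer(head_hidden),
    drop_attention = drop_attention, drop_transition = drop_transition,
    drop_affinity = drop_affinity, symmetrize = isTRUE(symmetrize)
  )
  class(cfg) <- "codroplet_config"
  cfg
}

# ---- graph representation -------------------------------------------------

#' Residue graph representation
#'
#' Container for the node/edge representation of one protein (single chain)
#' or a combined two-chain complex.  Edges are stored as an `N^2 x c` matrix
#' in column-major pair order: the row for residue pair `(i, j)` is
#' `i + (j - 1) * N`.
#'
#' @param nodes `N x c_n` numeric matrix of node features.
#' @param edges `N^2 x c` numeric matrix of edge features.
#' @param chain Integer vector of length `N`: 0 for chain A, 1 for chain B.
#' @return An object of class `codroplet_graph`.
#' @export
graph_rep <- function(nodes, edges, chain = rep(0L, nrow(nodes))) {
  stopifnot(is.matrix(nodes), is.matrix(edges))
  n <- nrow(nodes)
  if (nrow(edges) != n * n) {
    stop("edges must have N^2 rows for N nodes", call. = FALSE)
  }
  if (length(chain) != n) stop("chain labels must have length N", call. = FALSE)
  if (!all(is.finite(nodes)) || !all(is.finite(edges))) {
    stop("graph features must be finite", call. = FALSE)
  }
  structure(
    list(nodes = nodes, edges = edges, chain = as.integer(chain), n_res = n),
    class = "codroplet_graph"
  )
}

#' @export
print.codroplet_graph <- function(x, ...) {
  cat(sprintf(
    "<codroplet_graph> %d residues (%d chain%s), nodes %dx%d, edges %dx%d\n",
    x$n_res, length(unique(x$chain)),
    if (length(unique(x$chain)) > 1L) "s" else "",
    nrow(x$nodes), ncol(x$nodes), nrow(x$edges), ncol(x$edges)
  ))
  invisible(x)
}

edge_row_index <- function(i, j, n) i + (j - 1L) * n

# ---- parameter initialisation --------------------------------------------

rand_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)), n_in, n_out)
}

init_ln <- function(c) list(g = rep(1, c), b = rep(0, c))

#' Initialise a transition block
#'
#' A transition block is layer normalisation followed by a two-layer MLP
#' with ReLU whose hidden width expands the input channel count by
#' `n_expand`; the second linear targets `c_out` (equal to `c_in` for the
#' dimension-preserving form).
#'
#' @param c_in,c_out Input and output channel counts.
#' @param n_expand Expansion factor of the hidden layer.
#' @return A named parameter list.
#' @export
init_transition_params <- function(c_in, c_out = c_in, n_expand = 4L) {
  hid <- c_in * n_expand
  list(
    ln = init_ln(c_in),
    W1 = rand_mat(c_in, hid), b1 = rep(0, hid),
    W2 = rand_mat(hid, c_out), b2 = rep(0, c_out)
  )
}

#' Initialise a self-attention block
#'
#' @param c_n,c_e Node and edge channel counts.
#' @param n_head Number of heads; must divide `c_n`.
#' @param edge_mlp_hidden Hidden width of the edge-update MLP.
#' @return A named parameter list.
#' @export
init_attention_params <- function(c_n, c_e, n_head, edge_mlp_hidden = c_e) {
  if (c_n %% n_head != 0L) {
    stop("c_n must be divisible by n_head", call. = FALSE)
  }
  list(
    ln_n = init_ln(c_n), ln_e = init_ln(c_e),
    Wq = rand_mat(c_n, c_n), Wk = rand_mat(c_n, c_n), Wv = rand_mat(c_n, c_n),
    Wb = rand_mat(c_e, n_head),
    Wg = rand_mat(c_n, c_n), bg = rep(0, c_n),
    We1 = rand_mat(n_head, edge_mlp_hidden), be1 = rep(0, edge_mlp_hidden),
    We2 = rand_mat(edge_mlp_hidden, c_e), be2 = rep(0, c_e),
    Wo = rand_mat(c_n, c_n), bo = rep(0, c_n)
  )
}

#' Initialise all model parameters
#'
#' Draws every weight matrix from a zero-mean Gaussian with standard
#' deviation `1/sqrt(fan_in)`; biases and layer-norm offsets start at zero,
#' layer-norm gains at one.
#'
#' @param config A [net_config()] object.
#' @param seed Integer seed controlling the draw.
#' @return Nested parameter list of class `codroplet_params`.
#' @export
init_params <- function(config = net_config(), seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    ne <- config$n_expand
    enc <- list(
      t_msa = init_transition_params(config$c_msa, config$c_msa, ne),
      ln_msa = init_ln(config$c_msa),
      t_struc = init_transition_params(config$c_struc, config$c_struc, ne),
      ln_struc = init_ln(config$c_struc),
      t_pair = init_transition_params(config$c_pair, config$c_pair, ne),
      ln_pair = init_ln(config$c_pair),
      t_resi = init_transition_params(config$c_msa + config$c_struc,
                                      config$c_n, ne),
      t_edge = init_transition_params(config$c_pair, config$c_e - 1L, ne)
    )
    layers <- lapply(seq_len(config$n_layers), function(i) {
      list(
        att = init_attention_params(config$c_n, config$c_e, config$n_head,
                                    config$edge_mlp_hidden),
        ln_node = init_ln(config$c_n),
        t_node = init_transition_params(config$c_n, config$c_n, ne),
        ln_edge = init_ln(config$c_e),
        t_edge = init_transition_params(config$c_e, config$c_e, ne)
      )
    })
    head <- list(
      ln = init_ln(config$c_n),
      W1 = rand_mat(config$c_n, config$head_res_hidden),
      b1 = rep(0, config$head_res_hidden),
      W2 = rand_mat(config$head_res_hidden, config$head_res_out),
      b2 = rep(0, config$head_res_out),
      W3 = rand_mat(config$head_res_out, config$head_hidden[1L]),
      b3 = rep(0, config$head_hidden[1L]),
      W4 = rand_mat(config$head_hidden[1L], config$head_hidden[2L]),
      b4 = rep(0, config$head_hidden[2L]),
      W5 = rand_mat(config$head_hidden[2L], 1L),
      b5 = 0
    )
    structure(list(enc = enc, layers = layers, head = head),
              class = "codroplet_params")
  })
}

# ---- transition block -----------------------------------------------------

trans_fwd <- function(x, p) {
  ln <- ln_fwd(x, p$ln$g, p$ln$b)
  l1 <- lin_fwd(ln$out, p$W1, p$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- lin_fwd(r1$out, p$W2, p$b2)
  list(out = l2$out, ln = ln, l1 = l1, r1 = r1, l2 = l2)
}

trans_bwd <- function(dout, cache, p) {
  g2 <- lin_bwd(dout, cache$l2, p$W2)
  dr <- relu_bwd(g2$dx, cache$r1)
  g1 <- lin_bwd(dr, cache$l1, p$W1)
  gl <- ln_bwd(g1$dx, cache$ln)
  list(
    dx = gl$dx,
    grads = list(ln = list(g = gl$dg, b = gl$db),
                 W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
  )
}

#' Transition block
#'
#' Applies layer normalisation followed by a two-layer MLP with ReLU whose
#' hidden width is `n_expand` times the input channel count.  Accepts a
#' vector (one token) or a matrix (rows are tokens).
#'
#' @param a Numeric vector of length `c` or matrix with `c` columns.
#' @param params Parameters from [init_transition_params()].
#' @param out_dim Optional; if supplied, validated against the parameters.
#' @return Output of the same row count, `out_dim` columns.
#' @export
transition <- function(a, params, out_dim = NULL) {
  vec <- is.null(dim(a))
  x <- if (vec) matrix(a, nrow = 1L) else a
  if (ncol(x) != nrow(params$W1)) {
    stop(sprintf("transition expects %d input channels, got %d",
                 nrow(params$W1), ncol(x)), call. = FALSE)
  }
  if (!is.null(out_dim) && out_dim != ncol(params$W2)) {
    stop(sprintf("transition parameters target %d channels, not %d",
                 ncol(params$W2), out_dim), call. = FALSE)
  }
  out <- trans_fwd(x, params)$out
  if (vec) drop(out) else out
}

# ---- self-attention with pair bias ---------------------------------------

att_fwd <- function(nodes, edges, p, n_head) {
  n <- nrow(nodes)
  c_n <- ncol(nodes)
  cp <- c_n %/% n_head
  scale <- 1 / sqrt(cp)

  ln_n <- ln_fwd(nodes, p$ln_n$g, p$ln_n$b)
  ln_e <- ln_fwd(edges, p$ln_e$g, p$ln_e$b)
  nl <- ln_n$out
  el <- ln_e$out

  Q <- nl %*% p$Wq
  K <- nl %*% p$Wk
  V <- nl %*% p$Wv
  B <- el %*% p$Wb                       # N^2 x n_head pair bias
  Gpre <- nl %*% p$Wg + rep(p$bg, each = n)
  G <- sigmoid(Gpre)

  Alog <- matrix(0, n * n, n_head)        # pre-bias logits, flattened (i,j)
  Pmat <- matrix(0, n * n, n_head)        # softmaxed attention weights
  O <- matrix(0, n, c_n)                  # gated per-head outputs, concat
  PV <- matrix(0, n, c_n)                 # ungated aggregation (cached)
  for (h in seq_len(n_head)) {
    idx <- ((h - 1L) * cp + 1L):(h * cp)
    A_h <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
    Alog[, h] <- as.vector(A_h)
    P_h <- softmax_rows(A_h + matrix(B[, h], n, n))
    Pmat[, h] <- as.vector(P_h)
    pv <- P_h %*% V[, idx, drop = FALSE]
    PV[, idx] <- pv
    O[, idx] <- G[, idx, drop = FALSE] * pv
  }

  # Edge update from the pre-bias, pre-softmax logits.
  e1 <- lin_fwd(Alog, p$We1, p$be1)
  r1 <- relu_fwd(e1$out)
  e2 <- lin_fwd(r1$out, p$We2, p$be2)

  o_lin <- lin_fwd(O, p$Wo, p$bo)

  list(
    nodes = o_lin$out, edges = e2$out,
    ln_n = ln_n, ln_e = ln_e, Q = Q, K = K, V = V, B = B,
    G = G, Alog = Alog, Pmat = Pmat, PV = PV, O = O,
    e1 = e1, r1 = r1, e2 = e2, o_lin = o_lin,
    n_head = n_head, cp = cp, scale = scale, n = n
  )
}

att_bwd <- function(dnodes, dedges, cache, p) {
  n <- cache$n
  n_head <- cache$n_head
  cp <- cache$cp
  scale <- cache$scale

  go <- lin_bwd(dnodes, cache$o_lin, p$Wo)
  dO <- go$dx

  ge2 <- lin_bwd(dedges, cache$e2, p$We2)
  dr1 <- relu_bwd(ge2$dx, cache$r1)
  ge1 <- lin_bwd(dr1, cache$e1, p$We1)
  dAlog_edge <- ge1$dx                    # N^2 x n_head

  dQ <- matrix(0, n, n_head * cp)
  dK <- matrix(0, n, n_head * cp)
  dV <- matrix(0, n, n_head * cp)
  dG <- matrix(0, n, n_head * cp)
  dB <- matrix(0, n * n, n_head)

  for (h in seq_len(n_head)) {
    idx <- ((h - 1L) * cp + 1L):(h * cp)
    P_h <- matrix(cache$Pmat[, h], n, n)
    V_h <- cache$V[, idx, drop = FALSE]
    G_h <- cache$G[, idx, drop = FALSE]
    pv_h <- cache$PV[, idx, drop = FALSE]
    dO_h <- dO[, idx, drop = FALSE]

    dG[, idx] <- dO_h * pv_h
    dPV_h <- dO_h * G_h
    dP_h <- tcrossprod(dPV_h, V_h)
    dV[, idx] <- crossprod(P_h, dPV_h)
    dS_h <- softmax_rows_bwd(dP_h, P_h)   # into (A + B)
    dB[, h] <- as.vector(dS_h)
    dA_h <- dS_h + matrix(dAlog_edge[, h], n, n)
    Q_h <- cache$Q[, idx, drop = FALSE]
    K_h <- cache$K[, idx, drop = FALSE]
    dQ[, idx] <- (dA_h %*% K_h) * scale
    dK[, idx] <- crossprod(dA_h, Q_h) * scale
  }

  dGpre <- dG * cache$G * (1 - cache$G)
  nl <- cache$ln_n$out
  el <- cache$ln_e$out

  dnl <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
    tcrossprod(dV, p$Wv) + tcrossprod(dGpre, p$Wg)
  del <- tcrossprod(dB, p$Wb)

  gln_n <- ln_bwd(dnl, cache$ln_n)
  gln_e <- ln_bwd(del, cache$ln_e)

  list(
    dnodes = gln_n$dx, dedges = gln_e$dx,
    grads = list(
      ln_n = list(g = gln_n$dg, b = gln_n$db),
      ln_e = list(g = gln_e$dg, b = gln_e$db),
      Wq = crossprod(nl, dQ), Wk = crossprod(nl, dK), Wv = crossprod(nl, dV),
      Wb = crossprod(el, dB),
      Wg = crossprod(nl, dGpre), bg = colSums(dGpre),
      We1 = ge1$dW, be1 = ge1$db,
      We2 = ge2$dW, be2 = ge2$db,
      Wo = go$dW, bo = go$db
    )
  )
}

#' Gated self-attention with pair bias
#'
#' Updates a residue graph: per-head queries, keys and values come from the
#' layer-normalised nodes, a scalar per-head bias comes from the
#' layer-normalised edges, and a sigmoid gate modulates the aggregated
#' values.  The edge output is computed from the pre-bias, pre-softmax
#' attention logits through a two-layer MLP; the node output uses the
#' softmax of logits plus pair bias.
#'
#' @param graph A [graph_rep()] object.
#' @param params Parameters from [init_attention_params()].
#' @param n_head Number of attention heads.
#' @return A `codroplet_graph` with updated nodes and edges (the block
#'   output itself, without residual connection).
#' @export
self_attention <- function(graph, params, n_head = 8L) {
  stopifnot(inherits(graph, "codroplet_graph"))
  if (ncol(graph$nodes) %% n_head != 0L) {
    stop("n_head must divide the node channel count", call. = FALSE)
  }
  f <- att_fwd(graph$nodes, graph$edges, params, n_head)
  graph_rep(f$nodes, f$edges, graph$chain)
}
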