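# Model-level composition: protein encoder, two-chain combination, the
# transformer stack and the prediction head, plus full forward/backward for
# training.  Forward functions return caches consumed by the matching
# backward functions; public wrappers expose only the outputs.

# ---- protein encoder ------------------------------------------------------

enc_fwd <- function(bundle, p) {
  L <- bundle$L
  f_pair <- bundle$f_pair
  dim(f_pair) <- c(L * L, dim(bundle$f_pair)[3L])  # column-major (i,j) rows

  t_m <- trans_fwd(bundle$f_msa, p$t_msa)
  ln_m <- ln_fwd(t_m$out, p$ln_msa$g, p$ln_msa$b)
  t_s <- trans_fwd(bundle$f_struc, p$t_struc)
  ln_s <- ln_fwd(t_s$out, p$ln_struc$g, p$ln_struc$b)
  t_p <- trans_fwd(f_pair, p$t_pair)
  ln_p <- ln_fwd(t_p$out, p$ln_pair$g, p$ln_pair$b)

  resi <- cbind(ln_m$out, ln_s$out)
  t_r <- trans_fwd(resi, p$t_resi)
  t_e <- trans_fwd(ln_p$out, p$t_edge)

  list(
    nodes = t_r$out, edges = t_e$out, L = L,
    t_m = t_m, ln_m = ln_m, t_s = t_s, ln_s = ln_s,
    t_p = t_p, ln_p = ln_p, t_r = t_r, t_e = t_e,
    c_msa = ncol(bundle$f_msa)
  )
}

enc_bwd <- function(dnodes, dedges, cache, p) {
  gr <- trans_bwd(dnodes, cache$t_r, p$t_resi)
  ge <- trans_bwd(dedges, cache$t_e, p$t_edge)

  c_msa <- cache$c_msa
  d_ln_m_out <- gr$dx[, seq_len(c_msa), drop = FALSE]
  d_ln_s_out <- gr$dx[, (c_msa + 1L):ncol(gr$dx), drop = FALSE]

  gl_m <- ln_bwd(d_ln_m_out, cache$ln_m)
  gm <- trans_bwd(gl_m$dx, cache$t_m, p$t_msa)
  gl_s <- ln_bwd(d_ln_s_out, cache$ln_s)
  gs <- trans_bwd(gl_s$dx, cache$t_s, p$t_struc)
  gl_p <- ln_bwd(ge$dx, cache$ln_p)
  gp <- trans_bwd(gl_p$dx, cache$t_p, p$t_pair)

  list(grads = list(
    t_msa = gm$grads, ln_msa = list(g = gl_m$dg, b = gl_m$db),
    t_struc = gs$grads, ln_struc = list(g = gl_s$dg, b = gl_s$db),
    t_pair = gp$grads, ln_pair = list(g = gl_p$dg, b = gl_p$db),
    t_resi = gr$grads, t_edge = ge$grads
  ))
}

#' Encode a protein feature bundle into a residue graph
#'
#' The single and structure representations each pass through a transition
#' block and layer normalisation, are concatenated residue-wise and
#' projected to the node dimension; the pair representation passes through
#' a transition block and layer normalisation and is projected to
#' `c_e - 1` edge channels (the last edge channel is reserved for the
#' same-chain/different-chain indicator attached at combination).
#'
#' @param bundle A [feature_bundle()].
#' @param params Full model parameters from [init_params()] (the `enc`
#'   component is used).
#' @return Single-chain `codroplet_graph` with `c_e - 1` edge channels.
#' @export
encode_protein <- function(bundle, params) {
  stopifnot(inherits(bundle, "codroplet_bundle"))
  p <- if (!is.null(params$enc)) params$enc else params
  f <- enc_fwd(bundle, p)
  graph_rep(f$nodes, f$edges, rep(0L, f$L))
}

# ---- two-chain combination ------------------------------------------------

# Index bookkeeping for combining chains A (n_a residues) and B (n_b):
# combined pair row r = i + (j - 1) * n for pair (i, j), n = n_a + n_b.
combine_index <- function(n_a, n_b) {
  n <- n_a + n_b
  ia <- seq_len(n_a)
  ib <- n_a + seq_len(n_b)
  list(
    n = n,
    rows_aa = as.vector(outer(ia, ia, function(i, j) i + (j - 1L) * n)),
    rows_bb = as.vector(outer(ib, ib, function(i, j) i + (j - 1L) * n)),
    chain = c(rep(0L, n_a), rep(1L, n_b))
  )
}

#' Combine two encoded single-chain graphs into one complex
#'
#' Nodes are concatenated; intra-chain edge blocks carry the encoded
#' `c_e - 1` channels while inter-chain residue pairs are padded with zero
#' vectors in those channels; the reserved final channel is the binary
#' relative positional encoding: 1 where the two residues come from
#' different chains, 0 where they share a chain (including two copies of
#' the same protein, which still count as different chains).
#'
#' @param rep_a,rep_b Single-chain graphs from [encode_protein()].
#' @return Combined `codroplet_graph` with `c_e` edge channels.
#' @export
combine_complex <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "codroplet_graph"), inherits(rep_b, "codroplet_graph"))
  if (any(rep_a$chain != 0L) || any(rep_b$chain != 0L)) {
    stop("combine_complex expects single-chain inputs", call. = FALSE)
  }
  if (ncol(rep_a$edges) != ncol(rep_b$edges)) {
    stop("chains encoded with different edge widths", call. = FALSE)
  }
  n_a <- rep_a$n_res
  n_b <- rep_b$n_res
  ci <- combine_index(n_a, n_b)
  c_e <- ncol(rep_a$edges) + 1L

  nodes <- rbind(rep_a$nodes, rep_b$nodes)
  edges <- matrix(0, ci$n * ci$n, c_e)
  edges[ci$rows_aa, seq_len(c_e - 1L)] <- rep_a$edges
  edges[ci$rows_bb, seq_len(c_e - 1L)] <- rep_b$edges
  # chain indicator: 1 iff residues are on different chains
  same <- outer(ci$chain, ci$chain, `==`)
  edges[, c_e] <- as.numeric(!as.vector(same))
  graph_rep(nodes, edges, ci$chain)
}

# Route gradients of the combined graph back to the two chains.
combine_bwd <- function(dnodes, dedges, n_a, n_b) {
  ci <- combine_index(n_a, n_b)
  k <- ncol(dedges) - 1L
  list(
    dnodes_a = dnodes[seq_len(n_a), , drop = FALSE],
    dnodes_b = dnodes[n_a + seq_len(n_b), , drop = FALSE],
    dedges_a = dedges[ci$rows_aa, seq_len(k), drop = FALSE],
    dedges_b = dedges[ci$rows_bb, seq_len(k), drop = FALSE]
  )
}

# ---- transformer stack ----------------------------------------------------

layer_fwd <- function(nodes, edges, p, config, training) {
  att <- att_fwd(nodes, edges, p$att, config$n_head)
  dn <- drop_fwd(att$nodes, config$drop_attention, training)
  de <- drop_fwd(att$edges, config$drop_attention, training)
  n1 <- nodes + dn$out
  e1 <- edges + de$out

  ln_n <- ln_fwd(n1, p$ln_node$g, p$ln_node$b)
  tn <- trans_fwd(ln_n$out, p$t_node)
  dtn <- drop_fwd(tn$out, config$drop_transition, training)
  n2 <- n1 + dtn$out

  ln_e <- ln_fwd(e1, p$ln_edge$g, p$ln_edge$b)
  te <- trans_fwd(ln_e$out, p$t_edge)
  dte <- drop_fwd(te$out, config$drop_transition, training)
  e2 <- e1 + dte$out

  list(nodes = n2, edges = e2, att = att, dn = dn, de = de,
       ln_n = ln_n, tn = tn, dtn = dtn, ln_e = ln_e, te = te, dte = dte)
}

layer_bwd <- function(dnodes, dedges, cache, p) {
  # edge transition branch
  dte <- drop_bwd(dedges, cache$dte)
  gte <- trans_bwd(dte, cache$te, p$t_edge)
  gln_e <- ln_bwd(gte$dx, cache$ln_e)
  de1 <- dedges + gln_e$dx

  # node transition branch
  dtn <- drop_bwd(dnodes, cache$dtn)
  gtn <- trans_bwd(dtn, cache$tn, p$t_node)
  gln_n <- ln_bwd(gtn$dx, cache$ln_n)
  dn1 <- dnodes + gln_n$dx

  # attention branch
  datt_n <- drop_bwd(dn1, cache$dn)
  datt_e <- drop_bwd(de1, cache$de)
  gatt <- att_bwd(datt_n, datt_e, cache$att, p$att)

  list(
    dnodes = dn1 + gatt$dnodes,
    dedges = de1 + gatt$dedges,
    grads = list(
      att = gatt$grads,
      ln_node = list(g = gln_n$dg, b = gln_n$db),
      t_node = gtn$grads,
      ln_edge = list(g = gln_e$dg, b = gln_e$db),
      t_edge = gte$grads
    )
  )
}

stack_fwd <- function(nodes, edges, layers, config, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    cc <- layer_fwd(nodes, edges, layers[[i]], config, training)
    nodes <- cc$nodes
    edges <- cc$edges
    caches[[i]] <- cc
  }
  list(nodes = nodes, edges = edges, caches = caches)
}

stack_bwd <- function(dnodes, dedges, caches, layers) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- layer_bwd(dnodes, dedges, caches[[i]], layers[[i]])
    dnodes <- g$dnodes
    dedges <- g$dedges
    grads[[i]] <- g$grads
  }
  list(dnodes = dnodes, dedges = dedges, grads = grads)
}

#' Run the transformer stack over a combined residue graph
#'
#' Applies `n_layers` transformer blocks.  Each block adds the
#' self-attention output to the current nodes and edges through dropout,
#' then adds a node transition (on layer-normalised nodes) and an edge
#' transition residually, each through dropout.  With `training = FALSE`
#' dropout is the identity and the output is deterministic.
#'
#' @param graph Combined `codroplet_graph`.
#' @param params Full model parameters (the `layers` component is used).
#' @param config A [net_config()].
#' @param training Logical; enables dropout (the caller seeds the RNG).
#' @return Updated `codroplet_graph`.
#' @export
transformer_stack <- function(graph, params, config = net_config(),
                              training = FALSE) {
  stopifnot(inherits(graph, "codroplet_graph"))
  layers <- if (!is.null(params$layers)) params$layers else params
  f <- stack_fwd(graph$nodes, graph$edges, layers, config, training)
  graph_rep(f$nodes, f$edges, graph$chain)
}

# ---- prediction head ------------------------------------------------------

head_fwd <- function(nodes, p, config, training) {
  ln <- ln_fwd(nodes, p$ln$g, p$ln$b)
  dr <- drop_fwd(ln$out, config$drop_affinity, training)
  l1 <- lin_fwd(dr$out, p$W1, p$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- lin_fwd(r1$out, p$W2, p$b2)
  pooled <- colMeans(l2$out)

  pm <- matrix(pooled, nrow = 1L)
  l3 <- lin_fwd(pm, p$W3, p$b3)
  r3 <- relu_fwd(l3$out)
  l4 <- lin_fwd(r3$out, p$W4, p$b4)
  r4 <- relu_fwd(l4$out)
  l5 <- lin_fwd(r4$out, p$W5, p$b5)
  logit <- drop(l5$out)
  prob <- sigmoid(logit)

  list(prob = prob, pooled = pooled, logit = logit,
       ln = ln, dr = dr, l1 = l1, r1 = r1, l2 = l2,
       l3 = l3, r3 = r3, l4 = l4, r4 = r4, l5 = l5,
       n_res = nrow(nodes))
}

# Backward from dlogit (scalar gradient of the loss w.r.t. the pre-sigmoid
# logit; for cross-entropy this is prob - label).
head_bwd <- function(dlogit, cache, p) {
  g5 <- lin_bwd(matrix(dlogit, 1L, 1L), cache$l5, p$W5)
  dr4 <- relu_bwd(g5$dx, cache$r4)
  g4 <- lin_bwd(dr4, cache$l4, p$W4)
  dr3 <- relu_bwd(g4$dx, cache$r3)
  g3 <- lin_bwd(dr3, cache$l3, p$W3)
  dpooled <- drop(g3$dx)

  n <- cache$n_res
  dl2 <- matrix(rep(dpooled / n, each = n), n)
  g2 <- lin_bwd(dl2, cache$l2, p$W2)
  dr1 <- relu_bwd(g2$dx, cache$r1)
  g1 <- lin_bwd(dr1, cache$l1, p$W1)
  ddr <- drop_bwd(g1$dx, cache$dr)
  gln <- ln_bwd(ddr, cache$ln)

  list(
    dnodes = gln$dx,
    grads = list(
      ln = list(g = gln$dg, b = gln$db),
      W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
      W3 = g3$dW, b3 = g3$db, W4 = g4$dW, b4 = g4$db,
      W5 = g5$dW, b5 = g5$db
    )
  )
}

#' Co-condensation prediction head
#'
#' Projects every residue of the complex (layer-norm, dropout, two-layer
#' MLP), average-pools over all residues to a whole-complex representation,
#' and maps it through a three-layer MLP with sigmoid output to a
#' probability.  When a label is supplied, the binary cross-entropy loss is
#' returned, plus `l2_lambda` times the sum of squared weight-matrix
#' entries of the supplied parameters.
#'
#' @param graph `codroplet_graph` produced by the stack.
#' @param params Full model parameters (the `head` component is used; the
#'   L2 term sums over all weight matrices in `params`).
#' @param label Optional 0/1 label.
#' @param l2_lambda Nonnegative L2 coefficient.
#' @param config A [net_config()].
#' @param training Logical; enables head dropout.
#' @return List with `probability`, `pooled_repr` and (with a label) `loss`.
#' @export
pps_head <- function(graph, params, label = NULL, l2_lambda = 0,
                     config = net_config(), training = FALSE) {
  stopifnot(inherits(graph, "codroplet_graph"), l2_lambda >= 0)
  p <- if (!is.null(params$head)) params$head else params
  f <- head_fwd(graph$nodes, p, config, training)
  out <- list(probability = f$prob, pooled_repr = f$pooled)
  if (!is.null(label)) {
    if (!(length(label) == 1L && label %in% c(0, 1))) {
      stop("label must be 0 or 1", call. = FALSE)
    }
    out$loss <- bce_loss(f$prob, label) + l2_lambda * param_l2(params)
  }
  out
}

bce_loss <- function(prob, label) {
  eps <- 1e-12
  -label * log(prob + eps) - (1 - label) * log(1 - prob + eps)
}

# ---- full model -----------------------------------------------------------

model_fwd <- function(bundle_a, bundle_b, params, config, training = FALSE) {
  ea <- enc_fwd(bundle_a, params$enc)
  eb <- enc_fwd(bundle_b, params$enc)
  comb <- combine_complex(
    graph_rep(ea$nodes, ea$edges, rep(0L, ea$L)),
    graph_rep(eb$nodes, eb$edges, rep(0L, eb$L))
  )
  st <- stack_fwd(comb$nodes, comb$edges, params$layers, config, training)
  hd <- head_fwd(st$nodes, params$head, config, training)
  list(prob = hd$prob, ea = ea, eb = eb, st = st, hd = hd,
       n_a = ea$L, n_b = eb$L)
}

# Gradient of BCE(label) + l2_lambda * param_l2 w.r.t. all parameters.
model_bwd <- function(fwd, label, params, config, l2_lambda = 0) {
  dlogit <- fwd$prob - label
  gh <- head_bwd(dlogit, fwd$hd, params$head)
  n <- fwd$n_a + fwd$n_b
  dedges0 <- matrix(0, n * n, config$c_e)
  gs <- stack_bwd(gh$dnodes, dedges0, fwd$st$caches, params$layers)
  gc <- combine_bwd(gs$dnodes, gs$dedges, fwd$n_a, fwd$n_b)
  ga <- enc_bwd(gc$dnodes_a, gc$dedges_a, fwd$ea, params$enc)
  gb <- enc_bwd(gc$dnodes_b, gc$dedges_b, fwd$eb, params$enc)

  grads <- list(
    enc = param_add(ga$grads, gb$grads),
    layers = gs$grads,
    head = gh$grads
  )
  if (l2_lambda > 0) {
    grads <- param_add(grads, param_map(function(x) l2_lambda * x,
                                        param_l2_grad(params)))
  }
  grads
}

#' Score one protein pair
#'
#' Runs the full forward pipeline in evaluation mode: encode each bundle,
#' combine into a two-chain complex, run the transformer stack and the
#' prediction head.  With `symmetrize = TRUE` (the default, set in the
#' config) the score is the mean of the two chain orders, making the score
#' exactly order-free.
#'
#' @param bundle_a,bundle_b Feature bundles of the two proteins.
#' @param params Model parameters.
#' @param config A [net_config()].
#' @return Probability in (0, 1).
#' @export
predict_pair <- function(bundle_a, bundle_b, params, config = net_config()) {
  p1 <- model_fwd(bundle_a, bundle_b, params, config, training = FALSE)$prob
  if (!isTRUE(config$symmetrize)) return(p1)
  p2 <- model_fwd(bundle_b, bundle_a, params, config, training = FALSE)$prob
  (p1 + p2) / 2
}

#' Loss and gradient for one labelled pair
#'
#' Convenience wrapper used by the trainer and by gradient checks: full
#' forward pass plus backpropagation of the cross-entropy (+ L2) loss.
#'
#' @inheritParams predict_pair
#' @param label 0/1 label.
#' @param l2_lambda L2 coefficient.
#' @param training Logical; enables dropout (caller seeds the RNG).
#' @return List with `probability`, `loss`, and `grads` (same shape as
#'   `params`).
#' @export
pair_loss_grad <- function(bundle_a, bundle_b, label, params,
                           config = net_config(), l2_lambda = 0,
                           training = FALSE) {
  fwd <- model_fwd(bundle_a, bundle_b, params, config, training)
  grads <- model_bwd(fwd, label, params, config, l2_lambda)
  list(
    probability = fwd$prob,
    loss = bce_loss(fwd$prob, label) + l2_lambda * param_l2(params),
    grads = grads
  )
}
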