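# Batched forward/backward over a minibatch of pairs.  All row-wise
# operations (linear maps, layer norm, transitions, the per-residue head
# projection) run on matrices whose rows stack every protein or complex in
# the batch, so each weight matrix is read once per step; only the small
# N x N attention products and the pooling are per-graph loops.  Unique
# proteins are encoded once per batch even when several pairs share them.
#
# This path is used by the trainer and the batch scorer; it computes
# exactly the same function as the single-pair path (model_fwd/model_bwd),
# which serves as its reference in the tests.

batch_layout <- function(pair_ids, bundles) {
  uids <- unique(as.vector(t(pair_ids)))
  L <- vapply(uids, function(id) bundles[[id]]$L, integer(1L))
  names(L) <- uids
  node_off <- c(0L, cumsum(L))            # protein rows in encoder stacks
  pair_off <- c(0L, cumsum(L^2))
  B <- nrow(pair_ids)
  ia <- match(pair_ids[, 1L], uids)
  ib <- match(pair_ids[, 2L], uids)
  N <- L[ia] + L[ib]
  cn_off <- c(0L, cumsum(N))              # complex node rows
  ce_off <- c(0L, cumsum(N^2))            # complex edge rows
  list(uids = uids, L = L, node_off = node_off, pair_off = pair_off,
       B = B, ia = ia, ib = ib, N = N, cn_off = cn_off, ce_off = ce_off)
}

prot_node_rows <- function(lay, p) (lay$node_off[p] + 1L):lay$node_off[p + 1L]
prot_pair_rows <- function(lay, p) (lay$pair_off[p] + 1L):lay$pair_off[p + 1L]
cx_node_rows <- function(lay, k) (lay$cn_off[k] + 1L):lay$cn_off[k + 1L]
cx_edge_rows <- function(lay, k) (lay$ce_off[k] + 1L):lay$ce_off[k + 1L]

# ---- batched encoder ------------------------------------------------------

batch_enc_fwd <- function(lay, bundles, p) {
  msa <- do.call(rbind, lapply(lay$uids, function(id) bundles[[id]]$f_msa))
  struc <- do.call(rbind, lapply(lay$uids, function(id) bundles[[id]]$f_struc))
  pairf <- do.call(rbind, lapply(lay$uids, function(id) {
    fp <- bundles[[id]]$f_pair
    dim(fp) <- c(dim(fp)[1L]^2, dim(fp)[3L])
    fp
  }))

  t_m <- trans_fwd(msa, p$t_msa)
  ln_m <- ln_fwd(t_m$out, p$ln_msa$g, p$ln_msa$b)
  t_s <- trans_fwd(struc, p$t_struc)
  ln_s <- ln_fwd(t_s$out, p$ln_struc$g, p$ln_struc$b)
  t_p <- trans_fwd(pairf, p$t_pair)
  ln_p <- ln_fwd(t_p$out, p$ln_pair$g, p$ln_pair$b)

  resi <- cbind(ln_m$out, ln_s$out)
  t_r <- trans_fwd(resi, p$t_resi)
  t_e <- trans_fwd(ln_p$out, p$t_edge)

  list(nodes = t_r$out, edges = t_e$out,
       t_m = t_m, ln_m = ln_m, t_s = t_s, ln_s = ln_s,
       t_p = t_p, ln_p = ln_p, t_r = t_r, t_e = t_e,
       c_msa = ncol(msa))
}

batch_enc_bwd <- function(dnodes, dedges, cache, p) {
  gr <- trans_bwd(dnodes, cache$t_r, p$t_resi)
  ge <- trans_bwd(dedges, cache$t_e, p$t_edge)
  c_msa <- cache$c_msa
  gl_m <- ln_bwd(gr$dx[, seq_len(c_msa), drop = FALSE], cache$ln_m)
  gm <- trans_bwd(gl_m$dx, cache$t_m, p$t_msa)
  gl_s <- ln_bwd(gr$dx[, (c_msa + 1L):ncol(gr$dx), drop = FALSE], cache$ln_s)
  gs <- trans_bwd(gl_s$dx, cache$t_s, p$t_struc)
  gl_p <- ln_bwd(ge$dx, cache$ln_p)
  gp <- trans_bwd(gl_p$dx, cache$t_p, p$t_pair)
  list(
    t_msa = gm$grads, ln_msa = list(g = gl_m$dg, b = gl_m$db),
    t_struc = gs$grads, ln_struc = list(g = gl_s$dg, b = gl_s$db),
    t_pair = gp$grads, ln_pair = list(g = gl_p$dg, b = gl_p$db),
    t_resi = gr$grads, t_edge = ge$grads
  )
}

# ---- batched combination --------------------------------------------------

# For each pair, the intra-chain blocks of the complex edge matrix map
# 1:1 onto contiguous rows of the encoder edge stack; precompute both row
# index vectors once per batch.
batch_combine_index <- function(lay) {
  src <- integer(0)   # rows in encoder edge stack
  dst <- integer(0)   # rows in complex edge stack
  diff_chain <- rep(0, lay$ce_off[lay$B + 1L])
  for (k in seq_len(lay$B)) {
    a <- lay$ia[k]; b <- lay$ib[k]
    ci <- combine_index(lay$L[a], lay$L[b])
    off <- lay$ce_off[k]
    src <- c(src, prot_pair_rows(lay, a), prot_pair_rows(lay, b))
    dst <- c(dst, off + ci$rows_aa, off + ci$rows_bb)
    same <- outer(ci$chain, ci$chain, `==`)
    diff_chain[off + seq_len(ci$n^2)] <- as.numeric(!as.vector(same))
  }
  list(src = src, dst = dst, diff_chain = diff_chain)
}

batch_combine_fwd <- function(lay, enc_nodes, enc_edges, c_e, cidx) {
  nodes <- matrix(0, lay$cn_off[lay$B + 1L], ncol(enc_nodes))
  for (k in seq_len(lay$B)) {
    nodes[cx_node_rows(lay, k), ] <- rbind(
      enc_nodes[prot_node_rows(lay, lay$ia[k]), , drop = FALSE],
      enc_nodes[prot_node_rows(lay, lay$ib[k]), , drop = FALSE]
    )
  }
  edges <- matrix(0, lay$ce_off[lay$B + 1L], c_e)
  edges[cidx$dst, seq_len(c_e - 1L)] <- enc_edges[cidx$src, , drop = FALSE]
  edges[, c_e] <- cidx$diff_chain
  list(nodes = nodes, edges = edges)
}

batch_combine_bwd <- function(lay, dnodes, dedges, cidx) {
  denc_nodes <- matrix(0, lay$node_off[length(lay$uids) + 1L], ncol(dnodes))
  for (k in seq_len(lay$B)) {
    rows <- cx_node_rows(lay, k)
    na <- lay$L[lay$ia[k]]
    ra <- prot_node_rows(lay, lay$ia[k])
    rb <- prot_node_rows(lay, lay$ib[k])
    denc_nodes[ra, ] <- denc_nodes[ra, , drop = FALSE] +
      dnodes[rows[seq_len(na)], , drop = FALSE]
    denc_nodes[rb, ] <- denc_nodes[rb, , drop = FALSE] +
      dnodes[rows[(na + 1L):length(rows)], , drop = FALSE]
  }
  k_ch <- ncol(dedges) - 1L
  denc_edges <- matrix(0, lay$pair_off[length(lay$uids) + 1L], k_ch)
  # src rows are distinct only when no protein repeats; accumulate safely
  dslice <- dedges[cidx$dst, seq_len(k_ch), drop = FALSE]
  if (anyDuplicated(cidx$src)) {
    acc <- rowsum(dslice, cidx$src)
    denc_edges[as.integer(rownames(acc)), ] <- acc
  } else {
    denc_edges[cidx$src, ] <- dslice
  }
  list(dnodes = denc_nodes, dedges = denc_edges)
}

# ---- batched attention ----------------------------------------------------

batch_att_fwd <- function(lay, nodes, edges, p, n_head) {
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
  Bb <- el %*% p$Wb
  Gpre <- nl %*% p$Wg + rep(p$bg, each = nrow(nl))
  G <- sigmoid(Gpre)

  Alog <- matrix(0, nrow(el), n_head)
  Pmat <- matrix(0, nrow(el), n_head)
  PV <- matrix(0, nrow(nl), c_n)
  O <- matrix(0, nrow(nl), c_n)
  for (k in seq_len(lay$B)) {
    nr <- cx_node_rows(lay, k)
    er <- cx_edge_rows(lay, k)
    n <- lay$N[k]
    for (h in seq_len(n_head)) {
      idx <- ((h - 1L) * cp + 1L):(h * cp)
      A_h <- tcrossprod(Q[nr, idx, drop = FALSE],
                        K[nr, idx, drop = FALSE]) * scale
      Alog[er, h] <- as.vector(A_h)
      P_h <- softmax_rows(A_h + matrix(Bb[er, h], n, n))
      Pmat[er, h] <- as.vector(P_h)
      pv <- P_h %*% V[nr, idx, drop = FALSE]
      PV[nr, idx] <- pv
      O[nr, idx] <- G[nr, idx, drop = FALSE] * pv
    }
  }

  e1 <- lin_fwd(Alog, p$We1, p$be1)
  r1 <- relu_fwd(e1$out)
  e2 <- lin_fwd(r1$out, p$We2, p$be2)
  o_lin <- lin_fwd(O, p$Wo, p$bo)

  list(nodes = o_lin$out, edges = e2$out,
       ln_n = ln_n, ln_e = ln_e, Q = Q, K = K, V = V, B = Bb,
       G = G, Alog = Alog, Pmat = Pmat, PV = PV, O = O,
       e1 = e1, r1 = r1, e2 = e2, o_lin = o_lin,
       n_head = n_head, cp = cp, scale = scale)
}

batch_att_bwd <- function(lay, dnodes, dedges, cache, p) {
  n_head <- cache$n_head
  cp <- cache$cp
  scale <- cache$scale

  go <- lin_bwd(dnodes, cache$o_lin, p$Wo)
  dO <- go$dx
  ge2 <- lin_bwd(dedges, cache$e2, p$We2)
  dr1 <- relu_bwd(ge2$dx, cache$r1)
  ge1 <- lin_bwd(dr1, cache$e1, p$We1)
  dAlog_edge <- ge1$dx

  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(dO), ncol(dO))
  dV <- matrix(0, nrow(dO), ncol(dO))
  dB <- matrix(0, nrow(dedges), n_head)
  dG <- dO * cache$PV

  for (k in seq_len(lay$B)) {
    nr <- cx_node_rows(lay, k)
    er <- cx_edge_rows(lay, k)
    n <- lay$N[k]
    for (h in seq_len(n_head)) {
      idx <- ((h - 1L) * cp + 1L):(h * cp)
      P_h <- matrix(cache$Pmat[er, h], n, n)
      V_h <- cache$V[nr, idx, drop = FALSE]
      dPV_h <- dO[nr, idx, drop = FALSE] * cache$G[nr, idx, drop = FALSE]
      dP_h <- tcrossprod(dPV_h, V_h)
      dV[nr, idx] <- crossprod(P_h, dPV_h)
      dS_h <- softmax_rows_bwd(dP_h, P_h)
      dB[er, h] <- as.vector(dS_h)
      dA_h <- dS_h + matrix(dAlog_edge[er, h], n, n)
      dQ[nr, idx] <- (dA_h %*% cache$K[nr, idx, drop = FALSE]) * scale
      dK[nr, idx] <- crossprod(dA_h, cache$Q[nr, idx, drop = FALSE]) * scale
    }
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

# ---- batched stack layer --------------------------------------------------

batch_layer_fwd <- function(lay, nodes, edges, p, config, training) {
  att <- batch_att_fwd(lay, nodes, edges, p$att, config$n_head)
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

batch_layer_bwd <- function(lay, dnodes, dedges, cache, p) {
  dte <- drop_bwd(dedges, cache$dte)
  gte <- trans_bwd(dte, cache$te, p$t_edge)
  gln_e <- ln_bwd(gte$dx, cache$ln_e)
  de1 <- dedges + gln_e$dx
  dtn <- drop_bwd(dnodes, cache$dtn)
  gtn <- trans_bwd(dtn, cache$tn, p$t_node)
  gln_n <- ln_bwd(gtn$dx, cache$ln_n)
  dn1 <- dnodes + gln_n$dx
  datt_n <- drop_bwd(dn1, cache$dn)
  datt_e <- drop_bwd(de1, cache$de)
  gatt <- batch_att_bwd(lay, datt_n, datt_e, cache$att, p$att)
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

# ---- batched head ---------------------------------------------------------

batch_head_fwd <- function(lay, nodes, p, config, training) {
  ln <- ln_fwd(nodes, p$ln$g, p$ln$b)
  dr <- drop_fwd(ln$out, config$drop_affinity, training)
  l1 <- lin_fwd(dr$out, p$W1, p$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- lin_fwd(r1$out, p$W2, p$b2)
  group <- rep.int(seq_len(lay$B), lay$N)
  pooled <- rowsum(l2$out, group, reorder = TRUE) / lay$N
  l3 <- lin_fwd(pooled, p$W3, p$b3)
  r3 <- relu_fwd(l3$out)
  l4 <- lin_fwd(r3$out, p$W4, p$b4)
  r4 <- relu_fwd(l4$out)
  l5 <- lin_fwd(r4$out, p$W5, p$b5)
  probs <- unname(sigmoid(drop(l5$out)))
  list(probs = probs, ln = ln, dr = dr, l1 = l1, r1 = r1, l2 = l2,
       l3 = l3, r3 = r3, l4 = l4, r4 = r4, l5 = l5)
}

batch_head_bwd <- function(lay, dlogit, cache, p) {
  g5 <- lin_bwd(matrix(dlogit, ncol = 1L), cache$l5, p$W5)
  dr4 <- relu_bwd(g5$dx, cache$r4)
  g4 <- lin_bwd(dr4, cache$l4, p$W4)
  dr3 <- relu_bwd(g4$dx, cache$r3)
  g3 <- lin_bwd(dr3, cache$l3, p$W3)
  dpooled <- g3$dx / lay$N                       # B x c, row per complex
  dl2 <- dpooled[rep.int(seq_len(lay$B), lay$N), , drop = FALSE]
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

# ---- full batched model ---------------------------------------------------

batch_model_fwd <- function(pair_ids, bundles, params, config,
                            training = FALSE) {
  lay <- batch_layout(pair_ids, bundles)
  enc <- batch_enc_fwd(lay, bundles, params$enc)
  cidx <- batch_combine_index(lay)
  comb <- batch_combine_fwd(lay, enc$nodes, enc$edges, config$c_e, cidx)
  nodes <- comb$nodes
  edges <- comb$edges
  caches <- vector("list", config$n_layers)
  for (i in seq_len(config$n_layers)) {
    cc <- batch_layer_fwd(lay, nodes, edges, params$layers[[i]], config,
                          training)
    nodes <- cc$nodes
    edges <- cc$edges
    caches[[i]] <- cc
  }
  hd <- batch_head_fwd(lay, nodes, params$head, config, training)
  list(probs = hd$probs, lay = lay, enc = enc, cidx = cidx,
       layer_caches = caches, hd = hd)
}

# Mean-over-batch cross-entropy gradient (L2 handled by the optimiser).
batch_model_bwd <- function(fwd, labels, params, config) {
  lay <- fwd$lay
  dlogit <- (fwd$probs - labels) / lay$B
  gh <- batch_head_bwd(lay, dlogit, fwd$hd, params$head)
  dnodes <- gh$dnodes
  dedges <- matrix(0, lay$ce_off[lay$B + 1L], config$c_e)
  layer_grads <- vector("list", config$n_layers)
  for (i in rev(seq_len(config$n_layers))) {
    g <- batch_layer_bwd(lay, dnodes, dedges, fwd$layer_caches[[i]],
                         params$layers[[i]])
    dnodes <- g$dnodes
    dedges <- g$dedges
    layer_grads[[i]] <- g$grads
  }
  gc <- batch_combine_bwd(lay, dnodes, dedges, fwd$cidx)
  genc <- batch_enc_bwd(gc$dnodes, gc$dedges, fwd$enc, params$enc)
  list(enc = genc, layers = layer_grads, head = gh$grads)
}
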