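# Shared fixtures and independent oracle implementations.  The oracles are
# deliberately written as plain nested loops over residues, heads and
# channels, so they share no code path with the package's vectorised
# implementation.

tiny_config <- function(n_layers = 2L, n_head = 2L) {
  net_config(c_msa = 6L, c_pair = 5L, c_struc = 7L, c_n = 8L, c_e = 4L,
             n_head = n_head, n_layers = n_layers, edge_mlp_hidden = 4L,
             head_res_hidden = 6L, head_res_out = 5L, head_hidden = c(4L, 3L))
}

random_bundle <- function(id, L, seed, cfg = tiny_config()) {
  set.seed(seed)
  feature_bundle(
    id,
    matrix(rnorm(L * cfg$c_msa), L),
    array(rnorm(L * L * cfg$c_pair), c(L, L, cfg$c_pair)),
    matrix(rnorm(L * cfg$c_struc), L)
  )
}

random_graph <- function(N, c_n, c_e, seed) {
  set.seed(seed)
  graph_rep(matrix(rnorm(N * c_n), N), matrix(rnorm(N * N * c_e), N * N))
}

# edge matrices in the package are column-major flattened over (i, j)
edge_at <- function(edges, i, j, n) edges[i + (j - 1L) * n, ]

# ---- oracles --------------------------------------------------------------

oracle_layernorm <- function(x, g, b, eps = 1e-5) {
  t(apply(x, 1L, function(r) {
    mu <- mean(r)
    sd2 <- mean((r - mu)^2)
    g * (r - mu) / sqrt(sd2 + eps) + b
  }))
}

# Straight-line transition: layer norm, two-layer MLP with ReLU.
oracle_transition <- function(x, p) {
  h <- oracle_layernorm(x, p$ln$g, p$ln$b)
  h <- h %*% p$W1
  for (i in seq_len(nrow(h))) h[i, ] <- h[i, ] + p$b1
  h[h < 0] <- 0
  out <- h %*% p$W2
  for (i in seq_len(nrow(out))) out[i, ] <- out[i, ] + p$b2
  out
}

# Nested-loop gated self-attention with pair bias.  Follows the block
# definition element by element: per-head q/k/v and gates from the
# layer-normed nodes, scalar pair bias from the layer-normed edges, edge
# output from the pre-bias logits, node output from softmaxed biased
# logits with sigmoid gating.
oracle_attention <- function(nodes, edges, p, n_head) {
  N <- nrow(nodes)
  c_n <- ncol(nodes)
  cp <- c_n / n_head
  nl <- oracle_layernorm(nodes, p$ln_n$g, p$ln_n$b)
  el <- oracle_layernorm(edges, p$ln_e$g, p$ln_e$b)

  q <- array(0, c(N, n_head, cp))
  k <- array(0, c(N, n_head, cp))
  v <- array(0, c(N, n_head, cp))
  g <- array(0, c(N, n_head, cp))
  for (i in seq_len(N)) {
    for (h in seq_len(n_head)) {
      cols <- ((h - 1) * cp + 1):(h * cp)
      q[i, h, ] <- drop(nl[i, ] %*% p$Wq[, cols])
      k[i, h, ] <- drop(nl[i, ] %*% p$Wk[, cols])
      v[i, h, ] <- drop(nl[i, ] %*% p$Wv[, cols])
      g[i, h, ] <- 1 / (1 + exp(-(drop(nl[i, ] %*% p$Wg[, cols]) + p$bg[cols])))
    }
  }
  a <- array(0, c(N, N, n_head))
  bb <- array(0, c(N, N, n_head))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      for (h in seq_len(n_head)) {
        a[i, j, h] <- sum(q[i, h, ] * k[j, h, ]) / sqrt(cp)
        bb[i, j, h] <- sum(el[i + (j - 1) * N, ] * p$Wb[, h])
      }
    }
  }
  # edge output from pre-bias logits
  e_out <- matrix(0, N * N, length(p$be2))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      hvec <- drop(a[i, j, ] %*% p$We1) + p$be1
      hvec[hvec < 0] <- 0
      e_out[i + (j - 1) * N, ] <- drop(hvec %*% p$We2) + p$be2
    }
  }
  # node output
  n_out <- matrix(0, N, c_n)
  for (i in seq_len(N)) {
    o_concat <- numeric(0)
    for (h in seq_len(n_head)) {
      w <- exp(a[i, , h] + bb[i, , h])
      w <- w / sum(w)
      o_h <- numeric(cp)
      for (j in seq_len(N)) o_h <- o_h + w[j] * v[j, h, ]
      o_concat <- c(o_concat, g[i, h, ] * o_h)
    }
    n_out[i, ] <- drop(o_concat %*% p$Wo) + p$bo
  }
  list(nodes = n_out, edges = e_out)
}

# Fit a least-squares linear probe of a class label on summary features and
# report training accuracy (the planted-signal decodability oracle).
probe_accuracy <- function(features, classes) {
  y <- ifelse(classes == classes[1L], 1, -1)
  fit <- lm.fit(cbind(1, features), y)
  pred <- ifelse(cbind(1, features) %*% fit$coefficients > 0, 1, -1)
  mean(pred == y)
}

make_store <- function(records, clusters, cfg, seed = 1L, noise_sd = 0.1) {
  st <- feature_store(withr::local_tempdir(.local_envir = parent.frame()))
  featurize_records(records, st, clusters, noise_sd = noise_sd, seed = seed,
                    dims = cfg)
  st
}
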