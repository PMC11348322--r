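# Network blocks against independent nested-loop oracles, closed forms,
# and structural invariants.

test_that("transition matches closed forms and the straight-line oracle", {
  # zero weights and biases map anything to zero
  p0 <- init_transition_params(4L, 4L)
  p0$W1[] <- 0; p0$W2[] <- 0
  expect_equal(transition(rnorm(4), p0), rep(0, 4))

  # hidden width is c * n_expand
  set.seed(1)
  p <- init_transition_params(4L, 4L, n_expand = 4L)
  expect_equal(dim(p$W1), c(4L, 16L))

  # random instances match an independently coded LN + MLP composition,
  # for both the dimension-preserving and re-projecting forms
  for (case in list(c(5L, 5L), c(6L, 3L))) {
    set.seed(sum(case))
    pp <- init_transition_params(case[1L], case[2L], n_expand = 4L)
    x <- matrix(rnorm(4L * case[1L]), 4L)
    expect_equal(transition(x, pp, out_dim = case[2L]),
                 oracle_transition(x, pp), tolerance = 1e-6)
  }
  expect_error(transition(rnorm(5), p), "expects 4 input channels")
  expect_error(transition(rnorm(4), p, out_dim = 7L), "not 7")
})

test_that("self-attention with a single residue reduces to the gated value", {
  set.seed(3)
  p <- init_attention_params(8L, 4L, n_head = 2L)
  g <- random_graph(1L, 8L, 4L, seed = 4L)
  out <- self_attention(g, p, n_head = 2L)
  # softmax over a single j is 1, so the node update is gate * value
  nl <- oracle_layernorm(g$nodes, p$ln_n$g, p$ln_n$b)
  v <- drop(nl %*% p$Wv)
  gate <- 1 / (1 + exp(-(drop(nl %*% p$Wg) + p$bg)))
  expect_equal(drop(out$nodes), drop((gate * v) %*% p$Wo) + p$bo,
               tolerance = 1e-10)
})

test_that("self-attention matches the nested-loop oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- init_attention_params(8L, 4L, n_head = 2L)
    g <- random_graph(3L, 8L, 4L, seed = seed + 10L)
    out <- self_attention(g, p, n_head = 2L)
    ref <- oracle_attention(g$nodes, g$edges, p, n_head = 2L)
    expect_equal(out$nodes, ref$nodes, tolerance = 1e-6)
    expect_equal(out$edges, ref$edges, tolerance = 1e-6)
  }
  expect_error(self_attention(random_graph(2L, 8L, 4L, 1L),
                              init_attention_params(8L, 4L, 2L), n_head = 3L),
               "divide")
})

test_that("attention softmax rows sum to one for every residue and head", {
  set.seed(9)
  p <- init_attention_params(8L, 4L, n_head = 2L)
  g <- random_graph(5L, 8L, 4L, seed = 20L)
  f <- codroplet:::att_fwd(g$nodes, g$edges, p, 2L)
  for (h in 1:2) {
    P <- matrix(f$Pmat[, h], 5L, 5L)
    expect_equal(rowSums(P), rep(1, 5L), tolerance = 1e-6)
  }
})

test_that("encoder emits the contracted shapes and zero maps to zero", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 2L)
  b <- random_bundle("x", 5L, seed = 1L, cfg)
  g <- encode_protein(b, params)
  expect_equal(dim(g$nodes), c(5L, cfg$c_n))
  expect_equal(dim(g$edges), c(25L, cfg$c_e - 1L))

  # a zero bundle with zero biases encodes to zero (LN of a constant row is
  # zero once gains multiply a zero-centred input, biases being zero)
  pz <- codroplet:::param_map(function(x) x * 0, params)
  pz$enc$t_msa$ln$g[] <- 1; pz$enc$t_struc$ln$g[] <- 1
  pz$enc$t_pair$ln$g[] <- 1; pz$enc$t_resi$ln$g[] <- 1
  pz$enc$t_edge$ln$g[] <- 1
  bz <- feature_bundle("z", matrix(0, 4, cfg$c_msa),
                       array(0, c(4, 4, cfg$c_pair)),
                       matrix(0, 4, cfg$c_struc))
  gz <- encode_protein(bz, pz)
  expect_equal(max(abs(gz$nodes)), 0)
  expect_equal(max(abs(gz$edges)), 0)
})

test_that("encoding is permutation-equivariant in the residue index", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 7L)
  L <- 6L
  b <- random_bundle("x", L, seed = 3L, cfg)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  bp <- feature_bundle("x", b$f_msa[perm, ], b$f_pair[perm, perm, ],
                       b$f_struc[perm, ])
  g <- encode_protein(b, params)
  gp <- encode_protein(bp, params)
  expect_equal(gp$nodes, g$nodes[perm, ], tolerance = 1e-10)
  # permute-encode equals encode-permute on the pair grid
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      expect_equal(edge_at(gp$edges, i, j, L),
                   edge_at(g$edges, perm[i], perm[j], L), tolerance = 1e-10)
    }
  }
})

test_that("complex combination lays out blocks and the chain indicator exactly", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 5L)
  a <- encode_protein(random_bundle("a", 2L, 1L, cfg), params)
  b <- encode_protein(random_bundle("b", 3L, 2L, cfg), params)
  cx <- combine_complex(a, b)
  n <- 5L
  expect_equal(dim(cx$edges), c(25L, cfg$c_e))
  expect_equal(cx$chain, c(0L, 0L, 1L, 1L, 1L))
  expect_equal(cx$nodes, rbind(a$nodes, b$nodes))
  k <- cfg$c_e - 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      e <- edge_at(cx$edges, i, j, n)
      same <- (i <= 2L) == (j <= 2L)
      # reserved channel is exactly the cross-chain indicator
      expect_identical(e[cfg$c_e], as.numeric(!same))
      if (i <= 2L && j <= 2L) {
        expect_equal(e[1:k], edge_at(a$edges, i, j, 2L))
      } else if (i > 2L && j > 2L) {
        expect_equal(e[1:k], edge_at(b$edges, i - 2L, j - 2L, 3L))
      } else {
        expect_equal(e[1:k], rep(0, k))  # inter-chain padding
      }
    }
  }
  # two copies of the same protein still count as different chains
  cc <- combine_complex(a, a)
  expect_equal(matrix(cc$edges[, cfg$c_e], 4L, 4L),
               rbind(cbind(matrix(0, 2, 2), matrix(1, 2, 2)),
                     cbind(matrix(1, 2, 2), matrix(0, 2, 2))))
  expect_true(all(cx$edges[, cfg$c_e] %in% c(0, 1)))
  expect_error(combine_complex(cx, a), "single-chain")
})

test_that("the transformer stack is deterministic in eval mode and identity at depth zero", {
  cfg <- tiny_config(n_layers = 2L)
  params <- init_params(cfg, seed = 3L)
  cx <- combine_complex(
    encode_protein(random_bundle("a", 2L, 1L, cfg), params),
    encode_protein(random_bundle("b", 2L, 2L, cfg), params)
  )
  o1 <- transformer_stack(cx, params, cfg, training = FALSE)
  o2 <- transformer_stack(cx, params, cfg, training = FALSE)
  expect_identical(o1$nodes, o2$nodes)
  expect_identical(o1$edges, o2$edges)

  cfg0 <- tiny_config(n_layers = 0L)
  p0 <- init_params(cfg0, seed = 3L)
  o0 <- transformer_stack(cx, p0, cfg0, training = FALSE)
  expect_identical(o0$nodes, cx$nodes)
  expect_identical(o0$edges, cx$edges)
})

test_that("one stack layer equals the hand-composed attention+transition chain", {
  cfg <- tiny_config(n_layers = 1L)
  params <- init_params(cfg, seed = 9L)
  cx <- combine_complex(
    encode_protein(random_bundle("a", 2L, 4L, cfg), params),
    encode_protein(random_bundle("b", 2L, 5L, cfg), params)
  )
  out <- transformer_stack(cx, params, cfg, training = FALSE)

  lp <- params$layers[[1L]]
  att <- oracle_attention(cx$nodes, cx$edges, lp$att, cfg$n_head)
  n1 <- cx$nodes + att$nodes
  e1 <- cx$edges + att$edges
  n2 <- n1 + oracle_transition(oracle_layernorm(n1, lp$ln_node$g, lp$ln_node$b),
                               lp$t_node)
  e2 <- e1 + oracle_transition(oracle_layernorm(e1, lp$ln_edge$g, lp$ln_edge$b),
                               lp$t_edge)
  expect_equal(out$nodes, n2, tolerance = 1e-6)
  expect_equal(out$edges, e2, tolerance = 1e-6)
})

test_that("the prediction head obeys its closed forms and the pooling oracle", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 11L)
  cx <- combine_complex(
    encode_protein(random_bundle("a", 3L, 6L, cfg), params),
    encode_protein(random_bundle("b", 2L, 7L, cfg), params)
  )
  g <- transformer_stack(cx, params, cfg)

  # zero final weights: probability = sigmoid(final bias)
  pz <- params
  pz$head$W5[] <- 0
  pz$head$b5 <- 0.7
  expect_equal(pps_head(g, pz, config = cfg)$probability,
               1 / (1 + exp(-0.7)))
  pz$head$b5 <- 0
  expect_equal(pps_head(g, pz, config = cfg)$probability, 0.5)

  # cross-entropy closed form at p = 0.5
  out <- pps_head(g, pz, label = 1L, l2_lambda = 0, config = cfg)
  expect_equal(out$loss, -log(0.5), tolerance = 1e-6)

  # pooled vector is the arithmetic mean of per-residue projections
  hp <- params$head
  per_res <- matrix(0, 5L, cfg$head_res_out)
  ln <- oracle_layernorm(g$nodes, hp$ln$g, hp$ln$b)
  for (i in 1:5) {
    h1 <- drop(ln[i, ] %*% hp$W1) + hp$b1
    h1[h1 < 0] <- 0
    per_res[i, ] <- drop(h1 %*% hp$W2) + hp$b2
  }
  res <- pps_head(g, params, config = cfg)
  expect_equal(res$pooled_repr, colMeans(per_res), tolerance = 1e-6)
  expect_error(pps_head(g, params, label = 2, config = cfg), "label")
})

test_that("the loss adds the L2 weight penalty when configured", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 1L)
  cx <- combine_complex(
    encode_protein(random_bundle("a", 2L, 1L, cfg), params),
    encode_protein(random_bundle("b", 2L, 2L, cfg), params)
  )
  g <- transformer_stack(cx, params, cfg)
  l0 <- pps_head(g, params, label = 1L, l2_lambda = 0, config = cfg)$loss
  l1 <- pps_head(g, params, label = 1L, l2_lambda = 1e-3, config = cfg)$loss
  expect_equal(l1 - l0, 1e-3 * codroplet:::param_l2(params), tolerance = 1e-9)
})

test_that("pair prediction is bounded, symmetric and reproducible", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 21L)
  a <- random_bundle("a", 3L, 1L, cfg)
  b <- random_bundle("b", 4L, 2L, cfg)
  p_ab <- predict_pair(a, b, params, cfg)
  expect_gt(p_ab, 0)
  expect_lt(p_ab, 1)
  # symmetrized score is exactly order-free
  expect_identical(p_ab, predict_pair(b, a, params, cfg))
  # repeated eval-mode calls are bit-identical
  expect_identical(p_ab, predict_pair(a, b, params, cfg))
  # the architecture is intrinsically order-symmetric (no residue-position
  # encoding; the chain indicator is symmetric under swapping), so even the
  # unsymmetrized scores agree to numerical precision
  cfg_ns <- tiny_config()
  cfg_ns$symmetrize <- FALSE
  expect_equal(predict_pair(a, b, params, cfg_ns),
               predict_pair(b, a, params, cfg_ns), tolerance = 1e-9)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 42L)
  a <- random_bundle("a", 3L, 1L, cfg)
  b <- random_bundle("b", 2L, 2L, cfg)
  res <- pair_loss_grad(a, b, 1L, params, cfg, l2_lambda = 1e-3)
  flat <- codroplet:::param_flatten(params)
  gflat <- codroplet:::param_flatten(res$grads)
  set.seed(7)
  idx <- sample(length(flat), 10L)
  h <- 1e-5
  for (i in idx) {
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    lp <- pair_loss_grad(a, b, 1L,
                         codroplet:::param_unflatten(params, fp), cfg,
                         l2_lambda = 1e-3)$loss
    lm <- pair_loss_grad(a, b, 1L,
                         codroplet:::param_unflatten(params, fm), cfg,
                         l2_lambda = 1e-3)$loss
    num <- (lp - lm) / (2 * h)
    expect_equal(gflat[i], num, tolerance = 1e-3)
  }
})

test_that("the batched minibatch path reproduces the single-pair path exactly", {
  cfg <- tiny_config()
  params <- init_params(cfg, seed = 13L)
  bundles <- list(A = random_bundle("A", 3L, 1L, cfg),
                  B = random_bundle("B", 2L, 2L, cfg),
                  C = random_bundle("C", 4L, 3L, cfg))
  pid <- rbind(c("A", "B"), c("B", "C"), c("A", "A"), c("C", "A"))
  labels <- c(1, 0, 1, 0)
  fwd <- codroplet:::batch_model_fwd(pid, bundles, params, cfg)
  ref_probs <- vapply(1:4, function(i) {
    codroplet:::model_fwd(bundles[[pid[i, 1L]]], bundles[[pid[i, 2L]]],
                          params, cfg)$prob
  }, numeric(1L))
  expect_equal(fwd$probs, ref_probs, tolerance = 1e-12)

  bg <- codroplet:::param_flatten(
    codroplet:::batch_model_bwd(fwd, labels, params, cfg)
  )
  gsum <- NULL
  for (i in 1:4) {
    r <- pair_loss_grad(bundles[[pid[i, 1L]]], bundles[[pid[i, 2L]]],
                        labels[i], params, cfg)
    gsum <- if (is.null(gsum)) r$grads else
      codroplet:::param_add(gsum, r$grads)
  }
  expect_equal(bg, codroplet:::param_flatten(gsum) / 4, tolerance = 1e-10)
})

test_that("network configuration rejects inconsistent head geometry", {
  expect_error(net_config(c_n = 10L, n_head = 4L), "divisible")
  expect_error(init_attention_params(10L, 4L, 4L), "divisible")
})
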