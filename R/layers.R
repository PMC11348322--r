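# Numerical primitives for the network: linear maps, layer normalisation,
# activations, row softmax and dropout, each with a forward pass returning a
# cache and a matching backward pass.  All primitives operate on matrices
# whose rows are tokens (residues or residue pairs) and whose columns are
# channels, so every heavy step is a BLAS matrix product.
#
# Backward passes return gradients with respect to inputs and parameters;
# parameter gradients use the same names as the parameters themselves.

LN_EPS <- 1e-5

# ---- linear ---------------------------------------------------------------

lin_fwd <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  list(out = out, x = x)
}

lin_bwd <- function(dout, cache, W, has_bias = TRUE) {
  g <- list(
    dx = tcrossprod(dout, W),
    dW = crossprod(cache$x, dout)
  )
  if (has_bias) g$db <- colSums(dout)
  g
}

# ---- layer normalisation (per row, over channels) -------------------------

ln_fwd <- function(x, g, b, eps = LN_EPS) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = out, xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(dout, cache) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dxhat <- dout * rep(cache$g, each = n)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# ---- activations ----------------------------------------------------------

relu_fwd <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, mask = x > 0)
}

relu_bwd <- function(dout, cache) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max subtraction for stability.
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  p <- exp(x - m)
  p / rowSums(p)
}

softmax_rows_bwd <- function(dout, p) {
  p * (dout - rowSums(dout * p))
}

# ---- dropout --------------------------------------------------------------

# Inverted dropout.  Draws its mask from the current RNG state; callers seed
# the stream.  With training = FALSE (or rate 0) it is the identity.
drop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

drop_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# ---- parameter-tree helpers ----------------------------------------------

# Parameters are nested named lists of numeric arrays.  These helpers walk
# two trees of identical shape.

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

param_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) param_map(f, x))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

param_add <- function(a, b) param_map2(`+`, a, b)

param_zero_like <- function(a) param_map(function(x) x * 0, a)

param_flatten <- function(a) {
  if (is.list(a)) unlist(a, recursive = TRUE, use.names = FALSE)
  else as.numeric(a)
}

param_count <- function(a) length(param_flatten(a))

# Sum of squares over weight matrices only (names starting with "W");
# biases and layer-norm gains are excluded from L2 regularisation.
param_l2 <- function(a) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        if (is.list(x[[i]])) walk(x[[i]])
        else if (!is.null(nm) && startsWith(nm[i], "W")) {
          total <<- total + sum(x[[i]]^2)
        }
      }
    }
  }
  walk(a)
  total
}

# Gradient of param_l2: 2 * W on weight entries, zero elsewhere.
param_l2_grad <- function(a) {
  rec <- function(x, nm_self) {
    if (is.list(x)) {
      out <- mapply(rec, x, names(x) %||% rep("", length(x)),
                    SIMPLIFY = FALSE)
      names(out) <- names(x)
      out
    } else if (startsWith(nm_self, "W")) {
      2 * x
    } else {
      x * 0
    }
  }
  rec(a, "")
}

# Depth-first list of the tree's leaf vectors (no data copying; the list
# elements alias the tree's own vectors, which is what lets the optimiser
# update the tree in place).
param_leaves <- function(a) {
  out <- list()
  n <- 0L
  rec <- function(x) {
    if (is.list(x)) {
      for (el in x) rec(el)
    } else {
      n <<- n + 1L
      out[[n]] <<- x
    }
  }
  rec(a)
  out
}

# Per-leaf weight flag (1 for names starting with "W"), parallel to
# param_leaves() order.
param_leaf_wflags <- function(a) {
  out <- numeric(0)
  rec <- function(x, nm_self) {
    if (is.list(x)) {
      nms <- names(x) %||% rep("", length(x))
      for (i in seq_along(x)) rec(x[[i]], nms[i])
    } else {
      out[length(out) + 1L] <<- if (startsWith(nm_self, "W")) 1 else 0
    }
  }
  rec(a, "")
  out
}

# Deep copy of a parameter tree, so in-place optimisation never mutates a
# caller's object.
param_copy <- function(a) param_map(function(x) x + 0, a)

# Assign a flat numeric vector back into the tree (used by gradient checks).
param_unflatten <- function(template, values) {
  idx <- 0L
  rec <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rec)
      names(out) <- names(x)
      out
    } else {
      n <- length(x)
      v <- values[(idx + 1L):(idx + n)]
      idx <<- idx + n
      array(v, dim = dim(x) %||% n, dimnames = dimnames(x))
    }
  }
  out <- rec(template)
  stopifnot(idx == length(values))
  out
}
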