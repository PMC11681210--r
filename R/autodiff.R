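# Minimal reverse-mode automatic differentiation over dense 4-D tensors
# (height, width, channel, sample). Nodes are environments holding a value,
# an accumulated gradient, parent links and a backward closure; ad_backward()
# walks the tape in reverse topological order. Only what the network blocks
# need is implemented.

.ad_env <- new.env(parent = emptyenv())
.ad_env$id <- 0L

ad_next_id <- function() {
  .ad_env$id <- .ad_env$id + 1L
  .ad_env$id
}

new_node <- function(value, parents = list(), backfn = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$requires <- requires
  e$need <- requires ||
    any(vapply(parents, function(p) p$need, logical(1)))
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

ad_param <- function(value) new_node(value, requires = TRUE)
ad_const <- function(value) new_node(value)
is_node <- function(x) inherits(x, "ad_node")
node_value <- function(x) if (is_node(x)) x$value else x

# Reverse pass: accumulate d(loss)/d(node) into node$grad for every node on
# a path from a parameter to `loss` (a scalar node).
ad_backward <- function(loss) {
  post <- vector("list", 256L)
  k <- 0L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$id)
    if (!is.null(visited[[key]])) return(invisible(NULL))
    assign(key, TRUE, envir = visited)
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(post)) length(post) <<- 2L * k
    post[[k]] <<- n
    invisible(NULL)
  }
  visit(loss)
  loss$grad <- 1
  for (i in rev(seq_len(k))) {
    n <- post[[i]]
    if (is.null(n$backfn) || is.null(n$grad) || !n$need) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$need || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ----------------------------------------------------------

ad_relu <- function(x) {
  xv <- x$value
  v <- xv
  v[v < 0] <- 0
  new_node(v, list(x), function(g) list(g * (xv > 0)))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  new_node(v, list(x), function(g) list(g * v * (1 - v)))
}

ad_add <- function(x, y) {
  if (!identical(dim(x$value), dim(y$value)))
    stop_shape("elementwise add requires identical tensor shapes")
  new_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

# x * mask, where mask has either the same channel count as x or a single
# channel broadcast across all of x's channels.
ad_mul_mask <- function(x, m) {
  xv <- x$value
  mv <- m$value
  dx <- dim(xv)
  dm <- dim(mv)
  if (!identical(dx[c(1, 2, 4)], dm[c(1, 2, 4)]))
    stop_shape("attention mask spatial/batch shape must match the input")
  if (dm[3] == dx[3]) {
    new_node(xv * mv, list(x, m),
             function(g) list(g * mv, g * xv))
  } else if (dm[3] == 1L) {
    mb <- mv[, , rep(1L, dx[3]), , drop = FALSE]
    new_node(xv * mb, list(x, m), function(g) {
      dmf <- g * xv
      dm1 <- array(0, dm)
      for (c in seq_len(dx[3]))
        dm1 <- dm1 + dmf[, , c, , drop = FALSE]
      list(g * mb, dm1)
    })
  } else {
    stop_shape("mask channels must be 1 or match the input channels")
  }
}

# ---- channel concatenation ------------------------------------------------

ad_concat <- function(nodes) {
  vs <- lapply(nodes, function(n) n$value)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], integer(1))
  for (v in vs)
    if (!identical(dim(v)[c(1, 2, 4)], d1[c(1, 2, 4)]))
      stop_shape("concatenated feature maps must share spatial and batch shape")
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (i in seq_along(vs)) {
    out[, , off + seq_len(cs[i]), ] <- vs[[i]]
    off <- off + cs[i]
  }
  offsets <- cumsum(c(0L, cs))
  new_node(out, nodes, function(g) {
    lapply(seq_along(nodes), function(i)
      g[, , offsets[i] + seq_len(cs[i]), , drop = FALSE])
  })
}

# ---- convolutions and pooling --------------------------------------------

ad_conv2d <- function(x, w, b, dilation = 1L) {
  v <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(dilation))
  xv <- x$value
  wv <- w$value
  need_dx <- x$need
  new_node(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, as.integer(dilation), need_dx)
    list(if (need_dx) r$dx else NULL, r$dw, r$db)
  })
}

ad_convt2 <- function(x, w, b) {
  v <- cpp_convt2_fwd(x$value, w$value, b$value)
  xv <- x$value
  wv <- w$value
  new_node(v, list(x, w, b), function(g) {
    r <- cpp_convt2_bwd(xv, wv, g)
    list(r$dx, r$dw, r$db)
  })
}

ad_maxpool2 <- function(x) {
  r <- cpp_maxpool2_fwd(x$value)
  xd <- dim(x$value)
  new_node(r$y, list(x), function(g)
    list(cpp_maxpool2_bwd(r$idx, g, xd)))
}

ad_maxpool3_same <- function(x) {
  r <- cpp_maxpool3_same_fwd(x$value)
  xd <- dim(x$value)
  new_node(r$y, list(x), function(g)
    list(cpp_maxpool3_same_bwd(r$idx, g, xd)))
}

# ---- per-channel helpers --------------------------------------------------

# Broadcast a per-channel vector over (H, W, C, N): element (h,w,c,n) gets
# v[c]. Relies on column-major recycling over the batch dimension.
bc_chan <- function(v, d) rep(v, each = d[1] * d[2])

# Per-channel sum over (H, W, N).
sum_chan <- function(x) {
  cs <- colSums(x, dims = 2)
  if (is.matrix(cs)) rowSums(cs) else cs
}

# ---- batch normalization --------------------------------------------------

# `rs` is an environment with running `mean` and `var` (per channel),
# updated during training and used verbatim in inference mode.
ad_batchnorm <- function(x, gamma, beta, rs, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  gv <- gamma$value
  bv <- beta$value
  if (training) {
    m <- d[1] * d[2] * d[4]
    mu <- sum_chan(xv) / m
    va <- pmax(sum_chan(xv * xv) / m - mu^2, 0)
    istd <- 1 / sqrt(va + eps)
    xhat <- (xv - bc_chan(mu, d)) * bc_chan(istd, d)
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * va
    new_node(xhat * bc_chan(gv, d) + bc_chan(bv, d),
             list(x, gamma, beta), function(g) {
      dgamma <- sum_chan(g * xhat)
      dbeta <- sum_chan(g)
      dxhat <- g * bc_chan(gv, d)
      s1 <- sum_chan(dxhat)
      s2 <- sum_chan(dxhat * xhat)
      dx <- bc_chan(istd, d) *
        (dxhat - bc_chan(s1 / m, d) - xhat * bc_chan(s2 / m, d))
      list(dx, dgamma, dbeta)
    })
  } else {
    istd <- 1 / sqrt(rs$var + eps)
    xhat <- (xv - bc_chan(rs$mean, d)) * bc_chan(istd, d)
    new_node(xhat * bc_chan(gv, d) + bc_chan(bv, d),
             list(x, gamma, beta), function(g) {
      list(g * bc_chan(gv * istd, d), sum_chan(g * xhat), sum_chan(g))
    })
  }
}

# ---- dropout --------------------------------------------------------------

# Inverted dropout; identity in inference mode or at rate 0. Draws from the
# session RNG, so seeded training loops are reproducible.
ad_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (runif(length(x$value)) >= rate) / (1 - rate)
  dim(keep) <- dim(x$value)
  new_node(x$value * keep, list(x), function(g) list(g * keep))
}

# ---- global pooling, tiled back to the spatial grid -----------------------

ad_gmaxpool_tile <- function(x) {
  xv <- x$value
  d <- dim(xv)
  hw <- d[1] * d[2]
  xm <- matrix(xv, hw, d[3] * d[4])
  amax <- vapply(seq_len(ncol(xm)), function(j) which.max(xm[, j]), integer(1))
  mx <- xm[cbind(amax, seq_along(amax))]
  v <- array(rep(mx, each = hw), d)
  new_node(v, list(x), function(g) {
    s <- as.vector(colSums(g, dims = 2))
    dxm <- matrix(0, hw, d[3] * d[4])
    dxm[cbind(amax, seq_along(amax))] <- s
    list(array(dxm, d))
  })
}

ad_gavgpool_tile <- function(x) {
  xv <- x$value
  d <- dim(xv)
  hw <- d[1] * d[2]
  mu <- as.vector(colSums(xv, dims = 2)) / hw
  v <- array(rep(mu, each = hw), d)
  new_node(v, list(x), function(g) {
    s <- as.vector(colSums(g, dims = 2)) / hw
    list(array(rep(s, each = hw), d))
  })
}

# ---- binary cross-entropy -------------------------------------------------

# Mean negative Bernoulli log-likelihood in nats; probabilities clipped to
# [eps, 1 - eps] before the logs.
ad_bce <- function(p, y, eps = 1e-7) {
  pv <- p$value
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pc)
  v <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / n
  new_node(v, list(p), function(g) {
    inner <- (pc - y) / (pc * (1 - pc)) / n
    inner[pv < eps | pv > 1 - eps] <- 0
    dim(inner) <- dim(pv)
    list(g * inner)
  })
}
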