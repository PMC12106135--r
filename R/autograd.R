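# Minimal tape-free reverse-mode autodiff over base-R matrices.
#
# Every differentiable quantity is an `ag_node`: an environment holding a
# numeric matrix `value`, its parents, and a backward closure returning the
# parent gradients. The graph is rebuilt on every forward pass; parameters are
# persistent leaf nodes owned by a parameter store so gradients accumulate
# across the slices of a mini-batch.

new_ag_node <- function(value, parents = list(), bfun = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bfun <- bfun
  e$requires <- requires
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

ag_const <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  new_ag_node(x)
}

is_ag_node <- function(x) inherits(x, "ag_node")

ag_op <- function(value, parents, bfun) {
  req <- FALSE
  for (p in parents) if (isTRUE(p$requires)) { req <- TRUE; break }
  new_ag_node(value, parents, if (req) bfun else NULL, requires = req)
}

# ---- primitive operations ---------------------------------------------------

ag_mm <- function(a, b) {
  ag_op(a$value %*% b$value, list(a, b), function(g) {
    list(
      if (a$requires) tcrossprod(g, b$value),
      if (b$requires) crossprod(a$value, g)
    )
  })
}

# a %*% t(b)
ag_mmT <- function(a, b) {
  ag_op(tcrossprod(a$value, b$value), list(a, b), function(g) {
    list(
      if (a$requires) g %*% b$value,
      if (b$requires) crossprod(g, a$value)
    )
  })
}

ag_add <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_op(a$value + b$value, list(a, b), function(g) {
    list(if (a$requires) g, if (b$requires) g)
  })
}

# a: n x d, bias: 1 x d (broadcast over rows)
ag_add_bias <- function(a, bias) {
  bv <- as.vector(bias$value)
  ag_op(a$value + rep(bv, each = nrow(a$value)), list(a, bias), function(g) {
    list(
      if (a$requires) g,
      if (bias$requires) matrix(colSums(g), 1L)
    )
  })
}

ag_scale <- function(a, s) {
  ag_op(a$value * s, list(a), function(g) list(if (a$requires) g * s))
}

ag_relu <- function(a) {
  keep <- a$value > 0
  ag_op(a$value * keep, list(a), function(g) list(if (a$requires) g * keep))
}

ag_gelu <- function(a) {
  x <- a$value
  P <- stats::pnorm(x)
  ag_op(x * P, list(a), function(g) {
    list(if (a$requires) g * (P + x * stats::dnorm(x)))
  })
}

ag_softmax_rows <- function(a) {
  x <- a$value
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  S <- e / rowSums(e)
  ag_op(S, list(a), function(g) {
    list(if (a$requires) S * (g - rowSums(g * S)))
  })
}

# Row-wise layer normalization with learned gain/offset (1 x d each).
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  val <- xhat * rep(gv, each = nrow(x)) + rep(as.vector(beta$value), each = nrow(x))
  ag_op(val, list(a, gamma, beta), function(g) {
    dxhat <- g * rep(gv, each = nrow(g))
    list(
      if (a$requires) inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)),
      if (gamma$requires) matrix(colSums(g * xhat), 1L),
      if (beta$requires) matrix(colSums(g), 1L)
    )
  })
}

# Row gather (idx may contain duplicates).
ag_rows <- function(a, idx) {
  ag_op(a$value[idx, , drop = FALSE], list(a), function(g) {
    if (!a$requires) return(list(NULL))
    da <- matrix(0, nrow(a$value), ncol(a$value))
    acc <- rowsum(g, group = idx)
    da[as.integer(rownames(acc)), ] <- acc
    list(da)
  })
}

ag_rbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ag_op(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$requires) g[starts[i]:ends[i], , drop = FALSE]
    })
  })
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ag_op(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$requires) g[, starts[i]:ends[i], drop = FALSE]
    })
  })
}

# Bijective element rearrangement: out[k] = vec(a)[map[k]] (column-major).
ag_perm_elements <- function(a, map, nrow_out, ncol_out) {
  v <- a$value
  stopifnot(length(map) == length(v))
  ag_op(matrix(v[map], nrow_out, ncol_out), list(a), function(g) {
    if (!a$requires) return(list(NULL))
    gv <- numeric(length(v))
    gv[map] <- as.vector(g)
    list(matrix(gv, nrow(v), ncol(v)))
  })
}

# ---- backward pass ----------------------------------------------------------

.ag_env <- new.env(parent = emptyenv())
.ag_env$visit <- 0L

ag_backward <- function(root, grad_root) {
  if (!isTRUE(root$requires)) return(invisible(NULL))
  vid <- .ag_env$visit + 1L
  .ag_env$visit <- vid

  topo <- vector("list", 512L)
  n <- 0L
  visit <- function(nd) {
    if (identical(nd$.visited, vid)) return(invisible(NULL))
    nd$.visited <- vid
    for (p in nd$parents) if (isTRUE(p$requires)) visit(p)
    n <<- n + 1L
    if (n > length(topo)) topo[[2L * n]] <<- NULL
    topo[[n]] <<- nd
    invisible(NULL)
  }
  visit(root)

  root$grad <- if (is.null(root$grad)) grad_root else root$grad + grad_root
  for (i in rev(seq_len(n))) {
    nd <- topo[[i]]
    g <- nd$grad
    if (is.null(g) || is.null(nd$bfun)) next
    pg <- nd$bfun(g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    if (!identical(nd, root) && is.null(nd$is_param)) nd$grad <- NULL
  }
  invisible(NULL)
}

# ---- parameter store --------------------------------------------------------

new_param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  class(e) <- "ag_param_store"
  e
}

ps_add <- function(store, name, value, trainable = TRUE, group = "core") {
  if (!is.matrix(value)) value <- as.matrix(value)
  nd <- new_ag_node(value, requires = trainable)
  nd$is_param <- TRUE
  nd$name <- name
  nd$group <- group
  store$params[[name]] <- nd
  invisible(nd)
}

ps_get <- function(store, name) {
  nd <- store$params[[name]]
  if (is.null(nd)) stop("unknown parameter: ", name, call. = FALSE)
  nd
}

ps_names <- function(store) names(store$params)

ps_zero_grads <- function(store) {
  for (nd in store$params) nd$grad <- NULL
  invisible(NULL)
}

ps_set_trainable <- function(store, trainable_fun) {
  for (nd in store$params) nd$requires <- isTRUE(trainable_fun(nd$name, nd$group))
  invisible(NULL)
}

ps_count <- function(store, trainable_only = FALSE) {
  tot <- 0
  for (nd in store$params) {
    if (!trainable_only || isTRUE(nd$requires)) tot <- tot + length(nd$value)
  }
  tot
}

ps_state_dict <- function(store) lapply(store$params, function(nd) nd$value)

ps_load_state <- function(store, state) {
  for (nm in names(state)) {
    nd <- ps_get(store, nm)
    stopifnot(all(dim(nd$value) == dim(as.matrix(state[[nm]]))))
    nd$value <- as.matrix(state[[nm]])
  }
  invisible(NULL)
}

# ---- AdamW ------------------------------------------------------------------

adamw_new <- function(store, lr = 5e-5, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.1) {
  e <- new.env(parent = emptyenv())
  e$store <- store
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2
  e$eps <- eps; e$wd <- weight_decay
  e$t <- 0L
  e$m <- list(); e$v <- list()
  class(e) <- "adamw"
  e
}

adamw_step <- function(opt, grad_scale = 1) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nd in opt$store$params) {
    if (!isTRUE(nd$requires) || is.null(nd$grad)) next
    g <- nd$grad * grad_scale
    nm <- nd$name
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    nd$value <- nd$value - opt$lr * ((m / bc1) / (sqrt(v / bc2) + opt$eps) + opt$wd * nd$value)
  }
  invisible(NULL)
}

# ---- seeded RNG helpers -----------------------------------------------------

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage label,
# kept inside 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
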