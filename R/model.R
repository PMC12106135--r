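# Promptable segmentation model: a scale-configurable ViT image encoder with
# serial bottleneck adapters, a sparse prompt encoder, and a two-way
# cross-attention mask decoder. All forward passes run on the package's
# autodiff engine so adapters (and optionally the decoder) can be trained on
# CPU.

#' Image-encoder configuration
#'
#' @param image_size,patch_size Input side length and patch side length in
#'   pixels; `image_size` must be divisible by `patch_size`.
#' @param embed_dim Token embedding dimension d.
#' @param depth Number of transformer blocks.
#' @param heads Attention heads (must divide `embed_dim`).
#' @param global_attn_indices 0-based indices of blocks using global
#'   attention; remaining blocks use local windowed attention with window
#'   side `max(2, grid/4)` tokens.
#' @param mlp_ratio Hidden width of the MLP sub-layer as a multiple of d.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(image_size = 1024, patch_size = 16, embed_dim = 768,
                           depth = 12, heads = 12,
                           global_attn_indices = c(2, 5, 8, 11),
                           mlp_ratio = 4) {
  if (image_size %% patch_size != 0) {
    stop("image_size must be divisible by patch_size", call. = FALSE)
  }
  stopifnot(embed_dim %% heads == 0,
            all(global_attn_indices >= 0 & global_attn_indices < depth))
  structure(
    list(image_size = image_size, patch_size = patch_size,
         embed_dim = embed_dim, depth = depth, heads = heads,
         global_attn_indices = global_attn_indices, mlp_ratio = mlp_ratio),
    class = "encoder_config"
  )
}

#' Bottleneck adapter configuration
#'
#' @param m Bottleneck dimension (`0 < m <= embed_dim`). The default 100 is
#'   the dimension found to balance capacity and parameter count.
#' @param placement Character subset of
#'   `c("after_attention", "after_mlp")`: where each serial adapter sits
#'   inside every transformer block.
#' @param include_bias Include bias vectors in the two projections?
#' @return An `adapter_config` list.
#' @export
adapter_config <- function(m = 100,
                           placement = c("after_attention", "after_mlp"),
                           include_bias = TRUE) {
  placement <- match.arg(placement, several.ok = TRUE)
  stopifnot(m > 0)
  structure(list(m = as.integer(m), placement = placement,
                 include_bias = include_bias),
            class = "adapter_config")
}

#' Model presets
#'
#' `"vit_b"` is the ViT-B/16 geometry (patch 16, d = 768, 12 blocks, four
#' uniformly distributed global-attention blocks); `"tiny"` is a desk-scale
#' preset (image 64, patch 8, d = 64, 4 all-global blocks) that runs a full
#' forward/backward pass on CPU in well under a second.
#'
#' @param name `"vit_b"` or `"tiny"`.
#' @return An `encoder_config`.
#' @export
model_preset <- function(name = c("tiny", "vit_b")) {
  name <- match.arg(name)
  switch(name,
    vit_b = encoder_config(),
    tiny = encoder_config(image_size = 64, patch_size = 8, embed_dim = 64,
                          depth = 4, heads = 2, global_attn_indices = 0:3,
                          mlp_ratio = 4)
  )
}

# Xavier/Glorot-scaled random init for weight matrices; embeddings and
# adapter down-projections use a small fixed scale instead.
rand_mat <- function(nr, nc, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

#' Build a segmentation model
#'
#' Assembles encoder, sparse prompt encoder and mask decoder parameters into
#' one parameter store. `init = "zeros"` allocates all-zero weights (useful
#' for parameter accounting); `init = "random"` draws small random weights
#' with the given seed. Adapters are added separately via
#' [insert_adapters()].
#'
#' @param enc An [encoder_config()].
#' @param decoder_depth Number of two-way transformer blocks in the decoder.
#' @param init `"random"` or `"zeros"`.
#' @param seed Seed for random initialization.
#' @return A `seg_model` environment.
#' @export
build_model <- function(enc = model_preset("tiny"), decoder_depth = 2,
                        init = c("random", "zeros"), seed = 1L) {
  init <- match.arg(init)
  d <- enc$embed_dim
  p <- enc$patch_size
  g <- enc$image_size %/% p
  n <- g * g
  store <- new_param_store()
  mk <- if (init == "zeros") {
    function(nr, nc, sd = NULL) matrix(0, nr, nc)
  } else {
    rand_mat
  }
  # biases start at zero; embeddings and tokens at a small fixed scale
  mk0 <- function(nr, nc) matrix(0, nr, nc)
  emb <- function(nr, nc) mk(nr, nc, sd = 0.02)
  build <- function() {
    add <- function(name, value, group = "encoder") ps_add(store, name, value, group = group)
    add("enc.patch.W", mk(p * p, d))
    add("enc.patch.b", mk0(1, d))
    add("enc.pos", emb(n, d))
    dh <- d %/% enc$heads
    attn_params <- function(prefix, group, dim_q = d, dim_kv = d) {
      for (h in seq_len(enc$heads)) {
        add(paste0(prefix, ".h", h, ".Wq"), mk(dim_q, dh), group)
        add(paste0(prefix, ".h", h, ".Wk"), mk(dim_kv, dh), group)
        add(paste0(prefix, ".h", h, ".Wv"), mk(dim_kv, dh), group)
      }
      add(paste0(prefix, ".Wo"), mk(d, d), group)
      add(paste0(prefix, ".bo"), mk0(1, d), group)
    }
    ln_params <- function(prefix, group, width = d) {
      add(paste0(prefix, ".g"), matrix(1, 1, width), group)
      add(paste0(prefix, ".b"), matrix(0, 1, width), group)
    }
    for (i in seq_len(enc$depth)) {
      b <- paste0("enc.b", i)
      ln_params(paste0(b, ".ln1"), "encoder")
      attn_params(paste0(b, ".attn"), "encoder")
      ln_params(paste0(b, ".ln2"), "encoder")
      hid <- round(d * enc$mlp_ratio)
      add(paste0(b, ".mlp.W1"), mk(d, hid))
      add(paste0(b, ".mlp.b1"), mk0(1, hid))
      add(paste0(b, ".mlp.W2"), mk(hid, d))
      add(paste0(b, ".mlp.b2"), mk0(1, d))
    }
    # sparse prompt encoder: random Fourier positional basis + learned
    # per-type embeddings (foreground point, background point, two box
    # corners) + a padding token for empty prompt sets
    ps_add(store, "prompt.pe.B",
           if (init == "zeros") matrix(0, 2, d %/% 2) else rand_mat(2, d %/% 2, 1),
           group = "prompt")
    add("prompt.type.emb", emb(4, d), "prompt")
    add("prompt.pad", emb(1, d), "prompt")
    # mask decoder; the neck normalizes the encoder's residual stream before
    # cross-attention, as the embedding scale drifts with depth
    ln_params("dec.neck", "decoder")
    add("dec.token.mask", emb(1, d), "decoder")
    for (j in seq_len(decoder_depth)) {
      b <- paste0("dec.b", j)
      ln_params(paste0(b, ".ln_self"), "decoder")
      attn_params(paste0(b, ".self"), "decoder")
      ln_params(paste0(b, ".ln_t2i"), "decoder")
      attn_params(paste0(b, ".t2i"), "decoder")
      ln_params(paste0(b, ".ln_mlp"), "decoder")
      add(paste0(b, ".mlp.W1"), mk(d, 2 * d), "decoder")
      add(paste0(b, ".mlp.b1"), mk0(1, 2 * d), "decoder")
      add(paste0(b, ".mlp.W2"), mk(2 * d, d), "decoder")
      add(paste0(b, ".mlp.b2"), mk0(1, d), "decoder")
      ln_params(paste0(b, ".ln_i2t"), "decoder")
      attn_params(paste0(b, ".i2t"), "decoder")
    }
    c1 <- max(1L, d %/% 4L)
    c2 <- max(1L, d %/% 8L)
    add("dec.up1.W", mk(d, 4 * c1), "decoder")
    add("dec.up1.b", mk0(1, 4 * c1), "decoder")
    add("dec.up2.W", mk(c1, 4 * c2), "decoder")
    add("dec.up2.b", mk0(1, 4 * c2), "decoder")
    add("dec.hyper.W1", mk(d, d), "decoder")
    add("dec.hyper.b1", mk0(1, d), "decoder")
    add("dec.hyper.W2", mk(d, c2), "decoder")
    add("dec.hyper.b2", mk0(1, c2), "decoder")
    # output-logit bias initialized at the foreground prior (~10%), so early
    # training does not have to crush a half-probability field to background
    add("dec.out.bias",
        if (init == "zeros") matrix(0, 1, 1) else matrix(-2, 1, 1), "decoder")
  }
  if (init == "random") with_seed(seed, build()) else build()

  mdl <- new.env(parent = emptyenv())
  mdl$enc_cfg <- enc
  mdl$dec_depth <- decoder_depth
  mdl$adapter_cfg <- NULL
  mdl$store <- store
  mdl$policy <- "full"
  mdl$cache <- new.env(parent = emptyenv())
  class(mdl) <- "seg_model"
  freeze_policy(mdl, "full")
  mdl
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "<seg_model: image %d, patch %d, d=%d, depth %d; adapters: %s; policy %s>\n",
    x$enc_cfg$image_size, x$enc_cfg$patch_size, x$enc_cfg$embed_dim,
    x$enc_cfg$depth,
    if (is.null(x$adapter_cfg)) "none" else paste0("m=", x$adapter_cfg$m),
    x$policy))
  cat(sprintf("  parameters: %s total, %s trainable\n",
              format(ps_count(x$store), big.mark = ","),
              format(ps_count(x$store, TRUE), big.mark = ",")))
  invisible(x)
}

#' Insert serial bottleneck adapters into the encoder
#'
#' Adds one adapter after the attention sub-layer and/or one after the MLP
#' sub-layer of every transformer block, per `cfg$placement`. Down
#' projections are initialized with small random weights and up projections
#' with zeros, so the adapted encoder is functionally identical to the
#' unadapted one at initialization. Original weights are untouched.
#'
#' @param model A [build_model()] result.
#' @param cfg An [adapter_config()].
#' @param seed Seed for the down-projection initialization.
#' @return The model, invisibly (modified in place).
#' @export
insert_adapters <- function(model, cfg = adapter_config(), seed = 2L) {
  d <- model$enc_cfg$embed_dim
  if (cfg$m > d) stop("adapter bottleneck m exceeds embed_dim", call. = FALSE)
  with_seed(seed, {
    for (i in seq_len(model$enc_cfg$depth)) {
      for (site in cfg$placement) {
        tag <- if (site == "after_attention") "attn" else "mlp"
        pre <- paste0("enc.b", i, ".adapter.", tag)
        ps_add(model$store, paste0(pre, ".Wdown"), rand_mat(d, cfg$m),
               group = "adapter")
        ps_add(model$store, paste0(pre, ".Wup"), matrix(0, cfg$m, d),
               group = "adapter")
        if (cfg$include_bias) {
          ps_add(model$store, paste0(pre, ".bdown"), matrix(0, 1, cfg$m),
                 group = "adapter")
          ps_add(model$store, paste0(pre, ".bup"), matrix(0, 1, d),
                 group = "adapter")
        }
      }
    }
  })
  model$adapter_cfg <- cfg
  freeze_policy(model, model$policy)
  invisible(model)
}

#' Bottleneck adapter forward pass
#'
#' `W_up ReLU(W_down x + b_down) + b_up + x` applied per token (rows of
#' `x`); the residual term makes a zero `W_up` the identity.
#'
#' @param x Token-feature matrix `n x d`.
#' @param w List with `W_down` (`d x m`), `W_up` (`m x d`) and optional
#'   `b_down`, `b_up`.
#' @return `n x d` matrix.
#' @export
adapter_forward <- function(x, w) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(w$W_down) || ncol(w$W_down) != nrow(w$W_up) ||
      ncol(w$W_up) != ncol(x)) {
    stop("adapter weight shapes do not match input", call. = FALSE)
  }
  h <- x %*% w$W_down
  if (!is.null(w$b_down)) h <- h + rep(as.vector(w$b_down), each = nrow(h))
  out <- pmax(h, 0) %*% w$W_up
  if (!is.null(w$b_up)) out <- out + rep(as.vector(w$b_up), each = nrow(out))
  out + x
}

#' Apply a parameter-freezing policy
#'
#' `adapters_only` trains only adapter parameters; `adapters_plus_decoder`
#' additionally trains the mask decoder and prompt embeddings; `full` trains
#' everything. Frozen parameters are never touched by an optimizer step.
#'
#' @param model A `seg_model`.
#' @param policy Policy name.
#' @return The model, invisibly.
#' @export
freeze_policy <- function(model,
                          policy = c("adapters_only", "adapters_plus_decoder",
                                     "full")) {
  if (!policy[1] %in% c("adapters_only", "adapters_plus_decoder", "full")) {
    stop("unknown freeze policy: ", policy[1], call. = FALSE)
  }
  policy <- policy[1]
  ps_set_trainable(model$store, switch(policy,
    adapters_only = function(name, group) group == "adapter",
    adapters_plus_decoder = function(name, group) {
      group %in% c("adapter", "decoder", "prompt")
    },
    full = function(name, group) TRUE
  ))
  model$policy <- policy
  invisible(model)
}

#' Count trainable parameters
#'
#' @param model A `seg_model` with a freeze policy applied.
#' @param trainable_only Count only parameters marked trainable?
#' @return Integer-valued count.
#' @export
count_trainable_params <- function(model, trainable_only = TRUE) {
  ps_count(model$store, trainable_only)
}

# ---- forward passes ---------------------------------------------------------

# token-major (row-major over the g x g grid) patch pixel index table
patch_index <- function(image_size, patch_size) {
  g <- image_size %/% patch_size
  idx <- matrix(0L, g * g, patch_size * patch_size)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    t <- (i - 1L) * g + j
    rows <- ((i - 1L) * patch_size + 1L):(i * patch_size)
    cols <- ((j - 1L) * patch_size + 1L):(j * patch_size)
    # column-major order within the patch
    idx[t, ] <- as.integer(outer(rows, (cols - 1L) * image_size, "+"))
  }
  idx
}

mh_attention <- function(model, prefix, q_node, kv_node = NULL) {
  if (is.null(kv_node)) kv_node <- q_node
  st <- model$store
  heads <- model$enc_cfg$heads
  dh <- model$enc_cfg$embed_dim %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    Wq <- ps_get(st, paste0(prefix, ".h", h, ".Wq"))
    Wk <- ps_get(st, paste0(prefix, ".h", h, ".Wk"))
    Wv <- ps_get(st, paste0(prefix, ".h", h, ".Wv"))
    Q <- ag_mm(q_node, Wq)
    K <- ag_mm(kv_node, Wk)
    V <- ag_mm(kv_node, Wv)
    A <- ag_softmax_rows(ag_scale(ag_mmT(Q, K), 1 / sqrt(dh)))
    outs[[h]] <- ag_mm(A, V)
  }
  cat_ <- if (heads > 1) ag_cbind(outs) else outs[[1]]
  ag_add_bias(ag_mm(cat_, ps_get(st, paste0(prefix, ".Wo"))),
              ps_get(st, paste0(prefix, ".bo")))
}

ag_layernorm_p <- function(model, prefix, x) {
  ag_layernorm(x, ps_get(model$store, paste0(prefix, ".g")),
               ps_get(model$store, paste0(prefix, ".b")))
}

ag_adapter <- function(model, block, tag, x) {
  cfg <- model$adapter_cfg
  site <- if (tag == "attn") "after_attention" else "after_mlp"
  if (is.null(cfg) || !(site %in% cfg$placement)) return(x)
  st <- model$store
  pre <- paste0("enc.b", block, ".adapter.", tag)
  h <- ag_mm(x, ps_get(st, paste0(pre, ".Wdown")))
  if (cfg$include_bias) h <- ag_add_bias(h, ps_get(st, paste0(pre, ".bdown")))
  out <- ag_mm(ag_relu(h), ps_get(st, paste0(pre, ".Wup")))
  if (cfg$include_bias) out <- ag_add_bias(out, ps_get(st, paste0(pre, ".bup")))
  ag_add(out, x)
}

# window partition of the token grid (row-major token order); returns list of
# index vectors plus the order restoring the original sequence
window_partition <- function(g, w) {
  stopifnot(g %% w == 0)
  nwin <- g %/% w
  idx <- list()
  for (wi in seq_len(nwin)) for (wj in seq_len(nwin)) {
    rows <- ((wi - 1) * w + 1):(wi * w)
    cols <- ((wj - 1) * w + 1):(wj * w)
    idx[[length(idx) + 1L]] <- as.integer(outer((rows - 1L) * g, cols, "+"))
  }
  ord <- order(unlist(idx))
  list(windows = idx, restore = ord)
}

encoder_block <- function(model, i, x) {
  enc <- model$enc_cfg
  g <- enc$image_size %/% enc$patch_size
  h <- ag_layernorm_p(model, paste0("enc.b", i, ".ln1"), x)
  global <- (i - 1L) %in% enc$global_attn_indices
  wside <- max(2L, g %/% 4L)
  if (!global && g %% wside == 0 && wside < g) {
    key <- paste0("win", g, "_", wside)
    wp <- model$cache[[key]]
    if (is.null(wp)) {
      wp <- window_partition(g, wside)
      model$cache[[key]] <- wp
    }
    parts <- lapply(wp$windows, function(ix) {
      mh_attention(model, paste0("enc.b", i, ".attn"), ag_rows(h, ix))
    })
    a <- ag_rows(ag_rbind(parts), wp$restore)
  } else {
    a <- mh_attention(model, paste0("enc.b", i, ".attn"), h)
  }
  a <- ag_adapter(model, i, "attn", a)
  x <- ag_add(x, a)
  h2 <- ag_layernorm_p(model, paste0("enc.b", i, ".ln2"), x)
  st <- model$store
  b <- paste0("enc.b", i)
  m <- ag_add_bias(ag_mm(h2, ps_get(st, paste0(b, ".mlp.W1"))),
                   ps_get(st, paste0(b, ".mlp.b1")))
  m <- ag_add_bias(ag_mm(ag_gelu(m), ps_get(st, paste0(b, ".mlp.W2"))),
                   ps_get(st, paste0(b, ".mlp.b2")))
  m <- ag_adapter(model, i, "mlp", m)
  ag_add(x, m)
}

#' Encode an image into a patch-embedding grid
#'
#' @param model A `seg_model`.
#' @param image Numeric matrix of side `image_size` with values in `[0, 1]`.
#' @param as_node Return the autodiff node (internal use) instead of the
#'   numeric matrix?
#' @return `n_tokens x d` embedding matrix (row-major token order over the
#'   grid), or its node.
#' @export
encode_image <- function(model, image, as_node = FALSE) {
  enc <- model$enc_cfg
  image <- as.matrix(image)
  if (nrow(image) != enc$image_size || ncol(image) != enc$image_size) {
    stop(sprintf("image must be %d x %d", enc$image_size, enc$image_size),
         call. = FALSE)
  }
  key <- paste0("pidx", enc$image_size, "_", enc$patch_size)
  pidx <- model$cache[[key]]
  if (is.null(pidx)) {
    pidx <- patch_index(enc$image_size, enc$patch_size)
    model$cache[[key]] <- pidx
  }
  X <- matrix(image[pidx], nrow(pidx), ncol(pidx))
  st <- model$store
  x <- ag_add(
    ag_add_bias(ag_mm(ag_const(X), ps_get(st, "enc.patch.W")),
                ps_get(st, "enc.patch.b")),
    ps_get(st, "enc.pos")
  )
  for (i in seq_len(enc$depth)) x <- encoder_block(model, i, x)
  if (as_node) x else x$value
}

#' Construct a sparse prompt set
#'
#' @param points Data frame with columns `x`, `y` (pixel coordinates) and
#'   `label` (`"foreground"` or `"background"`), or `NULL`.
#' @param boxes Data frame with columns `x0`, `y0`, `x1`, `y1`
#'   (`x0 < x1`, `y0 < y1`), or `NULL`.
#' @return A `prompt_set`.
#' @export
prompt_set <- function(points = NULL, boxes = NULL) {
  if (!is.null(points)) {
    stopifnot(all(c("x", "y", "label") %in% names(points)),
              all(points$label %in% c("foreground", "background")))
  }
  if (!is.null(boxes)) {
    stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(boxes)),
              all(boxes$x0 < boxes$x1), all(boxes$y0 < boxes$y1))
  }
  structure(list(points = points, boxes = boxes), class = "prompt_set")
}

fourier_pe <- function(B, xy01) {
  # xy01: k x 2 coordinates in [0,1]; B: 2 x (d/2)
  proj <- 2 * pi * (as.matrix(xy01) %*% B)
  cbind(sin(proj), cos(proj))
}

#' Encode sparse prompts
#'
#' Each point yields one token (positional encoding plus the learned
#' foreground/background embedding); each box yields two corner tokens. An
#' empty prompt set yields the learned padding token.
#'
#' @param model A `seg_model`.
#' @param prompts A [prompt_set()].
#' @param as_node Return the autodiff node?
#' @return `k x d` sparse embedding matrix (or node).
#' @export
encode_prompts <- function(model, prompts = prompt_set(), as_node = FALSE) {
  sz <- model$enc_cfg$image_size
  st <- model$store
  coords <- NULL
  types <- integer(0)
  if (!is.null(prompts$points) && nrow(prompts$points)) {
    if (any(prompts$points$x < 0 | prompts$points$x > sz |
            prompts$points$y < 0 | prompts$points$y > sz)) {
      stop("point prompt outside image bounds", call. = FALSE)
    }
    coords <- rbind(coords, cbind(prompts$points$x, prompts$points$y))
    types <- c(types, ifelse(prompts$points$label == "foreground", 1L, 2L))
  }
  if (!is.null(prompts$boxes) && nrow(prompts$boxes)) {
    b <- prompts$boxes
    if (any(b$x0 < 0 | b$y0 < 0 | b$x1 > sz | b$y1 > sz)) {
      stop("box prompt outside image bounds", call. = FALSE)
    }
    for (r in seq_len(nrow(b))) {
      coords <- rbind(coords, c(b$x0[r], b$y0[r]), c(b$x1[r], b$y1[r]))
      types <- c(types, 3L, 4L)
    }
  }
  if (is.null(coords)) {
    nd <- ps_get(st, "prompt.pad")
    return(if (as_node) nd else nd$value)
  }
  pe <- fourier_pe(ps_get(st, "prompt.pe.B")$value, coords / sz)
  nd <- ag_add(ag_const(pe), ag_rows(ps_get(st, "prompt.type.emb"), types))
  if (as_node) nd else nd$value
}

# dense positional-encoding grid for the image embedding (token-major)
image_pe_grid <- function(model) {
  enc <- model$enc_cfg
  g <- enc$image_size %/% enc$patch_size
  key <- paste0("imgpe", g)
  pe <- model$cache[[key]]
  if (is.null(pe)) {
    ctr <- (seq_len(g) - 0.5) / g
    xy <- cbind(rep(ctr, each = g), rep(ctr, times = g))  # row-major tokens
    # token t = (i-1)*g + j: x = col center j, y = row center i
    xy <- cbind(rep(ctr, times = g), rep(ctr, each = g))
    pe <- fourier_pe(ps_get(model$store, "prompt.pe.B")$value, xy)
    model$cache[[key]] <- pe
  }
  pe
}

# pixel-shuffle element map: (g^2 x 4c) -> ((2g)^2 x c), both token-major
shuffle_map <- function(g, c_out) {
  n_in <- g * g
  g2 <- 2L * g
  map <- integer(g2 * g2 * c_out)
  for (ch in seq_len(c_out)) for (s in 1:4) {
    di <- if (s <= 2) 1L else 2L
    dj <- if (s %% 2 == 1) 1L else 2L
    col_in <- (s - 1L) * c_out + ch
    for (i in seq_len(g)) for (j in seq_len(g)) {
      t_in <- (i - 1L) * g + j
      o <- (2L * (i - 1L) + di - 1L) * g2 + (2L * (j - 1L) + dj - 1L) + 1L
      map[(ch - 1L) * g2 * g2 + o] <- (col_in - 1L) * n_in + t_in
    }
  }
  map
}

# dense bilinear upsampling matrix from a (g x g) token-major grid to an
# (H x H) row-major pixel grid
bilinear_upsample_matrix <- function(g, H) {
  f <- H / g
  M <- matrix(0, H * H, g * g)
  pos <- (seq_len(H) - 0.5) / f + 0.5
  lo <- pmin(pmax(floor(pos), 1), g)
  hi <- pmin(lo + 1, g)
  fr <- pmin(pmax(pos - lo, 0), 1)
  for (r in seq_len(H)) for (cc in seq_len(H)) {
    q <- (r - 1L) * H + cc
    for (a in 1:2) for (b in 1:2) {
      gi <- if (a == 1) lo[r] else hi[r]
      gj <- if (b == 1) lo[cc] else hi[cc]
      wgt <- (if (a == 1) 1 - fr[r] else fr[r]) *
        (if (b == 1) 1 - fr[cc] else fr[cc])
      t <- (gi - 1L) * g + gj
      M[q, t] <- M[q, t] + wgt
    }
  }
  M
}

decoder_block <- function(model, j, tok, img) {
  b <- paste0("dec.b", j)
  st <- model$store
  tok <- ag_add(tok, mh_attention(model, paste0(b, ".self"),
                                  ag_layernorm_p(model, paste0(b, ".ln_self"), tok)))
  tok <- ag_add(tok, mh_attention(model, paste0(b, ".t2i"),
                                  ag_layernorm_p(model, paste0(b, ".ln_t2i"), tok),
                                  img))
  h <- ag_layernorm_p(model, paste0(b, ".ln_mlp"), tok)
  h <- ag_add_bias(ag_mm(h, ps_get(st, paste0(b, ".mlp.W1"))),
                   ps_get(st, paste0(b, ".mlp.b1")))
  h <- ag_add_bias(ag_mm(ag_gelu(h), ps_get(st, paste0(b, ".mlp.W2"))),
                   ps_get(st, paste0(b, ".mlp.b2")))
  tok <- ag_add(tok, h)
  img <- ag_add(img, mh_attention(model, paste0(b, ".i2t"),
                                  ag_layernorm_p(model, paste0(b, ".ln_i2t"), img),
                                  tok))
  list(tok = tok, img = img)
}

#' Decode a mask from image and prompt embeddings
#'
#' Runs the two-way transformer (token-to-image and image-to-token
#' attention), upsamples the image embedding with two learned pixel-shuffle
#' stages, maps the mask token through the hypernetwork MLP into a dynamic
#' per-pixel classifier, and bilinearly upsamples the resulting logit grid to
#' the input resolution.
#'
#' @param model A `seg_model`.
#' @param image_embedding Node or matrix from [encode_image()].
#' @param sparse_embeddings Node or matrix from [encode_prompts()].
#' @param as_node Return the logits node?
#' @return `image_size x image_size` logit matrix (or its node, as an
#'   `H*W x 1` column in row-major pixel order).
#' @export
decode_mask <- function(model, image_embedding, sparse_embeddings,
                        as_node = FALSE) {
  enc <- model$enc_cfg
  d <- enc$embed_dim
  g <- enc$image_size %/% enc$patch_size
  if (!is_ag_node(image_embedding)) image_embedding <- ag_const(image_embedding)
  if (!is_ag_node(sparse_embeddings)) sparse_embeddings <- ag_const(sparse_embeddings)
  if (ncol(image_embedding$value) != d || ncol(sparse_embeddings$value) != d) {
    stop("embedding dimension mismatch", call. = FALSE)
  }
  st <- model$store
  tok <- ag_rbind(list(ps_get(st, "dec.token.mask"), sparse_embeddings))
  img <- ag_layernorm_p(model, "dec.neck", image_embedding)
  img <- ag_add(img, ag_const(image_pe_grid(model)))
  for (j in seq_len(model$dec_depth)) {
    bl <- decoder_block(model, j, tok, img)
    tok <- bl$tok; img <- bl$img
  }
  c1 <- max(1L, d %/% 4L); c2 <- max(1L, d %/% 8L)
  key1 <- paste0("shuf", g, "_", c1); key2 <- paste0("shuf", 2 * g, "_", c2)
  if (is.null(model$cache[[key1]])) model$cache[[key1]] <- shuffle_map(g, c1)
  if (is.null(model$cache[[key2]])) model$cache[[key2]] <- shuffle_map(2L * g, c2)
  u <- ag_add_bias(ag_mm(img, ps_get(st, "dec.up1.W")), ps_get(st, "dec.up1.b"))
  u <- ag_gelu(ag_perm_elements(u, model$cache[[key1]], 4L * g * g, c1))
  u <- ag_add_bias(ag_mm(u, ps_get(st, "dec.up2.W")), ps_get(st, "dec.up2.b"))
  u <- ag_gelu(ag_perm_elements(u, model$cache[[key2]], 16L * g * g, c2))
  mt <- ag_rows(tok, 1L)
  w <- ag_add_bias(ag_mm(mt, ps_get(st, "dec.hyper.W1")), ps_get(st, "dec.hyper.b1"))
  w <- ag_add_bias(ag_mm(ag_gelu(w), ps_get(st, "dec.hyper.W2")),
                   ps_get(st, "dec.hyper.b2"))
  low <- ag_add_bias(ag_mmT(u, w), ps_get(st, "dec.out.bias"))
  keyu <- paste0("bilin", 4 * g, "_", enc$image_size)
  if (is.null(model$cache[[keyu]])) {
    model$cache[[keyu]] <- bilinear_upsample_matrix(4L * g, enc$image_size)
  }
  logits <- ag_mm(ag_const(model$cache[[keyu]]), low)
  if (as_node) return(logits)
  matrix(logits$value, enc$image_size, enc$image_size, byrow = TRUE)
}

#' Whole-image box prompt
#'
#' The default fully automatic prompt: one box spanning the entire image.
#'
#' @param model A `seg_model`.
#' @return A [prompt_set()].
#' @export
whole_image_prompt <- function(model) {
  sz <- model$enc_cfg$image_size
  prompt_set(boxes = data.frame(x0 = 0, y0 = 0, x1 = sz, y1 = sz))
}

#' Bounding-box prompt from a ground-truth mask
#'
#' Tight box around the positive pixels, dilated by `margin` pixels and
#' clipped to the image; falls back to the whole-image box for an empty mask.
#'
#' @param model A `seg_model`.
#' @param mask Binary matrix.
#' @param margin Dilation margin in pixels.
#' @return A [prompt_set()].
#' @export
mask_box_prompt <- function(model, mask, margin = 3) {
  idx <- which(as.matrix(mask) > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(whole_image_prompt(model))
  sz <- model$enc_cfg$image_size
  prompt_set(boxes = data.frame(
    x0 = max(0, min(idx[, 2]) - 1 - margin),
    y0 = max(0, min(idx[, 1]) - 1 - margin),
    x1 = min(sz, max(idx[, 2]) + margin),
    y1 = min(sz, max(idx[, 1]) + margin)
  ))
}

#' Full forward pass: image to logits node
#'
#' @param model A `seg_model`.
#' @param image Preprocessed slice (matrix in `[0, 1]`).
#' @param prompts A [prompt_set()]; defaults to the whole-image box.
#' @return Logits node (`H*W x 1`, row-major pixel order).
#' @export
forward_logits <- function(model, image, prompts = NULL) {
  if (is.null(prompts)) prompts <- whole_image_prompt(model)
  emb <- encode_image(model, image, as_node = TRUE)
  sp <- encode_prompts(model, prompts, as_node = TRUE)
  decode_mask(model, emb, sp, as_node = TRUE)
}

#' Predict a segmentation mask
#'
#' @inheritParams forward_logits
#' @param threshold Probability threshold for binarization.
#' @return List with `prob` (matrix in `(0, 1)`) and `mask` (binary matrix).
#' @export
predict_mask <- function(model, image, prompts = NULL, threshold = 0.5) {
  node <- forward_logits(model, image, prompts)
  H <- model$enc_cfg$image_size
  prob <- matrix(stats::plogis(node$value), H, H, byrow = TRUE)
  list(prob = prob, mask = (prob >= threshold) * 1L)
}

#' Save / load model checkpoints
#'
#' Checkpoints are flat name-to-array archives (the parameter store's state
#' dict) plus the configurations needed to rebuild the model.
#'
#' @param model A `seg_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(
    state = ps_state_dict(model$store),
    enc_cfg = model$enc_cfg,
    dec_depth = model$dec_depth,
    adapter_cfg = model$adapter_cfg,
    policy = model$policy
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  mdl <- build_model(ck$enc_cfg, decoder_depth = ck$dec_depth, init = "zeros")
  if (!is.null(ck$adapter_cfg)) insert_adapters(mdl, ck$adapter_cfg)
  ps_load_state(mdl$store, ck$state)
  freeze_policy(mdl, ck$policy)
  mdl
}

#' Load published ViT weights by name mapping
#'
#' Best-effort loader for externally converted encoder checkpoints supplied
#' as a named list of arrays using the released naming scheme
#' (`patch_embed.proj.*`, `pos_embed`,
#' `blocks.{i}.{norm1,attn.qkv,attn.proj,norm2,mlp.lin1,mlp.lin2}.*`), with
#' weight matrices in (out, in) orientation. Only the encoder sub-layers
#' this architecture shares are mapped: fused qkv projections are split
#' across heads, relative-position tables are ignored. No download happens
#' here; the user provides the list (e.g. read from an `.rds` conversion of
#' the published checkpoint).
#'
#' @param model A `seg_model` whose geometry matches the checkpoint
#'   (e.g. the `vit_b` preset).
#' @param state Named list of numeric arrays.
#' @return The model, invisibly; unmapped entries are reported in a message.
#' @export
load_vit_weights <- function(model, state) {
  d <- model$enc_cfg$embed_dim
  heads <- model$enc_cfg$heads
  dh <- d %/% heads
  st <- model$store
  set_val <- function(name, value) {
    nd <- ps_get(st, name)
    value <- matrix(value, nrow(nd$value), ncol(nd$value))
    nd$value <- value
  }
  used <- character(0)
  grab <- function(key) {
    used <<- c(used, key)
    state[[key]]
  }
  if (!is.null(state[["patch_embed.proj.weight"]])) {
    # (d, p*p) out-by-in -> our (p*p, d)
    set_val("enc.patch.W", t(grab("patch_embed.proj.weight")))
    set_val("enc.patch.b", grab("patch_embed.proj.bias"))
  }
  if (!is.null(state[["pos_embed"]])) set_val("enc.pos", grab("pos_embed"))
  for (i in seq_len(model$enc_cfg$depth)) {
    k <- function(suffix) sprintf("blocks.%d.%s", i - 1L, suffix)
    b <- paste0("enc.b", i)
    if (is.null(state[[k("attn.qkv.weight")]])) next
    set_val(paste0(b, ".ln1.g"), grab(k("norm1.weight")))
    set_val(paste0(b, ".ln1.b"), grab(k("norm1.bias")))
    qkv <- grab(k("attn.qkv.weight"))  # (3d, d), rows q then k then v
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      set_val(paste0(b, ".attn.h", h, ".Wq"), t(qkv[cols, , drop = FALSE]))
      set_val(paste0(b, ".attn.h", h, ".Wk"), t(qkv[d + cols, , drop = FALSE]))
      set_val(paste0(b, ".attn.h", h, ".Wv"), t(qkv[2 * d + cols, , drop = FALSE]))
    }
    set_val(paste0(b, ".attn.Wo"), t(grab(k("attn.proj.weight"))))
    set_val(paste0(b, ".attn.bo"), grab(k("attn.proj.bias")))
    set_val(paste0(b, ".ln2.g"), grab(k("norm2.weight")))
    set_val(paste0(b, ".ln2.b"), grab(k("norm2.bias")))
    set_val(paste0(b, ".mlp.W1"), t(grab(k("mlp.lin1.weight"))))
    set_val(paste0(b, ".mlp.b1"), grab(k("mlp.lin1.bias")))
    set_val(paste0(b, ".mlp.W2"), t(grab(k("mlp.lin2.weight"))))
    set_val(paste0(b, ".mlp.b2"), grab(k("mlp.lin2.bias")))
  }
  unused <- setdiff(names(state), used)
  if (length(unused)) {
    message("load_vit_weights: ", length(unused), " entries not mapped (",
            paste(utils::head(unused, 3), collapse = ", "),
            if (length(unused) > 3) ", ..." else "", ")")
  }
  invisible(model)
}
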