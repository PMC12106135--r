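# Model module: adapter algebra, parameter accounting, freeze policies,
# encoder/prompt/decoder contracts.

test_that("adapter_forward implements the bottleneck residual form", {
  # hand evaluation: d=2, m=1, x=(1,2), W_down=(1,1)', W_up=(1,2)
  w <- list(W_down = matrix(c(1, 1), 2, 1), W_up = matrix(c(1, 2), 1, 2),
            b_down = matrix(0, 1, 1), b_up = matrix(0, 1, 2))
  out <- adapter_forward(matrix(c(1, 2), 1, 2), w)
  expect_equal(as.vector(out), c(4, 8))

  # zero up-projection is the identity
  withr::with_seed(30, {
    x <- matrix(rnorm(20), 5, 4)
    w0 <- list(W_down = matrix(rnorm(8), 4, 2), W_up = matrix(0, 2, 4))
    expect_equal(adapter_forward(x, w0), x)
    # negative pre-activation with zero biases: ReLU kills the branch
    wn <- list(W_down = matrix(-abs(rnorm(8)), 4, 2),
               W_up = matrix(rnorm(8), 2, 4))
    xp <- matrix(abs(rnorm(20)), 5, 4)
    expect_equal(adapter_forward(xp, wn), xp)
  })
  expect_error(adapter_forward(matrix(0, 2, 3), w), "shapes")
})

test_that("insert_adapters places adapters per block and respects m <= d", {
  m <- tiny_test_model(adapters = FALSE)
  insert_adapters(m, adapter_config(m = 4))
  n_adapters <- sum(grepl("\\.adapter\\..*\\.Wdown$", ps_names(m$store)))
  expect_equal(n_adapters, 2 * m$enc_cfg$depth)

  m2 <- tiny_test_model(adapters = FALSE)
  insert_adapters(m2, adapter_config(m = 4, placement = "after_attention"))
  expect_equal(sum(grepl("\\.adapter\\..*\\.Wdown$", ps_names(m2$store))),
               m2$enc_cfg$depth)

  m3 <- tiny_test_model(adapters = FALSE)
  expect_error(insert_adapters(m3, adapter_config(m = 64)), "exceeds")
})

test_that("zero-initialized adapters leave the encoder output unchanged", {
  withr::with_seed(31, {
    base <- tiny_test_model(seed = 7, adapters = FALSE)
    adapted <- tiny_test_model(seed = 7, adapters = FALSE)
    insert_adapters(adapted, adapter_config(m = 4), seed = 99)
    for (i in 1:3) {
      img <- matrix(runif(32 * 32), 32, 32)
      expect_identical(encode_image(adapted, img), encode_image(base, img))
    }
  })
})

test_that("trainable-parameter counts match the closed form", {
  count_adapters <- function(d, m, depth, bias) {
    enc <- encoder_config(image_size = 8 * max(1, d %/% 8), patch_size = 8,
                          embed_dim = d, depth = depth, heads = 2,
                          global_attn_indices = seq_len(depth) - 1)
    mdl <- build_model(enc, init = "zeros")
    insert_adapters(mdl, adapter_config(m = m, include_bias = bias))
    freeze_policy(mdl, "adapters_only")
    count_trainable_params(mdl)
  }
  # tiny config: 4 adapters * (2*32*4 + 4 + 32) = 1168
  expect_equal(count_adapters(32, 4, 2, TRUE), 1168)
  expect_equal(count_adapters(32, 4, 2, FALSE), 4 * (2 * 32 * 4))

  m <- tiny_test_model()
  freeze_policy(m, "full")
  expect_equal(count_trainable_params(m),
               count_trainable_params(m, trainable_only = FALSE))
  freeze_policy(m, "adapters_only")
  expect_equal(count_trainable_params(m) +
                 sum(vapply(m$store$params,
                            function(p) if (!isTRUE(p$requires)) length(p$value) else 0L,
                            numeric(1))),
               count_trainable_params(m, trainable_only = FALSE))
  expect_error(freeze_policy(m, "everything"), "unknown")
})

test_that("one optimizer step under adapters_only leaves the backbone bit-identical", {
  withr::with_seed(32, {
    m <- tiny_test_model(seed = 3)
    freeze_policy(m, "adapters_only")
    frozen_names <- Filter(function(nm) !isTRUE(ps_get(m$store, nm)$requires),
                           ps_names(m$store))
    before <- lapply(frozen_names, function(nm) ps_get(m$store, nm)$value)
    sl <- list(image = matrix(runif(1024), 32, 32),
               mask = square_mask(32, 10, 20))
    train(m, list(sl), train_config(epochs = 1, lr = 0.01, batch_size = 1,
                                    loss = loss_spec(c(bce = 1)), seed = 1))
    after <- lapply(frozen_names, function(nm) ps_get(m$store, nm)$value)
    expect_identical(before, after)
    # and the adapters did move
    expect_gt(max(abs(ps_get(m$store, "enc.b1.adapter.attn.Wup")$value)), 0)
  })
})

test_that("encode_image yields the expected grid and batch behaviour", {
  m <- tiny_test_model(seed = 5)
  img <- matrix(runif(1024), 32, 32)
  e1 <- encode_image(m, img)
  expect_equal(dim(e1), c(16, 32))  # 4x4 grid of 32-dim tokens
  expect_identical(e1, encode_image(m, img))
  img2 <- matrix(runif(1024), 32, 32)
  # per-image encoding is order-independent
  expect_identical(encode_image(m, img2), {
    encode_image(m, img)
    encode_image(m, img2)
  })
  expect_error(encode_image(m, matrix(0, 16, 16)), "32 x 32")
})

test_that("windowed attention partitions the grid and restores token order", {
  wp <- window_partition(8, 2)
  expect_equal(length(wp$windows), 16)
  all_idx <- unlist(wp$windows)
  expect_setequal(all_idx, 1:64)
  expect_equal(all_idx[wp$restore], 1:64)
  # a non-global block in a larger encoder still produces the right shape
  enc <- encoder_config(image_size = 64, patch_size = 8, embed_dim = 32,
                        depth = 2, heads = 2, global_attn_indices = 1,
                        mlp_ratio = 2)
  m <- build_model(enc, decoder_depth = 1, seed = 11)
  e <- encode_image(m, matrix(runif(4096), 64, 64))
  expect_equal(dim(e), c(64, 32))
})

test_that("prompt encoding counts tokens and validates bounds", {
  m <- tiny_test_model(seed = 6)
  ps <- prompt_set(points = data.frame(x = 10, y = 12, label = "foreground"),
                   boxes = data.frame(x0 = 2, y0 = 2, x1 = 30, y1 = 28))
  emb <- encode_prompts(m, ps)
  expect_equal(nrow(emb), 3)  # 1 point + 2 box corners
  expect_equal(ncol(emb), 32)
  expect_identical(emb, encode_prompts(m, ps))

  empty <- encode_prompts(m, prompt_set())
  expect_equal(nrow(empty), 1)  # padding token

  expect_error(encode_prompts(m, prompt_set(points = data.frame(
    x = 100, y = 0, label = "foreground"))), "bounds")
  expect_error(prompt_set(boxes = data.frame(x0 = 5, y0 = 0, x1 = 2, y1 = 3)))
})

test_that("decode_mask returns full-resolution logits deterministically", {
  m <- tiny_test_model(seed = 8)
  img <- matrix(runif(1024), 32, 32)
  emb <- encode_image(m, img)
  sp <- encode_prompts(m, whole_image_prompt(m))
  lg <- decode_mask(m, emb, sp)
  expect_equal(dim(lg), c(32, 32))
  pr <- 1 / (1 + exp(-lg))
  expect_true(all(pr > 0 & pr < 1))
  expect_identical(lg, decode_mask(m, emb, sp))
  expect_error(decode_mask(m, emb[, 1:10], sp), "mismatch")
})

test_that("checkpoints round-trip weights and preserve predictions", {
  withr::with_seed(33, {
    m <- tiny_test_model(seed = 9)
    freeze_policy(m, "adapters_plus_decoder")
    img <- matrix(runif(1024), 32, 32)
    p0 <- predict_mask(m, img)$prob
    ck <- tempfile(fileext = ".rds")
    save_checkpoint(m, ck)
    m2 <- load_checkpoint(ck)
    expect_identical(predict_mask(m2, img)$prob, p0)
    expect_equal(m2$policy, "adapters_plus_decoder")
  })
})

test_that("published-style encoder weights map onto the model by name", {
  withr::with_seed(34, {
    m <- tiny_test_model(seed = 21, adapters = FALSE)
    d <- 32; heads <- 2; dh <- 16
    qkv <- matrix(rnorm(3 * d * d), 3 * d, d)
    state <- list(
      "patch_embed.proj.weight" = matrix(rnorm(d * 64), d, 64),
      "patch_embed.proj.bias" = rnorm(d),
      "pos_embed" = matrix(rnorm(16 * d), 16, d),
      "blocks.0.norm1.weight" = runif(d), "blocks.0.norm1.bias" = rnorm(d),
      "blocks.0.attn.qkv.weight" = qkv,
      "blocks.0.attn.proj.weight" = matrix(rnorm(d * d), d, d),
      "blocks.0.attn.proj.bias" = rnorm(d),
      "blocks.0.norm2.weight" = runif(d), "blocks.0.norm2.bias" = rnorm(d),
      "blocks.0.mlp.lin1.weight" = matrix(rnorm(2 * d * d), 2 * d, d),
      "blocks.0.mlp.lin1.bias" = rnorm(2 * d),
      "blocks.0.mlp.lin2.weight" = matrix(rnorm(2 * d * d), d, 2 * d),
      "blocks.0.mlp.lin2.bias" = rnorm(d),
      "blocks.0.attn.rel_pos_h" = matrix(0, 3, dh)  # intentionally unmapped
    )
    expect_message(load_vit_weights(m, state), "not mapped")
    # q slice of head 2 lands in the right per-head matrix, transposed
    expect_equal(ps_get(m$store, "enc.b1.attn.h2.Wq")$value,
                 t(qkv[17:32, , drop = FALSE]))
    expect_equal(ps_get(m$store, "enc.b1.attn.h1.Wk")$value,
                 t(qkv[d + (1:16), , drop = FALSE]))
    expect_equal(as.vector(ps_get(m$store, "enc.patch.b")$value),
                 state[["patch_embed.proj.bias"]])
    # block 2 had no entries: untouched random init remains
    expect_gt(stats::sd(ps_get(m$store, "enc.b2.attn.Wo")$value), 0)
  })
})
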