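# Splitting, training mechanics, bootstrap and the Friedman/Nemenyi protocol.

make_scan_table <- function(n_pos, n_neg) {
  tibble::tibble(
    scan_id = sprintf("s%03d", seq_len(n_pos + n_neg)),
    positive = c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  )
}

test_that("stratified split keeps the class ratio and partitions the ids", {
  tab <- make_scan_table(80, 20)
  sp <- stratified_split(tab, seed = 5)
  expect_equal(length(sp$test_ids), 20)
  expect_equal(length(sp$folds), 5)
  td <- tidy(sp)
  # 20% test per stratum: 16 positive, 4 negative
  expect_equal(sum(td$positive[td$role == "test"]), 16)
  val_sizes <- table(td$fold[td$role == "cv"])
  expect_true(all(val_sizes == 16))
  pos_per_fold <- tapply(td$positive[td$role == "cv"], td$fold[td$role == "cv"], sum)
  expect_true(all(pos_per_fold %in% c(12, 13)))

  # partition: every id exactly once across test + validation folds
  expect_setequal(td$scan_id, tab$scan_id)
  expect_equal(anyDuplicated(td$scan_id), 0)
  for (f in seq_len(5)) {
    expect_setequal(c(sp$folds[[f]]$train_ids, sp$folds[[f]]$val_ids),
                    setdiff(tab$scan_id, sp$test_ids))
    expect_length(intersect(sp$folds[[f]]$train_ids, sp$folds[[f]]$val_ids), 0)
  }

  # determinism
  sp2 <- stratified_split(tab, seed = 5)
  expect_identical(tidy(sp2), td)
  sp3 <- stratified_split(tab, seed = 6)
  expect_false(identical(sp3$test_ids, sp$test_ids))
})

test_that("stratified split rejects strata smaller than the fold count", {
  expect_error(stratified_split(make_scan_table(20, 4), seed = 1),
               "fewer remaining scans")
  expect_error(stratified_split(make_scan_table(5, 3), seed = 1), "at least 10")
})

test_that("training with lr ~ 0 leaves weights unchanged and loss decreases otherwise", {
  withr::with_seed(40, {
    sl <- list(image = matrix(runif(1024), 32, 32),
               mask = square_mask(32, 8, 18))
    m <- tiny_test_model(seed = 13)
    freeze_policy(m, "full")
    w0 <- ps_state_dict(m$store)
    train(m, list(sl), train_config(epochs = 2, lr = 1e-300, batch_size = 1,
                                    loss = loss_spec(c(bce = 1)),
                                    weight_decay = 0, seed = 1))
    w1 <- ps_state_dict(m$store)
    expect_equal(w0, w1, tolerance = 1e-12)

    m2 <- tiny_test_model(seed = 13)
    freeze_policy(m2, "full")
    fit <- train(m2, list(sl), train_config(epochs = 8, lr = 1e-3,
                                            batch_size = 1,
                                            loss = loss_spec(c(bce = 1)),
                                            seed = 1))
    expect_lt(fit$log$loss[8], fit$log$loss[1])
  })
})

test_that("resuming from saved optimizer state reproduces an uninterrupted run", {
  withr::with_seed(41, {
    slices <- lapply(1:4, function(i) {
      list(image = matrix(runif(1024), 32, 32),
           mask = square_mask(32, 5 + i, 15 + i))
    })
    cfg <- function(ep) train_config(epochs = ep, lr = 1e-3, batch_size = 2,
                                     loss = loss_spec(c(bce = 0.5, dice = 0.5)),
                                     seed = 7)
    a <- tiny_test_model(seed = 17); freeze_policy(a, "adapters_plus_decoder")
    train(a, slices, cfg(6))

    b <- tiny_test_model(seed = 17); freeze_policy(b, "adapters_plus_decoder")
    half <- train(b, slices, cfg(3))
    train(b, slices, cfg(6), start_epoch = 4, opt_state = half$opt_state)
    expect_identical(ps_state_dict(a$store), ps_state_dict(b$store))
  })
})

test_that("non-finite loss aborts with a diagnostic", {
  m <- tiny_test_model(seed = 19)
  freeze_policy(m, "full")
  sl <- list(image = matrix(0.5, 32, 32), mask = square_mask(32, 10, 20))
  bad <- loss_spec(c(bce = 1))
  # poison a weight to force a non-finite forward pass
  pw <- ps_get(m$store, "dec.hyper.W1")
  pw$value[1, 1] <- Inf
  expect_error(
    train(m, list(sl), train_config(epochs = 1, lr = 1e-3, loss = bad, seed = 1)),
    "non-finite loss"
  )
})

test_that("percentile bootstrap matches an independent implementation", {
  expect_equal(unlist(bootstrap_ci(rep(3.5, 10), B = 200, seed = 2)[, c("mean", "lo", "hi")]),
               c(mean = 3.5, lo = 3.5, hi = 3.5))
  withr::with_seed(42, {
    x <- rnorm(40)
    ci <- bootstrap_ci(x, B = 500, alpha = 0.1, seed = 11)
    expect_lte(ci$lo, ci$mean)
    expect_gte(ci$hi, ci$mean)

    # independent resampler at matched RNG settings
    means2 <- with_seed(11, vapply(seq_len(500), function(b) {
      mean(x[sample.int(40, 40, replace = TRUE)])
    }, numeric(1)))
    qs <- unname(stats::quantile(means2, c(0.05, 0.95), type = 7))
    expect_equal(c(ci$lo, ci$hi), qs, tolerance = 1e-12)
  })
  # balanced 0/1 values: CI brackets 0.5 within Monte-Carlo error
  y <- rep(c(0, 1), 20)
  ci2 <- bootstrap_ci(y, B = 4000, seed = 3)
  expect_lt(ci2$lo, 0.5)
  expect_gt(ci2$hi, 0.5)
  expect_error(bootstrap_ci(1), "length")
})

test_that("Friedman statistic matches the rank-sum formula and base R", {
  # consistent ranking over 4 blocks, 3 models: rank sums (4, 8, 12)
  x <- cbind(worst = c(1, 2, 1, 3), mid = c(4, 5, 3, 6), best = c(9, 9, 8, 9))
  fr <- friedman_test(x)
  expect_equal(fr$statistic, 8)
  expect_equal(fr$df, 2)
  expect_equal(fr$p_value, stats::pchisq(8, 2, lower.tail = FALSE))
  expect_equal(unname(fr$mean_ranks), c(1, 2, 3))
  # cross-check against the base implementation on tie-free data
  bf <- stats::friedman.test(x)
  expect_equal(fr$statistic, unname(bf$statistic))
  expect_equal(fr$p_value, unname(bf$p.value))

  # identical columns: no ranking signal
  same <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  fr0 <- friedman_test(same)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)

  # invariance to strictly monotone transforms
  withr::with_seed(43, {
    y <- matrix(rnorm(40), 10, 4)
    expect_equal(friedman_test(y)$statistic, friedman_test(exp(y))$statistic)
  })
  expect_error(friedman_test(matrix(1:4, 2, 2)), "at least 3")
})

test_that("tidy and glance methods expose the Friedman fit", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fr <- friedman_test(x)
  td <- tidy(fr)
  expect_equal(td$model, c("a", "b", "c"))
  expect_equal(sum(td$mean_rank), 6)  # ranks 1..3 average to 2 per block
  gl <- glance(fr)
  expect_equal(gl$n_blocks, 10)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})

test_that("Nemenyi critical values match published table constants", {
  # studentized-range-based q values for alpha = 0.05, k = 2..6
  published <- c(1.960, 2.343, 2.569, 2.728, 2.850)
  computed <- vapply(2:6, function(k) nemenyi_q(0.05, k), numeric(1))
  expect_equal(computed, published, tolerance = 2e-3)
  expect_equal(nemenyi_q(0.10, 3), 2.052, tolerance = 2e-3)
})

test_that("Nemenyi post-hoc flags dominant models and honours the gate", {
  withr::with_seed(44, {
    base <- rnorm(10)
    x <- cbind(a = base + 5, b = base + 0.05 * rnorm(10), c = base)
    nm <- nemenyi_posthoc(x, alpha = 0.05)
    expect_false(is.null(nm))
    expect_true(isSymmetric(unname(nm$significant + 0)) ||
                  all(nm$significant == t(nm$significant), na.rm = TRUE))
    expect_true(all(is.na(diag(nm$significant))))
    expect_true(nm$significant["a", "c"])
    # identical columns are never flagged
    y <- cbind(a = base, b = base, c = base + 3)
    nm2 <- nemenyi_posthoc(y, alpha = 0.05)
    expect_false(nm2$significant["a", "b"])
    expect_equal(nm2$rank_diff["a", "b"], 0)

    # gatekeeping: not significant -> warning, NULL unless forced
    z <- matrix(rnorm(30), 10, 3)
    while (friedman_test(z)$p_value < 0.2) z <- matrix(rnorm(30), 10, 3)
    expect_warning(res <- nemenyi_posthoc(z), "not significant")
    expect_null(res)
    expect_warning(res2 <- nemenyi_posthoc(z, force = TRUE), "anyway")
    expect_false(is.null(res2))
    cm <- compare_models(z)
    expect_null(cm$nemenyi)
  })
})

test_that("Nemenyi flags agree with an exact reference computation", {
  withr::with_seed(45, {
    x <- cbind(m1 = runif(12), m2 = runif(12) + 0.8, m3 = runif(12) + 1.6)
    nm <- nemenyi_posthoc(x, alpha = 0.05, force = TRUE)
    # reference: direct formula with the published q constant for k = 3
    ranks <- t(apply(x, 1, rank))
    cd_ref <- 2.343 * sqrt(3 * 4 / (6 * 12))
    dif <- abs(outer(colMeans(ranks), colMeans(ranks), "-"))
    expect_equal(unname(nm$significant[upper.tri(nm$significant)]),
                 unname((dif > cd_ref)[upper.tri(dif)]))
  })
})
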