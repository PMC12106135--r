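# Experiment machinery: stratified train/validation/test splitting, the
# training loop (AdamW over the autodiff graph), percentile-bootstrap
# confidence intervals, and the Friedman / Nemenyi statistical comparison
# with the gatekeeping order used for model comparisons.

#' Stratified test split plus k-fold cross-validation folds
#'
#' Holds out `test_frac` of the scans as a test set and partitions the
#' remainder into `k` disjoint folds, stratifying both by the positive /
#' negative scan label so each subset preserves the global class ratio.
#' Deterministic given `seed`.
#'
#' @param scan_table Data frame with columns `scan_id` and `positive`
#'   (logical or 0/1).
#' @param seed Integer seed.
#' @param test_frac Held-out fraction (default 20%).
#' @param k Number of folds (default 5).
#' @return A `fold_split`: list with `test_ids`, `folds` (each a list with
#'   `train_ids`, `val_ids`), `strata` and `seed`.
#' @export
stratified_split <- function(scan_table, seed = 1L, test_frac = 0.2, k = 5L) {
  stopifnot(all(c("scan_id", "positive") %in% names(scan_table)))
  scan_table <- dplyr::distinct(tibble::as_tibble(scan_table), .data$scan_id,
                                .keep_all = TRUE)
  if (nrow(scan_table) < 10) stop("need at least 10 scans", call. = FALSE)
  pos <- as.logical(scan_table$positive)
  ids_by_stratum <- split(scan_table$scan_id, pos)
  if (length(ids_by_stratum) < 2) stop("both strata must be present", call. = FALSE)

  shuffled <- with_seed(derive_seed(seed, "split"), {
    lapply(ids_by_stratum, function(ids) sample(ids, length(ids)))
  })
  test_ids <- character(0)
  rest <- list()
  for (s in names(shuffled)) {
    ids <- shuffled[[s]]
    nt <- round(test_frac * length(ids))
    test_ids <- c(test_ids, ids[seq_len(nt)])
    rest[[s]] <- ids[-seq_len(nt)]
    if (length(rest[[s]]) < k) {
      stop("stratum '", s, "' has fewer remaining scans (", length(rest[[s]]),
           ") than folds (", k, "); reduce k or add scans of that class",
           call. = FALSE)
    }
  }
  # per-fold positive quota: floor share plus one for the first remainder
  # folds; negatives fill each fold to its target size
  n_rest <- sum(lengths(rest))
  npos <- length(rest[["TRUE"]])
  size_f <- n_rest %/% k + (seq_len(k) <= n_rest %% k)
  pos_f <- npos %/% k + (seq_len(k) <= npos %% k)
  neg_f <- size_f - pos_f
  if (any(neg_f < 0)) neg_f <- pmax(neg_f, 0)
  fold_of <- character(0)
  assign_ids <- function(ids, counts) {
    f <- rep(seq_len(k), counts)[seq_along(ids)]
    stats::setNames(f, ids)
  }
  fmap <- c(assign_ids(rest[["TRUE"]], pos_f), assign_ids(rest[["FALSE"]], neg_f))
  folds <- lapply(seq_len(k), function(f) {
    val <- names(fmap)[fmap == f]
    list(train_ids = sort(names(fmap)[fmap != f]), val_ids = sort(val))
  })
  structure(
    list(test_ids = sort(test_ids), folds = folds,
         strata = tibble::tibble(scan_id = scan_table$scan_id, positive = pos),
         seed = as.integer(seed), k = k),
    class = "fold_split"
  )
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split: %d test scans, %d folds, seed %d>\n",
              length(x$test_ids), length(x$folds), x$seed))
  invisible(x)
}

#' Tidy a fold split into a long assignment table
#'
#' @param x A `fold_split`.
#' @param ... Unused.
#' @return Tibble with columns `scan_id`, `role` (`"test"` or `"cv"`),
#'   `fold` (validation fold index, `NA` for test scans) and `positive`.
#' @export
tidy.fold_split <- function(x, ...) {
  val_fold <- function(id) {
    for (f in seq_along(x$folds)) if (id %in% x$folds[[f]]$val_ids) return(f)
    NA_integer_
  }
  tab <- tibble::tibble(
    scan_id = c(x$test_ids, unlist(lapply(x$folds, `[[`, "val_ids"))),
    role = c(rep("test", length(x$test_ids)),
             rep("cv", sum(lengths(lapply(x$folds, `[[`, "val_ids")))))
  )
  tab$fold <- ifelse(tab$role == "cv",
                     vapply(tab$scan_id, val_fold, integer(1)), NA_integer_)
  dplyr::left_join(tab, x$strata, by = "scan_id")
}

#' Training configuration
#'
#' Defaults follow the reference fine-tuning recipe: AdamW with learning rate
#' 5e-5 and weight decay 0.1, batch size 2, 50 epochs, BCE loss. For training
#' from random initialization (no pretrained backbone), a larger learning
#' rate (around 1e-3) and the `adapters_plus_decoder` policy are appropriate.
#'
#' @param epochs Number of epochs (an epoch iterates all training slices,
#'   shuffled per epoch from the run seed).
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW weight decay.
#' @param batch_size Slices per optimizer step.
#' @param loss A [loss_spec()].
#' @param seed Run seed (drives shuffling and augmentation).
#' @param prompt `"whole_image"` (fully automatic) or `"gt_box"` (tight
#'   ground-truth box dilated by `prompt_margin`).
#' @param prompt_margin Box dilation margin in pixels.
#' @param augment Optional [augment_spec()]; `NULL` disables augmentation.
#' @param warmup_steps Linear learning-rate warmup over this many optimizer
#'   steps (0 disables; recommended for training from random initialization).
#' @param clip_norm Global gradient-norm clipping threshold (`Inf` disables).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, lr = 5e-5, weight_decay = 0.1,
                         batch_size = 2, loss = loss_spec(), seed = 1L,
                         prompt = c("whole_image", "gt_box"),
                         prompt_margin = 3, augment = NULL,
                         warmup_steps = 0L, clip_norm = Inf) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, warmup_steps >= 0,
            clip_norm > 0)
  prompt <- match.arg(prompt)
  structure(
    list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
         batch_size = as.integer(batch_size), loss = loss,
         seed = as.integer(seed), prompt = prompt,
         prompt_margin = prompt_margin, augment = augment,
         warmup_steps = as.integer(warmup_steps), clip_norm = clip_norm),
    class = "train_config"
  )
}

slice_prompt <- function(model, mask, cfg) {
  if (cfg$prompt == "gt_box") mask_box_prompt(model, mask, cfg$prompt_margin)
  else whole_image_prompt(model)
}

#' Train a segmentation model
#'
#' Optimizes the model's trainable parameters (per its freeze policy) with
#' AdamW on the configured loss. Supports warm starts from a checkpoint and
#' exact resumption (`start_epoch` plus the returned optimizer state), which
#' reproduces an uninterrupted run bit for bit. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model A `seg_model` with its freeze policy applied.
#' @param data List of training slices, each a list with `image` (matrix in
#'   `[0, 1]`) and `mask` (binary matrix).
#' @param cfg A [train_config()].
#' @param init_checkpoint Optional checkpoint path to initialize weights from.
#' @param start_epoch First epoch index (for resumption).
#' @param opt_state Optimizer state from a previous [train()] result.
#' @return List with `model`, `log` (tibble of per-epoch mean losses) and
#'   `opt_state`.
#' @export
train <- function(model, data, cfg = train_config(), init_checkpoint = NULL,
                  start_epoch = 1L, opt_state = NULL) {
  stopifnot(length(data) >= 1)
  if (!is.null(init_checkpoint)) {
    ck <- readRDS(init_checkpoint)
    ps_load_state(model$store, ck$state)
  }
  opt <- adamw_new(model$store, lr = cfg$lr, weight_decay = cfg$weight_decay)
  if (!is.null(opt_state)) {
    opt$m <- opt_state$m; opt$v <- opt_state$v; opt$t <- opt_state$t
  }
  n <- length(data)
  log <- vector("list", cfg$epochs - start_epoch + 1L)
  li <- 0L
  for (epoch in start_epoch:cfg$epochs) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)), sample.int(n))
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      ps_zero_grads(model$store)
      bl <- 0
      for (s in ord[i:j]) {
        sl <- data[[s]]
        img <- sl$image; msk <- sl$mask
        if (!is.null(cfg$augment)) {
          a <- augment(img, msk, cfg$augment,
                       seed = derive_seed(cfg$seed, paste0("aug", epoch, "_", s)))
          img <- a$image; msk <- a$mask
        }
        node <- forward_logits(model, img, slice_prompt(model, msk, cfg))
        # clamp away from 0/1 so the sigmoid chain rule below keeps its
        # saturation-robust form (e.g. BCE's gradient stays p - y)
        p <- .clamp(stats::plogis(as.vector(node$value)))
        y <- as.vector(t(msk))  # row-major pixel order, matching the logits
        lg <- suppressWarnings(
          combined_loss(p, y, cfg$loss,
                        sdm = if ("boundary" %in% names(cfg$loss$components)) {
                          as.vector(t(suppressWarnings(signed_distance_map(msk))))
                        },
                        gradient = TRUE))
        if (!is.finite(lg$value)) {
          stop(sprintf(
            "non-finite loss (%.4g) at epoch %d, slice %d: aborting (check loss spec / learning rate)",
            lg$value, epoch, s), call. = FALSE)
        }
        grad_z <- lg$grad * p * (1 - p)
        ag_backward(node, matrix(grad_z, ncol = 1))
        bl <- bl + lg$value
      }
      nbatch <- j - i + 1L
      gscale <- 1 / nbatch
      if (is.finite(cfg$clip_norm)) {
        sq <- 0
        for (nd in model$store$params) {
          if (isTRUE(nd$requires) && !is.null(nd$grad)) {
            sq <- sq + sum((nd$grad * gscale)^2)
          }
        }
        gn <- sqrt(sq)
        if (gn > cfg$clip_norm) gscale <- gscale * cfg$clip_norm / gn
      }
      if (cfg$warmup_steps > 0) {
        opt$lr <- cfg$lr * min(1, (opt$t + 1) / cfg$warmup_steps)
      }
      adamw_step(opt, grad_scale = gscale)
      ep_loss <- ep_loss + bl / nbatch
      nb <- nb + 1L
      i <- j + 1L
    }
    li <- li + 1L
    log[[li]] <- tibble::tibble(epoch = epoch, loss = ep_loss / nb)
  }
  list(model = model,
       log = dplyr::bind_rows(log),
       opt_state = list(m = opt$m, v = opt$v, t = opt$t))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Numeric vector of per-scan values (n >= 2).
#' @param B Number of bootstrap resamples.
#' @param alpha Two-sided miscoverage (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return Tibble with columns `mean`, `lo`, `hi`, `B`, `n`.
#' @export
bootstrap_ci <- function(values, B = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(length(values) >= 2)
  n <- length(values)
  means <- with_seed(seed, {
    vapply(seq_len(B), function(b) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  qs <- unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2), type = 7))
  tibble::tibble(mean = mean(values), lo = qs[1], hi = qs[2], B = B, n = n)
}

#' Friedman rank test over blocked model scores
#'
#' Ranks the k models within each of the n blocks (average ranks on ties) and
#' computes the chi-square statistic
#' `12 / (n k (k + 1)) * sum(R_j^2) - 3 n (k + 1)` with `k - 1` degrees of
#' freedom.
#'
#' @param score_matrix Numeric matrix, blocks (e.g. scans) in rows and models
#'   in columns; column names identify the models.
#' @return A `friedman_test` object with `statistic`, `p_value`, `df` and
#'   per-model `mean_ranks`.
#' @export
friedman_test <- function(score_matrix) {
  x <- as.matrix(score_matrix)
  n <- nrow(x); k <- ncol(x)
  if (k < 3) {
    stop("Friedman test needs at least 3 models; use a paired test for 2",
         call. = FALSE)
  }
  stopifnot(n >= 2)
  if (is.null(colnames(x))) colnames(x) <- paste0("model", seq_len(k))
  ranks <- t(apply(x, 1, rank))
  R <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  structure(
    list(statistic = stat, df = k - 1,
         p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
         mean_ranks = colMeans(ranks), n = n, k = k,
         models = colnames(x), ranks = ranks),
    class = "friedman_test"
  )
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman test: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("mean ranks:\n")
  print(round(x$mean_ranks, 3))
  invisible(x)
}

#' @export
tidy.friedman_test <- function(x, ...) {
  tibble::tibble(model = x$models, mean_rank = unname(x$mean_ranks),
                 rank_sum = unname(colSums(x$ranks)))
}

#' @export
glance.friedman_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_blocks = x$n, n_models = x$k)
}

# Nemenyi critical value: studentized range at infinite df over sqrt(2)
nemenyi_q <- function(alpha, k) stats::qtukey(1 - alpha, k, Inf) / sqrt(2)

#' Nemenyi post-hoc pairwise comparison
#'
#' Computed after a significant Friedman test (the gatekeeping the protocol
#' prescribes): a pair of models differs when the absolute difference of
#' their mean ranks exceeds the critical difference
#' `CD = q_alpha,k * sqrt(k (k + 1) / (6 n))`. Calling it when the Friedman
#' test is not significant raises a warning and returns `NULL` unless
#' `force = TRUE`.
#'
#' @inheritParams friedman_test
#' @param alpha Significance level (0.05 or 0.10).
#' @param force Compute even when the Friedman gate fails?
#' @return A `nemenyi_posthoc` object with the critical difference, the mean
#'   ranks, and symmetric matrices of rank differences and significance
#'   flags; or `NULL` when gated.
#' @export
nemenyi_posthoc <- function(score_matrix, alpha = 0.05, force = FALSE) {
  fr <- friedman_test(score_matrix)
  if (fr$p_value >= alpha) {
    warning(sprintf(
      "Friedman test not significant (p = %.3g >= %.2g); %s",
      fr$p_value, alpha,
      if (force) "computing Nemenyi post-hoc anyway (force = TRUE)"
      else "skipping Nemenyi post-hoc (use force = TRUE to compute anyway)"))
    if (!force) return(invisible(NULL))
  }
  cd <- nemenyi_q(alpha, fr$k) * sqrt(fr$k * (fr$k + 1) / (6 * fr$n))
  dif <- abs(outer(fr$mean_ranks, fr$mean_ranks, "-"))
  sig <- dif > cd
  diag(sig) <- NA
  structure(
    list(critical_difference = cd, alpha = alpha, mean_ranks = fr$mean_ranks,
         rank_diff = dif, significant = sig, friedman = fr),
    class = "nemenyi_posthoc"
  )
}

#' @export
print.nemenyi_posthoc <- function(x, ...) {
  cat(sprintf("Nemenyi post-hoc (alpha = %.2f): CD = %.4g\n", x$alpha,
              x$critical_difference))
  print(x$significant)
  invisible(x)
}

#' @export
tidy.nemenyi_posthoc <- function(x, ...) {
  ms <- names(x$mean_ranks)
  idx <- which(upper.tri(x$rank_diff), arr.ind = TRUE)
  tibble::tibble(
    model1 = ms[idx[, 1]], model2 = ms[idx[, 2]],
    rank_diff = x$rank_diff[idx], significant = x$significant[idx]
  )
}

#' Compare models with the Friedman/Nemenyi protocol
#'
#' Runs the omnibus Friedman test and, only when it is significant at
#' `alpha`, the Nemenyi post-hoc.
#'
#' @inheritParams nemenyi_posthoc
#' @return List with `friedman` and `nemenyi` (`NULL` when gated).
#' @export
compare_models <- function(score_matrix, alpha = 0.05) {
  fr <- friedman_test(score_matrix)
  nm <- if (fr$p_value < alpha) nemenyi_posthoc(score_matrix, alpha) else NULL
  list(friedman = fr, nemenyi = nm)
}

#' Intensity-band baseline segmenter
#'
#' Labels pixels whose preprocessed intensity falls in `[lo, hi]`: on
#' windowed, min-max-normalized head CT this captures the hyperdense band
#' between brain tissue and bone. Used as a classical baseline in model
#' comparisons.
#'
#' @param image Preprocessed slice in `[0, 1]`.
#' @param lo,hi Intensity band.
#' @return Binary mask matrix.
#' @export
threshold_segmenter <- function(image, lo = 0.3, hi = 0.8) {
  ((image >= lo) & (image <= hi)) * 1L
}
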