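# Mask readers/writers (NIfTI, per-slice PNG), run configuration, JSON-lines
# logging, and the end-to-end pipeline driver.

#' Write binary masks
#'
#' NIfTI (`.nii` / `.nii.gz`) for volumes, or a directory of per-slice PNG
#' files (`slice%03d.png`, foreground stored as white).
#'
#' @param path Output `.nii`/`.nii.gz` file or directory (PNG mode).
#' @param masks Binary matrix or `H x W x C` array.
#' @return `path`, invisibly.
#' @export
write_masks <- function(path, masks) {
  masks <- (as.array(masks) > 0) * 1L
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(masks), path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (length(dim(masks)) == 2L) masks <- array(masks, c(dim(masks), 1L))
    for (k in seq_len(dim(masks)[3])) {
      png::writePNG(masks[, , k] * 1.0,
                    file.path(path, sprintf("slice%03d.png", k)))
    }
  }
  invisible(path)
}

#' Read binary masks
#'
#' Values are coerced to 0/1; inputs that are not binary within `tol` (after
#' mapping the PNG 0/255 convention to 0/1) are rejected.
#'
#' @param path `.nii`/`.nii.gz` file or directory of per-slice PNGs.
#' @param tol Binariness tolerance.
#' @return Integer array of 0/1 values.
#' @export
read_masks <- function(path, tol = 0.1) {
  vals <- if (grepl("\\.nii(\\.gz)?$", path)) {
    as.array(RNifti::readNifti(path))
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no mask files at ", path, call. = FALSE)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
    array(unlist(slices), c(dim(slices[[1]]), length(slices)))
  }
  off <- pmin(abs(vals), abs(vals - 1))
  if (any(off > tol)) {
    stop("mask at ", path, " is not binary (max deviation ",
         format(max(off), digits = 3), ")", call. = FALSE)
  }
  out <- (vals > 0.5) * 1L
  array(out, dim(vals))
}

#' Default run configuration
#'
#' Nests every constant the pipeline consumes: phantom generation, the
#' preprocessing block, model preset and adapter dimension, training
#' settings, fold layout and metric options. Any part can be overridden via
#' a YAML file ([read_run_config()]) or by editing the returned list.
#'
#' @param seed Global seed; every stage derives its own stream from it.
#' @param output Output directory for artifacts.
#' @return A nested `run_config` list.
#' @export
default_run_config <- function(seed = 1L, output = tempfile("hemadapt_run")) {
  structure(list(
    seed = as.integer(seed),
    output = output,
    phantom = list(n_scans = 14, slices_per_scan = c(4, 6), image_size = 64,
                   fraction_positive = 0.64, lesion_area_px = c(40, 300),
                   noise_sd = 4, annotator_perturb_px = 2),
    preprocess = list(window = c(0, 140), target = 64, orient = FALSE,
                      hu_threshold = 100),
    model = list(preset = "tiny", adapter_m = 8, decoder_depth = 2,
                 policy = "adapters_plus_decoder"),
    train = list(epochs = 8, lr = 1.5e-3, weight_decay = 0.1, batch_size = 1,
                 loss = "bce:0.25,dice:0.75", prompt = "whole_image"),
    split = list(test_frac = 0.2, k = 3),
    metrics = list(threshold = 0.5),
    agreement = list(bins = c(0, 2000, 4000, 6000, 8000, Inf))
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_run_config()] entries.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_into(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), usr), class = "run_config")
}

#' Hash a run configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any constant changes.
#'
#' @param config A `run_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(path, ...) {
  rec <- list(...)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = path, append = TRUE)
}

write_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order:
#' `simulate -> preprocess -> split -> train -> evaluate -> compare ->
#' agreement`. Artifacts (CSV tables, the checkpoint, the written phantom
#' dataset) land under `config$output`, every one tagged with the config
#' hash in the JSON-lines run log; re-running with the same configuration
#' reproduces the metric CSVs byte for byte.
#'
#' The `compare` stage scores three segmenters per test scan — the trained
#' model, the intensity-band baseline and an all-background predictor — and
#' applies the Friedman/Nemenyi protocol to their scan-level Dice.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param stages Character vector of stages to run.
#' @return Invisibly, a list with the key in-memory results
#'   (`dataset`, `split`, `model`, `metrics`, `comparison`, `agreement`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "preprocess", "split", "train",
                                    "evaluate", "compare", "agreement")) {
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out, "run_log.jsonl")
  log_line(logf, event = "start", config_hash = hash, seed = config$seed,
           r_version = as.character(getRversion()))
  res <- list()
  seed <- config$seed

  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  run_stage <- function(stage, fun) {
    log_line(logf, event = "stage", stage = stage, config_hash = hash,
             seed = derive_seed(seed, stage))
    tryCatch(fun(), error = function(e) fail(stage, e))
  }

  state_path <- file.path(out, "work")
  dir.create(state_path, showWarnings = FALSE)
  load_state <- function(name) {
    f <- file.path(state_path, paste0(name, ".rds"))
    if (!file.exists(f)) stop("missing upstream artifact: ", name, call. = FALSE)
    readRDS(f)
  }
  save_state <- function(name, value) {
    saveRDS(value, file.path(state_path, paste0(name, ".rds")))
    value
  }

  if ("simulate" %in% stages) {
    res$dataset <- run_stage("simulate", function() {
      ph <- config$phantom
      spec <- phantom_spec(
        n_scans = ph$n_scans, slices_per_scan = ph$slices_per_scan,
        image_size = ph$image_size, fraction_positive = ph$fraction_positive,
        lesion_area_px = ph$lesion_area_px, noise_sd = ph$noise_sd,
        annotator_perturb_px = ph$annotator_perturb_px,
        seed = derive_seed(seed, "simulate")
      )
      ds <- generate_phantom_dataset(spec)
      write_phantom_dataset(ds, file.path(out, "data"))
      save_state("dataset", ds)
    })
  }

  if ("preprocess" %in% stages) {
    res$prep <- run_stage("preprocess", function() {
      ds <- res$dataset %||% load_state("dataset")
      pp <- config$preprocess
      w <- window_spec(pp$window[1], pp$window[2])
      prep <- lapply(ds$scans, function(s) {
        vol <- read_ct_series(file.path(out, "data", "dicom", s$volume$scan_id))
        pr <- preprocess_scan(vol, mask = s$gt, window = w,
                              target = pp$target, orient = isTRUE(pp$orient),
                              hu_threshold = pp$hu_threshold)
        list(scan_id = s$volume$scan_id, image = pr$image, mask = pr$mask,
             positive = s$positive)
      })
      names(prep) <- vapply(prep, `[[`, character(1), "scan_id")
      save_state("prep", prep)
    })
  }

  if ("split" %in% stages) {
    res$split <- run_stage("split", function() {
      ds <- res$dataset %||% load_state("dataset")
      scan_tab <- dplyr::distinct(ds$manifest, .data$scan_id,
                                  positive = .data$scan_positive)
      sp <- stratified_split(scan_tab, seed = derive_seed(seed, "split"),
                             test_frac = config$split$test_frac,
                             k = config$split$k)
      write_table(tidy.fold_split(sp), file.path(out, "split.csv"))
      save_state("split", sp)
    })
  }

  slices_of <- function(prep, ids) {
    slices <- list()
    for (id in ids) {
      p <- prep[[id]]
      for (k in seq_len(dim(p$image)[3])) {
        slices[[length(slices) + 1L]] <- list(image = p$image[, , k],
                                              mask = p$mask[, , k],
                                              scan_id = id, slice = k)
      }
    }
    slices
  }

  if ("train" %in% stages) {
    res$fit <- run_stage("train", function() {
      prep <- res$prep %||% load_state("prep")
      sp <- res$split %||% load_state("split")
      mc <- config$model
      mdl <- build_model(model_preset(mc$preset),
                         decoder_depth = mc$decoder_depth,
                         seed = derive_seed(seed, "model_init"))
      insert_adapters(mdl, adapter_config(m = mc$adapter_m),
                      seed = derive_seed(seed, "adapter_init"))
      freeze_policy(mdl, mc$policy)
      tc <- config$train
      cfg <- train_config(epochs = tc$epochs, lr = tc$lr,
                          weight_decay = tc$weight_decay,
                          batch_size = tc$batch_size,
                          loss = parse_loss_spec(tc$loss),
                          seed = derive_seed(seed, "train"),
                          prompt = tc$prompt)
      fit <- train(mdl, slices_of(prep, sp$folds[[1]]$train_ids), cfg,
                   init_checkpoint = tc$init_checkpoint)
      save_checkpoint(mdl, file.path(out, "model.ckpt.rds"))
      write_table(fit$log, file.path(out, "train_log.csv"))
      save_state("fit", list(log = fit$log))
      list(model = mdl, log = fit$log)
    })
  }

  get_model <- function() {
    if (!is.null(res$fit)) res$fit$model
    else load_checkpoint(file.path(out, "model.ckpt.rds"))
  }

  if ("evaluate" %in% stages) {
    res$metrics <- run_stage("evaluate", function() {
      prep <- res$prep %||% load_state("prep")
      sp <- res$split %||% load_state("split")
      mdl <- get_model()
      thr <- config$metrics$threshold
      slice_tabs <- list()
      scan_pairs <- list()
      for (id in sp$test_ids) {
        p <- prep[[id]]
        C <- dim(p$image)[3]
        pred <- array(0L, dim(p$image))
        for (k in seq_len(C)) {
          pred[, , k] <- predict_mask(mdl, p$image[, , k], threshold = thr)$mask
        }
        pairs <- lapply(seq_len(C), function(k) {
          mask_pair(pred[, , k], p$mask[, , k])
        })
        slice_tabs[[id]] <- suppressWarnings(
          metrics_report(pairs, ids = sprintf("%s_s%02d", id, seq_len(C)),
                         level = "slice", fold = 1L))
        scan_pairs[[id]] <- mask_pair(pred, p$mask)
      }
      slice_tab <- dplyr::bind_rows(slice_tabs)
      scan_tab <- suppressWarnings(
        metrics_report(scan_pairs, ids = names(scan_pairs), level = "scan",
                       fold = 1L))
      write_table(slice_tab, file.path(out, "metrics_slice.csv"))
      write_table(scan_tab, file.path(out, "metrics_scan.csv"))
      write_table(aggregate_folds(slice_tab, "slice"),
                  file.path(out, "summary_slice.csv"))
      save_state("metrics", list(slice = slice_tab, scan = scan_tab))
    })
  }

  if ("compare" %in% stages) {
    res$comparison <- run_stage("compare", function() {
      prep <- res$prep %||% load_state("prep")
      sp <- res$split %||% load_state("split")
      mdl <- get_model()
      thr <- config$metrics$threshold
      segmenters <- list(
        adapter_model = function(img) predict_mask(mdl, img, threshold = thr)$mask,
        intensity_band = function(img) threshold_segmenter(img),
        all_background = function(img) matrix(0L, nrow(img), ncol(img))
      )
      ids <- sp$test_ids
      scores <- sapply(segmenters, function(f) {
        vapply(ids, function(id) {
          p <- prep[[id]]
          pred <- array(0L, dim(p$image))
          for (k in seq_len(dim(p$image)[3])) pred[, , k] <- f(p$image[, , k])
          dice(mask_pair(pred, p$mask))
        }, numeric(1))
      })
      cmp <- compare_models(scores)
      write_table(
        cbind(tibble::tibble(scan_id = ids), tibble::as_tibble(scores)),
        file.path(out, "compare_scores.csv"))
      write_table(glance.friedman_test(cmp$friedman),
                  file.path(out, "compare_friedman.csv"))
      if (!is.null(cmp$nemenyi)) {
        write_table(tidy.nemenyi_posthoc(cmp$nemenyi),
                    file.path(out, "compare_pairs.csv"))
      }
      save_state("comparison", list(scores = scores,
                                    friedman = glance.friedman_test(cmp$friedman)))
      cmp
    })
  }

  if ("agreement" %in% stages) {
    res$agreement <- run_stage("agreement", function() {
      ds <- res$dataset %||% load_state("dataset")
      ref <- list(); cmpm <- list()
      for (s in ds$scans) {
        for (k in seq_len(dim(s$gt)[3])) {
          ref[[length(ref) + 1L]] <- s$gt[, , k]
          cmpm[[length(cmpm) + 1L]] <- s$annotator_b[, , k]
        }
      }
      ar <- agreement_report(ref, cmpm)
      bins <- size_binned_agreement(ref, cmpm, bins = config$agreement$bins)
      write_table(ar$per_slice, file.path(out, "agreement_slices.csv"))
      write_table(bins, file.path(out, "agreement_bins.csv"))
      save_state("agreement", list(summary = ar$summary, bins = bins))
      list(report = ar, bins = bins)
    })
  }

  log_line(logf, event = "done", config_hash = hash)
  invisible(res)
}
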