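# Segmentation training losses: BCE, soft Dice, Focal Tversky, and the
# distance-map boundary loss, plus weighted combinations. Each loss has a
# closed-form gradient with respect to the predicted probabilities so the
# model's logits can be trained without tracking the loss in the autodiff
# graph.

#' Loss specification
#'
#' @param components Named numeric vector of non-negative weights over
#'   `"bce"`, `"dice"`, `"focal_tversky"`, `"boundary"`. Weights may be given
#'   as the printed percentages (e.g. `c(bce = 50, boundary = 50)`); they are
#'   normalized to sum to one before combining.
#' @param alpha Tversky false-positive weight in `(0, 1)` (the false-negative
#'   weight is `1 - alpha`).
#' @param gamma Focal exponent (> 0).
#' @param epsilon Tversky smoothing constant (>= 0).
#' @param dice_smooth Dice smoothing constant.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(components = c(bce = 1), alpha = 0.4, gamma = 1,
                      epsilon = 0.01, dice_smooth = 1e-6) {
  stopifnot(length(components) >= 1, all(components >= 0), sum(components) > 0,
            alpha > 0, alpha < 1, gamma > 0, epsilon >= 0)
  known <- c("bce", "dice", "focal_tversky", "boundary")
  if (!all(names(components) %in% known)) {
    stop("unknown loss component: ",
         paste(setdiff(names(components), known), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(components = components / sum(components), alpha = alpha,
         gamma = gamma, epsilon = epsilon, dice_smooth = dice_smooth),
    class = "loss_spec"
  )
}

#' Parse a loss specification string
#'
#' Accepts the configuration syntax `"bce:0.5,boundary:0.5"`.
#'
#' @param x Character scalar.
#' @param ... Passed to [loss_spec()].
#' @return A `loss_spec`.
#' @export
parse_loss_spec <- function(x, ...) {
  parts <- strsplit(trimws(strsplit(x, ",")[[1]]), ":")
  w <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, numeric(1))
  names(w) <- vapply(parts, `[[`, character(1), 1)
  loss_spec(components = w, ...)
}

.check_pair <- function(probs, target) {
  if (!all(dim(as.matrix(probs)) == dim(as.matrix(target)))) {
    stop("probs and target shapes differ", call. = FALSE)
  }
}

.clamp <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]`.
#'
#' @param probs Predicted probabilities in `(0, 1)`.
#' @param target Binary ground truth of the same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(probs, target) {
  .check_pair(probs, target)
  p <- .clamp(probs)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_loss_grad <- function(probs, target) {
  p <- .clamp(probs)
  (p - target) / (p * (1 - p)) / length(p)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p y) + smooth) / (sum(p) + sum(y) + smooth)`.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, target, smooth = 1e-6) {
  .check_pair(probs, target)
  1 - (2 * sum(probs * target) + smooth) / (sum(probs) + sum(target) + smooth)
}

dice_loss_grad <- function(probs, target, smooth = 1e-6) {
  num <- 2 * sum(probs * target) + smooth
  den <- sum(probs) + sum(target) + smooth
  -(2 * target * den - num) / den^2
}

#' Focal Tversky loss
#'
#' Tversky index `TI = (TP + eps) / (TP + alpha FP + (1 - alpha) FN + eps)`
#' on soft counts `TP = sum(p y)`, `FP = sum(p (1 - y))`, `FN = sum((1 - p) y)`,
#' with loss `(1 - TI)^gamma`. The index is clamped away from 0 and 1 before
#' exponentiation to guard against the gradient blow-ups this loss is known
#' for when the index fluctuates rapidly.
#'
#' @inheritParams bce_loss
#' @param alpha False-positive weight in `(0, 1)`.
#' @param gamma Focal exponent.
#' @param epsilon Smoothing constant.
#' @param clamp Clamping margin for the Tversky index.
#' @return Scalar loss.
#' @export
focal_tversky_loss <- function(probs, target, alpha = 0.4, gamma = 1,
                               epsilon = 0.01, clamp = 1e-6) {
  .check_pair(probs, target)
  stopifnot(alpha > 0, alpha < 1)
  ti <- .tversky_index(probs, target, alpha, epsilon)
  (1 - min(max(ti, clamp), 1 - clamp))^gamma
}

.tversky_index <- function(probs, target, alpha, epsilon) {
  tp <- sum(probs * target)
  fp <- sum(probs * (1 - target))
  fn <- sum((1 - probs) * target)
  (tp + epsilon) / (tp + alpha * fp + (1 - alpha) * fn + epsilon)
}

focal_tversky_loss_grad <- function(probs, target, alpha = 0.4, gamma = 1,
                                    epsilon = 0.01, clamp = 1e-6) {
  tp <- sum(probs * target)
  fp <- sum(probs * (1 - target))
  fn <- sum((1 - probs) * target)
  den <- tp + alpha * fp + (1 - alpha) * fn + epsilon
  ti <- (tp + epsilon) / den
  if (ti <= clamp || ti >= 1 - clamp) {
    return(array(0, dim(as.array(probs))))
  }
  # d ti / d p = (y * den - (tp + eps) * (y + alpha (1-y) - (1-alpha) y)) / den^2
  dden <- target + alpha * (1 - target) - (1 - alpha) * target
  dti <- (target * den - (tp + epsilon) * dden) / den^2
  -gamma * (1 - ti)^(gamma - 1) * dti
}

#' Signed distance map of a binary mask
#'
#' Euclidean distance to the nearest mask-boundary pixel (a mask pixel with a
#' 4-neighbour background pixel): negative strictly inside the mask, positive
#' outside, zero on the boundary itself. An all-background mask returns the
#' maximum image diagonal everywhere (with a warning); an all-foreground mask
#' returns its negative.
#'
#' @param mask Binary matrix.
#' @return Numeric matrix of signed distances (pixels).
#' @export
signed_distance_map <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1L
  H <- nrow(m); W <- ncol(m)
  dmax <- sqrt(H^2 + W^2)
  if (all(m == 0)) {
    warning("signed_distance_map: empty mask, returning +max distance")
    return(matrix(dmax, H, W))
  }
  if (all(m == 1)) {
    warning("signed_distance_map: full mask, returning -max distance")
    return(matrix(-dmax, H, W))
  }
  b <- boundary_pixels(m)
  # distance of every pixel to the boundary set via EBImage's exact EDT:
  # distmap(x) gives, for each nonzero pixel of x, the distance to the nearest
  # zero pixel, so distance-to-B is distmap(1 - B).
  d <- EBImage::distmap(1 - b, metric = "euclidean")
  d <- matrix(as.numeric(d), H, W)
  d[m == 1] <- -d[m == 1]
  d[b == 1] <- 0
  d
}

# Mask pixels with at least one 4-neighbour background pixel (image border
# counts as background).
boundary_pixels <- function(m) {
  m <- (as.matrix(m) > 0) * 1L
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  up <- pad[1:H, 2:(W + 1)]
  dn <- pad[3:(H + 2), 2:(W + 1)]
  lf <- pad[2:(H + 1), 1:W]
  rt <- pad[2:(H + 1), 3:(W + 2)]
  b <- m * ((up == 0) | (dn == 0) | (lf == 0) | (rt == 0))
  storage.mode(b) <- "integer"
  b
}

#' Boundary (surface) loss
#'
#' Mean over pixels of `sdm * probs`: the predicted probability mass
#' integrated against the ground truth's signed distance map, so probability
#' inside the target contributes negatively and probability outside
#' positively. Sign-indefinite by construction.
#'
#' @param probs Predicted probabilities.
#' @param sdm Signed distance map of the ground-truth mask
#'   (see [signed_distance_map()]).
#' @return Scalar loss.
#' @export
boundary_loss <- function(probs, sdm) {
  .check_pair(probs, sdm)
  mean(sdm * probs)
}

boundary_loss_grad <- function(probs, sdm) sdm / length(sdm)

#' Evaluate a combined loss
#'
#' Computes the weighted sum of the components of a [loss_spec()] (weights
#' normalized to sum to one) and, optionally, its gradient with respect to the
#' predicted probabilities.
#'
#' @param probs Predicted probabilities.
#' @param target Binary ground truth.
#' @param spec A [loss_spec()].
#' @param sdm Signed distance map of `target`; computed on the fly when a
#'   boundary component is present and `sdm` is `NULL`.
#' @param gradient Also return the gradient?
#' @return Scalar loss, or `list(value, grad)` when `gradient = TRUE`.
#' @export
combined_loss <- function(probs, target, spec, sdm = NULL, gradient = FALSE) {
  stopifnot(inherits(spec, "loss_spec"))
  w <- spec$components
  if ("boundary" %in% names(w) && is.null(sdm)) {
    sdm <- suppressWarnings(signed_distance_map(target))
  }
  val <- 0
  grad <- if (gradient) probs * 0
  for (nm in names(w)) {
    wi <- w[[nm]]
    if (wi == 0) next
    val <- val + wi * switch(nm,
      bce = bce_loss(probs, target),
      dice = dice_loss(probs, target, spec$dice_smooth),
      focal_tversky = focal_tversky_loss(probs, target, spec$alpha,
                                         spec$gamma, spec$epsilon),
      boundary = boundary_loss(probs, sdm)
    )
    if (gradient) {
      grad <- grad + wi * switch(nm,
        bce = bce_loss_grad(probs, target),
        dice = dice_loss_grad(probs, target, spec$dice_smooth),
        focal_tversky = focal_tversky_loss_grad(probs, target, spec$alpha,
                                                spec$gamma, spec$epsilon),
        boundary = boundary_loss_grad(probs, sdm)
      )
    }
  }
  if (gradient) list(value = val, grad = grad) else val
}
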