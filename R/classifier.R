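#' Train the mouse-versus-background patch classifier
#'
#' Binary classifier over candidate-region crops, following the standard
#' protocol: a random 80/20 train/validation split, cross-entropy loss, and a
#' fixed learning rate over a fixed number of epochs for the iterative
#' backbone. Patches are resized to `config$patch_size_px` and reduced to
#' intensity/shape features (mean, spread, foreground fraction, contrast,
#' elongation, bounding-box fill); the `"logistic"` backbone fits a logistic
#' regression on them, the `"mlp"` backbone a single-hidden-layer network
#' trained one epoch at a time so the report carries a true per-epoch loss
#' curve. Both backbones are deterministic under a fixed seed.
#'
#' @param labeled_patches Tibble (or data frame) with a `patch` list-column
#'   of numeric matrices (gray 0-255) and a `label` column (1 = mouse,
#'   0 = background).
#' @param config A [train_config()].
#' @return A `mouse_classifier`: backbone fit plus a training report
#'   (per-epoch cross-entropy, final train/validation accuracy). Use
#'   [tidy()] for the loss curve, [glance()] for the summary row.
#' @export
train_classifier <- function(labeled_patches, config = train_config()) {
  lp <- as_tibble(labeled_patches)
  stopifnot(all(c("patch", "label") %in% names(lp)))
  y <- as.integer(lp$label)
  if (length(unique(y)) < 2) {
    abort("training requires both classes (mouse and background) present")
  }
  X <- do.call(rbind, lapply(lp$patch, patch_features, size = config$patch_size_px))

  set.seed(config$seed)
  n <- nrow(X)
  n_train <- round(config$split_fraction * n)
  train_idx <- sort(sample.int(n, n_train))
  val_idx <- setdiff(seq_len(n), train_idx)

  Xt <- X[train_idx, , drop = FALSE]; yt <- y[train_idx]
  Xv <- X[val_idx, , drop = FALSE];  yv <- y[val_idx]

  if (config$backbone == "logistic") {
    df <- as.data.frame(Xt); df$y <- yt
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    p_t <- suppressWarnings(as.numeric(predict(fit, as.data.frame(Xt),
                                               type = "response")))
    report <- tibble(epoch = 1L, train_loss = cross_entropy(yt, p_t))
  } else {
    sc <- feature_scaling(Xt)
    Zt <- scale_features(Xt, sc)
    wts <- NULL
    losses <- numeric(config$epochs)
    for (e in seq_len(config$epochs)) {
      args <- list(Zt, yt, size = config$hidden_units, entropy = TRUE,
                   maxit = 1, decay = 1e-4, trace = FALSE,
                   rang = 0.5, abstol = 0, reltol = 0)
      if (!is.null(wts)) args$Wts <- wts  # warm start from the last epoch
      fit <- suppressWarnings(do.call(nnet::nnet, args))
      wts <- fit$wts
      losses[e] <- cross_entropy(yt, as.numeric(predict(fit, Zt)))
    }
    fit$feature_scaling <- sc
    p_t <- as.numeric(predict(fit, Zt))
    report <- tibble(epoch = seq_len(config$epochs), train_loss = losses)
  }

  obj <- structure(
    list(backbone = config$backbone, fit = fit,
         patch_size = config$patch_size_px, config = config,
         train_idx = train_idx, report = report),
    class = "mouse_classifier"
  )
  p_v <- predict_scores(obj, Xv)
  obj$train_accuracy <- mean((p_t > 0.5) == (yt == 1))
  obj$val_accuracy <- if (length(yv)) mean((p_v > 0.5) == (yv == 1)) else NA_real_
  obj
}

cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

feature_scaling <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  list(mu = mu, sd = sg)
}

scale_features <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
}

# Score a feature matrix with either backbone; always in [0,1]. The logistic
# branch applies the coefficients directly (rank-deficient NA coefficients
# count as zero), bypassing predict.glm's model-frame machinery on the
# per-frame hot path.
predict_scores <- function(classifier, X) {
  if (nrow(X) == 0) return(numeric(0))
  p <- if (classifier$backbone == "logistic") {
    beta <- classifier$fit$coefficients
    beta[is.na(beta)] <- 0
    as.numeric(stats::plogis(
      beta[1] + X[, names(beta)[-1], drop = FALSE] %*% beta[-1]))
  } else {
    as.numeric(predict(classifier$fit,
                       scale_features(X, classifier$fit$feature_scaling)))
  }
  pmin(pmax(p, 0), 1)
}

#' @export
print.mouse_classifier <- function(x, ...) {
  cat(sprintf(
    "<mouse_classifier> backbone=%s, patch=%dpx, train acc %.3f, val acc %.3f\n",
    x$backbone, x$patch_size, x$train_accuracy, x$val_accuracy))
  invisible(x)
}

#' @method tidy mouse_classifier
#' @export
tidy.mouse_classifier <- function(x, ...) x$report

#' @method glance mouse_classifier
#' @export
glance.mouse_classifier <- function(x, ...) {
  tibble(backbone = x$backbone,
         n_train = length(x$train_idx),
         train_accuracy = x$train_accuracy,
         val_accuracy = x$val_accuracy,
         final_loss = tail(x$report$train_loss, 1))
}

#' Score a single patch
#'
#' @param classifier A `mouse_classifier`.
#' @param patch Numeric matrix crop (gray 0-255); resized internally to the
#'   classifier's patch size.
#' @return Confidence in `[0, 1]` that the patch is the mouse. Deterministic
#'   given the model state.
#' @export
score_patch <- function(classifier, patch) {
  if (!is.matrix(patch) || length(patch) == 0) {
    abort("cannot score an empty patch")
  }
  predict_scores(classifier,
                 matrix(patch_features(patch, classifier$patch_size),
                        nrow = 1,
                        dimnames = list(NULL, patch_feature_names())))
}

# --- patch features ---------------------------------------------------------

patch_feature_names <- function() {
  c("mean_gray", "sd_gray", "fg_frac", "contrast", "elongation", "bbox_fill")
}

# Nearest-neighbour resize to size x size.
resize_patch <- function(patch, size) {
  nr <- nrow(patch); nc <- ncol(patch)
  ri <- pmin(pmax(floor((seq_len(size) - 0.5) * nr / size) + 1, 1), nr)
  ci <- pmin(pmax(floor((seq_len(size) - 0.5) * nc / size) + 1, 1), nc)
  patch[ri, ci, drop = FALSE]
}

# Intensity/shape features of a resized patch. The crop is lightly smoothed
# first so pixel noise cannot glitch the Otsu split or the moment estimates
# (a one-frame feature glitch becomes a spurious prediction-score jump and a
# false activity call downstream). The foreground is the minority side of
# the patch's Otsu split (the object is smaller than its surround in a
# candidate crop), which stays stable when the crop also contains part of a
# shadow or distractor; a contrast gate zeroes the shape features on
# featureless crops where Otsu would only split noise.
patch_features <- function(patch, size) {
  p <- cpp_gauss_blur(resize_patch(patch, size), 1)
  m <- mean(p); s <- sd(p)
  out <- c(mean_gray = m / 255, sd_gray = s / 255,
           fg_frac = 0, contrast = 0, elongation = 0, bbox_fill = 0)
  thr <- cpp_otsu(p, 255)
  fg <- p > thr
  if (mean(fg) > 0.5) fg <- !fg
  if (any(fg) && any(!fg)) {
    contrast <- abs(mean(p[fg]) - mean(p[!fg]))
    if (contrast > 8) {  # below this the split is just noise
      out["fg_frac"] <- mean(fg)
      out["contrast"] <- contrast / 255
      idx <- which(fg, arr.ind = TRUE)
      if (nrow(idx) > 4) {
        cv <- stats::cov(idx)
        ev <- sort(abs(eigen(cv, symmetric = TRUE, only.values = TRUE)$values),
                   decreasing = TRUE)
        if (ev[2] > 1e-9) out["elongation"] <- min(sqrt(ev[1] / ev[2]), 10)
        bb <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
        out["bbox_fill"] <- nrow(idx) / bb
      }
    }
  }
  out
}

#' Harvest labelled training patches from a simulation
#'
#' Builds a labelled patch set from a ground truth and scenario without any
#' manual annotation, using the detector's own candidate extraction so the
#' crop geometry at training time matches the crop geometry at scoring time:
#' frames are sampled at random (covering light and dark phases and both
#' postures), candidate regions are extracted, and each candidate crop is
#' labelled positive when it contains the mouse — its mask covers the true
#' position, or its centroid lies within one mouse radius of it (this keeps
#' blobs where the mouse merges with a distractor or shadow positive) — and
#' negative otherwise (distractor blobs, shadows).
#'
#' @param truth A `cage_truth` (trajectory added if absent).
#' @param scenario A [cage_scenario()].
#' @param n_per_class Target patches per class (classes are truncated to a
#'   common achievable size, at least this when enough frames exist).
#' @param params A [vision_params()]; defaults to the scenario's expected
#'   mouse area.
#' @param seed Seed for frame sampling.
#' @return Tibble with `patch` (list-column) and `label` (1/0), suitable for
#'   [train_classifier()].
#' @export
harvest_training_patches <- function(truth, scenario, n_per_class = 200,
                                     params = NULL, seed = 1L) {
  if (is.null(truth$trajectory)) truth <- add_trajectory(truth, scenario)
  if (is.null(params)) {
    params <- vision_params(
      expected_area_px = round(pi * 1.4 * 0.75 * scenario$mouse_radius_px^2))
  }
  rc <- render_context(truth, scenario)
  set.seed(seed)
  n_frames <- nrow(truth$trajectory)
  pos <- list(); neg <- list()
  order_frames <- sample.int(n_frames)
  r_match <- scenario$mouse_radius_px
  for (i in order_frames) {
    if (length(pos) >= n_per_class && length(neg) >= n_per_class) break
    f <- render_frame_ctx(rc, i)
    cands <- extract_roi_candidates(f, params)
    if (nrow(cands) == 0) next
    mr <- truth$trajectory$row[i]; mc <- truth$trajectory$col[i]
    d <- sqrt((cands$row - mr)^2 + (cands$col - mc)^2)
    truth_px <- round(mr) + (round(mc) - 1L) * nrow(f)
    covers <- vapply(cands$pixels, function(px) truth_px %in% px, logical(1))
    for (k in seq_len(nrow(cands))) {
      crop <- crop_candidate(f, cands[k, ])
      if (covers[k] || d[k] <= r_match) {
        if (length(pos) < n_per_class) pos[[length(pos) + 1]] <- crop
      } else if (length(neg) < n_per_class) {
        neg[[length(neg) + 1]] <- crop
      }
    }
  }
  # scenes without distractors yield few or no negative candidates; top the
  # negative class up with random background crops away from the mouse, the
  # same size as a typical mouse crop
  if (length(neg) < n_per_class) {
    side <- round(2.8 * scenario$mouse_radius_px)
    half <- side %/% 2
    n_fill <- n_per_class - length(neg)
    fill_frames <- sample.int(n_frames, n_fill, replace = TRUE)
    for (k in seq_len(n_fill)) {
      i <- fill_frames[k]
      f <- render_frame_ctx(rc, i)
      mr <- truth$trajectory$row[i]; mc <- truth$trajectory$col[i]
      repeat {
        r0 <- runif(1, half + 1, scenario$height_px - half)
        c0 <- runif(1, half + 1, scenario$width_px - half)
        if (sqrt((r0 - mr)^2 + (c0 - mc)^2) >= 3 * scenario$mouse_radius_px) break
      }
      neg[[length(neg) + 1]] <-
        f[(round(r0) - half):(round(r0) + half),
          (round(c0) - half):(round(c0) + half)]
    }
  }
  if (!length(pos) || !length(neg)) {
    abort("could not harvest both classes from this simulation")
  }
  tibble(patch = c(pos, neg),
         label = rep(c(1L, 0L), c(length(pos), length(neg))))
}

#' Save / load a trained classifier
#'
#' The model is serialised to a single file with a JSON sidecar recording the
#' backbone, patch size and training seed.
#'
#' @param classifier A `mouse_classifier`.
#' @param path Model file path; the sidecar is written to `<path>.json`.
#' @return `write_classifier`: invisibly, `path`. `read_classifier`: the
#'   restored `mouse_classifier`.
#' @export
write_classifier <- function(classifier, path) {
  saveRDS(classifier, path)
  jsonlite::write_json(
    list(backbone = classifier$backbone,
         patch_size_px = classifier$patch_size,
         seed = classifier$config$seed,
         train_accuracy = classifier$train_accuracy,
         val_accuracy = classifier$val_accuracy),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "mouse_classifier"))
  obj
}
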