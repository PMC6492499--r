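#' Configuration of the patch classification network
#'
#' Describes a compact residual bottleneck network for classifying 240 x 240
#' bouton patches. Compared with a generic 50-layer residual classifier, the
#' stem uses only stride-1 convolutions and a single pooling layer, so its
#' output feature map is half the input size (120 x 120) rather than a
#' quarter; and the stage widths are greatly reduced, since telling boutons
#' from non-bouton swellings is a far simpler task than natural-image
#' classification. Global average pooling over the last stage yields the
#' 64-dimensional penultimate feature used both for classification and for
#' downstream morphology analysis.
#'
#' @param input_size input patch side length in pixels (default 240).
#' @param in_channels input channels (1: grayscale).
#' @param stem_width channels of the stem convolution.
#' @param stem_kernel stem kernel size (odd).
#' @param stage_widths bottleneck output channels per stage; the last entry
#'   must equal `embedding_dim`.
#' @param blocks_per_stage number of bottleneck blocks per stage.
#' @param stage_strides stride of the first block of each stage.
#' @param bottleneck_factor reduction factor of the inner 3x3 convolution.
#' @param dropout_rate dropout applied to the pooled feature during training.
#' @param embedding_dim penultimate feature dimension (64).
#' @param n_classes output classes (2: bouton / non-bouton).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(input_size = 240L, in_channels = 1L,
                              stem_width = 8L, stem_kernel = 3L,
                              stage_widths = c(16L, 32L, 64L, 64L),
                              blocks_per_stage = rep(1L, length(stage_widths)),
                              stage_strides = c(2L, 2L, 2L, 2L),
                              bottleneck_factor = 4L, dropout_rate = 0.5,
                              embedding_dim = 64L, n_classes = 2L) {
  cfg <- list(input_size = as.integer(input_size),
              in_channels = as.integer(in_channels),
              stem_width = as.integer(stem_width),
              stem_kernel = as.integer(stem_kernel),
              stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              stage_strides = as.integer(stage_strides),
              bottleneck_factor = as.integer(bottleneck_factor),
              dropout_rate = dropout_rate,
              embedding_dim = as.integer(embedding_dim),
              n_classes = as.integer(n_classes))
  if (cfg$embedding_dim != utils::tail(cfg$stage_widths, 1)) {
    stop("last stage width must equal embedding_dim (global average pooling ",
         "produces the penultimate feature)")
  }
  if (length(cfg$blocks_per_stage) != length(cfg$stage_widths) ||
      length(cfg$stage_strides) != length(cfg$stage_widths)) {
    stop("stage_widths, blocks_per_stage and stage_strides must align")
  }
  if (cfg$stem_kernel %% 2L != 1L) stop("stem_kernel must be odd")
  if (cfg$in_channels != 1L) {
    stop("only single-channel (grayscale) input patches are supported")
  }
  class(cfg) <- "classifier_config"
  cfg
}

#' Build the network description from a configuration
#'
#' Lays out the stem (stride-1 convolution, rectified-linear activation, one
#' 2x2 max pooling) and the residual bottleneck blocks, and records every
#' layer's shape. No parameters are allocated; see [init_classifier()].
#'
#' @param config a [classifier_config()].
#' @return a `bouton_network`: list with `config`, `blocks` (per-block
#'   channel/stride descriptors) and `stem_out_size`.
#' @export
build_network <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  size <- config$input_size %/% 2L   # after the single stem pooling
  blocks <- list()
  cin <- config$stem_width
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    mid <- max(1L, w %/% config$bottleneck_factor)
    for (b in seq_len(config$blocks_per_stage[s])) {
      stride <- if (b == 1L) config$stage_strides[s] else 1L
      blocks[[length(blocks) + 1L]] <-
        list(cin = cin, mid = mid, cout = w, stride = stride,
             proj = (stride != 1L || cin != w))
      cin <- w
      if (stride != 1L) size <- out_conv_size(size, 3L, stride, 1L)
    }
  }
  structure(list(config = config, blocks = blocks,
                 stem_out_size = config$input_size %/% 2L,
                 final_size = size),
            class = "bouton_network")
}

out_conv_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

#' Count learnable parameters of a network configuration
#'
#' @param config a [classifier_config()].
#' @return total number of scalar weights and biases.
#' @export
count_parameters <- function(config) {
  net <- build_network(config)
  cfg <- net$config
  n <- cfg$stem_kernel^2 * cfg$in_channels * cfg$stem_width +
    3 * cfg$stem_width                           # bias + batch-norm scale/shift
  for (bl in net$blocks) {
    n <- n + bl$cin * bl$mid + 3 * bl$mid +      # 1x1 reduce (+ bn)
      9 * bl$mid * bl$mid + 3 * bl$mid +         # 3x3 (+ bn)
      bl$mid * bl$cout + 3 * bl$cout             # 1x1 expand (+ bn)
    if (bl$proj) n <- n + bl$cin * bl$cout + 3 * bl$cout
  }
  n + cfg$embedding_dim * cfg$n_classes + cfg$n_classes
}

#' A 50-layer reference configuration with unreduced widths
#'
#' The classical bottleneck layout (stages 256/512/1024/2048 with 3/4/6/3
#' blocks); used to quantify how much the default bouton classifier shrinks
#' the feature maps.
#'
#' @return a `classifier_config`.
#' @export
reference_wide_config <- function() {
  classifier_config(stem_width = 64L, stem_kernel = 7L,
                    stage_widths = c(256L, 512L, 1024L, 2048L),
                    blocks_per_stage = c(3L, 4L, 6L, 3L),
                    stage_strides = c(1L, 2L, 2L, 2L),
                    embedding_dim = 2048L)
}

#' Initialize network parameters
#'
#' He-normal weight initialization (`sd = sqrt(2 / fan_in)`), zero biases.
#'
#' @param net a [build_network()] result.
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
init_classifier <- function(net, seed = 0L) {
  withr::with_seed(seed, init_classifier_params_local(net))
}

he_conv <- function(k, cin, cout) {
  fan <- k * k * cin
  list(w = array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / fan)),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass. x: array (H, W, C, N). Returns probs (N x n_classes),
# features (N x embedding_dim) and, when `keep_caches` (training mode), the
# activations needed for backpropagation. Every convolution is followed by
# batch normalization (batch statistics during training, running statistics
# at inference so predictions do not depend on batch partitioning), as in
# the residual architecture this classifier is based on. Rectified-linear
# activations are fused into the C++ ops and the residual addition mutates
# the freshly allocated main-branch tensor, so no large temporaries are
# copied in R.
network_forward <- function(net, params, x, dropout_mask = NULL,
                            keep_caches = FALSE) {
  cfg <- net$config
  training <- keep_caches
  eps <- 1e-5
  bn_stats <- list()
  bn <- function(z, nm, relu) {
    p <- params[[nm]]
    r <- .bn_forward_cpp(z, p$gamma, p$beta, p$rmean, p$rvar, training, eps,
                         relu)
    if (training) bn_stats[[nm]] <<- r[c("mean", "var", "invstd", "xhat")]
    r$y
  }
  pad_stem <- (cfg$stem_kernel - 1L) %/% 2L
  stem <- .stem_forward_cpp(x, params$stem$w, params$stem$b, pad_stem)
  # batch norm transforms its input in place; in training mode the pre-norm
  # pooled activations must survive for the stem's rectifier gate, so norm
  # a copy
  h <- bn(if (keep_caches) stem$y + 0 else stem$y, "stem_bn", FALSE)
  caches <- if (keep_caches) list(x = x, stem_y = stem$y,
                                  stem_idx = stem$idx) else NULL
  for (i in seq_along(net$blocks)) {
    bl <- net$blocks[[i]]
    pw <- params[[paste0("b", i, "_c1")]]
    h1 <- bn(.conv_forward_cpp(h, pw$w, pw$b, 1L, 0L, FALSE),
             paste0("b", i, "_bn1"), TRUE)
    pw <- params[[paste0("b", i, "_c2")]]
    h2 <- bn(.conv_forward_cpp(h1, pw$w, pw$b, bl$stride, 1L, FALSE),
             paste0("b", i, "_bn2"), TRUE)
    pw <- params[[paste0("b", i, "_c3")]]
    h3 <- bn(.conv_forward_cpp(h2, pw$w, pw$b, 1L, 0L, FALSE),
             paste0("b", i, "_bn3"), FALSE)
    sc <- if (bl$proj) {
      pw <- params[[paste0("b", i, "_proj")]]
      bn(.conv_forward_cpp(h, pw$w, pw$b, bl$stride, 0L, FALSE),
         paste0("b", i, "_bnp"), FALSE)
    } else h
    out <- .add_relu_inplace_cpp(h3, sc)
    if (keep_caches) {
      caches[[paste0("b", i)]] <- list(input = h, h1 = h1, h2 = h2, out = out)
    }
    h <- out
  }
  if (keep_caches) caches$bn_stats <- bn_stats
  d <- dim(h)
  feat <- t(matrix(colMeans(matrix(h, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  feat_d <- if (is.null(dropout_mask)) feat else feat * dropout_mask
  logits <- feat_d %*% params$fc$w +
    matrix(params$fc$b, nrow(feat), cfg$n_classes, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (keep_caches) {
    caches$feat <- feat; caches$feat_d <- feat_d; caches$last_dim <- d
  }
  list(probs = probs, features = feat, caches = caches)
}

# Backward pass for softmax cross-entropy. y_onehot: N x n_classes.
# Returns gradients with the same structure as `params`.
network_backward <- function(net, params, fwd, y_onehot, dropout_mask = NULL) {
  caches <- fwd$caches
  n <- nrow(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / n
  grads <- list()
  grads$fc <- list(w = t(caches$feat_d) %*% dlogits, b = colSums(dlogits))
  dfeat <- dlogits %*% t(params$fc$w)
  if (!is.null(dropout_mask)) dfeat <- dfeat * dropout_mask
  d <- caches$last_dim
  dh <- array(rep(t(dfeat) / (d[1] * d[2]), each = d[1] * d[2]), d)
  bn_bw <- function(dy, nm) {
    st <- caches$bn_stats[[nm]]
    g <- .bn_backward_cpp(dy, st$xhat, params[[nm]]$gamma, st$invstd)
    grads[[nm]] <<- list(gamma = g$dgamma, beta = g$dbeta)
    g$dx
  }
  for (i in rev(seq_along(net$blocks))) {
    bl <- net$blocks[[i]]
    cache <- caches[[paste0("b", i)]]
    dz <- .relu_backward_inplace_cpp(dh, cache$out)
    dzc <- dz + 0   # pristine copy for the shortcut branch
    d3 <- bn_bw(dz, paste0("b", i, "_bn3"))
    pw <- params[[paste0("b", i, "_c3")]]
    g3 <- .conv_backward_cpp(cache$h2, pw$w, d3, 1L, 0L, TRUE)
    grads[[paste0("b", i, "_c3")]] <- list(w = g3$dw, b = g3$db)
    dh2 <- bn_bw(.relu_backward_inplace_cpp(g3$dx, cache$h2),
                 paste0("b", i, "_bn2"))
    pw <- params[[paste0("b", i, "_c2")]]
    g2 <- .conv_backward_cpp(cache$h1, pw$w, dh2, bl$stride, 1L, TRUE)
    grads[[paste0("b", i, "_c2")]] <- list(w = g2$dw, b = g2$db)
    dh1 <- bn_bw(.relu_backward_inplace_cpp(g2$dx, cache$h1),
                 paste0("b", i, "_bn1"))
    pw <- params[[paste0("b", i, "_c1")]]
    g1 <- .conv_backward_cpp(cache$input, pw$w, dh1, 1L, 0L, TRUE)
    grads[[paste0("b", i, "_c1")]] <- list(w = g1$dw, b = g1$db)
    din <- g1$dx
    if (bl$proj) {
      dp <- bn_bw(dzc, paste0("b", i, "_bnp"))
      pw <- params[[paste0("b", i, "_proj")]]
      gp <- .conv_backward_cpp(cache$input, pw$w, dp, bl$stride, 0L, TRUE)
      grads[[paste0("b", i, "_proj")]] <- list(w = gp$dw, b = gp$db)
      din <- .add_inplace_cpp(din, gp$dx)
    } else {
      din <- .add_inplace_cpp(din, dzc)
    }
    dh <- din
  }
  ds <- bn_bw(dh, "stem_bn")
  pad_stem <- (net$config$stem_kernel - 1L) %/% 2L
  gs <- .stem_backward_cpp(caches$x, params$stem$w, ds, caches$stem_y,
                           caches$stem_idx, pad_stem)
  grads$stem <- list(w = gs$dw, b = gs$db)
  grads
}

#' Train the patch classification network
#'
#' Mini-batch stochastic gradient descent with momentum on the two-class
#' softmax cross-entropy, with a per-iteration learning-rate decay
#' `lr_t = lr / (1 + decay * t)`. Samples are split into a stratified
#' train/validation partition; the parameters achieving the best validation
#' accuracy are returned. Fully deterministic given identical seed, data and
#' configuration.
#'
#' @param images 3D array `(H, W, N)` of patch images, or a list of
#'   `patch_sample` objects (in which case `labels` defaults to their
#'   labels).
#' @param labels character vector of length N with two classes
#'   (conventionally `"bouton"` and `"non_bouton"`).
#' @param config a [classifier_config()].
#' @param batch_size mini-batch size (default 60).
#' @param lr initial learning rate (default 1e-2).
#' @param decay learning-rate decay per iteration (default 1e-6).
#' @param momentum momentum coefficient (default 0.9).
#' @param epochs maximum training epochs (at most ~50 are ever needed).
#' @param val_fraction held-out validation fraction (default 0.2,
#'   stratified).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param preprocess optional function applied to each mini-batch image
#'   stack `(H, W, n)` before the network (e.g. up-sampling compactly stored
#'   projections); must return a stack sized to the network input.
#' @param train_transform optional stochastic augmentation function applied
#'   to training mini-batches only (before `preprocess`), drawing from the
#'   training RNG stream; see [random_patch_transform()].
#' @param early_stop_acc stop when validation accuracy reaches this value
#'   (default `NULL`: never).
#' @param verbose print per-epoch progress.
#' @return a `trained_classifier`: list with `config`, `net`, `params`,
#'   `classes`, `log` (per-epoch data frame), `seed`, `best_val_acc`.
#' @export
train_classifier <- function(images, labels = NULL,
                             config = classifier_config(), batch_size = 60L,
                             lr = 1e-2, decay = 1e-6, momentum = 0.9,
                             epochs = 50L, val_fraction = 0.2, seed = 0L,
                             preprocess = NULL, train_transform = NULL,
                             early_stop_acc = NULL, verbose = FALSE) {
  if (is.list(images) && !is.array(images)) {
    if (is.null(labels)) {
      labels <- vapply(images, function(s) s$label, character(1))
    }
    images <- patches_to_array(images)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training requires at least two classes; got only: ",
         paste(classes, collapse = ", "))
  }
  y <- match(labels, classes)
  n <- dim(images)[3]
  tab <- table(labels)
  message_if(verbose, sprintf("training on %d samples (%s)", n,
                              paste(names(tab), tab, sep = "=",
                                    collapse = ", ")))
  net <- build_network(config)
  withr::with_seed(seed, {
    params <- init_classifier_params_local(net)
    vel <- rapply(params, function(a) a * 0, how = "replace")
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      k <- max(1L, round(length(ix) * val_fraction))
      sample(ix, k)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), val_idx)
    best <- list(acc = -1, params = params)
    log <- NULL
    iter <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        xb <- batch_stack(images, idx, preprocess, config,
                          transform = train_transform)
        yb <- y[idx]
        onehot <- matrix(0, length(idx), config$n_classes)
        onehot[cbind(seq_along(idx), yb)] <- 1
        dm <- if (config$dropout_rate > 0) {
          matrix(stats::rbinom(length(idx) * config$embedding_dim, 1,
                               1 - config$dropout_rate) /
                   (1 - config$dropout_rate),
                 length(idx), config$embedding_dim)
        } else NULL
        fwd <- network_forward(net, params, xb, dropout_mask = dm,
                               keep_caches = TRUE)
        grads <- network_backward(net, params, fwd, onehot, dropout_mask = dm)
        iter <- iter + 1L
        lr_t <- lr / (1 + decay * iter)
        upd <- sgd_update(params, vel, grads, lr_t, momentum)
        params <- upd$params; vel <- upd$vel
        eps <- 1e-12
        ep_loss <- ep_loss -
          sum(log(pmax(fwd$probs[cbind(seq_along(idx), yb)], eps)))
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs) == yb)
      }
      params <- recalibrate_bn(net, params, images, train_idx, preprocess,
                               config, batch_size)
      val_pred <- predict_batches(net, params, images, val_idx, preprocess,
                                  config)
      val_acc <- mean(max.col(val_pred) == y[val_idx])
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(ord),
                                   train_acc = ep_correct / length(ord),
                                   val_acc = val_acc, lr = lr_t))
      message_if(verbose, sprintf(
        "epoch %d: loss %.4f, train acc %.3f, val acc %.3f",
        ep, ep_loss / length(ord), ep_correct / length(ord), val_acc))
      if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
      if (!is.null(early_stop_acc) && val_acc >= early_stop_acc) break
    }
    structure(list(config = config, net = net, params = best$params,
                   classes = classes, log = log, seed = seed,
                   best_val_acc = best$acc),
              class = "trained_classifier")
  })
}

# init under the caller's (already seeded) RNG stream
init_classifier_params_local <- function(net) {
  cfg <- net$config
  bn_init <- function(C) list(gamma = rep(1, C), beta = numeric(C),
                              rmean = numeric(C), rvar = rep(1, C))
  p <- list()
  p$stem <- he_conv(cfg$stem_kernel, cfg$in_channels, cfg$stem_width)
  p$stem_bn <- bn_init(cfg$stem_width)
  for (i in seq_along(net$blocks)) {
    bl <- net$blocks[[i]]
    p[[paste0("b", i, "_c1")]] <- he_conv(1L, bl$cin, bl$mid)
    p[[paste0("b", i, "_bn1")]] <- bn_init(bl$mid)
    p[[paste0("b", i, "_c2")]] <- he_conv(3L, bl$mid, bl$mid)
    p[[paste0("b", i, "_bn2")]] <- bn_init(bl$mid)
    p[[paste0("b", i, "_c3")]] <- he_conv(1L, bl$mid, bl$cout)
    p[[paste0("b", i, "_bn3")]] <- bn_init(bl$cout)
    if (bl$proj) {
      p[[paste0("b", i, "_proj")]] <- he_conv(1L, bl$cin, bl$cout)
      p[[paste0("b", i, "_bnp")]] <- bn_init(bl$cout)
    }
  }
  p$fc <- list(w = matrix(stats::rnorm(cfg$embedding_dim * cfg$n_classes, 0,
                                       sqrt(2 / cfg$embedding_dim)),
                          cfg$embedding_dim, cfg$n_classes),
               b = numeric(cfg$n_classes))
  p
}

# Set the inference-mode normalization statistics to the average batch
# statistics of (up to) a few mini-batches of training data under the
# current weights. Recomputing them explicitly keeps inference faithful to
# the trained network even after few updates, when an exponential running
# average would still be dominated by stale early-training values.
recalibrate_bn <- function(net, params, images, idx, preprocess, config,
                           batch_size = 60L, max_batches = 10L) {
  idx <- sample(idx)   # mix classes: samples are often stored label-ordered
  starts <- seq(1L, length(idx), by = batch_size)
  starts <- starts[seq_len(min(length(starts), max_batches))]
  acc <- list()
  for (start in starts) {
    sub <- idx[start:min(start + batch_size - 1L, length(idx))]
    xb <- batch_stack(images, sub, preprocess, config)
    fwd <- network_forward(net, params, xb, keep_caches = TRUE)
    for (nm in names(fwd$caches$bn_stats)) {
      st <- fwd$caches$bn_stats[[nm]]
      if (is.null(acc[[nm]])) {
        acc[[nm]] <- list(mean = st$mean, var = st$var, n = 1L)
      } else {
        acc[[nm]]$mean <- acc[[nm]]$mean + st$mean
        acc[[nm]]$var <- acc[[nm]]$var + st$var
        acc[[nm]]$n <- acc[[nm]]$n + 1L
      }
    }
  }
  for (nm in names(acc)) {
    params[[nm]]$rmean <- acc[[nm]]$mean / acc[[nm]]$n
    params[[nm]]$rvar <- acc[[nm]]$var / acc[[nm]]$n
  }
  params
}

sgd_update <- function(params, vel, grads, lr, momentum) {
  for (nm in names(grads)) {
    for (key in names(grads[[nm]])) {
      v <- momentum * vel[[nm]][[key]] - lr * grads[[nm]][[key]]
      vel[[nm]][[key]] <- v
      params[[nm]][[key]] <- params[[nm]][[key]] + v
    }
  }
  list(params = params, vel = vel)
}

batch_stack <- function(images, idx, preprocess, config, transform = NULL) {
  xb <- images[, , idx, drop = FALSE]
  if (!is.null(transform)) xb <- transform(xb)
  if (!is.null(preprocess)) xb <- preprocess(xb)
  dim(xb) <- c(dim(xb)[1], dim(xb)[2], 1L, length(idx))
  if (dim(xb)[1] != config$input_size) {
    stop("patch size ", dim(xb)[1], " does not match network input ",
         config$input_size)
  }
  xb
}

predict_batches <- function(net, params, images, idx, preprocess, config,
                            batch_size = 60L, features = FALSE) {
  probs <- NULL; feats <- NULL
  for (start in seq(1L, length(idx), by = batch_size)) {
    sub <- idx[start:min(start + batch_size - 1L, length(idx))]
    xb <- batch_stack(images, sub, preprocess, config)
    fwd <- network_forward(net, params, xb)
    probs <- rbind(probs, fwd$probs)
    if (features) feats <- rbind(feats, fwd$features)
  }
  if (features) feats else probs
}

#' Predict bouton probabilities for patches
#'
#' @param clf a `trained_classifier` from [train_classifier()].
#' @param patches 3D array `(H, W, N)`, a single matrix, or a list of
#'   `patch_sample` objects, at the network input size.
#' @param positive_class class whose probability is reported
#'   (default `"bouton"`; falls back to the first class).
#' @return numeric vector of probabilities in `[0, 1]`, one per patch.
#' @export
classify_patches <- function(clf, patches, positive_class = "bouton") {
  stopifnot(inherits(clf, "trained_classifier"))
  arr <- patches_to_array(patches)
  if (dim(arr)[1] != clf$config$input_size ||
      dim(arr)[2] != clf$config$input_size) {
    stop("patch shape ", dim(arr)[1], "x", dim(arr)[2],
         " does not match the network input size ", clf$config$input_size)
  }
  probs <- predict_batches(clf$net, clf$params, arr, seq_len(dim(arr)[3]),
                           NULL, clf$config)
  k <- match(positive_class, clf$classes)
  if (is.na(k)) k <- 1L
  as.numeric(probs[, k])
}

#' Extract the 64-dimensional penultimate features of patches
#'
#' The pooled activation of the last hidden layer, a learned morphological
#' embedding of each swelling (size, intensity, context) usable for subtype
#' analysis.
#'
#' @inheritParams classify_patches
#' @return numeric matrix `N x embedding_dim`.
#' @export
extract_features <- function(clf, patches) {
  stopifnot(inherits(clf, "trained_classifier"))
  arr <- patches_to_array(patches)
  predict_batches(clf$net, clf$params, arr, seq_len(dim(arr)[3]), NULL,
                  clf$config, features = TRUE)
}

#' Filter candidates by classifier probability
#'
#' Extracts the classification patch around each candidate from the parent
#' volume, predicts its bouton probability, and keeps candidates with
#' probability at or above the threshold. Candidate order is preserved and
#' each surviving detection carries its probability in column `prob`.
#'
#' @param candidates candidate data frame (columns `x_um`, `y_um`, `z_um`,
#'   ...).
#' @param clf a `trained_classifier`.
#' @param volume the parent [bouton_volume()].
#' @param prob_threshold minimum probability to keep (default 0.5).
#' @param crop_size,upsample patch preparation parameters, see
#'   [extract_patch()].
#' @return detections data frame (subset of `candidates` with `prob` added).
#' @export
filter_candidates <- function(candidates, clf, volume, prob_threshold = 0.5,
                              crop_size = c(60, 60, 7), upsample = 4) {
  if (nrow(candidates) == 0L) {
    candidates$prob <- numeric(0)
    return(candidates)
  }
  patches <- lapply(seq_len(nrow(candidates)), function(i) {
    extract_patch(volume, as.numeric(candidates[i, c("x_um", "y_um", "z_um")]),
                  crop_size = crop_size, upsample = upsample)
  })
  prob <- classify_patches(clf, patches)
  out <- candidates[prob >= prob_threshold, , drop = FALSE]
  out$prob <- prob[prob >= prob_threshold]
  rownames(out) <- NULL
  out
}

patches_to_array <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 3L) return(patches)
  if (is.matrix(patches)) {
    return(array(patches, c(dim(patches), 1L)))
  }
  if (inherits(patches, "patch_sample")) patches <- list(patches)
  imgs <- lapply(patches, function(p) if (inherits(p, "patch_sample"))
    p$image else p)
  array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
}

#' Save / load a trained classifier
#'
#' The checkpoint embeds the architecture configuration, the learned
#' parameters, the training log and the RNG seed.
#'
#' @param clf a `trained_classifier`.
#' @param path checkpoint file path.
#' @return `path` (save) or the classifier (load).
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "trained_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("classifier checkpoint not found: ", path)
  clf <- readRDS(path)
  if (!inherits(clf, "trained_classifier")) {
    stop("file is not a trained classifier checkpoint: ", path)
  }
  clf
}

message_if <- function(cond, ...) if (cond) message(...)
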