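test_that("configuration invariants are enforced", {
  cfg <- classifier_config()
  expect_equal(cfg$input_size, 240L)
  expect_equal(cfg$embedding_dim, 64L)
  net <- build_network(cfg)
  expect_equal(net$stem_out_size, 120L)   # half the input: one pooling only
  expect_error(classifier_config(stage_widths = c(16L, 32L),
                                 stage_strides = c(2L, 2L),
                                 embedding_dim = 64L),
               "embedding_dim")
  expect_error(classifier_config(stem_kernel = 4L), "odd")
})

test_that("the reduced default has under 10% of the wide reference's weights", {
  expect_lt(count_parameters(classifier_config()),
            0.1 * count_parameters(reference_wide_config()))
})

test_that("the stem halves a 240x240 input", {
  cfg <- classifier_config()
  net <- build_network(cfg)
  params <- init_classifier(net, seed = 1)
  x <- array(runif(240 * 240), c(240, 240, 1, 1))
  stem <- boutonfinder:::.stem_forward_cpp(x, params$stem$w, params$stem$b, 1L)
  expect_equal(dim(stem$y), c(120L, 120L, cfg$stem_width, 1L))
})

test_that("forward pass yields normalized probabilities on any input", {
  net <- build_network(tiny_config())
  params <- init_classifier(net, seed = 2)
  x <- array(0, c(32, 32, 1, 3))
  fwd <- boutonfinder:::network_forward(net, params, x)
  expect_equal(rowSums(fwd$probs), rep(1, 3))
  expect_true(all(fwd$probs >= 0 & fwd$probs <= 1))
  expect_equal(ncol(fwd$features), 64L)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- classifier_config(input_size = 16L, stem_width = 4L,
                           stage_widths = c(8L, 8L),
                           blocks_per_stage = c(1L, 1L),
                           stage_strides = c(1L, 2L), embedding_dim = 8L,
                           dropout_rate = 0)
  net <- build_network(cfg)
  params <- init_classifier(net, seed = 3)
  set.seed(3)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  lossfn <- function(p) {
    f <- boutonfinder:::network_forward(net, p, x, keep_caches = TRUE)
    -sum(log(pmax(f$probs[y == 1], 1e-12))) / 2
  }
  fwd <- boutonfinder:::network_forward(net, params, x, keep_caches = TRUE)
  grads <- boutonfinder:::network_backward(net, params, fwd, y)
  eps <- 1e-6
  for (nm in c("stem", "b1_c2", "b2_proj", "b2_bn2", "fc")) {
    for (key in names(grads[[nm]])) {
      for (t in 1:2) {
        p2 <- params
        p2[[nm]][[key]][t] <- p2[[nm]][[key]][t] + eps
        num <- (lossfn(p2) - lossfn(params)) / eps
        g <- grads[[nm]][[key]][t]
        expect_lt(abs(num - g) / max(1e-4, abs(g) + abs(num)), 1e-3)
      }
    }
  }
})

test_that("training separates an intensity-separable patch set", {
  fit <- tiny_trained()
  expect_gte(fit$clf$best_val_acc, 0.95)
  expect_lte(nrow(fit$clf$log), 50L)
})

test_that("training is deterministic and a zero learning rate is a no-op", {
  tp <- separable_patches(n = 60)
  a <- train_classifier(tp$images, tp$labels, config = tiny_config(),
                        epochs = 1, seed = 7, lr = 0.01)
  b <- train_classifier(tp$images, tp$labels, config = tiny_config(),
                        epochs = 1, seed = 7, lr = 0.01)
  expect_equal(a$log$val_acc, b$log$val_acc)
  expect_equal(a$params, b$params)
  frozen <- train_classifier(tp$images, tp$labels, config = tiny_config(),
                             epochs = 1, seed = 7, lr = 0)
  init <- init_classifier(build_network(tiny_config()), seed = 7)
  # weights (not normalization statistics) must be untouched by lr = 0
  for (nm in names(init)) {
    for (key in intersect(names(init[[nm]]), c("w", "b", "gamma", "beta"))) {
      expect_equal(frozen$params[[nm]][[key]], init[[nm]][[key]],
                   ignore_attr = TRUE)
    }
  }
  expect_error(train_classifier(tp$images, rep("bouton", 60),
                                config = tiny_config(), epochs = 1),
               "two classes")
})

test_that("classification is consistent across batch partitions", {
  fit <- tiny_trained()
  imgs <- fit$data$images[, , 1:70]
  all_at_once <- classify_patches(fit$clf, imgs)
  one_by_one <- vapply(1:70, function(i)
    classify_patches(fit$clf, imgs[, , i]), numeric(1))
  expect_lt(max(abs(all_at_once - one_by_one)), 1e-6)
  expect_true(all(all_at_once >= 0 & all_at_once <= 1))
  expect_error(classify_patches(fit$clf, array(0, c(17, 17, 2))), "input size")
})

test_that("probabilities are robust to 180-degree rotation after training", {
  fit <- tiny_trained()
  imgs <- fit$data$images[, , 1:40]
  rot <- imgs
  for (i in 1:40) rot[, , i] <- boutonfinder:::rot90(imgs[, , i], 2)
  p1 <- classify_patches(fit$clf, imgs)
  p2 <- classify_patches(fit$clf, rot)
  expect_lt(stats::median(abs(p1 - p2)), 0.05)
})

test_that("penultimate features are 64-d, deterministic and separable", {
  fit <- tiny_trained()
  imgs <- fit$data$images
  feats <- extract_features(fit$clf, imgs)
  expect_equal(ncol(feats), 64L)
  same <- extract_features(fit$clf, imgs[, , c(1, 1)])
  expect_equal(same[1, ], same[2, ])
  y <- as.integer(fit$data$labels == "bouton")
  probe <- suppressWarnings(stats::glm.fit(cbind(1, feats), y,
                                           family = stats::binomial()))
  acc <- mean((probe$fitted.values >= 0.5) == y)
  expect_gte(acc, 0.9)
})

test_that("filter_candidates thresholds keep order and attach probabilities", {
  fit <- tiny_trained()
  arr <- array(100, c(64, 64, 9))
  arr[30:34, 30:34, 5] <- 4000
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  cands <- data.frame(x_um = c(6.2, 6.4), y_um = c(6.2, 6.4), z_um = c(4, 4),
                      rho = c(5, 4), delta = c(1, 1), lambda = c(0, 0),
                      source_segment = 1L)
  kept_all <- filter_candidates(cands, fit$clf, vol, prob_threshold = 0,
                                crop_size = c(8, 8, 3), upsample = 4)
  expect_equal(nrow(kept_all), 2L)
  expect_equal(kept_all[, names(cands)], cands, ignore_attr = TRUE)
  expect_true(all(kept_all$prob >= 0 & kept_all$prob <= 1))
  none <- filter_candidates(cands, fit$clf, vol, prob_threshold = 1 + 1e-9,
                            crop_size = c(8, 8, 3), upsample = 4)
  expect_equal(nrow(none), 0L)
})

test_that("classifier checkpoints round-trip with config and seed", {
  fit <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(fit$clf, path)
  back <- load_classifier(path)
  expect_equal(back$seed, fit$clf$seed)
  expect_equal(back$config, fit$clf$config)
  p1 <- classify_patches(fit$clf, fit$data$images[, , 1:5])
  p2 <- classify_patches(back, fit$data$images[, , 1:5])
  expect_equal(p1, p2)
})
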