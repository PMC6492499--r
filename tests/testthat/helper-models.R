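# Shared fixtures that are expensive to build: constructed lazily, once per
# test run, inside this environment.
.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(dropout = 0.5) {
  classifier_config(input_size = 32L, stem_width = 4L,
                    stage_widths = c(16L, 64L), blocks_per_stage = c(1L, 1L),
                    stage_strides = c(2L, 2L), embedding_dim = 64L,
                    dropout_rate = dropout)
}

# A small, linearly separable patch set: bright central blobs ("bouton")
# versus faint ones ("non_bouton"), 32 x 32 pixels.
separable_patches <- function(n = 400, seed = 100) {
  withr::with_seed(seed, {
    imgs <- array(0, c(32, 32, n))
    labels <- rep(c("bouton", "non_bouton"), length.out = n)
    g <- outer(dnorm(1:32, 16.5, 3), dnorm(1:32, 16.5, 3))
    g <- g / max(g)
    for (i in seq_len(n)) {
      amp <- if (labels[i] == "bouton") runif(1, 0.7, 1) else runif(1, 0.1, 0.3)
      imgs[, , i] <- amp * g + matrix(rnorm(32 * 32, 0, 0.03), 32)
    }
    list(images = imgs, labels = labels)
  })
}

tiny_trained <- function() {
  if (is.null(.fixtures$tiny_clf)) {
    tp <- separable_patches()
    .fixtures$tiny_sep <- tp
    .fixtures$tiny_clf <- train_classifier(
      tp$images, tp$labels, config = tiny_config(), epochs = 8, seed = 1,
      lr = 0.03, early_stop_acc = 0.99)
  }
  list(clf = .fixtures$tiny_clf, data = .fixtures$tiny_sep)
}
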