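# The full surrogate benchmark (classifier training + 18 pyramidal-like and
# 2 basket-like blocks), built once per test run and shared by the
# acceptance tests. This is the expensive fixture: ~12 minutes on one CPU.

benchmark_classifier <- function() {
  if (is.null(.fixtures$bench_clf)) {
    tp <- generate_training_patches(n = 5000L, seed = 0L)
    .fixtures$bench_clf <- train_classifier(
      tp$images, tp$labels, epochs = 4L, lr = 0.05, seed = 0L,
      preprocess = training_patch_preprocess,
      train_transform = random_patch_transform)
  }
  .fixtures$bench_clf
}

benchmark_block <- function(spec, seed, clf) {
  scene <- simulate_scene(spec, seed = seed)
  cfg <- default_config()
  candidates <- merge_candidates(
    lapply(divide_tree(scene$skeleton), function(s)
      detect_block(extract_tube(scene$volume, s))),
    merge_radius = cfg$skeleton$merge_radius)
  detections <- filter_candidates(candidates, clf, scene$volume)
  truth_bt <- scene$truth[scene$truth$class == "bouton", ]
  list(full = compute_metrics(truth_bt, detections),
       initial = compute_metrics(truth_bt, candidates))
}

benchmark_results <- function() {
  if (is.null(.fixtures$bench)) {
    clf <- benchmark_classifier()
    pyr <- lapply(1:18, function(k)
      benchmark_block(scene_preset("pyramidal"), seed = k, clf))
    bas <- lapply(101:102, function(k)
      benchmark_block(scene_preset("basket"), seed = k, clf))
    .fixtures$bench <- list(pyr = pyr, bas = bas)
  }
  .fixtures$bench
}
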