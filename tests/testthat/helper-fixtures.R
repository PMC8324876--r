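# Shared synthetic study fixture: 8 classes x 40 tiles of 150x150 pixels,
# with feature tables computed lazily once per session and reused across
# test files (extraction is the expensive step).

.fixture_env <- new.env(parent = emptyenv())

fixture_get <- function(key, build) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

study_tileset <- function() {
  fixture_get("tiles", function() {
    generate_dataset(synth_config(n_classes = 8, n_per_class = 40,
                                  tile_side = 150, seed = 42))
  })
}

study_plan <- function() {
  fixture_get("plan", function() {
    make_splits(tile_labels(study_tileset()), holdout_frac = 0.1, k = 10,
                seed = 42)
  })
}

ft_subset_for_test <- function(tab, idx) {
  tab$features <- tab$features[idx, , drop = FALSE]
  tab$labels <- tab$labels[idx]
  tab$tile_ids <- tab$tile_ids[idx]
  tab
}

study_features <- function(wavelet = "haar", level = 1) {
  fixture_get(paste0("feat_", wavelet, "_", level), function() {
    extract_batch(study_tileset(), wavelet_spec(wavelet, level))
  })
}
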