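# Desk-scale study fixtures shared by the acceptance suite: one dataset
# and paired untrained/trained models per task, built once per session.
# Training conditions follow the desk-scale configuration documented in
# the methods vignette (batch 64; lr 1e-3 for recognition, 4e-3 for
# decoding, which compensates the small number of optimizer updates).

desk_dataset <- function() {
  memo("desk_ds", function() generate_dataset(dataset_config(), seed = 2026))
}

desk_pair_seeds <- function() c(101L, 202L, 303L, 404L, 505L)

desk_art_pair <- function(k) {
  memo(paste0("art_pair_", k), function() {
    ds <- desk_dataset()
    seed <- desk_pair_seeds()[k]
    untrained <- build_network(desk_architecture(seed = seed), "art")
    trained <- train_network(untrained, ds, lr = 1e-3, batch_size = 64L,
                             max_epochs = 12L, seed = seed)
    list(untrained = untrained, trained = trained)
  })
}

desk_tdt_pair <- function(k) {
  memo(paste0("tdt_pair_", k), function() {
    ds <- desk_dataset()
    seed <- desk_pair_seeds()[k]
    untrained <- build_network(desk_architecture(seed = seed), "tdt")
    trained <- train_network(untrained, ds, task = "tdt", lr = 4e-3,
                             batch_size = 64L, max_epochs = 24L, seed = seed)
    list(untrained = untrained, trained = trained)
  })
}

# analysis sample set: horizontal-plane movements
desk_analysis_idx <- function(n_max = 150L) {
  ds <- desk_dataset()
  hz <- which(ds$manifest$plane == "horizontal")
  hz[seq_len(min(length(hz), n_max))]
}

tuned_mask <- function(fits, threshold = 0.2) {
  fits$test_r2 > threshold & fits$test_r2 != 1 & fits$test_r2 >= -0.1
}

# direction-tuned unit count for one model over the given layers
direction_tuned_count <- function(net, layers = seq_along(net$layers)) {
  ds <- desk_dataset()
  idx <- desk_analysis_idx()
  sum(vapply(layers, function(L)
    sum(tuned_mask(layer_tuning_fits(net, ds, L, idx, "direction",
                                     seed = 5))), numeric(1)))
}
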