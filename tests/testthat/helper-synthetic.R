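# Shared fixtures: everything is generated in code at test time.

# desk-scale generator configuration: small canvas, proportionally small
# grains, counts scaled to what a 64 px canvas can host
desk_synth_config <- function(seed, n_grains = c(15, 40), image_size = c(64, 64)) {
  synthetic_config(image_size = image_size, n_grains = n_grains,
                   n_branches = c(2, 4), grain_axes = c(2.5, 4, 1.2, 2),
                   seed = seed)
}

# population per-channel stats straight from in-memory arrays
stats_from_arrays <- function(images) {
  pix <- vapply(1:3, function(c) {
    v <- unlist(lapply(images, function(im) im[, , c]))
    c(mean(v), sqrt(mean((v - mean(v))^2)))
  }, numeric(2))
  normalization_stats(pix[1, ], pmax(pix[2, ], 1e-6))
}

# n generated panicles turned into training items at the given stride
gen_desk_items <- function(n, seed0, stats = NULL, stride = 4) {
  gens <- lapply(seq_len(n), function(i)
    generate_panicle_image(desk_synth_config(seed0 + i),
                           image_id = sprintf("img%04d", i)))
  if (is.null(stats))
    stats <- stats_from_arrays(lapply(gens, `[[`, "image"))
  items <- lapply(gens, function(g)
    make_training_item(g$image, g$ann, stats, stride))
  list(items = items, stats = stats,
       truths = vapply(gens, function(g) n_points(g$ann), numeric(1)))
}

# uniformly random in-bounds annotation set (caller controls the RNG seed)
rand_annotations <- function(n, width = 100, height = 100, id = "rand") {
  point_annotations(id, width, height,
                    x = runif(n, 0, width - 1e-9),
                    y = runif(n, 0, height - 1e-9))
}
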