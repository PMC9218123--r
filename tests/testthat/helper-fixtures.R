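# Small in-code fixtures shared across test files.

# A handful of small annotated scenes with low counts (fast to render/train).
tiny_scene_set <- function(n, size = 48L, mu = 5, max_count = 12L, seed = 11L) {
  p <- scene_params(
    image_size = size,
    count_distribution = count_nbinom(mu = mu, size = 2, max_count = max_count),
    seed = seed)
  seeds <- sndm:::derive_seeds(seed, n)
  lapply(seeds, function(s) generate_scene(p, seed = s))
}

# Annotation with hand-placed boxes on a simple geometry.
manual_annotation <- function(boxes, size = 64L) {
  c0 <- (size - 1) / 2
  geom <- sndm:::new_dish_geometry(size, size, c0, c0, 0.46 * size)
  colony_annotation("manual", geom, boxes)
}

# Fake density_outputs for aggregation tests (counts tied to map sums).
fake_member <- function(map, beta = 1) {
  structure(list(P0 = map, beta = beta, predicted_count = sum(map)),
            class = "density_outputs")
}
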