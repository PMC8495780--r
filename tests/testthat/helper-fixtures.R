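# Shared fixtures, built in code.

# three-tip tree used throughout: ((A:1,B:1):1,C:2);
toy_tree <- function() gutscaling::read_newick("((A:1,B:1):1,C:2);")

star_tree <- function() gutscaling::read_newick("(A:1,B:1,C:1);")

# brute-force shared root-to-MRCA path lengths by walking tip-to-root paths
brute_force_shared_paths <- function(tree, species = tree$tip.label) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent_of[node]
    }
    c(nodes, root)
  }
  idx <- match(species, tree$tip.label)
  paths <- lapply(idx, path_to_root)
  M <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  for (i in seq_along(species)) {
    for (k in seq_along(species)) {
      mrca <- intersect(paths[[i]], paths[[k]])[1L]
      # shared path = distance from root down to the mrca
      node <- mrca
      d <- 0
      while (node != root) {
        d <- d + len_of[node]
        node <- parent_of[node]
      }
      M[i, k] <- d
    }
  }
  M
}

# small noiseless synthetic table: deterministic linear predictor
tiny_specimens <- function() {
  gutscaling::as_specimens(data.frame(
    species = rep(c("A", "B", "C"), each = 3),
    sl_cm = c(10, 15, 20, 12, 18, 24, 8, 16, 32),
    il_cm = c(20, 30, 40, 25, 37, 50, 15, 30, 60),
    matrix(0.5, 9, 10, dimnames = list(NULL, paste0("d", 1:10, "_cm")))
  ))
}

tiny_metadata <- function() {
  gutscaling::as_species_metadata(data.frame(
    species = c("A", "B", "C"),
    tl = c(2.0, 3.2, 4.4),
    el = c(2.0, 2.5, 3.5),
    stomach = c(1, 1, 0),
    durophagy = c(0, 1, 0),
    max_size_cm = c(40, 50, 60)
  ))
}

# quick fitted model on a small synthetic dataset, reused by summary tests
quick_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- gutscaling::simulate_dataset(n_species = 25, n_per_species = c(4, 12),
                                         seed = 42)
      fit <- gutscaling::fit_gut_model(
        ds$specimens, ds$metadata, ds$tree, response = "length",
        chains = 2, iter = 1200, warmup = 400, seed = 5,
        compute_diagnostics = FALSE)
      cache <<- list(ds = ds, fit = fit)
    }
    cache
  }
})
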