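# Jaccard index between two pixel label sets
jaccard <- function(a_idx, b_idx)
  length(intersect(a_idx, b_idx)) / length(union(a_idx, b_idx))

# match segmented labels to truth labels by maximal pixel overlap and
# return the per-truth-nucleus Jaccard indices
jaccard_vs_truth <- function(seg, truth_mask) {
  truth_ids <- sort(unique(truth_mask[truth_mask > 0]))
  vapply(truth_ids, function(id) {
    t_idx <- which(truth_mask == id)
    labs <- seg[t_idx]
    labs <- labs[labs > 0]
    if (!length(labs)) return(0)
    best <- as.integer(names(which.max(table(labs))))
    jaccard(which(seg == best), t_idx)
  }, numeric(1))
}

# brute-force minimum-total-distance assignment between two point sets of
# equal small size (exhaustive over permutations) -- tracking oracle
brute_force_assignment <- function(prev, cur) {
  n <- nrow(prev)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(sqrt((prev$x - cur$x[p])^2 + (prev$y - cur$y[p])^2))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# a small rendered field shared by segmentation tests
make_test_field <- function(n = 12, seed = 7, noise_sd = 0, size = 420) {
  pop <- make_cell_population(n, seed = seed)
  pop <- place_cells(pop, size, size, margin = 6, seed = seed + 1)
  render_field(pop, field_spec(size, size, noise_sd = noise_sd,
                               seed = seed + 2))
}
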