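# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small condensed-phase trajectory (cheap; used by several property tests)
fixture_condensed_traj <- function() {
  if (is.null(.fixture_env$traj)) {
    top <- build_topology(build_ctd("cons", 2))
    cfg <- sim_config(box = c(8, 8, 8), n_chains = 6, n_steps = 20000,
                      seed = 99, sample_every = 2000, friction = 0.3)
    .fixture_env$traj <- run_dynamics(top, cfg)
  }
  .fixture_env$traj
}

# hand-built single-chain trajectory from an explicit frame list
make_traj <- function(frames, chain_id = NULL, box = NULL,
                      is_backbone = NULL) {
  nb <- nrow(frames[[1]])
  arr <- array(0, dim = c(length(frames), nb, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  structure(list(
    frames = arr,
    chain_id = if (is.null(chain_id)) rep(1L, nb) else chain_id,
    residue = seq_len(nb),
    is_backbone = if (is.null(is_backbone)) rep(TRUE, nb) else is_backbone,
    type = rep("S", nb), box = box, topologies = NULL
  ), class = "cg_trajectory")
}

# independent brute-force connected components (BFS), used as the oracle
# against the package's graph-based clustering
brute_components <- function(adj) {
  n <- nrow(adj)
  memb <- rep(0L, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (memb[s] > 0) next
    cl <- cl + 1L
    queue <- s
    memb[s] <- cl
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & memb == 0L)
      memb[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  memb
}

# brute-force minimum-image distance
mi_dist <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}
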