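# shared fixtures and independent oracles

sphere_grid <- function(n_modes = 20, n_grid = 1000) {
  integrate_profile(shape_profile(rep(0, n_modes)), n_grid = n_grid)
}

# brute-force union-find over an explicit pair list (oracle for the
# igraph-backed cluster counter)
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(table(roots))
}

# grid-search oracle for the orientation-minimized deviatoric density
omega_scan_min <- function(params, H, D, n = 4001) {
  om <- seq(0, pi, length.out = n)
  min(deviatoric_density(params, H, D, om))
}

fast_settings <- function(...) {
  minimizer_settings(n_grid = 600, maxit = 1200, rounds = 10, ...)
}
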