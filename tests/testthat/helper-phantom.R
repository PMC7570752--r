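# Small phantoms shared across test files. All fixtures are generated in
# code; sizes are kept small so the default test run stays fast.

tiny_phantom <- function(seed = 1, H = 24, W = 24, target = 30, ...) {
  cfg <- phantom_config(H = H, W = W, target_fibrosis = target, seed = seed, ...)
  truth <- synth_label_map(cfg)
  cubes <- synth_cube(truth, config = cfg)
  list(cfg = cfg, truth = truth, tissue = cubes$tissue,
       paraffin = cubes$paraffin)
}

# noise-free, contamination-free phantom: pixels equal their endmembers
clean_phantom <- function(seed = 1, H = 16, W = 16, target = 30) {
  tiny_phantom(seed = seed, H = H, W = W, target = target,
               paraffin_amp_range = c(0, 0), baseline_coef_range = c(0, 0),
               scatter_range = c(1, 1), noise_sd = 0)
}

# exhaustive optimal 2-means over all bipartitions (oracle; n <= ~15)
exhaustive_two_means <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    i1 <- sum(rowSums(sweep(X[grp, , drop = FALSE], 2,
                            colMeans(X[grp, , drop = FALSE]))^2))
    i2 <- sum(rowSums(sweep(X[!grp, , drop = FALSE], 2,
                            colMeans(X[!grp, , drop = FALSE]))^2))
    best <- min(best, i1 + i2)
  }
  best
}

# wrap an N x B spectra matrix as an N x 1 spectral image
as_strip_image <- function(X, axis) {
  spectral_image(array(X, c(nrow(X), 1, ncol(X))), axis)
}
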