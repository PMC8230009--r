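# Shared fixture builders and independent oracles.

const_volume <- function(shape, value, voxel_size_um = 5) {
  voxel_volume(array(value, shape), voxel_size_um)
}

# quantize doubles to IEEE single precision (the f32 storage domain)
as_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

random_f32_volume <- function(shape, seed, voxel_size_um = 5) {
  set.seed(seed)
  voxel_volume(array(as_f32(stats::runif(prod(shape), -50, 5000)), shape),
               voxel_size_um)
}

# exhaustive between-class-variance search over every interior bin edge;
# written independently of the implementation (fresh sums per candidate),
# same documented tie rule (ties -> highest edge)
otsu_brute_force <- function(bin_edges, counts) {
  n_bins <- length(counts)
  centers <- (bin_edges[-1L] + bin_edges[-(n_bins + 1L)]) / 2
  best_crit <- -Inf
  best_edge <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1L):n_bins])
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / (n0 + n1); w1 <- n1 / (n0 + n1)
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1L):n_bins] * centers[(k + 1L):n_bins]) / n1
    crit <- w0 * w1 * (mu0 - mu1)^2
    if (crit >= best_crit) {  # >= : ties resolve to the highest edge
      best_crit <- crit
      best_edge <- bin_edges[k + 1L]
    }
  }
  best_edge
}

# small two-region phantom written as arrays, bypassing generate_phantom, for
# tests that need ground truth independent of the generator
two_class_arrays <- function(n_each = 8000, seed = 1,
                             paraffin = c(20, 2), tissue = c(80, 5)) {
  set.seed(seed)
  shape <- c(20L, 20L, 2L * n_each / 400L)
  stopifnot(prod(shape) == 2L * n_each)
  truth <- array(c(rep(1L, n_each), rep(2L, n_each)), shape)
  vals <- numeric(2L * n_each)
  vals[truth == 1L] <- stats::rnorm(n_each, paraffin[1L], paraffin[2L])
  vals[truth == 2L] <- stats::rnorm(n_each, tissue[1L], tissue[2L])
  list(volume = voxel_volume(array(vals, shape), 5),
       truth = truth,
       roi = label_mask(array(1L, shape), c("1" = "all")))
}

write_slice_tiff <- function(mat, path, sample_type = "u16") {
  xgalvox:::tiff_codec_write(list(mat), path, sample_type)
}
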