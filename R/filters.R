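# separable Gaussian convolution with edge replication, as a shifted
# weighted sum over the kernel support (vectorized over whole rows/columns,
# so cost is O(pixels * kernel length) with no per-pixel R overhead)
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pass <- function(m) {
    nr <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    out <- k[1] * pad[seq_len(nr), , drop = FALSE]
    for (j in 2:length(k)) {
      out <- out + k[j] * pad[j:(j + nr - 1), , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(img))))
}
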