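# Geometric masks and small datasets built in code at test time.

disk_mask <- function(r, pad = 8) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

square_mask <- function(side, pad = 10) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

ellipse_mask <- function(a, b, pad = 10) {
  n <- 2L * (max(a, b) + pad) + 1L
  c0 <- max(a, b) + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - c0) / a)^2 + ((j - c0) / b)^2 <= 1)
}

# Two tight 1-D intensity blobs, optionally with impulse ("salt") outliers
# replacing the tail of the second blob.
two_blob_1d <- function(seed, n_per = 45, centers = c(0.25, 0.65),
                        sd = 0.02, n_salt = 0) {
  set.seed(seed)
  x <- c(rnorm(n_per, centers[1], sd), rnorm(n_per, centers[2], sd))
  if (n_salt > 0) x[(length(x) - n_salt + 1):length(x)] <- 1
  x
}

flat_image <- function(value, n = 32) gray_image(matrix(value, n, n))
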