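# Centered, unitary 3D FFT helpers. DC sits at 0-based index floor(N/2)
# (1-based floor(N/2)+1) along every axis; the unitary 1/sqrt(N) scaling makes
# the inverse transform the exact adjoint of the forward one, which the
# reconstruction operator relies on.

circshift_dim <- function(x, shift, dim_i) {
  if (shift == 0) return(x)
  n <- dim(x)[dim_i]
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1
  switch(dim_i,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

fftshift3 <- function(x) {
  d <- dim(x)
  for (i in 1:3) x <- circshift_dim(x, floor(d[i] / 2), i)
  x
}

ifftshift3 <- function(x) {
  d <- dim(x)
  for (i in 1:3) x <- circshift_dim(x, -floor(d[i] / 2), i)
  x
}

# image (DC-centered world) -> k-space (DC-centered)
kspace_fwd <- function(img) {
  fftshift3(fft(ifftshift3(img))) / sqrt(length(img))
}

# k-space (DC-centered) -> image
kspace_inv <- function(ksp) {
  fftshift3(fft(ifftshift3(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

# integer k-space frequency values (cycles per FOV) along an axis of length n,
# matching the centered convention above
k_values <- function(n) seq_len(n) - 1 - floor(n / 2)
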