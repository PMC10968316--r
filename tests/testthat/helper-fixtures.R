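# Small phantoms reused across tests: generated in code, never stored.

make_phantom <- function(matrix_size = 32, n_slices = 10, noise_sd = 0,
                         seed = 1) {
  generate_phantom(phantom_spec(matrix_size = matrix_size,
                                n_slices = n_slices,
                                noise_sd = noise_sd, seed = seed))
}

make_volume <- function(matrix_size = 32, n_slices = 10, noise_sd = 0,
                        seed = 1) {
  normalize_volume(make_phantom(matrix_size, n_slices, noise_sd, seed)$volume)
}

# integer-index circular-free shift oracle for pure-translation transforms
shift_volume_oracle <- function(a, t) {
  d <- dim(a)
  out <- array(0, d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - t[ax]
    i[i < 1 | i > d[ax]] <- NA
    i
  })
  for (k in seq_len(d[3])) {
    if (is.na(src[[3]][k])) next
    rows <- which(!is.na(src[[1]]))
    cols <- which(!is.na(src[[2]]))
    out[rows, cols, k] <- a[src[[1]][rows], src[[2]][cols], src[[3]][k]]
  }
  out
}
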