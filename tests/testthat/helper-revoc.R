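# shared measurement helpers for the suite

# dominant frequency of a signal by full-length FFT
peak_freq <- function(sig) {
  n <- length(sig$samples)
  sp <- Mod(stats::fft(sig$samples))[1:(n %/% 2L)]
  (which.max(sp) - 1L) * sig$rate / n
}

fft_bin_width <- function(sig) sig$rate / length(sig$samples)

rms <- function(x) sqrt(mean(x^2))

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# correlation against a possibly slightly shorter/longer reference
trimmed_cor <- function(a, b) {
  n <- min(length(a), length(b))
  stats::cor(a[seq_len(n)], b[seq_len(n)])
}
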