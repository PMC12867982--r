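# Shared constants and small numeric helpers.

# Gas constant, kcal/mol/K
.kB <- 1.987204e-3

#' Thermal energy in kcal/mol
#' @param temperature temperature in Kelvin.
#' @return `k_B * T` in kcal/mol.
#' @export
kT_kcal <- function(temperature) .kB * temperature

#' Wrap angles into (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s), same shape as `x`.
#' @export
wrap_deg <- function(x) {
  y <- x - 360 * floor(x / 360) # [0, 360)
  ifelse(y > 180, y - 360, y)
}

# minimum-image absolute angular difference in degrees
ang_diff <- function(a, b) abs(wrap_deg(a - b))

#' Derive a stream-specific RNG seed
#'
#' Deterministically maps a master seed and a stream index (e.g. an umbrella
#' window index) to an integer seed below 2^31, so that parallel streams are
#' reproducible independently of generation order.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(stream) * 16807 + 12345) %%
    2147483647
  as.integer(s)
}

# log-sum-exp over a vector or matrix rows
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# contiguous block assignment for block averaging: n items into n_blocks
block_index <- function(n, n_blocks) {
  stopifnot(n_blocks >= 1, n >= n_blocks)
  sort(rep_len(seq_len(n_blocks), n))
}

stop_lidfold <- function(msg, class) {
  abort(msg, class = c(class, "lidfold_error"))
}
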