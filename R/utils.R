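# Internal numerics shared across modules.

# Boltzmann constant in kcal/(mol K), CODATA value used throughout MD codes.
KB_KCAL <- 0.0019872041

kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

# log(mean(exp(x))) without overflow
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Minimum-image displacement along one periodic axis.
min_image <- function(dz, box_len) {
  if (is.null(box_len) || !is.finite(box_len) || box_len <= 0) return(dz)
  dz - box_len * round(dz / box_len)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Largest-remainder apportionment of `weights` into integer counts summing to
# `total`; ties broken by position (table order).
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) return(integer(length(weights)))
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

`%||%` <- rlang::`%||%`
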