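`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# population standard deviation (divisor n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
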