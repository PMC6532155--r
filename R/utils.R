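# Round half away from zero at `digits` decimals. Base round() rounds half to
# even, which does not match how array summary tables are conventionally
# printed (e.g. 0.025 -> 0.03).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) abort(sprintf(...))
  invisible(TRUE)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(TRUE)
}

# canonical chromosome ordering helper: order of appearance in a genome layout
chrom_factor <- function(chrom, genome = NULL) {
  lev <- if (is.null(genome)) unique(chrom) else genome$chrom
  factor(chrom, levels = lev)
}
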