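check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "phosflux_invalid_input")
  }
  invisible(x)
}

require_columns <- function(data, cols, what) {
  if (!is.data.frame(data)) {
    abort(sprintf("%s must be a data frame.", what),
          class = "phosflux_data_error")
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")),
          class = "phosflux_data_error")
  }
  invisible(data)
}

# round-half-up (display rounding for percent claims printed as integers;
# base round() is round-half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# per-draw seed derived from (base seed, draw index); stays < 2^31 so it is a
# valid integer seed, and draw i does not depend on how many draws are run
draw_seed <- function(seed, draw) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + draw * 104729) %%
               2147483647) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# quadrature for a sampled series: composite Simpson when the grid is
# uniform, Simpson under the substitution t = T u^2 when it is uniform in
# sqrt(t) (the solver's stretched output grid), trapezoid otherwise
integrate_series <- function(x, y) {
  is_uniform <- function(z) {
    d <- diff(z)
    diff(range(d)) <= 1e-8 * max(abs(d))
  }
  if (is_uniform(x)) return(simpson(x, y))
  u <- sqrt(x - x[1])
  if (is_uniform(u)) {
    # dt = 2 u du, so integrate y * 2u on the uniform u grid
    return(simpson(u, y * 2 * u))
  }
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# composite Simpson on a uniform grid (odd number of points required); falls
# back to trapezoid on the final interval when the point count is even
simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  h <- x[2] - x[1]
  m <- if (n %% 2 == 1) n else n - 1
  i <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1
  w[m] <- 1
  out <- h / 3 * sum(w * y[i])
  if (n %% 2 == 0) out <- out + h * (y[n - 1] + y[n]) / 2
  out
}
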