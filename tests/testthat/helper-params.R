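# small constructors used across test files

# uniform pathway parameters with selective overrides; km defaults to 1 for
# every reaction so half-saturation checks are easy to state
make_params <- function(vmax_val = 0.8, km_val = 1, vmax = NULL, km = NULL,
                        p = c(v5 = 0, v6 = 0, v7 = 0, v11 = 0),
                        hill_n = 2, ka = 0.5, ki = 0.5, transport_n = 2,
                        v10_substrate = "x4") {
  vm <- stats::setNames(rep(vmax_val, 12), paste0("v", 1:12))
  if (!is.null(vmax)) vm[names(vmax)] <- vmax
  kmv <- stats::setNames(rep(km_val, 11), paste0("Km", 2:12))
  if (!is.null(km)) kmv[names(km)] <- km
  pathway_params(vmax = vm, km = kmv, p = p, hill_n = hill_n, ka = ka,
                 ki = ki, transport_n = transport_n,
                 v10_substrate = v10_substrate)
}

zero_state <- stats::setNames(rep(0, 8), paste0("x", 1:8))

random_state <- function() stats::setNames(stats::runif(8, 0, 2),
                                           paste0("x", 1:8))
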