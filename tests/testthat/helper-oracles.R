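# Independent oracles. Each deliberately re-derives a quantity along a
# different route from the implementation it checks.

# Spherical law of cosines on the same fixed-radius sphere.
oracle_sloc_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  rad <- pi / 180
  c1 <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  r * acos(pmin(pmax(c1, -1), 1))
}

# Winding-number point-in-polygon test (the implementation uses an even-odd
# ray cast). `ring` is a closed 2-column (lon, lat) matrix.
oracle_winding_inside <- function(lon, lat, ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  vapply(seq_along(lon), function(k) {
    px <- lon[k]; py <- lat[k]
    wn <- 0
    for (i in seq_len(n - 1)) {
      cross <- (x[i + 1] - x[i]) * (py - y[i]) - (px - x[i]) * (y[i + 1] - y[i])
      if (y[i] <= py) {
        if (y[i + 1] > py && cross > 0) wn <- wn + 1
      } else {
        if (y[i + 1] <= py && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# Textbook split-R-hat computed step by step from its definition.
oracle_split_rhat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  seqs <- list()
  for (ch in seq_len(ncol(x))) {
    seqs <- c(seqs, list(x[1:half, ch]), list(x[(n - half + 1):n, ch]))
  }
  m <- length(seqs)
  nn <- half
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  W <- sum(vars) / m
  B <- nn / (m - 1) * sum((means - mean(means))^2)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# A shift_fit built from a known draw matrix, for methods that only consume
# draws (marginal summaries, convergence report).
fake_fit <- function(draws, chains = 2L, rhat = NULL) {
  kept <- nrow(draws) / chains
  if (is.null(rhat)) {
    rhat <- apply(draws, 2, function(col) {
      driftshift:::split_rhat(matrix(col, ncol = chains))
    })
    names(rhat) <- colnames(draws)
  }
  structure(
    list(
      draws = draws, chain = rep(seq_len(chains), each = kept),
      n_per_chain = kept, rhat = rhat,
      converged = max(rhat, na.rm = TRUE) <= 1.10,
      sd_y = 1, years = 2008:2009,
      spec = shift_model_spec(iterations = 2000, warmup = 1000), nobs = 0L
    ),
    class = "shift_fit"
  )
}

# Draw matrix with all six fixed-effect columns plus nuisance columns.
fixed_draw_matrix <- function(n = 400, seed = 1, constant = NULL) {
  set.seed(seed)
  nm <- c(
    "beta0", "grubbing", "wetland_obligate", "ece",
    "grubbing:ece", "wetland_obligate:ece", "sigma_year", "sigma_eps"
  )
  if (!is.null(constant)) {
    m <- matrix(rep(constant, each = n), nrow = n,
                dimnames = list(NULL, nm[seq_along(constant)]))
  } else {
    m <- matrix(rnorm(n * length(nm), mean = rep(c(140, 40, -80, -85, -110, 10, 25, 100), each = n), sd = 20),
                nrow = n, dimnames = list(NULL, nm))
  }
  m
}
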