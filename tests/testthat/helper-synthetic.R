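# Shared fixtures and oracles. Expensive objects are memoized per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_template <- function() {
  fixture("tpl", function() foot_template(hindfoot_tilt = 2,
                                          mla_static = 183))
}

default_calib <- function() {
  fixture("calib", function() {
    compute_static_reference(generate_static_trial(default_template()))
  })
}

default_walk <- function() {
  fixture("walk", function() {
    generate_walking_trial(default_template(), sim_spec(n_cycles = 3))
  })
}

# Apply a rigid transform (rotation R about the origin, then translation t)
# to every marker of a series.
transform_series <- function(series, R = diag(3), t = c(0, 0, 0)) {
  pos <- series$positions
  for (l in series$labels) {
    m <- matrix(pos[, , l], ncol = 3)
    pos[, , l] <- t(R %*% t(m)) + rep(t, each = nrow(m))
  }
  series$positions <- pos
  series
}

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# Independent brute-force inversion of the forward JCS composition: find the
# angle triple whose composed rotation matches R, by coarse multi-start plus
# quasi-Newton refinement of the Frobenius misfit. Never calls
# jcs_decompose.
oracle_jcs <- function(R) {
  obj <- function(th) {
    d <- jcs_compose(th[1], th[2], th[3]) - R
    sum(d * d)
  }
  grid <- seq(-60, 60, by = 40)
  starts <- as.matrix(expand.grid(grid, grid, grid))
  vals <- apply(starts, 1, obj)
  best <- starts[which.min(vals), ]
  fit <- stats::optim(best, obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
  fit$par
}

# A marker series built from a named list of constant marker positions.
constant_series <- function(markers, n = 1, rate = 100,
                            trial_kind = "static", side = "right") {
  labels <- names(markers)
  arr <- array(NA_real_, c(n, 3, length(labels)),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  for (l in labels) arr[, , l] <- rep(markers[[l]], each = n)
  marker_series(arr, rate = rate, side = side, trial_kind = trial_kind)
}
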