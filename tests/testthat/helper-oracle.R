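## Independent naive implementation of the symmetry functions: plain triple
## loops over atoms, formulas transcribed term by term. Used as the oracle
## that the vectorized featurizer must reproduce; shares no code with it.

naive_fc <- function(r, rc) if (r >= rc) 0 else 0.5 * (cos(pi * r / rc) + 1)

naive_featurize <- function(structure, layout, params) {
  X <- structure$coords
  el <- structure$elements
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  out <- matrix(0, n, layout$p, dimnames = list(NULL, layout$names))
  for (i in seq_len(n)) {
    col <- 0L
    for (E in layout$radial) {
      col <- col + 1L
      acc <- 0
      for (j in seq_len(n)) {
        if (j != i && el[j] == E) {
          r <- d(i, j)
          acc <- acc + exp(-params$eta * (r - params$rs)^2) * naive_fc(r, params$rc)
        }
      }
      out[i, col] <- acc
    }
    if (nrow(layout$angular)) {
      for (pp in seq_len(nrow(layout$angular))) {
        J <- layout$angular[pp, 1L]; K <- layout$angular[pp, 2L]
        acc <- 0
        for (j in seq_len(n)) {
          for (k in seq_len(n)) {
            if (j >= k || j == i || k == i) next
            cover <- (el[j] == J && el[k] == K) || (el[j] == K && el[k] == J)
            if (!cover) next
            rij <- d(i, j); rik <- d(i, k); rjk <- d(j, k)
            cosq <- sum((X[j, ] - X[i, ]) * (X[k, ] - X[i, ])) / (rij * rik)
            cosq <- min(1, max(-1, cosq))
            acc <- acc + (1 + params$lambda * cosq)^params$zeta *
              exp(-params$eta * (rij^2 + rik^2 + rjk^2)) *
              naive_fc(rij, params$rc) * naive_fc(rik, params$rc) *
              naive_fc(rjk, params$rc)
          }
        }
        out[i, col + pp] <- 2^(1 - params$zeta) * acc
      }
    }
  }
  out
}

## random test structure with well-separated atoms
random_structure <- function(n, elements = c("H", "C", "N", "O", "Fe"),
                             frame_id = 0L, spread = 4) {
  repeat {
    coords <- matrix(runif(n * 3, -spread, spread), n, 3)
    if (min(dist(coords)) > 0.5) break
  }
  structure3d(sample(elements, n, replace = TRUE), coords, frame_id)
}

## uniformly random proper rotation matrix (QR with positive diagonal)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(s, R, t) {
  structure3d(s$elements, s$coords %*% t(R) + rep(t, each = nrow(s$coords)),
              s$frame_id)
}

## small shared dataset for model-level tests (computed once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_params(n_frames = 30, seed = 99))
    }
    cache
  }
})
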