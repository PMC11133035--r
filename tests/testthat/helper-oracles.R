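# Independent oracles and small fixtures used across the test files.

# Dense orthonormal 2D DCT basis built directly from the defining cosine
# formula with explicit loops: deliberately independent of the package's
# separable-transform implementation.
oracle_dct2_basis <- function(h, w) {
  amp <- function(u, n) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  m <- h * w
  psi <- matrix(0, m, m)
  for (u in 0:(h - 1)) {
    for (v in 0:(w - 1)) {
      col <- u * w + v + 1
      for (r in 1:h) {
        for (cc in 1:w) {
          row <- (r - 1) * w + cc
          psi[row, col] <- amp(u, h) * cos(pi * (2 * r - 1) * u / (2 * h)) *
            amp(v, w) * cos(pi * (2 * cc - 1) * v / (2 * w))
        }
      }
    }
  }
  psi
}

# Exhaustive best gamma-sparse approximation: enumerate all supports of
# size gamma and keep the one retaining the most squared magnitude.
oracle_topk_support <- function(v, gamma) {
  subsets <- utils::combn(length(v), gamma)
  energy <- apply(subsets, 2, function(idx) sum(v[idx]^2))
  sort(subsets[, which.max(energy)])
}

# A small dot template plus matched stimuli/responses, shared by tests
# that just need a working simulated observer.
tiny_sim <- function(l = 500, shape = c(8, 8), sigma = 0, seed = 42) {
  tpl <- make_dot_template(shape, center = ceiling(shape / 2), radius = 2)
  phi <- generate_stimuli(l, shape, seed = seed)
  y <- simulate_responses(tpl, phi, noise_spec(sigma), seed = seed + 1)
  list(template = tpl, stimuli = phi, responses = y)
}

# Template whose centered image is proportional to one DCT basis column:
# any non-DC basis image rescaled into [0, 1].
basis_function_template <- function(spec, index) {
  psi <- build_basis(spec)
  b <- psi[, index]
  px <- (b - min(b)) / (max(b) - min(b))
  new_template(unvec_rm(px, spec$height, spec$width), label = "basisfn")
}

unvec_rm <- function(v, h, w) matrix(v, h, w, byrow = TRUE)
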