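# Independent oracles, deliberately written without reusing the package's
# internal code paths.

# angle reduction by repeated subtraction
oracle_reduce <- function(a) {
  while (a > 180) a <- a - 360
  while (a <= -180) a <- a + 360
  a
}

# brute-force shortest lattice vectors: enumerate k, compute the unrolled
# displacement trigonometrically, sort by length
oracle_vector_length <- function(rise, twist, k, radius) {
  step <- oracle_reduce(k * twist)
  sqrt((radius * step * pi / 180)^2 + (k * rise)^2)
}

oracle_principal <- function(rise, twist, radius, k_max) {
  len <- vapply(seq_len(k_max), function(k)
    oracle_vector_length(rise, twist, k, radius), numeric(1))
  ord <- order(round(len, 9), seq_len(k_max))
  ord[1:2]
}

# random plausible helical symmetries for property tests
random_symmetries <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      rise_A = stats::runif(n, 1, 10),
      twist_deg = stats::runif(n, -179, 180)
    )
  })
}

sym_da6_l3 <- function() helical_symmetry(2.159, 85.495,
                                          r_lumen_A = 63.5, r_outer_A = 122)
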