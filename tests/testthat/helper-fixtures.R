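# Shared fixtures and independent oracles, built in code.

toy_helix <- local({
  cache <- list()
  function(n = 20) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <<- build_toy_structure("helix", length = n)
    cache[[key]]
  }
})

# Independent closed-form loss oracles (distance potential special cases).
oracle_harmonic <- function(x, c) 0.5 * (x / c)^2
oracle_geman_mcclure <- function(x, c) {
  u <- (x / c)^2
  2 * u / (u + 4)
}
oracle_welsch <- function(x, c) 1 - exp(-0.5 * (x / c)^2)

# Independent dihedral oracle: angle between plane normals with the sign
# taken from the handedness of (n1, n2, b2). Deliberately different
# construction from the package's atan2 route.
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  s <- sign(sum(cross(n1, n2) * b2))
  if (s < 0) -ang else ang
}

# Random rigid transform (rotation from a normalised quaternion).
random_rigid_transform <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  list(rotation = r, translation = rnorm(3, 0, 10))
}

apply_rigid <- function(struct, transform) {
  xyz <- as.matrix(struct[, c("x", "y", "z")]) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  struct$x <- xyz[, 1]; struct$y <- xyz[, 2]; struct$z <- xyz[, 3]
  struct
}

# Numerically locate the peak gradient magnitude of a periodic torsion
# energy function (degrees in, energy out) by dense grid + refinement.
peak_gradient <- function(energy_fun) {
  g <- function(th) {
    h <- 1e-4
    abs((energy_fun(th + h) - energy_fun(th - h)) / (2 * h * pi / 180))
  }
  th <- seq(0.01, 179.99, length.out = 2000)
  vals <- g(th)
  i <- which.max(vals)
  lo <- th[max(i - 2, 1)]; hi <- th[min(i + 2, length(th))]
  opt <- stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-10)
  opt$objective
}

# Brute-force distance-restraint enumeration oracle for self-restraint on a
# single-chain structure: double loop over eligible atoms with the cutoff,
# same-residue and unordered-deduplication rules applied literally.
brute_force_self_restraints <- function(struct, opts = restraint_options()) {
  allowed <- c("CA", "CB", "CG", "CG1", "OG", "OG1", opts$custom_atom_names)
  at <- struct[struct$atom %in% allowed, ]
  keys <- paste(at$chain, at$resno, at$icode, at$atom, sep = "|")
  res <- paste(at$chain, at$resno, at$icode, sep = "|")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rows <- list()
  n <- nrow(at)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (res[i] == res[j]) next
      r0 <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r0 > opts$distance_cutoff) next
      a1 <- min(keys[i], keys[j]); a2 <- max(keys[i], keys[j])
      rows[[length(rows) + 1]] <- data.frame(
        atom1 = a1, atom2 = a2, r0 = r0,
        k = opts$kappa, tau = opts$tolerance * r0,
        c = opts$well_half_width * r0,
        alpha = -2 - opts$fall_off * log(r0)
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$atom1, out$atom2), ]
}
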