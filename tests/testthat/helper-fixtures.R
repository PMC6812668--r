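# shared fixtures: packaged assets loaded once per test run
CAT <- load_catalog()
FMAP <- load_family_map()

# independent dihedral oracle: project the two outer bonds onto the plane
# perpendicular to the p2-p3 axis and measure the rotation between the
# projections (a different construction from the atan2-of-normals formula)
oracle_dihedral <- function(p1, p2, p3, p4) {
  ax <- p3 - p2
  ax <- ax / sqrt(sum(ax^2))
  u <- (p1 - p2) - sum((p1 - p2) * ax) * ax
  w <- (p4 - p3) - sum((p4 - p3) * ax) * ax
  s <- sum(ax * rotasuite:::cross3(u, w))
  ang <- atan2(s, sum(u * w)) * 180 / pi
  ang %% 360
}

# a clearly separable low-noise generator parameter set for fixtures
separable_params <- function() {
  p <- default_shift_params()
  p$noise_sd <- 1e-3
  p
}

# all bonded (i,j,k) angle triples of a template
template_angle_triples <- function(tpl) {
  nb <- lapply(seq_len(nrow(tpl$atoms)), function(i)
    unique(c(tpl$bonds[tpl$bonds[, 1] == i, 2],
             tpl$bonds[tpl$bonds[, 2] == i, 1])))
  out <- list()
  for (j in seq_along(nb)) {
    ns <- nb[[j]]
    if (length(ns) < 2) next
    cmb <- utils::combn(ns, 2)
    for (c_ in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
  }
  out
}

measure_geometry <- function(tpl, coords) {
  lens <- apply(tpl$bonds, 1, function(b)
    sqrt(sum((coords[b[1], ] - coords[b[2], ])^2)))
  angs <- vapply(template_angle_triples(tpl), function(tr)
    bond_angle(coords[tr[1], ], coords[tr[2], ], coords[tr[3], ]),
    numeric(1))
  list(lengths = lens, angles = angs)
}
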