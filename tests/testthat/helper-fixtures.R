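# Shared fixtures and independent oracles, all built in code.

# A constant-SAF table: Phi(E) = phi0 everywhere (closed-form S-values).
const_saf <- function(phi0, site = "site_a", source = "AM",
                      cellularity = 0.7, emin = 1, emax = 1e4) {
  grid <- c(emin, 10, 100, 1000, emax)
  grid <- sort(unique(grid[grid >= emin & grid <= emax]))
  saf_table(site, source, grid, rep(phi0, length(grid)), cellularity)
}

# A power-law SAF table Phi(E) = c / E (log-log linear interpolation is
# exact for power laws).
powerlaw_saf <- function(c0, site = "site_a", source = "AM",
                         cellularity = 0.7) {
  grid <- c(1, 5, 20, 100, 500, 2500, 1e4)
  saf_table(site, source, grid, c0 / grid, cellularity)
}

# Tiny skeleton: n sites with constant self-SAFs and scaled cross tables,
# masses given explicitly. Used for hand-computable averaging checks.
toy_skeleton <- function(masses_AM, masses_IM, masses_TB, phi0 = 0.5,
                         cellularity = NULL) {
  n <- length(masses_AM)
  names <- paste0("site_", letters[seq_len(n)])
  if (is.null(cellularity)) {
    cellularity <- ifelse(masses_AM + masses_IM > 0,
                          masses_AM / (masses_AM + masses_IM), 1)
  }
  sites <- lapply(seq_len(n), function(i) {
    skeletal_site(names[i], masses_AM[i], masses_IM[i], masses_TB[i],
                  max(cellularity[i], 1e-6))
  })
  tables <- list()
  for (i in seq_len(n)) {
    for (src in c("AM", "IM", "TBV", "TBS")) {
      scale <- switch(src, AM = 1, TBS = 0.6, IM = 0.4, TBV = 0.25)
      tables[[length(tables) + 1L]] <-
        const_saf(phi0 * scale / max(masses_AM[i], 0.01), site = names[i],
                  source = src, cellularity = max(cellularity[i], 1e-6))
    }
  }
  skeleton_model("male", sites, tables, n_sites = n)
}

# Independent brute-force S-value oracle: merges every emission (discrete
# lines plus the continuous spectrum discretised as midpoint pseudo-lines on
# a 1e5-point list) and sums y * E * Phi(E) term by term.
brute_force_svalue <- function(nuclide, table, n_points = 1e5) {
  s <- 0
  for (d in nuclide$discrete) {
    s <- s + d$yield * d$energy_keV * interpolate_saf(table, d$energy_keV)
  }
  for (b in nuclide$beta_branches) {
    if (b$fraction == 0) next
    edges <- seq(0, b$endpoint_keV, length.out = n_points + 1)
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    w <- diff(edges)
    dens <- marrowdose:::beta_shape(mid, b$endpoint_keV, b$daughter_Z,
                                    kind = b$kind)
    dens <- dens * (b$fraction / sum(dens * w))
    s <- s + sum(dens * w * mid * interpolate_saf(table, mid))
  }
  s * 1.602176634e-16 * 1e9
}

# Random nuclide for property checks: a couple of beta branches plus a few
# discrete lines.
random_nuclide <- function(seed) {
  set.seed(seed)
  nb <- sample(0:2, 1)
  betas <- lapply(seq_len(nb), function(i) {
    beta_branch(runif(1, 50, 2200), runif(1, 0.1, 0.5), sample(20:80, 1),
                sample(c("allowed", "first_forbidden_unique"), 1))
  })
  nd <- sample(1:4, 1)
  discs <- lapply(seq_len(nd), function(i) {
    discrete_emission(runif(1, 2, 500), runif(1, 0.01, 3),
                      sample(c("conversion", "auger"), 1))
  })
  radionuclide(paste0("rand", seed), 1, betas, discs)
}

random_saf_table <- function(seed) {
  set.seed(seed + 1000)
  grid <- sort(unique(signif(exp(runif(12, log(1), log(1e4))), 6)))
  grid[1] <- 1; grid[length(grid)] <- 1e4
  saf <- exp(runif(length(grid), log(1e-3), log(2)))
  saf_table("site_a", "AM", grid, saf, 0.7)
}
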