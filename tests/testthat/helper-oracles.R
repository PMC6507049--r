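# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: Monte Carlo SASA instead of the golden-spiral
# construction, dense-matrix label propagation instead of the igraph
# components path, closed forms where available.

# Monte Carlo SASA: random directions per atom, fraction of points outside
# all other expanded spheres times the expanded-sphere area.
mc_sasa_oracle <- function(atoms, probe = 1.4, nsamp = 20000, seed = 42) {
  set.seed(seed)
  rex <- atoms$radius + probe
  total <- 0
  for (i in seq_len(nrow(atoms))) {
    u <- matrix(stats::rnorm(3 * nsamp), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * rex[i], 2, c(atoms$x[i], atoms$y[i], atoms$z[i]), "+")
    outside <- rep(TRUE, nsamp)
    for (j in seq_len(nrow(atoms))[-i]) {
      d2 <- (p[, 1] - atoms$x[j])^2 + (p[, 2] - atoms$y[j])^2 +
        (p[, 3] - atoms$z[j])^2
      outside <- outside & d2 >= rex[j]^2
    }
    total <- total + mean(outside) * 4 * pi * rex[i]^2
  }
  total
}

# Brute-force connected components over points of equal class within a
# link distance: full O(N^2) adjacency + iterative label propagation.
brute_components_oracle <- function(X, classes, link_distance) {
  n <- nrow(X)
  lab <- seq_len(n)
  D <- as.matrix(stats::dist(X))
  adj <- D <= link_distance & outer(classes, classes, "==")
  diag(adj) <- FALSE
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(lab[i], lab[nb])
        if (m < lab[i]) { lab[i] <- m; changed <- TRUE }
        upd <- nb[lab[nb] > m]
        if (length(upd)) { lab[upd] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lab
}

# Canonical form of a partition: list of sorted member sets, ordered.
canon_partition <- function(membership) {
  parts <- unname(split(seq_along(membership), membership))
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  unname(parts[order(vapply(parts, `[`, 1L, 1))])
}

# Exhaustive threshold scan maximising balanced accuracy (ties: smallest).
brute_threshold_oracle <- function(sizes, labels) {
  u <- sort(unique(sizes))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  bal <- vapply(cand, function(t) {
    pred <- sizes > t
    (mean(pred[labels]) + mean(!pred[!labels])) / 2
  }, 0)
  list(threshold = cand[which(bal == max(bal))[1]], balanced = max(bal))
}

# Henderson-Hasselbalch protonation fraction.
hh_frac <- function(pKa, pH) 1 / (1 + 10^(pH - pKa))

# Random titratable-site system: n sites in a box, mixed acids and bases.
rand_site_system <- function(n, seed, box = 20) {
  set.seed(seed)
  types <- sample(c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR"), n,
                  replace = TRUE)
  repeat {
    xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
    if (n == 1 || min(stats::dist(xyz)) > 1.5) break
  }
  sites <- data.frame(chain = "A", resno = seq_len(n), type = types,
                      pKa = unname(chargepatch:::.MODEL_PKA[types]),
                      q0 = unname(chargepatch:::.SITE_Q0[types]),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  list(sites = sites, W = interaction_matrix(sites, es_params()))
}

# Small helper: a charged toy helix structure.
toy_helix <- function(n = 20, subs = NULL) {
  make_toy("helix", n = n, substitutions = subs)$structure
}
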