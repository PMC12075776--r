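# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# OLS slope/intercept/slope-SE via stats::lm
lm_window_oracle <- function(t, y) {
  fit <- lm(y ~ t)
  s <- summary(fit)$coefficients
  list(slope = unname(coef(fit)["t"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       se = unname(s["t", "Std. Error"]))
}

# capsule solid/surface of revolution by numeric integration:
# axis x in [0, l], radius profile f(x) = hemisphere / cylinder / hemisphere
capsule_profile <- function(x, l, r) {
  ifelse(x < r, sqrt(pmax(r^2 - (x - r)^2, 0)),
         ifelse(x > l - r, sqrt(pmax(r^2 - (x - (l - r))^2, 0)), r))
}

integrate_capsule_volume <- function(l, r) {
  pi * integrate(function(x) capsule_profile(x, l, r)^2, 0, l,
                 rel.tol = 1e-10, subdivisions = 1000L)$value
}

integrate_capsule_surface <- function(l, r) {
  # hemispherical caps: 2*pi*integral of f*sqrt(1+f'^2) = 2*pi*r per unit x
  caps <- 2 * pi * r * (2 * r)
  side <- 2 * pi * r * (l - 2 * r)
  # cross-check the cap term by integration on the spherical zone formula
  zone <- 2 * pi * r * integrate(function(x) rep(1, length(x)), 0, 2 * r)$value
  stopifnot(abs(zone - caps) < 1e-9)
  caps + side
}

# brute-force single-linkage clustering by union-find on a symmetrized matrix
union_find_clusters <- function(ani, threshold, symmetrize = "mean") {
  n <- nrow(ani)
  sym <- if (symmetrize == "mean") (ani + t(ani)) / 2 else pmin(ani, t(ani))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !is.na(sym[i, j]) && sym[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, unique(roots)), rownames(ani))
}

# canonical form of a partition: sorted list of sorted member sets
partition_sets <- function(membership) {
  unname(lapply(split(names(membership), membership), sort))[
    order(vapply(split(names(membership), membership),
                 function(s) min(s), character(1)))]
}
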