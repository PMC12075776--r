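toy_counts <- function() {
  counts <- matrix(c(100, 0, 50,
                     200, 10, 0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  list(counts = counts,
       len = c(g1 = 1e6, g2 = 2e6, g3 = 5e5),
       bp = c(s1 = 1e6, s2 = 2e6))
}

test_that("RPKM follows the reads/kb/million-recruited-bp definition", {
  tc <- toy_counts()
  rt <- compute_rpkm(tc$counts, tc$len, tc$bp)
  # hand calculation: 100 reads, 1e6 bp genome, 1e6 recruited bp -> 0.1
  expect_equal(rt$rpkm["g1", "s1"], 100 / (1e6 / 1e3) / (1e6 / 1e6))
  expect_equal(rt$rpkm["g1", "s1"], 0.1)
  expect_equal(rt$rpkm["g2", "s1"], 0)          # zero count -> exactly 0
  expect_equal(rt$rpkm["g1", "s2"], 200 / 1e3 / 2)
  expect_error(compute_rpkm(tc$counts, c(g1 = 0, g2 = 1, g3 = 1), tc$bp),
               "positive")
  expect_error(compute_rpkm(tc$counts, tc$len, c(s1 = 0, s2 = 2e6)),
               "recruited_bp")
})

test_that("RPKM scales inversely with genome length and recruitment depth", {
  tc <- toy_counts()
  base <- compute_rpkm(tc$counts, tc$len, tc$bp)$rpkm
  len2 <- tc$len; len2["g1"] <- tc$len["g1"] * 3
  r2 <- compute_rpkm(tc$counts, len2, tc$bp)$rpkm
  expect_equal(r2["g1", ], base["g1", ] / 3)
  expect_equal(r2["g2", ], base["g2", ])
  bp2 <- tc$bp; bp2["s2"] <- tc$bp["s2"] * 5
  r3 <- compute_rpkm(tc$counts, tc$len, bp2)$rpkm
  expect_equal(r3[, "s2"], base[, "s2"] / 5)
  # doubling counts and recruited bp together changes nothing
  r4 <- compute_rpkm(tc$counts * 2, tc$len, tc$bp * 2)$rpkm
  expect_equal(r4, base)
})

test_that("genome ranking orders by median RPKM", {
  set.seed(8)
  counts <- matrix(rpois(40, 50), nrow = 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  len <- setNames(c(1e6, 2e6, 5e5, 3e6), rownames(counts))
  bp <- setNames(rep(1e7, 10), colnames(counts))
  rt <- compute_rpkm(counts, len, bp)
  meds <- apply(rt$rpkm, 1, median)
  expect_equal(rt$genome_summary$genome,
               names(sort(meds, decreasing = TRUE)))
  expect_equal(rt$genome_summary$rank, 1:4)
})

test_that("subcluster sums conserve totals and ignore genome order", {
  tc <- toy_counts()
  rt <- compute_rpkm(tc$counts, tc$len, tc$bp)
  memb <- c(g1 = "sc1", g2 = "sc1", g3 = "sc2")
  sa <- subcluster_abundance(rt, memb)
  expect_equal(sa$sums["sc1", "s1"],
               rt$rpkm["g1", "s1"] + rt$rpkm["g2", "s1"])
  expect_equal(colSums(sa$sums), colSums(rt$rpkm))
  # permuting genomes changes nothing
  perm <- rt$rpkm[c(3, 1, 2), ]
  expect_equal(subcluster_abundance(perm, memb)$sums, sa$sums)
  # brute-force accumulation on the toy table
  brute <- sapply(colnames(rt$rpkm), function(s)
    tapply(rt$rpkm[, s], memb[rownames(rt$rpkm)], sum))
  expect_equal(unclass(sa$sums), brute[rownames(sa$sums), ],
               ignore_attr = TRUE)
  # unassigned genomes are excluded with a warning
  expect_warning(out <- subcluster_abundance(rt, c(g1 = "sc1", g2 = "sc1")),
                 "excluding")
  expect_equal(rownames(out$sums), "sc1")
  expect_error(subcluster_abundance(rt, setNames(character(0), character(0))),
               "empty membership")
})

test_that("ANI clustering splits blocks across the species boundary", {
  g <- paste0("g", 1:6)
  m <- matrix(90.5, 6, 6, dimnames = list(g, g))
  m[1:3, 1:3] <- 96.5
  m[4:6, 4:6] <- 96.8
  diag(m) <- 100
  # small asymmetric perturbation
  m[1, 2] <- 96.2; m[2, 1] <- 96.8
  cl <- ani_clusters(m, threshold = 95)
  expect_equal(length(unique(cl$clusters)), 2L)
  expect_equal(unname(cl$clusters[1:3]), rep(cl$clusters[["g1"]], 3))
  expect_true(cl$between[["max"]] < 95)
  expect_true(all(cl$within$min_ani >= 95, na.rm = TRUE))
  # all pairs above threshold -> one cluster
  hi <- matrix(97, 3, 3, dimnames = list(g[1:3], g[1:3])); diag(hi) <- 100
  expect_equal(length(unique(ani_clusters(hi, 95)$clusters)), 1L)
  # threshold 100 with all off-diagonal below -> singletons
  expect_equal(length(unique(ani_clusters(hi, 100)$clusters)), 3L)
})

test_that("ANI clustering equals brute-force union-find on random matrices", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    g <- paste0("g", seq_len(n))
    m <- matrix(runif(n * n, 88, 100), n, n, dimnames = list(g, g))
    diag(m) <- 100
    for (symm in c("mean", "min")) {
      cl <- ani_clusters(m, threshold = 95, symmetrize = symm)
      oracle <- union_find_clusters(m, 95, symmetrize = symm)
      expect_equal(partition_sets(cl$clusters), partition_sets(oracle))
    }
    # invariance to genome ordering
    perm <- sample(n)
    clp <- ani_clusters(m[perm, perm], threshold = 95)
    expect_equal(partition_sets(clp$clusters),
                 partition_sets(ani_clusters(m, threshold = 95)$clusters))
  }
})

test_that("clustering is stable under sub-margin symmetric perturbation", {
  g <- paste0("g", 1:5)
  m <- matrix(91, 5, 5, dimnames = list(g, g))
  m[1:2, 1:2] <- 97; m[3:5, 3:5] <- 96.5; diag(m) <- 100
  base <- partition_sets(ani_clusters(m, 95)$clusters)
  set.seed(9)
  for (i in 1:10) {
    eps <- matrix(runif(25, -0.4, 0.4), 5, 5)
    eps <- (eps + t(eps)) / 2; diag(eps) <- 0
    expect_equal(partition_sets(ani_clusters(pmin(m + eps, 100),
                                             95)$clusters), base)
  }
})

test_that("genome quality is completeness minus five times contamination", {
  expect_equal(genome_quality(100, 0), 100)
  expect_equal(genome_quality(90, 2), 80)
  set.seed(2)
  comp <- runif(20, 50, 100); cont <- runif(20, 0, 10)
  q <- genome_quality(comp, cont)
  expect_equal(order(q), order(comp - 5 * cont))
  expect_error(genome_quality(101, 0), "completeness")
  expect_error(genome_quality(90, -1), "contamination")
})

test_that("abundance-environment correlation is Spearman with NA handling", {
  sums <- rbind(sc1 = c(5, 4, 3, 2, 1), sc2 = c(1, 1, 1, 1, 1))
  colnames(sums) <- paste0("s", 1:5)
  env <- setNames(c(10, 12, 14, 16, 18), colnames(sums))
  out <- env_abundance_correlation(sums, env)
  expect_equal(out$rho[out$subcluster == "sc1"], -1)
  expect_false(out$defined[out$subcluster == "sc2"])  # constant abundance
  # matches direct rank computation on a scrambled table
  set.seed(4)
  a <- runif(8); e <- runif(8)
  s2 <- rbind(sc = a); colnames(s2) <- paste0("s", 1:8)
  out2 <- env_abundance_correlation(s2, setNames(e, colnames(s2)))
  expect_equal(out2$rho, cor(rank(a), rank(e)), tolerance = 1e-12)
  # missing metadata dropped pairwise; fewer than 3 pairs errors
  e3 <- setNames(c(1, 2, NA, NA, NA), paste0("s", 1:5))
  expect_error(env_abundance_correlation(sums, e3), "fewer than 3")
})

test_that("ANI files are read in square and fastANI long dialects", {
  sq <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genome,g1,g2", "g1,100,96.1", "g2,95.9,100"), sq)
  m1 <- read_ani(sq)
  expect_equal(m1["g1", "g2"], 96.1)
  expect_equal(dim(m1), c(2L, 2L))
  lg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\t96.1\t50\t60", "g2\tg1\t95.9\t48\t60"), lg)
  m2 <- read_ani(lg)
  expect_equal(m2["g1", "g2"], 96.1)
  expect_equal(m2["g2", "g1"], 95.9)
  expect_equal(diag(m2), c(g1 = 100, g2 = 100))
})
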