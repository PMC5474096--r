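cov_fixture <- function() {
  list(
    coverage = tibble::tibble(
      sample_id = c("s1", "s1", "s2"),
      contig_id = c("c1", "c2", "c1"),
      depth_sum = c(10000, 0, 5000)
    ),
    lengths = tibble::tibble(contig_id = c("c1", "c2"),
                             length = c(10000, 20000)),
    samples = tibble::tibble(sample_id = c("s1", "s2"),
                             read_bases = c(1e9, 1e9))
  )
}

test_that("abundance normalization follows the stated formula", {
  f <- cov_fixture()
  ab <- normalize_abundance(f$coverage, f$lengths, f$samples)
  get <- function(s, c) ab$abundance[ab$sample_id == s & ab$contig_id == c]
  # (10000 / 10000 bp) / 1e9 read bases * 1e9 = 1.0
  expect_equal(get("s1", "c1"), 1.0)
  expect_equal(get("s1", "c2"), 0)
  # missing (s2, c2) pair is zero coverage
  expect_equal(get("s2", "c2"), 0)

  ab_log <- normalize_abundance(f$coverage, f$lengths, f$samples, log = TRUE)
  expect_equal(ab_log$abundance[ab_log$sample_id == "s1" &
                                  ab_log$contig_id == "c1"],
               log10(2), tolerance = 1e-12)
  expect_equal(attr(ab_log, "transform"), "log10")

  # doubling depth and sequencing effort together changes nothing
  f2 <- f
  f2$coverage$depth_sum <- f2$coverage$depth_sum * 2
  f2$samples$read_bases <- f2$samples$read_bases * 2
  ab2 <- normalize_abundance(f2$coverage, f2$lengths, f2$samples)
  expect_equal(ab2$abundance, ab$abundance)
})

test_that("normalization errors name the offending contig or sample", {
  f <- cov_fixture()
  f$lengths$length[1] <- 0
  expect_error(normalize_abundance(f$coverage, f$lengths, f$samples), "c1")
  f <- cov_fixture()
  f$samples$read_bases[2] <- 0
  expect_error(normalize_abundance(f$coverage, f$lengths, f$samples), "s2")
  f <- cov_fixture()
  f$coverage <- dplyr::bind_rows(f$coverage, f$coverage[1, ])
  expect_error(normalize_abundance(f$coverage, f$lengths, f$samples),
               "duplicate")
})

long_ab <- function(m) {
  tibble::tibble(
    sample_id = rep(rownames(m), ncol(m)),
    contig_id = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m)
  )
}

test_that("alpha diversity reproduces hand-computed values", {
  ab <- long_ab(matrix(c(1, 1, 1, 1), 1,
                       dimnames = list("u", paste0("p", 1:4))))
  d <- alpha_diversity(ab)
  expect_equal(d$richness, 4)
  expect_equal(d$shannon, log(4))
  expect_equal(d$pielou, 1)

  single <- long_ab(matrix(c(2, 0, 0), 1, dimnames = list("s", paste0("p", 1:3))))
  d <- alpha_diversity(single)
  expect_equal(d$richness, 1)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$pielou))

  skew <- long_ab(matrix(c(4, 1), 1, dimnames = list("k", c("a", "b"))))
  d <- alpha_diversity(skew)
  expect_equal(d$shannon, -(0.8 * log(0.8) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_equal(round(d$shannon, 4), 0.5004)
  expect_equal(round(d$pielou, 4), 0.7219)

  empty <- long_ab(matrix(0, 1, 2, dimnames = list("e", c("a", "b"))))
  d <- alpha_diversity(empty)
  expect_equal(d$richness, 0)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$pielou))
})

test_that("Shannon is bounded by log richness, evenness lies in [0,1], and vegan agrees", {
  set.seed(51)
  m <- matrix(rexp(60), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("p", 1:10)))
  m[m < 0.3] <- 0
  d <- alpha_diversity(long_ab(m))
  expect_true(all(d$shannon <= log(d$richness) + 1e-12))
  expect_true(all(d$pielou >= 0 & d$pielou <= 1, na.rm = TRUE))
  # independent route: vegan on the same matrix
  expect_equal(d$shannon[match(rownames(m), d$sample_id)],
               unname(vegan::diversity(m, index = "shannon")),
               tolerance = 1e-12)
  expect_equal(d$richness[match(rownames(m), d$sample_id)],
               unname(rowSums(m > 0)))
})

test_that("Bray-Curtis matches hand arithmetic and distance axioms", {
  m <- matrix(c(1, 3, 1, 2, 0, 2), nrow = 3,
              dimnames = list(c("x", "y", "z"), c("p1", "p2")))
  # x = (1,2), y = (3,0): (|1-3| + |2-0|) / (1+3+2+0) = 4/6
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 2 / 3, tolerance = 1e-12)
  expect_equal(d["x", "z"], 0)            # identical profiles
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  disjoint <- matrix(c(1, 0, 0, 2), nrow = 2,
                     dimnames = list(c("a", "b"), c("p1", "p2")))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)

  set.seed(52)
  r <- matrix(rexp(40), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("p", 1:10)))
  dr <- bray_curtis(r)
  expect_true(all(dr >= 0 & dr <= 1))

  both_zero <- matrix(c(0, 0, 1, 0, 0, 1), nrow = 3,
                      dimnames = list(c("e1", "e2", "f"), c("p1", "p2")))
  expect_equal(bray_curtis(both_zero)["e1", "e2"], 0)
})

test_that("Mantel r is 1 on identical and affine-transformed matrices", {
  set.seed(53)
  pts <- matrix(runif(12), 6, 2)
  d1 <- as.matrix(dist(pts))
  dimnames(d1) <- list(paste0("s", 1:6), paste0("s", 1:6))
  res <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  res2 <- mantel_test(d1, 0.5 + 2 * d1, n_perm = 99, seed = 1)
  expect_equal(res2$r, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("Mantel r is invariant under joint relabeling and matches vegan", {
  set.seed(54)
  d1 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  d2 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  labs <- paste0("s", 1:6)
  dimnames(d1) <- dimnames(d2) <- list(labs, labs)
  r0 <- mantel_test(d1, d2, n_perm = 9, seed = 1)$r
  p <- sample(6)
  r1 <- mantel_test(d1[p, p], d2[p, p], n_perm = 9, seed = 1)$r
  expect_equal(r1, r0, tolerance = 1e-12)
  # independent route: vegan's mantel statistic
  expect_equal(r0, unname(vegan::mantel(d1, d2, permutations = 9)$statistic),
               tolerance = 1e-12)

  bad <- d2
  rownames(bad) <- colnames(bad) <- paste0("t", 1:6)
  expect_error(mantel_test(d1, bad), "labels")
  expect_error(mantel_test(d1[1:2, 1:2], d2[1:2, 1:2]), "at least 3")
})

test_that("abundance matrices pivot with both orientations", {
  f <- cov_fixture()
  ab <- normalize_abundance(f$coverage, f$lengths, f$samples)
  m <- abundance_matrix(ab)
  expect_equal(dim(m), c(2, 2))
  expect_equal(sort(rownames(m)), c("s1", "s2"))
  mt <- abundance_matrix(ab, rows = "contig")
  expect_equal(mt, t(m))
  expect_s3_class(plot_abundance_heatmap(ab), "ggplot")
})
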