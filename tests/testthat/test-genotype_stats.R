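test_that("PIC matches its closed forms and is relabeling invariant", {
  expect_equal(pic_botstein(1), 0)
  expect_equal(pic_botstein(c(0.5, 0.5)), 0.375)
  expect_equal(pic_botstein(rep(0.25, 4)), 0.703125)
  set.seed(163)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1)); p <- p / sum(p)
    v <- pic_botstein(p)
    expect_gte(v, 0); expect_lt(v, 1)
    expect_equal(v, pic_botstein(sample(p)))  # allele labels are arbitrary
  }
})

test_that("allele statistics summarize a genotype matrix correctly", {
  a1 <- rbind(c(1, 1, 1, 1),   # monomorphic
              c(1, 1, 2, 2),   # two equifrequent alleles
              c(NA, NA, NA, NA))
  a2 <- rbind(c(1, 1, 1, 1),
              c(1, 1, 2, 2),
              c(NA, NA, NA, NA))
  gm <- genotype_matrix(a1, a2)
  st <- allele_stats(gm)
  expect_equal(st$per_marker$pic, c(0, 0.375, NA))
  expect_equal(st$per_marker$n_alleles, c(1L, 2L, NA))
  expect_identical(st$per_marker$polymorphic, c(FALSE, TRUE, NA))
  expect_equal(st$panel$n_markers_scored, 2)
  expect_equal(st$panel$pct_polymorphic, 50)
  expect_error(allele_stats(genotype_matrix(matrix(1L, 2, 1))), ">= 2 accessions")
})

test_that("Nei-Li distance follows the band-sharing definition", {
  # identical accessions -> 0; fully disjoint band sets -> 1
  a1 <- rbind(c(1, 1, 3), c(2, 2, 4))
  a2 <- rbind(c(1, 1, 3), c(2, 2, 4))
  gm <- genotype_matrix(a1, a2, accession_ids = c("x", "y", "z"))
  D <- nei_li_distance(gm)
  expect_equal(D["x", "y"], 0)
  expect_equal(D["x", "z"], 1)
  expect_equal(diag(D), c(x = 0, y = 0, z = 0))
  expect_equal(D, t(D))

  # x bands {1,2}, y bands {2,3} at one marker: S = 2*1/4, D = 0.5
  gm2 <- genotype_matrix(rbind(c(1L, 2L)), rbind(c(2L, 3L)),
                         accession_ids = c("x", "y"))
  expect_equal(nei_li_distance(gm2)["x", "y"], 0.5)

  # a pair without jointly scored markers errors by name
  gm3 <- genotype_matrix(rbind(c(1L, NA), c(NA, 2L)), accession_ids = c("x", "y"))
  expect_error(nei_li_distance(gm3), "x / y")
})

test_that("neighbor joining solves the three-point formulas and additive matrices", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 1, 3))
  expect_equal(as.matrix(stats::cophenetic(ape::as.phylo(tr)))[c("A", "B", "C"), c("A", "B", "C")],
               dm)

  # additive 4-taxon matrix from ((A,B),(C,D)) with internal edge 5
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tipl <- c(A = 1, B = 2, C = 3, D = 4)
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["C", "D"] <- d4["D", "C"] <- 7
  for (x in c("A", "B")) for (y in c("C", "D"))
    d4[x, y] <- d4[y, x] <- tipl[x] + 5 + tipl[y]
  tr4 <- nj_tree(d4)
  expect_equal(as.matrix(stats::cophenetic(tr4))[LETTERS[1:4], LETTERS[1:4]], d4)
  expect_setequal(round(tr4$edge.length, 9), c(1, 2, 3, 4, 5))
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite|>= 3")
})

test_that("bootstrap support is 100 when every marker carries the same signal", {
  a1 <- matrix(rep(c(1L, 1L, 2L, 2L, 3L), each = 1, times = 25), nrow = 25,
               byrow = TRUE)
  gm <- genotype_matrix(a1, accession_ids = paste0("t", 1:5))
  D <- nei_li_distance(gm)
  tr <- nj_tree(D, gm, n_bootstrap = 40, seed = 7)
  expect_true(all(tr$node.label[-1] == 100))  # all internal splits recovered always
  # determinism given the seed
  tr2 <- nj_tree(D, gm, n_bootstrap = 40, seed = 7)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("simulated clusters separate with full bootstrap support", {
  gm <- simulate_genotypes(n_markers = 200,
                           group_sizes = c(A = 5, B = 5),
                           between_divergence = 0.3, within_divergence = 0.05,
                           seed = 19)
  D <- nei_li_distance(gm)
  within_A <- D[1:5, 1:5][upper.tri(D[1:5, 1:5])]
  between <- D[1:5, 6:10]
  expect_gt(mean(between), mean(within_A))
  tr <- nj_tree(D, gm, n_bootstrap = 60, seed = 23)
  # the bipartition separating group A from group B has 100% support
  a_tips <- gm$accession_ids[gm$groups == "A"]
  sub <- ape::subtrees(ape::root(tr, outgroup = a_tips[1], resolve.root = TRUE))
  support <- NA_real_
  for (i in seq_along(sub)) {
    tips <- sub[[i]]$tip.label
    if (setequal(tips, a_tips) || setequal(tips, setdiff(gm$accession_ids, a_tips))) {
      node <- sub[[i]]$name
      support <- tr$node.label[node - length(gm$accession_ids)]
    }
  }
  expect_equal(as.numeric(support), 100)
})

test_that("chi-square segregation screen matches hand arithmetic", {
  r1 <- segregation_chi2(c(75, 75), c(1, 1))
  expect_equal(r1$chi2, 0)
  expect_equal(r1$p, 1)
  r2 <- segregation_chi2(c(60, 40), c(1, 1))
  expect_equal(r2$chi2, 4)
  expect_equal(r2$df, 1L)
  expect_equal(r2$p, 0.0455, tolerance = 2e-3)
  r3 <- segregation_chi2(c(30, 10), c(3, 1))
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p, 1)
  expect_error(segregation_chi2(c(10, 10), c(1, 0)), "positive|ratio")
})

test_that("comparative Ct fold changes follow 2^-ddCt", {
  expect_equal(relative_expression(20, 18, 22, 20), 1)    # ddCt = 0
  expect_equal(relative_expression(19, 18, 22, 20), 2)    # ddCt = -1
  expect_equal(relative_expression(20, 18, 25, 18), 32)   # ddCt = 2 - 7 = -5
  expect_error(relative_expression(NA, 1, 1, 1), "finite")
})

test_that("genotype simulation respects its knobs and round-trips through CSV", {
  gm <- simulate_genotypes(n_markers = 60, group_sizes = c(A = 4, B = 4),
                           missing_rate = 0, seed = 29)
  expect_false(anyNA(gm$a1))
  gm_m <- simulate_genotypes(n_markers = 60, group_sizes = c(A = 4, B = 4),
                             missing_rate = 0.2, seed = 29)
  expect_gt(mean(is.na(gm_m$a1)), 0.05)
  # determinism
  gm2 <- simulate_genotypes(n_markers = 60, group_sizes = c(A = 4, B = 4),
                            missing_rate = 0, seed = 29)
  expect_identical(gm$a1, gm2$a1)
  # divergence 0: between-group distances match within-group distances closely
  g0 <- simulate_genotypes(n_markers = 500, group_sizes = c(A = 6, B = 6),
                           between_divergence = 0, within_divergence = 0.05,
                           seed = 31)
  D <- nei_li_distance(g0)
  w <- c(D[1:6, 1:6][upper.tri(diag(6))], D[7:12, 7:12][upper.tri(diag(6))])
  b <- as.vector(D[1:6, 7:12])
  se <- sqrt(stats::var(w) / length(w) + stats::var(b) / length(b))
  expect_lt(abs(mean(b) - mean(w)), 3 * se + 0.01)
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gm_m, f)
  back <- read_genotypes(f)
  expect_equal(unname(back$a1), unname(gm_m$a1))
  expect_equal(unname(back$a2), unname(gm_m$a2))
})
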