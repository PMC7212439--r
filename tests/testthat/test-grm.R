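test_that("the relationship formula reproduces hand-computed entries", {
  ## one locus, base p = 0.5: animal with dosage 2 has W = 1,
  ## G11 = 1 / (2 * 0.25 * 1) = 2; dosage 1 sits at the base mean (0)
  g <- computeGrm(matrix(c(2, 1), 2, 1,
                         dimnames = list(c("x", "y"), NULL)), 0.5)
  expect_equal(unname(diag(grmValues(g))), c(2, 0))
  ## identical genotypes give identical rows: G_ii = G_jj = G_ij
  set.seed(15)
  geno <- hweGeno(1, 40)[c(1, 1), ]
  rownames(geno) <- c("a", "b")
  v <- grmValues(computeGrm(geno, runif(40, 0.2, 0.8)))
  expect_equal(v["a", "a"], v["b", "b"])
  expect_equal(v["a", "a"], v["a", "b"])
})

test_that("dosage and frequency filters are enforced", {
  expect_error(computeGrm(matrix(3, 1, 1), 0.5), "0, 1, or 2")
  expect_error(computeGrm(matrix(2, 1, 1), 1), "monomorphic")
  g <- computeGrm(matrix(c(0, 1, 2, 2, 2, 2), 3, 2), c(0.5, 1))
  expect_equal(nLociUsed(g), 1L)                    # p = 1 excluded
})

test_that("locus selection by source follows set algebra", {
  loci <- data.frame(locus = 1:10, chrom = 1L, posCM = 1:10,
                     class = rep(c("marker", "qtl"), 5), baseFreq = 0.5)
  qtl <- c(2L, 6L)                                  # trait keeps 2 of 5 QTL
  m <- selectLoci(loci, "M", qtl)
  q <- selectLoci(loci, "Q", qtl)
  a <- selectLoci(loci, "A", qtl)
  expect_length(intersect(m, q), 0)
  expect_identical(a, sort(union(m, q)))
  expect_identical(q, qtl)                          # dropped QTL excluded
  expect_error(selectLoci(loci[loci$class == "qtl", ], "M", qtl), "empty")
})

test_that("incremental extension equals recomputation from scratch", {
  set.seed(16)
  geno <- hweGeno(8, 60)
  p <- colMeans(geno[1:5, ]) / 2
  p <- pmin(pmax(p, 0.05), 0.95)
  g5 <- computeGrm(geno[1:5, ], p)
  g8 <- extendGrm(g5, geno[6:8, ])
  full <- computeGrm(geno, p)
  expect_lt(max(abs(grmValues(g8) - grmValues(full))), 1e-12)
  expect_identical(grmValues(extendGrm(g5, geno[0, , drop = FALSE])),
                   grmValues(g5))
  ## associativity of repeated extension
  gAB <- extendGrm(extendGrm(g5, geno[6:7, ]), geno[8, , drop = FALSE])
  expect_lt(max(abs(grmValues(gAB) - grmValues(g8))), 1e-12)
})

test_that("permuting animals permutes the matrix consistently", {
  set.seed(17)
  geno <- hweGeno(6, 50)
  p <- rep(0.5, 50)
  v1 <- grmValues(computeGrm(geno, p))
  perm <- sample(6)
  v2 <- grmValues(computeGrm(geno[perm, ], p))
  expect_equal(v2, v1[perm, perm])
})

test_that("base-frequency scaling centers the mean diagonal near 1", {
  set.seed(18)
  geno <- hweGeno(100, 5000)
  p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  g <- computeGrm(geno[, keep], p[keep])
  expect_lt(abs(mean(diag(grmValues(g))) - 1), 0.1)
  ## PSD up to tolerance
  ev <- eigen(grmValues(g), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("sparse-haplotype and dense-dosage paths build the same matrix", {
  pools <- reducedPools()
  tab <- segregatingLoci(pools)
  dSparse <- founderDosage(pools, tab$locus)        # from sparse sets
  hm <- gocsim:::founderHapMatrix(pools, tab$locus) # dense 0/1 haplotypes
  n <- pools@popSize
  dDense <- hm[2 * seq_len(n) - 1L, ] + hm[2 * seq_len(n), ]
  rownames(dDense) <- rownames(dSparse)
  expect_identical(unname(dSparse), unname(dDense))
  keep <- tab$freq > 0 & tab$freq < 1
  gS <- grmValues(computeGrm(dSparse[, keep], tab$freq[keep]))
  gD <- grmValues(computeGrm(dDense[, keep], tab$freq[keep]))
  expect_lt(max(abs(gS - gD)), 1e-12)
})
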