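# Adjacency, t-maps and the cluster-based permutation test.

test_that("the 5-cm rule defines neighbours", {
  m <- data.frame(label = c("a", "b", "c"),
                  x_cm = c(0, 4.9, 10.0), y_cm = 0, z_cm = 0)
  adj <- buildAdjacency(m, 5)
  expect_equal(nrow(adj@edges), 1L)               # a-b at 4.9 cm only
  expect_equal(sort(adj@edges[1, ]), c(1L, 2L))
  m$x_cm[2] <- 5.1
  m$x_cm[3] <- 10.3
  expect_equal(nrow(buildAdjacency(m, 5)@edges), 0L)
  expect_equal(nrow(buildAdjacency(m, 0)@edges), 0L)
  m$x_cm[3] <- NA
  expect_error(buildAdjacency(m, 5), "missing")
})

test_that("identical conditions give a zero t-map", {
  set.seed(1)
  A <- array(rnorm(5 * 3 * 10), c(5, 3, 10))
  expect_message(tm <- pairedTMap(A, A), "sentinel")  # 0/0 cells logged
  expect_true(all(tm == 0))
})

test_that("the t-map matches the closed-form dependent-samples t", {
  set.seed(2)
  A <- array(rnorm(6 * 2 * 4), c(6, 2, 4)) + 1
  B <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  expect_equal(pairedTMap(A, B), bruteTMap(A, B), ignore_attr = TRUE,
               tolerance = 1e-12)
  # antisymmetry under sign flip of all differences
  expect_equal(pairedTMap(B, A), -pairedTMap(A, B), ignore_attr = TRUE)
})

test_that("zero-variance cells get the max-magnitude sentinel", {
  A <- array(rnorm(4 * 1 * 3, 0, 0.01), c(4, 1, 3))
  B <- A
  B[, 1, 2] <- A[, 1, 2] - 1          # constant unit difference
  expect_message(tm <- pairedTMap(A, B), "sentinel")
  expect_true(tm[1, 2] > abs(tm[1, 1]))
  expect_true(tm[1, 2] > abs(tm[1, 3]))
})

test_that("identical conditions yield no significant clusters", {
  set.seed(3)
  adj <- buildAdjacency(standardMontage()[1:4, ], 5)
  A <- array(rnorm(8 * 4 * 12), c(8, 4, 12))
  suppressMessages(
    res <- clusterPermutationTest(A, A, adj, nPermutations = 500))
  expect_false(any(res@significant))
})

test_that("Monte-Carlo equals the exhaustive sign-flip oracle at n = 4", {
  set.seed(4)
  m <- data.frame(label = c("p", "q"), x_cm = c(0, 3), y_cm = 0, z_cm = 0)
  adj <- buildAdjacency(m, 5)
  A <- array(rnorm(4 * 2 * 3, 2), c(4, 2, 3))
  B <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  res <- clusterPermutationTest(A, B, adj, nPermutations = 1000)
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 16L)

  # independent oracle: enumerate all 16 sign assignments with brute-force
  # clustering (helper code shares nothing with the package internals)
  thr <- qt(0.975, 3)
  nbr <- list(2L, 1L)
  tFor <- function(signs) {
    Af <- A; Bf <- B
    for (i in which(signs < 0)) { Af[i, , ] <- B[i, , ]; Bf[i, , ] <- A[i, , ] }
    bruteTMap(Af, Bf)
  }
  maxNull <- apply(as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1),
                                         s3 = c(1, -1), s4 = c(1, -1))),
                   1, function(sg) {
                     sums <- bruteClusterSums(tFor(sg), thr, nbr)
                     if (length(sums)) max(abs(sums)) else 0
                   })
  obsSums <- bruteClusterSums(bruteTMap(A, B), thr, nbr)
  expect_equal(sort(abs(res@summedT)), sort(abs(obsSums)), tolerance = 1e-9)
  pOracle <- vapply(res@summedT, function(st)
    mean(maxNull >= abs(st) - 1e-9), 0)
  expect_equal(res@pValues, pOracle, tolerance = 1e-12)
})

test_that("cluster structure is invariant to channel reordering", {
  set.seed(5)
  mont <- standardMontage()[1:6, ]
  A <- array(rnorm(8 * 6 * 15), c(8, 6, 15))
  A[, 2:3, 6:9] <- A[, 2:3, 6:9] + 2.5
  B <- array(rnorm(8 * 6 * 15), c(8, 6, 15))
  res1 <- clusterPermutationTest(A, B, buildAdjacency(mont, 5),
                                 nPermutations = 300, seed = 9)
  perm <- c(4, 2, 6, 1, 3, 5)
  res2 <- clusterPermutationTest(A[, perm, ], B[, perm, ],
                                 buildAdjacency(mont[perm, ], 5),
                                 nPermutations = 300, seed = 9)
  expect_equal(sort(res1@summedT), sort(res2@summedT), tolerance = 1e-9)
})

test_that("null permutation p-values are super-uniform at alpha", {
  out <- clusterTestFalsePositiveRate(nDatasets = 100, nSubjects = 12,
                                      nChannels = 4, nSamples = 20,
                                      nPermutations = 300, seed = 42)
  expect_lte(out$fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(6)
  m <- data.frame(label = "solo", x_cm = 0, y_cm = 0, z_cm = 0)
  adj <- buildAdjacency(m, 5)
  A <- array(rnorm(10 * 1 * 5, 1.2), c(10, 1, 5))
  B <- array(rnorm(10 * 1 * 5), c(10, 1, 5))
  exact <- clusterPermutationTest(A, B, adj, nPermutations = 1024)
  expect_true(exact@exhaustive)
  mc <- clusterPermutationTest(A, B, adj, nPermutations = 1000, seed = 1)
  expect_false(mc@exhaustive)
  expect_lt(max(abs(mc@pValues - exact@pValues)), 0.05)
})

test_that("few permutations draw a warning", {
  set.seed(7)
  adj <- buildAdjacency(standardMontage()[1:2, ], 5)
  A <- array(rnorm(5 * 2 * 4), c(5, 2, 4))
  expect_warning(clusterPermutationTest(A, A + 0.1, adj,
                                        nPermutations = 50),
                 "fewer than 100")
})
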