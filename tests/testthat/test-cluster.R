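make_profiles <- function(df) tibble::as_tibble(df)

test_that("heterogeneity matches hand values and the brute-force oracle", {
  # two members, one fraction, flux difference 1, identical abundance
  prof <- make_profiles(data.frame(
    protein = c("a", "b"), fraction = 4, flux = c(1, 2), q = c(3, 3)))
  expect_equal(cluster_heterogeneity(c("a", "b"), prof, 4, 4), 0.5)
  # identical members: zero
  prof2 <- make_profiles(data.frame(
    protein = c("a", "b"), fraction = 4, flux = 1, q = 1))
  expect_equal(cluster_heterogeneity(c("a", "b"), prof2, 4, 4), 0)
  # random 3-member case over several fractions vs the oracle
  set.seed(11)
  prof3 <- make_profiles(expand.grid(protein = c("a", "b", "c"),
                                     fraction = 3:7))
  prof3$flux <- runif(nrow(prof3))
  prof3$q <- runif(nrow(prof3))
  expect_equal(cluster_heterogeneity(c("a", "b", "c"), prof3, 3, 7),
               oracle_heterogeneity(c("a", "b", "c"), prof3, 3, 7))
  # missing values skip the affected fraction terms, as in the oracle
  prof3$flux[prof3$fraction == 5 & prof3$protein == "b"] <- NA
  expect_equal(cluster_heterogeneity(c("a", "b", "c"), prof3, 3, 7),
               oracle_heterogeneity(c("a", "b", "c"), prof3, 3, 7))
  expect_error(cluster_heterogeneity("a", prof3, 3, 7), "2 members")
})

test_that("heterogeneity is invariant under member permutation", {
  set.seed(5)
  prof <- make_profiles(expand.grid(protein = letters[1:4], fraction = 4:7))
  prof$flux <- runif(nrow(prof)); prof$q <- runif(nrow(prof))
  h1 <- cluster_heterogeneity(c("a", "b", "c", "d"), prof, 4, 7)
  h2 <- cluster_heterogeneity(c("d", "b", "a", "c"), prof, 4, 7)
  expect_identical(h1, h2)
})

test_that("alternative enumeration equals a brute-force powerset filter", {
  # 6-node toy contact graph
  f <- tempfile(fileext = ".tsv")
  ids <- c("t", "n1", "n2", "n3", "n4", "x")
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m["t", c("n1", "n2", "n3", "n4")] <- c(100, 200, 300, 400)
  m[c("n1", "n2", "n3", "n4"), "t"] <- c(100, 200, 300, 400)
  m["n1", "x"] <- m["x", "n1"] <- 50
  df <- as.data.frame(m)
  utils::write.table(df, f, sep = "\t", quote = FALSE, col.names = NA)
  cm <- load_contact_matrix(f)
  set.seed(2)
  prof <- make_profiles(expand.grid(protein = ids, fraction = 4:7))
  prof$flux <- runif(nrow(prof)); prof$q <- runif(nrow(prof))
  alt <- enumerate_alternatives("t", 3, cm, prof, 4, 7)
  expect_equal(nrow(alt$alternatives), choose(4, 2))
  # brute force: every subset of the powerset of non-target species that has
  # size 2 and consists only of contact neighbours of the target
  nb <- c("n1", "n2", "n3", "n4")
  brute <- combn(setdiff(ids, "t"), 2, simplify = FALSE)
  brute <- Filter(function(s) all(s %in% nb), brute)
  brute_H <- sort(vapply(brute, function(s) {
    oracle_heterogeneity(c("t", s), prof, 4, 7)
  }, numeric(1)))
  expect_equal(sort(alt$alternatives$H), brute_H)
  # all-contact cluster is scored too
  expect_equal(alt$all_contact_H,
               oracle_heterogeneity(c("t", nb), prof, 4, 7))
  # neighbour shortage flags the *** case
  alt2 <- enumerate_alternatives("x", 3, cm, prof, 4, 7)
  expect_true(alt2$no_alternatives)
  # size - 1 == neighbour count: exactly one candidate
  alt3 <- enumerate_alternatives("x", 2, cm, prof, 4, 7)
  expect_equal(nrow(alt3$alternatives), 1)
})

test_that("selected-cluster quantile uses the strictly-below convention", {
  expect_equal(selected_cluster_quantile(1, c(2, 3, 4)), 0)
  expect_equal(selected_cluster_quantile(5, c(1:4, 5, 6:9, 10)[-5]), 0.4444,
               tolerance = 1e-3)
  # selected is the maximum of 10 values: 9 of 10 alternatives strictly below
  expect_equal(selected_cluster_quantile(10, 1:10), 0.9)
  # all equal: ties favour the selected cluster
  expect_equal(selected_cluster_quantile(2, rep(2, 8)), 0)
  expect_error(selected_cluster_quantile(1, numeric(0)), "no alternative")
})

test_that("module distance follows the squared-difference formula", {
  prof <- make_profiles(data.frame(
    protein = c("a", "b", "c"), fraction = 5,
    flux = c(1, 2, 3), q = c(1, 1, 1)))
  # species equal to the module mean
  expect_equal(module_distance("b", c("a", "b", "c"), prof, 5), 0)
  # flux difference 2, abundance difference 0 -> d = 2
  prof2 <- make_profiles(data.frame(
    protein = c("a", "b"), fraction = 5, flux = c(4, 2), q = c(1, 1)))
  expect_equal(module_distance("a", "b", prof2, 5), 2)
  # toy module of 3 vs hand computation
  prof3 <- make_profiles(data.frame(
    protein = c("a", "b", "c", "s"), fraction = 6,
    flux = c(0.2, 0.4, 0.6, 0.1), q = c(1, 2, 3, 1.5)))
  d_hand <- 0.5 * ((mean(c(0.2, 0.4, 0.6)) - 0.1)^2 + (2 - 1.5)^2)
  expect_equal(module_distance("s", c("a", "b", "c"), prof3, 6), d_hand)
  expect_error(module_distance("zz", c("a", "b"), prof3, 6), "undefined")
})
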