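test_that("la_score is the mean triple product and fully symmetric", {
  expect_equal(la_score(c(1, -1), c(1, -1), c(1, -1)), 0)
  expect_equal(la_score(c(1, 1, -1), c(1, -1, -1), c(3, 0, 3)), 2)
  expect_error(la_score(1:3, 1:3, 1:4), "lengths")
  set.seed(1)
  for (rep in 1:20) {
    m <- sample(3:50, 1)
    x <- rnorm(m); y <- rnorm(m); z <- rnorm(m)
    la <- la_score(x, y, z)
    expect_identical(la, la_score(y, x, z))  # same product association
    tol <- 1e-13 * max(1, abs(la))
    expect_lt(abs(la - la_score(z, y, x)), tol)
    expect_lt(abs(la - la_score(z, x, y)), tol)
    expect_lte(abs(la), max(abs(x * y * z)))
  }
})

test_that("the null LA score is centred at zero", {
  set.seed(2)
  las <- replicate(4000, la_score(rnorm(30), rnorm(30), rnorm(30)))
  se <- sd(las) / sqrt(length(las))
  expect_lt(abs(mean(las)), 4 * se)
})

test_that("a degenerate all-zero mediator gives p = 1", {
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(la_permutation_test(x, y, rep(0, 20), n_perm = 100, seed = 1), 1)
})

test_that("sampled permutation p agrees with exhaustive enumeration at m = 6", {
  set.seed(3)
  x <- oracle_normal_scores(rnorm(6))
  y <- oracle_normal_scores(rnorm(6))
  z <- oracle_normal_scores(rnorm(6))
  obs <- la_score(x, y, z)
  perms <- oracle_perms(6)
  la_all <- apply(perms, 1, function(ix) mean(x * y * z[ix]))
  p_exact <- mean(abs(la_all) >= abs(obs))
  n_perm <- 20000
  p_samp <- la_permutation_test(x, y, z, n_perm = n_perm, seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_samp - p_exact), 3 * se + 2 / n_perm)
})

test_that("permutation p is invariant under a joint permutation of all series", {
  # exactly invariant under exhaustive enumeration of the permutation group
  set.seed(5)
  x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
  perms <- oracle_perms(6)
  exact_p <- function(x, y, z) {
    obs <- la_score(x, y, z)
    mean(apply(perms, 1, function(ix) abs(mean(x * y * z[ix]))) >= abs(obs))
  }
  jp <- sample(6)
  expect_equal(exact_p(x, y, z), exact_p(x[jp], y[jp], z[jp]), tolerance = 1e-12)

  # and invariant up to Monte-Carlo error for the sampled test
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  perm <- sample(40)
  p1 <- la_permutation_test(x, y, z, n_perm = 2000, seed = 6)
  p2 <- la_permutation_test(x[perm], y[perm], z[perm], n_perm = 2000, seed = 6)
  expect_lt(abs(p1 - p2), 3 * sqrt(0.5 * 0.5 / 2000) + 1e-3)
})

test_that("type classification is the documented bijection and rejects zeros", {
  expect_identical(classify_la_type(c("+", "-", "+", "-"), c("+", "+", "-", "-")),
                   c("A", "B", "C", "D"))
  expect_length(unique(classify_la_type(rep(c("+", "-"), 2), rep(c("+", "-"), each = 2))), 4L)
  expect_error(classify_la_type("0", "+"), "zero")
  expect_error(classify_la_type("+", ""), "zero")
})

test_that("generated triplets carry the geometry of their type", {
  # X, Y correlate positively only where Z is above its median -> LA > 0, LS +
  set.seed(7)
  hits <- 0L
  for (rep in 1:20) {
    tr <- simulate_mediated_triplet(120, "A", beta = 1, noise_sd = 0.5, seed = 700 + rep)
    zx <- rank_normal_transform(tr$x)$z
    zy <- rank_normal_transform(tr$y)$z
    zz <- rank_normal_transform(tr$z)$z
    hi <- zz > 0
    ok <- cor(zx[hi], zy[hi]) > cor(zx[!hi], zy[!hi]) &&
      la_score(zx, zy, zz) > 0 && local_similarity(zx, zy)$sign == "+"
    hits <- hits + ok
  }
  expect_gte(hits, 18L)
  # X, Y negatively correlated only where Z is low -> LA > 0, LS -
  tr <- simulate_mediated_triplet(200, "B", beta = 1.5, noise_sd = 0.3, seed = 8)
  zx <- rank_normal_transform(tr$x)$z
  zy <- rank_normal_transform(tr$y)$z
  zz <- rank_normal_transform(tr$z)$z
  expect_gt(la_score(zx, zy, zz), 0)
  expect_identical(local_similarity(zx, zy)$sign, "-")
  expect_identical(classify_la_type("-", "+"), "B")
})

test_that("mediator scanning recovers a planted mediator among null candidates", {
  set.seed(9)
  recovered <- 0L
  for (rep in 1:5) {
    tr <- simulate_mediated_triplet(120, "A", beta = 1, noise_sd = 0.5, seed = 90 + rep)
    vals <- rbind(X = tr$x, Y = tr$y, Z = tr$z, t(replicate(20, rnorm(120))))
    ids <- c("X", "Y", "Z", sprintf("N%02d", 1:20))
    nz <- normalize_table(abundance_table(vals, ids))
    pairs <- screen_pairs(nz)
    if (!nrow(pairs)) next
    trip <- scan_mediators(pairs, nz, n_perm = 1000, seed = 90 + rep)
    if (nrow(trip) == 1L && trip$z_id == "Z" && trip$la_type == "A")
      recovered <- recovered + 1L
  }
  expect_gte(recovered, 4L)
})

test_that("the effect cutoff and the self-mediation exclusion hold", {
  set.seed(10)
  tr <- simulate_mediated_triplet(120, "A", beta = 1, noise_sd = 0.5, seed = 11)
  vals <- rbind(X = tr$x, Y = tr$y, Z = tr$z, N1 = rnorm(120), N2 = rnorm(120))
  nz <- normalize_table(abundance_table(vals, c("X", "Y", "Z", "N1", "N2")))
  pairs <- screen_pairs(nz)
  expect_gte(nrow(pairs), 1L)
  trip_all <- scan_mediators(pairs, nz, n_perm = 500, seed = 12, keep_all = TRUE)
  # X and Y never appear as their own mediator
  expect_false(any(trip_all$z_id == trip_all$x_id | trip_all$z_id == trip_all$y_id))
  # a |LA| cutoff of 0.8 removes every weaker triplet
  trip_cut <- scan_mediators(pairs, nz, n_perm = 500, seed = 12, la_effect_cut = 0.8)
  expect_true(all(abs(trip_cut$la) >= 0.8))
  weaker <- trip_all[abs(trip_all$la) < 0.8, c("x_id", "y_id", "z_id")]
  if (nrow(weaker) && nrow(trip_cut))
    expect_equal(nrow(merge(weaker, trip_cut)), 0L)
})
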