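test_that("pseudopopulation pools units across sessions aligned by
           within-odour trial index", {
  g1 <- generate_session(quick_config(n_units = 3, n_trials_per_odour = 5,
                                      seed = 1))
  g2 <- generate_session(quick_config(n_units = 4, n_trials_per_odour = 5,
                                      seed = 2))
  pop <- build_pseudopopulation(list(g1$session, g2$session), n_trials = 5)
  expect_equal(dim(pop$counts), c(30, 7))
  expect_equal(pop$odour, rep(3:8, each = 5))
  # single session: matrix equals its own trial x unit count table
  pop1 <- build_pseudopopulation(g1$session, n_trials = 5)
  expect_equal(dim(pop1$counts), c(30, 3))
  expect_equal(pop$counts[, 1:3], pop1$counts)
  expect_error(build_pseudopopulation(g1$session, n_trials = 19),
               "fewer than 19")
})

test_that("odour-window spike counts land in the right cells", {
  tr <- toy_trials(c(3, 4), c(10, 30))
  s <- toy_session(list(c(10.1, 10.3, 10.45, 10.6, 29, 30.2)), tr)
  pop <- build_pseudopopulation(s, n_trials = 1)
  # odour 3: spikes at +0.1 +0.3 +0.45 (the +0.6 is outside [0, 0.5))
  expect_equal(unname(pop$counts[pop$odour == 3, 1]), 3)
  expect_equal(unname(pop$counts[pop$odour == 4, 1]), 1)
})

test_that("cross-odour distances partition into within and cross groups", {
  tr <- toy_trials(c(3, 3, 4, 4), c(10, 30, 50, 70))
  # two units; population vectors: (0,0), (1,0) for odour 3 and
  # (3,4), (3,5) for odour 4
  s <- toy_session(list(c(50.1, 50.2, 50.3, 70.1, 70.2, 70.3),
                        c(50.1, 50.2, 50.25, 50.3, 70.1, 70.15, 70.2,
                          70.3, 70.4, 30.1)), tr)
  pop <- build_pseudopopulation(s, n_trials = 2)
  ds <- cross_odour_distances(pop)
  expect_equal(ds$groups$w3, 1)                 # |(0,0)-(0,1)| = 1
  expect_true(5 %in% ds$groups$x3_4)            # |(0,0)-(3,4)| = 5
  expect_true(ds$degenerate)                    # too few distances per group
  # identical vectors for all trials: everything zero, flagged degenerate
  s0 <- toy_session(list(rep(0.5, 0)), tr)
  pop0 <- build_pseudopopulation(s0, n_trials = 2)
  ds0 <- cross_odour_distances(pop0)
  expect_true(all(unlist(ds0$groups) == 0))
  expect_true(ds0$degenerate)
})

test_that("distances are invariant to unit (column) permutation and the
           omnibus pipeline runs on a real population", {
  pop <- null_population(n_units = 20, seed = 3)
  ds <- cross_odour_distances(pop)
  perm <- pop
  set.seed(4)
  perm$counts <- perm$counts[, sample(ncol(perm$counts))]
  ds_p <- cross_odour_distances(perm)
  expect_equal(ds$groups, ds_p$groups)
  expect_false(ds$degenerate)
  expect_equal(length(ds$groups), 6 + 15)
  expect_equal(length(ds$groups$w3), choose(19, 2))
  expect_equal(length(ds$groups$x3_4), 19 * 19)
  expect_s3_class(ds$omnibus, "test_result")
  expect_equal(ds$omnibus$df[1], 20)
  expect_true(isSymmetric(ds$games_howell$p))
  expect_true(all(is.na(diag(ds$grid))))
  expect_true(all(ds$grid[!is.na(ds$grid)] >= 0 &
                    ds$grid[!is.na(ds$grid)] <= 1))
})

test_that("Gaussian classifier assigns by likelihood with deterministic
           tie-breaking", {
  x <- matrix(c(-6, -5, -4, 4, 5, 6), ncol = 1)
  labels <- c(3, 3, 3, 4, 4, 4)
  m <- fit_gaussian_classifier(x, labels)
  expect_equal(predict(m, 4), 4)
  expect_equal(predict(m, -5), 3)   # query at a class mean
  expect_equal(predict(m, 0), 3)    # equidistant: lowest carbon wins
  # matrix input gives one label per row
  expect_equal(predict(m, matrix(c(-4.5, 5.5), ncol = 1)), c(3, 4))
})

test_that("Gaussian classifier with isotropic pooled covariance equals
           nearest-class-mean assignment", {
  # identical isotropic scatter around each class mean
  offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  means <- rbind(c(0, 0), c(4, 1), c(-3, 2), c(1, -4))
  x <- do.call(rbind, lapply(1:4, function(i) {
    sweep(offsets, 2, means[i, ], "+")
  }))
  labels <- rep(3:6, each = 4)
  m <- fit_gaussian_classifier(x, labels)
  set.seed(5)
  queries <- matrix(runif(400, -5, 5), ncol = 2)
  pred <- predict(m, queries)
  nearest <- apply(queries, 1, function(q) {
    (3:6)[which.min(colSums((t(means) - q)^2))]
  })
  expect_equal(pred, nearest)
})

test_that("kNN/ECOC classifier behaves on coincident, separated and
           duplicated training data", {
  set.seed(6)
  x <- rbind(matrix(rnorm(20, 0), ncol = 2),
             matrix(rnorm(20, 8), ncol = 2))
  labels <- rep(c(3, 4), each = 10)
  m1 <- fit_knn_ecoc(x, labels, k = 1)
  expect_equal(predict(m1, x[1, ]), 3)   # coincident training point
  m3 <- fit_knn_ecoc(x, labels, k = 3)
  held <- rbind(c(0.5, -0.5), c(8.2, 7.9))
  expect_equal(predict(m3, held), c(3, 4))
  # duplicated training set: identical predictions
  m_dup <- fit_knn_ecoc(rbind(x, x), rep(labels, 2), k = 3)
  set.seed(7)
  q <- matrix(rnorm(40, 4), ncol = 2)
  expect_equal(predict(m3, q), predict(m_dup, q))
  expect_error(fit_knn_ecoc(x, labels, k = 0), "invalid k")
  expect_error(fit_knn_ecoc(x, labels, k = 50), "invalid k")
})

test_that("decoding is seeded-deterministic and validates sizes", {
  pop <- null_population(n_units = 25, seed = 8)
  c1 <- decode_accuracy(pop, "gaussian", sizes = c(10, 20), iters = 50,
                        seed = 9)
  c2 <- decode_accuracy(pop, "gaussian", sizes = c(10, 20), iters = 50,
                        seed = 9)
  expect_identical(c1, c2)
  expect_error(decode_accuracy(pop, sizes = 30, iters = 10), "exceeds")
  expect_error(decode_accuracy(pop, sizes = 2, iters = 10, pca_dim = 4),
               "pca_dim")
})

test_that("well-separated clusters decode nearly perfectly with both
           classifiers", {
  pop <- cluster_population(n_units = 60, sep = 30, seed = 10)
  cg <- decode_accuracy(pop, "gaussian", sizes = c(20, 60), iters = 100,
                        seed = 11)
  ck <- decode_accuracy(pop, "knn_ecoc", sizes = c(20, 60), iters = 100,
                        seed = 11)
  expect_true(all(cg$accuracy >= 0.95))
  expect_true(all(ck$accuracy >= 0.95))
  expect_true(all(cg$binomial_p < 1e-10))
})

test_that("odour-independent firing decodes at chance at every size", {
  pop <- null_population(n_units = 40, seed = 12)
  cv <- decode_accuracy(pop, "gaussian", sizes = c(10, 20, 40),
                        iters = 200, seed = 13)
  se3 <- 3 * sqrt(1 / 6 * 5 / 6 / 200)
  # dataset-level spread adds to iteration noise; allow both
  expect_true(all(abs(cv$accuracy - 1 / 6) < se3 + 0.05))
  # permuted labels are equally uninformative
  set.seed(14)
  perm <- pop
  perm$odour <- sample(perm$odour)
  cvp <- decode_accuracy(perm, "gaussian", sizes = c(10, 40), iters = 200,
                         seed = 15)
  expect_true(all(abs(cvp$accuracy - 1 / 6) < se3 + 0.05))
})

test_that("decoding accuracy grows with population size for tuned
           populations", {
  g <- generate_session(genotype_preset("control", n_units = 60,
                                        seed = 500))
  pop <- build_pseudopopulation(g$session)
  cv <- decode_accuracy(pop, "gaussian", sizes = c(10, 30, 60),
                        iters = 150, seed = 16)
  se2 <- 2 * sqrt(cv$accuracy * (1 - cv$accuracy) / 150)
  expect_true(all(diff(cv$accuracy) > -(se2[-1] + se2[-length(se2)])))
  expect_gt(cv$accuracy[3], 1 / 6)
})

test_that("decoding-curve comparison flags only real differences", {
  pop <- null_population(n_units = 20, seed = 17)
  cv <- decode_accuracy(pop, "gaussian", sizes = c(10, 20), iters = 60,
                        seed = 18)
  cmp_same <- compare_decoding_curves(cv, cv)
  expect_true(all(cmp_same$p_adj == 1))
  # all-correct vs chance-level outcomes
  cv_hi <- cv
  cv_hi$outcomes[] <- TRUE
  cv_hi$accuracy <- colMeans(cv_hi$outcomes)
  cmp <- compare_decoding_curves(cv_hi, cv)
  expect_true(all(cmp$p_adj < 1e-6))
  cv_short <- cv
  cv_short$sizes <- 10
  expect_error(compare_decoding_curves(cv, cv_short), "mismatched")
})
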