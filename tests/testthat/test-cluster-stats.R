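# Clustering of parameter vectors and the significance scan.

fake_params <- function(n, tau = 0.3, nn = 2, d = 2, a = 1, b = 0,
                        jitter = 0, seed = 1) {
  set.seed(seed)
  cbind(tau = pmax(0.05, tau + jitter * rnorm(n)),
        n = pmax(1, nn + jitter * rnorm(n)),
        d = pmax(0, d + jitter * rnorm(n)), a = a + jitter * rnorm(n),
        b = b + jitter * rnorm(n))
}

test_that("feature standardization is population-based and invertible", {
  params <- rbind(fake_params(10, jitter = 0.2, seed = 21),
                  fake_params(10, tau = 0.6, nn = 4, d = 3, jitter = 0.2,
                              seed = 22))
  fits <- make_fake_fits(params, rs = runif(20))
  fm <- build_features(fits)
  expect_true(all(abs(colMeans(fm$x)) < 1e-10))
  expect_equal(apply(fm$x, 2, function(c) sqrt(mean((c - mean(c))^2))),
               rep(1, 5), tolerance = 1e-10, ignore_attr = TRUE)

  # two distinct fits standardize to (-1, +1) columns under ddof 0
  two <- build_features(make_fake_fits(rbind(fake_params(1),
                                             fake_params(1, tau = 0.6,
                                                         nn = 4, d = 3,
                                                         a = 2, b = 1)),
                                       c(0.5, 0.6)))
  expect_true(all(abs(abs(two$x) - 1) < 1e-10))

  expect_error(build_features(make_fake_fits(fake_params(1), 0.5)),
               "at least 2")
  same <- make_fake_fits(rbind(fake_params(1), fake_params(1)), c(0.1, 0.2))
  expect_error(build_features(same), "zero-variance")
})

test_that("Ward linkage merges nearest points first and separates blobs", {
  # two points merge at their Euclidean distance
  x <- rbind(c(0, 0), c(3, 4))
  tree <- ward_linkage(x)
  expect_equal(tree$height, 5, tolerance = 1e-12)

  # 1-D points (0), (1), (10): first merge joins 0 and 1
  tree3 <- ward_linkage(matrix(c(0, 1, 10), ncol = 1))
  expect_identical(sort(tree3$merge[1, ]), c(-2L, -1L))

  # two tight, well-separated Gaussian blobs are recovered at a cut of 2
  set.seed(23)
  blob <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                matrix(rnorm(40, 10, 0.1), ncol = 2))
  lab <- cut_tree(ward_linkage(blob), 2)
  expect_identical(length(unique(lab[1:20])), 1L)
  expect_identical(length(unique(lab[21:40])), 1L)
  expect_false(lab[1] == lab[21])
})

test_that("tree cutting is nested and respects bounds", {
  set.seed(24)
  x <- matrix(rnorm(60), ncol = 3)
  tree <- ward_linkage(x)
  expect_identical(length(unique(cut_tree(tree, 1))), 1L)
  expect_identical(length(unique(cut_tree(tree, 20))), 20L)
  # refinement: clusters at N+1 refine clusters at N
  for (N in 2:6) {
    a <- cut_tree(tree, N); b <- cut_tree(tree, N + 1)
    for (k in unique(b)) expect_identical(length(unique(a[b == k])), 1L)
  }
  expect_error(cut_tree(tree, 0), "outside")
  expect_error(cut_tree(tree, 21), "outside")
})

test_that("Fisher Z and the cluster statistic match closed forms", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.6), 0.5 * log(1.6 / 0.4), tolerance = 1e-12)
  expect_equal(fisher_z(-0.37), -fisher_z(0.37), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))

  st <- cluster_zstat(rep(1, 4))
  expect_equal(st$z_star, 2, tolerance = 1e-12)   # sqrt(4) * 1
  expect_equal(cluster_zstat(0.7)$z_star, 0.7, tolerance = 1e-12)
  set.seed(25)
  zs <- rnorm(17)
  expect_equal(cluster_zstat(zs)$z_star, sqrt(17) * sum(zs) / 17,
               tolerance = 1e-12)
  expect_error(cluster_zstat(numeric(0)), "empty")
})

test_that("significance scan applies Bonferroni-corrected two-sided tests", {
  params <- rbind(fake_params(25, jitter = 0.05, seed = 26),
                  fake_params(25, tau = 0.6, nn = 4, d = 3, jitter = 0.05,
                              seed = 27))
  # all r = 0: nothing significant anywhere
  fits0 <- make_fake_fits(params, rs = rep(0, 50))
  tree <- ward_linkage(build_features(fits0))
  rep0 <- significance_scan(tree, rep(0, 50))
  expect_true(all(rep0$cs == 0))
  expect_true(rep0$p_values_approximate)

  # threshold oracle at N = 5, alpha = 0.05
  div5 <- rep0$divisions[["5"]]
  expect_equal(unique(div5$z_alpha), qnorm(1 - 0.005), tolerance = 1e-10)
  expect_equal(unique(div5$z_alpha), 2.5758293, tolerance = 1e-6)

  # all r = 0.9 with 50 fits: both clusters significant at N = 2
  rep9 <- significance_scan(tree, rep(0.9, 50))
  expect_identical(unname(rep9$cs[["2"]]), 2L)

  # partition conservation at every division
  for (N in names(rep9$divisions))
    expect_identical(sum(rep9$divisions[[N]]$size), 50L)

  # strengthening monotonicity: scaling all z up never lowers any C_S
  r_mixed <- c(rep(0.35, 25), rep(0.1, 25))
  weak <- significance_scan(tree, r_mixed)
  strong <- significance_scan(tree, tanh(2 * atanh(r_mixed)))
  expect_true(all(strong$cs >= weak$cs))
})

test_that("optimal-division logic picks the largest tied maximum", {
  mk <- function(cs) {
    structure(list(cs = setNames(cs, as.character(2:12)),
                   n_range = 2:12, divisions = list(), labels = list(),
                   alpha = 0.05, p_values_approximate = TRUE),
              class = "cluster_report")
  }
  # worked-example profile: 2:2, 3:2, 4:2, 5:2, then <= 1
  expect_identical(select_optimal(mk(c(2, 2, 2, 2, 1, 1, 1, 0, 0, 0, 0))), 5L)
  expect_identical(select_optimal(mk(c(1, 3, 2, 0, 0, 0, 0, 0, 0, 0, 0))), 3L)
  expect_identical(select_optimal(mk(rep(0, 11))), NA_integer_)
})

test_that("representative kernels are unit-area cluster means", {
  params <- rbind(fake_params(3, tau = 0.3, nn = 2, d = 2, seed = 28),
                  fake_params(2, tau = 0.5, nn = 3, d = 2.6, seed = 29))
  fits <- make_fake_fits(params, runif(5, 0.5, 0.9))
  labels <- c(1, 1, 1, 2, 2)
  reps <- representative_kernels(labels, fits, fs = 25)
  expect_identical(length(reps), 2L)
  for (rk in reps)
    expect_equal(sum(rk$kernel$values) / 25, 1, tolerance = 1e-6)
  expect_equal(reps[["1"]]$params$tau, 0.3, tolerance = 1e-12)
  expect_identical(reps[["1"]]$size, 3L)

  # singleton cluster reproduces its own kernel shape
  one <- representative_kernels(c(1, 2, 2, 2, 2), fits, fs = 25)
  gp <- fits[[1]]$params
  h <- gamma_kernel(gp, 25)
  expect_equal(one[["1"]]$kernel$values[seq_along(h)] * (sum(h) / 25),
               h, tolerance = 1e-9)
})

test_that("two-regime synthetic fits cluster into significant groups", {
  # end-to-end clustering recovery: fits from two distinct kernel regimes
  set.seed(30)
  n_per <- 30
  mk_regime <- function(gp, seed0, r_base) {
    lapply(seq_len(n_per), function(i) {
      ep <- make_known_epoch(gp, a = 1 + 0.05 * rnorm(1),
                             seed = seed0 + i, noise_sd = 0.15)
      f <- grid_fit(ep)
      f
    })
  }
  fits <- c(mk_regime(gamma_params(0.3, 2, 2), 300),
            mk_regime(gamma_params(0.6, 4, 3), 400))
  fm <- build_features(fits)
  tree <- ward_linkage(fm)
  lab <- cut_tree(tree, 2)
  truth <- rep(1:2, each = n_per)
  # Rand index
  pairs <- combn(length(lab), 2)
  agree <- (lab[pairs[1, ]] == lab[pairs[2, ]]) ==
    (truth[pairs[1, ]] == truth[pairs[2, ]])
  expect_gt(mean(agree), 0.9)

  rr <- vapply(fits, function(f) f$r, numeric(1))
  rep2 <- significance_scan(tree, rr, n_range = 2)
  expect_identical(unname(rep2$cs[["2"]]), 2L)
})
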