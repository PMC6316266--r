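test_that("the four-factor Box-Behnken design has its textbook structure", {
  design <- box_behnken(default_pit_ranges())
  expect_equal(nrow(design$runs), 27L)
  centre <- c(2.6, 2.6, 5.1, 0.1005)
  n_centre <- sum(apply(design$runs, 1, function(r) all(r == centre)))
  expect_equal(n_centre, 3L)
  # every edge run has exactly two coded coordinates at +-1
  edge <- design$coded[rowSums(design$coded != 0) > 0, , drop = FALSE]
  expect_equal(nrow(edge), 24L)
  expect_true(all(rowSums(edge != 0) == 2))
  expect_true(all(edge %in% c(-1, 0, 1)))
  # all runs inside the factor box
  lv <- do.call(rbind, default_pit_ranges())
  for (f in 1:4) {
    expect_true(all(design$runs[, f] >= lv[f, 1] - 1e-12 &
                      design$runs[, f] <= lv[f, 3] + 1e-12))
  }
})

test_that("generated runs equal the published design as a multiset", {
  design <- box_behnken(default_pit_ranges())
  published <- published_design_chi2()[, c("gamma", "psi", "beta", "Ku")]
  expect_identical(row_multiset(design$runs), row_multiset(published))
})

test_that("design generation matches a brute-force enumeration oracle", {
  fac <- list(a = c(-2, 0.5, 1), b = c(0, 1, 7), c = c(1, 2, 3),
              d = c(-1, 0, 4))
  names(fac) <- c("gamma", "psi", "beta", "Ku")
  design <- box_behnken(fac, center_replicates = 2)
  expect_identical(row_multiset(design$runs),
                   row_multiset(oracle_bbd(fac, 2)))
})

test_that("unsupported or non-monotone designs are rejected", {
  expect_error(box_behnken(default_pit_ranges()[1:3]), "4-factor")
  bad <- default_pit_ranges()
  bad$gamma <- c(5, 2, 1)
  expect_error(box_behnken(bad), "low < center < high")
})

test_that("chi-square discrepancy matches hand evaluation", {
  obs <- c(10.80, 35.33, 62.22, 89.27)
  expect_equal(chi2_discrepancy(obs, obs), 0)
  expect_equal(chi2_discrepancy(obs, obs + c(1, 0, 0, 0)), 1 / 10.80)
  # scaling both series by c scales the statistic by c
  pred <- obs + c(2, -1, 0.5, 0)
  expect_equal(chi2_discrepancy(2 * obs, 2 * pred),
               2 * chi2_discrepancy(obs, pred))
  # additive over points
  expect_equal(chi2_discrepancy(obs, pred),
               chi2_discrepancy(obs[1:2], pred[1:2]) +
                 chi2_discrepancy(obs[3:4], pred[3:4]))
  expect_error(chi2_discrepancy(obs, pred[1:3]), "length")
  expect_error(chi2_discrepancy(c(0, 1), c(1, 1)), "positive")
})

test_that("a known quadratic is recovered exactly and predictions are exact", {
  design <- box_behnken(default_pit_ranges())
  set.seed(31)
  truth <- rnorm(15)
  Z <- design$coded
  X <- pitcorr:::quad_model_matrix(Z)
  y <- as.vector(X %*% truth)
  surf <- fit_quadratic(design$runs, y, transform = "none")
  expect_equal(unname(surf$coefficients), truth, tolerance = 1e-8)
  expect_equal(predict(surf, design$runs), y, tolerance = 1e-8)

  flat <- fit_quadratic(design$runs, rep(4.2, 27))
  expect_equal(unname(flat$coefficients[1:14]), rep(0, 14), tolerance = 1e-10)
  expect_equal(unname(flat$coefficients[15]), 4.2)
})

test_that("least squares agrees with an independent normal-equations solve", {
  tab <- published_design_chi2()
  surf <- fit_quadratic(tab[, c("gamma", "psi", "beta", "Ku")], tab$chi2)
  # independent route: centre/scale by hand, solve X'X b = X'y directly
  pts <- as.matrix(tab[, c("gamma", "psi", "beta", "Ku")])
  ctr <- (apply(pts, 2, max) + apply(pts, 2, min)) / 2
  half <- (apply(pts, 2, max) - apply(pts, 2, min)) / 2
  Z <- sweep(sweep(pts, 2, ctr), 2, half, "/")
  X <- pitcorr:::quad_model_matrix(Z)
  b <- solve(crossprod(X), crossprod(X, tab$chi2))
  expect_equal(unname(surf$coefficients), as.vector(b), tolerance = 1e-6)
  res <- tab$chi2 - as.vector(X %*% b)
  expect_equal(unname(surf$residuals), res, tolerance = 1e-6)
  r2 <- 1 - sum(res^2) / sum((tab$chi2 - mean(tab$chi2))^2)
  expect_equal(surf$r_squared, r2, tolerance = 1e-8)
})

test_that("degenerate fits fail loudly", {
  design <- box_behnken(default_pit_ranges())
  runs <- design$runs
  runs$Ku <- 0.1005  # collapse one factor
  expect_error(fit_quadratic(runs, rnorm(27)), "singular|span")
  expect_error(fit_quadratic(design$runs[1:10, ], rnorm(10)), "15")
  expect_error(fit_quadratic(design$runs, c(rnorm(26), Inf)), "finite")
  expect_error(fit_quadratic(design$runs, c(rnorm(26), -1), "log"),
               "positive")
})

test_that("surface minimisation finds analytic optima", {
  ranges <- default_pit_ranges()
  design <- box_behnken(ranges)
  centre <- c(gamma = 2.6, psi = 2.6, beta = 5.1, Ku = 0.1005)

  # convex bowl about an interior point
  target <- c(gamma = 3.1, psi = 1.6, beta = 6.1, Ku = 0.15)
  y <- apply(design$runs, 1, function(r) {
    sum(((r - target) / (centre - c(0.1, 0.1, 0.1, 0.001)))^2)
  })
  surf <- fit_quadratic(design$runs, y)
  opt <- surface_minimize(surf, ranges)
  expect_equal(as.numeric(opt), as.numeric(target), tolerance = 1e-4)

  # linear decrease in gamma pushes the optimum to the gamma upper bound
  y2 <- -design$runs$gamma
  surf2 <- fit_quadratic(design$runs, y2)
  opt2 <- surface_minimize(surf2, ranges)
  expect_equal(unname(opt2["gamma"]), 5.1, tolerance = 1e-6)
})

test_that("factors the response is flat in resolve to the design centre", {
  ranges <- default_pit_ranges()
  design <- box_behnken(ranges)
  # response depends on gamma and beta only; psi and Ku are inert
  y <- (design$runs$gamma - 2.9)^2 + 0.3 * (design$runs$beta - 4)^2
  surf <- fit_quadratic(design$runs, y)
  opt <- surface_minimize(surf, ranges)
  expect_equal(unname(opt["gamma"]), 2.9, tolerance = 1e-4)
  expect_equal(unname(opt["beta"]), 4, tolerance = 1e-4)
  expect_equal(unname(opt["psi"]), 2.6, tolerance = 1e-6)
  expect_equal(unname(opt["Ku"]), 0.1005, tolerance = 1e-6)
})

test_that("design evaluation is reproducible and uses common random numbers", {
  mesh <- tiny_mesh()
  ds <- mgznca_immersion()
  fac <- default_pit_ranges()
  design <- box_behnken(fac, center_replicates = 1)
  sub <- design
  keep <- c(2, 13, 25)  # a Ku-low, a centre-ish and a Ku-high run
  sub$runs <- design$runs[keep, ]
  sub$coded <- design$coded[keep, ]

  a <- evaluate_design(sub, mesh, ds, reps = 2, seed = 7)
  b <- evaluate_design(sub, mesh, ds, reps = 2, seed = 7)
  expect_identical(a$chi2, b$chi2)

  # two runs that differ only in Ku score identically under common
  # random numbers: the dimensionless-aligned curve is Ku-invariant
  kuruns <- design
  kuruns$runs <- data.frame(gamma = c(2.6, 2.6), psi = c(2.6, 2.6),
                            beta = c(5.1, 5.1), Ku = c(0.05, 0.2))
  out <- evaluate_design(kuruns, mesh, ds, reps = 2, seed = 3)
  expect_equal(out$chi2[1], out$chi2[2], tolerance = 1e-10)
})

test_that("identical mesh counts give identical convergence rows", {
  p <- center_params(seed = 21)
  tab <- mesh_convergence_study(p, c(300, 300), n_seeds = 2, tau = 0.5)
  expect_equal(tab$mean_mass_at_tau[1], tab$mean_mass_at_tau[2])
  expect_equal(tab$rel_err_vs_finest[2], 0)
})
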