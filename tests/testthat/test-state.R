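test_that("initial state exposes the boundary with a reproducible pit field", {
  mesh <- tiny_mesh()
  p <- center_params(seed = 5)
  st <- init_state(mesh, p)
  expect_true(all(st$dP == 0))
  expect_identical(st$status == 1L, mesh$boundary)
  expect_true(all(is.na(st$lambda[!mesh$boundary])))
  expect_true(all(st$lambda[mesh$boundary] >= 0))

  st2 <- init_state(mesh, p)
  expect_identical(st$lambda, st2$lambda)

  one <- build_coupon_mesh(1.5, 1, element_size = 1)
  s1 <- init_state(one, p)
  expect_equal(s1$status, 1L)
  expect_length(s1$lambda[!is.na(s1$lambda)], 1L)
})

test_that("uniform mode pins every exposed pitting parameter at one", {
  mesh <- tiny_mesh()
  st <- init_state(mesh, center_params(mode = "uniform"))
  expect_true(all(st$lambda[mesh$boundary] == 1))
})

test_that("damage increments follow the kinetic law", {
  mesh <- build_coupon_mesh(1.5, 1, element_size = 1)
  p <- pit_params(2.6, 2.6, 5.1, Ku = 0.1005, mode = "uniform")
  st <- init_state(mesh, p)
  # lambda = 1, delta_u = Le: ddP = Ku * dt
  st1 <- damage_increment(st, p, dt = 1)
  expect_equal(st1$dP, 0.1005)
  expect_equal(st1$time, 1)

  # lambda = 0 never corrodes
  st$lambda[1] <- 0
  st2 <- damage_increment(st, p, dt = 100)
  expect_equal(st2$dP, 0)

  expect_error(damage_increment(st, p, dt = 0), "positive")
  expect_error(damage_increment(st, p, dt = -1), "positive")
})

test_that("an element's first passage to full damage matches 1/(Ku*lambda)", {
  mesh <- build_coupon_mesh(1.5, 1, element_size = 1)
  p <- pit_params(2.6, 2.6, 5.1, Ku = 0.1)
  st <- init_state(mesh, p)
  st$lambda[1] <- 2
  t_removed <- NA
  for (i in 1:200) {
    rate <- 0.1 * 2
    dt <- p$dt_frac / rate
    st <- damage_increment(st, p, dt)
    st <- remove_and_inherit(st, mesh, p)
    if (st$status[1] == 2L) {
      t_removed <- st$time
      break
    }
  }
  expect_lt(abs(t_removed - 5), p$dt_frac / (0.1 * 2) + 1e-12)
})

test_that("pit inheritance scales the donor parameter by beta", {
  bar <- build_bar_mesh(2, 1, 1)
  p <- pit_params(2.6, 2.6, beta = 5.1, Ku = 0.1005)
  st <- init_state(bar, p)
  st$lambda[1] <- 0.5
  st$lambda_expo[1] <- 0.5
  st$lambda[2] <- NA
  st$lambda_expo[2] <- NA
  st$status[2] <- 0L
  st$dP[1] <- 1
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$status[1], 2L)
  expect_equal(st$lambda[2], 0.5 * 5.1)  # 2.55

  # beta = 1 is identity inheritance
  p1 <- pit_params(2.6, 2.6, beta = 1, Ku = 0.1)
  st <- init_state(bar, p1)
  st$lambda[1] <- 0.77; st$lambda_expo[1] <- 0.77
  st$lambda[2] <- NA; st$lambda_expo[2] <- NA; st$status[2] <- 0L
  st$dP[1] <- 1
  st <- remove_and_inherit(st, bar, p1)
  expect_equal(st$lambda[2], 0.77)
})

test_that("inheritance compounds geometrically along a removal chain", {
  bar <- build_bar_mesh(3, 1, 1)
  p <- pit_params(1, 1, beta = 2, Ku = 0.1)
  st <- init_state(bar, p)
  st$lambda <- c(1, NA, NA)
  st$lambda_expo <- c(1, NA, NA)
  st$status <- c(1L, 0L, 0L)
  st$dP <- c(1, 0, 0)
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[2], 2)
  expect_equal(st$status[2], 1L)
  st$dP[2] <- 1
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[3], 4)
})

test_that("competing donors resolve to the maximum inherited value", {
  bar <- build_bar_mesh(3, 1, 1)
  p <- pit_params(1, 1, beta = 2, Ku = 0.1)
  st <- init_state(bar, p)
  st$lambda <- c(1, NA, 3)
  st$lambda_expo <- c(1, NA, 3)
  st$status <- c(1L, 0L, 1L)
  st$dP <- c(1, 0, 1)
  st <- remove_and_inherit(st, bar, p)
  # middle element hears beta*1 = 2 and beta*3 = 6; max rule keeps 6
  expect_equal(st$lambda[2], 6)
})

test_that("inherited values respect the lambda cap", {
  bar <- build_bar_mesh(2, 1, 1)
  p <- pit_params(1, 1, beta = 10, Ku = 0.1, lambda_cap = 50)
  st <- init_state(bar, p)
  st$lambda <- c(20, NA)
  st$lambda_expo <- c(20, NA)
  st$status <- c(1L, 0L)
  st$dP <- c(1, 0)
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[2], 50)
})

test_that("the initial-donor variant does not compound", {
  bar <- build_bar_mesh(3, 1, 1)
  p <- pit_params(1, 1, beta = 2, Ku = 0.1, inherit_donor = "initial")
  st <- init_state(bar, p)
  st$lambda <- c(1, NA, NA)
  st$lambda_expo <- c(1, NA, NA)
  st$status <- c(1L, 0L, 0L)
  st$dP <- c(1, 0, 0)
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[2], 2)        # beta * donor initial
  # raise the middle element's current lambda after exposure; the
  # initial-donor rule must still pass on its at-exposure value
  st$lambda[2] <- 10
  st$dP[2] <- 1
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[3], 4)        # beta * 2, not beta * 10
})

test_that("the newly-exposed variant leaves exposed neighbours alone", {
  bar <- build_bar_mesh(3, 1, 1)
  p <- pit_params(1, 1, beta = 2, Ku = 0.1, inherit_recipients = "newly")
  st <- init_state(bar, p)
  st$lambda <- c(5, 0.3, NA)
  st$lambda_expo <- c(5, 0.3, NA)
  st$status <- c(1L, 1L, 0L)
  st$dP <- c(1, 0, 0)
  st <- remove_and_inherit(st, bar, p)
  expect_equal(st$lambda[2], 0.3)  # already exposed: untouched
})

test_that("mass loss accounting matches direct counts", {
  mesh <- build_bar_mesh(10, 1, 1)
  p <- center_params()
  st <- init_state(mesh, p)
  expect_equal(compute_mass_loss(st, mesh, "partial"), 0)
  expect_equal(compute_mass_loss(st, mesh, "removed"), 0)

  st$status[1:3] <- 2L
  st$dP[1:3] <- 1
  expect_equal(compute_mass_loss(st, mesh, "partial"), 30)
  expect_equal(compute_mass_loss(st, mesh, "removed"), 30)

  st$dP[4] <- 0.5
  expect_equal(compute_mass_loss(st, mesh, "partial"), 35)
  expect_equal(compute_mass_loss(st, mesh, "removed"), 30)

  st$status[] <- 2L
  st$dP[] <- 1
  expect_equal(compute_mass_loss(st, mesh, "partial"), 100)
  expect_equal(compute_mass_loss(st, mesh, "removed"), 100)
})
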