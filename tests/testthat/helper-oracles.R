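# Independent brute-force oracles used across the suite.  These stay
# deliberately dumb (triple loops, explicit enumeration) so they cannot
# share a bug with the vectorised implementation.

# count of cubic cells whose centres fall inside the disc, using the
# axis-registered grid convention (one column of centres on the axis,
# first layer centre at Le/2)
oracle_disc_count <- function(diameter, thickness, Le) {
  r <- diameter / 2
  m <- ceiling(r / Le)
  count <- 0L
  for (i in -m:m) {
    for (j in -m:m) {
      if ((i * Le)^2 + (j * Le)^2 > r^2) next
      k <- 1L
      while ((k - 0.5) * Le <= thickness) {
        count <- count + 1L
        k <- k + 1L
      }
    }
  }
  count
}

# per-face scan for the exposed set: not removed, and at least one of
# the six faces is missing a living-or-removed... i.e. free surface or
# shared with a removed element
oracle_exposed <- function(mesh, state) {
  removed <- state$status == 2L
  lin <- array(0L, dim = mesh$dims)
  lin[mesh$ijk] <- seq_len(mesh$n_elements)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  out <- integer(0)
  for (e in seq_len(mesh$n_elements)) {
    if (removed[e]) next
    for (s in 1:6) {
      nb <- mesh$ijk[e, ] + offs[s, ]
      open <- any(nb < 1L) || any(nb > mesh$dims)
      if (!open) {
        id <- lin[nb[1], nb[2], nb[3]]
        open <- id == 0L || removed[id]
      }
      if (open) {
        out <- c(out, e)
        break
      }
    }
  }
  out
}

# explicit Box-Behnken enumeration: all factor pairs x {low,high}^2,
# remaining factors at centre, plus centre replicates
oracle_bbd <- function(factors, center_replicates = 3) {
  k <- length(factors)
  centers <- vapply(factors, `[`, numeric(1), 2)
  rows <- list()
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      for (a in c(1, 3)) {
        for (b in c(1, 3)) {
          run <- centers
          run[i] <- factors[[i]][a]
          run[j] <- factors[[j]][b]
          rows[[length(rows) + 1L]] <- run
        }
      }
    }
  }
  for (q in seq_len(center_replicates)) {
    rows[[length(rows) + 1L]] <- centers
  }
  do.call(rbind, rows)
}

# canonical sorted-row representation for multiset comparison
row_multiset <- function(m) {
  m <- as.matrix(m)
  rows <- apply(m, 1, function(r) paste(format(r, digits = 12), collapse = "|"))
  sort(rows)
}

published_design_chi2 <- function() {
  read.csv(system.file("extdata", "mgznca_design_chi2.csv",
                       package = "pitcorr"))
}

# small disc mesh + params used by several slow-ish tests
tiny_mesh <- function() build_coupon_mesh(6, 2, element_size = 1)

center_params <- function(...) {
  pit_params(gamma = 2.6, psi = 2.6, beta = 5.1, Ku = 0.1005, ...)
}
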