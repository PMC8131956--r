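test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  x <- matrix(rnorm(15, sd = 4), 5, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  # 90-degree rotation about z plus a translation is removed by the fit
  rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- sweep(x %*% rz, 2, c(5, -2, 11), "+")
  fit <- kabsch_superpose(moved, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$fitted, x, tolerance = 1e-8)
})

test_that("Kabsch rmsd matches the brute-force rotation-grid oracle", {
  set.seed(42)
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(1, 1, 2.5))
  y <- x + matrix(rnorm(12, sd = 0.4), 4, 3)
  expect_lt(abs(kabsch_superpose(y, x)$rmsd - grid_search_rmsd(y, x)), 0.01)
})

test_that("fitted rmsd never exceeds the unfitted rmsd", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(30, sd = 3), 10, 3)
    y <- x + matrix(rnorm(30, sd = seed / 5), 10, 3)
    expect_lte(kabsch_superpose(y, x)$rmsd,
               stressmap:::raw_rmsd(y, x) + 1e-12)
  }
})

test_that("superposition rejects degenerate input", {
  x <- matrix(rnorm(9), 3, 3)
  expect_error(kabsch_superpose(x, x[1:2, ]), "differ in size")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("domain RMSD series is zero for static or rigidly moving regions", {
  fab <- toy_fab_cached()
  st <- fab$structure
  xyz <- get_coords(st)
  static <- mk_traj(st, list(xyz, xyz, xyz))
  rs <- domain_rmsd_series(static, st, "CL", fab$map)
  expect_equal(rs$value, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(rs$time_ns, c(0, 0.1, 0.2))
  # rigid rotation of the whole frame each time step: fit removes it
  set.seed(5)
  rigid <- mk_traj(st, list(xyz, random_rigid(xyz), random_rigid(xyz)))
  expect_equal(domain_rmsd_series(rigid, st, "VL", fab$map)$value,
               c(0, 0, 0), tolerance = 1e-7)
})

test_that("domain RMSD of a displaced loop matches an independent optimiser", {
  fab <- toy_fab_cached()
  st <- fab$structure
  xyz <- get_coords(st)
  loop <- fab$groups$loop_idx[["CL"]]
  moved <- xyz
  moved[loop, 3] <- moved[loop, 3] - 4
  tr <- mk_traj(st, list(moved))
  got <- domain_rmsd_series(tr, st, "CL", fab$map)$value
  idx <- select_region(st, fab$map, "CL")
  # oracle: direct numerical minimisation over Euler angles + translation
  pm <- moved[idx, ]; pr <- xyz[idx, ]
  obj <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1]); cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    r <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)) %*%
      rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb)) %*%
      rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    sqrt(mean(rowSums((sweep(sweep(pm, 2, colMeans(pm)) %*% r, 2,
                             p[4:6], "+") - sweep(pr, 2, colMeans(pr)))^2)))
  }
  oracle <- optim(rep(0, 6), obj, method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 2000))$value
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("windowed RMSF partitions time and recovers closed-form cases", {
  topo <- mk_structure(rep("CA", 3), rep("C", 3), 1:3,
                       rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  map <- domain_map(list(ALL = c(1, 3)))
  base <- get_coords(topo)
  # 100 ns at 0.1 ns -> 10 windows of 10 ns
  frames <- rep(list(base), 1001)
  prof <- windowed_rmsf(mk_traj(topo, frames), "ALL", map, window_ns = 10)
  expect_equal(sort(unique(prof$window)), 1:10)
  expect_true(all(prof$rmsf == 0))
  # atoms alternating +/- delta about their means have RMSF exactly delta;
  # the displacement pattern is orthogonal to every rigid-body mode (zero
  # net translation and torque) so the per-frame fit stays the identity
  sq <- mk_structure(rep("CA", 4), rep("C", 4), 1:4,
                     rbind(c(5, 5, 0), c(5, -5, 0), c(-5, 5, 0), c(-5, -5, 0)))
  map4 <- domain_map(list(ALL = c(1, 4)))
  delta <- 0.4
  pattern <- c(1, -1, -1, 1) * delta
  frames <- lapply(1:20, function(f) {
    x <- get_coords(sq)
    x[, 3] <- x[, 3] + ifelse(f %% 2 == 0, 1, -1) * pattern
    x
  })
  prof <- windowed_rmsf(mk_traj(sq, frames), "ALL", map4, window_ns = 2)
  expect_equal(unique(round(prof$rmsf, 9)), delta, tolerance = 1e-7)
  expect_error(windowed_rmsf(mk_traj(sq, frames), "ALL", map4,
                             window_ns = 0.1), "two frames")
})

test_that("RMSF is invariant to adding rigid motion to a window's frames", {
  fab <- toy_fab_cached()
  st <- fab$structure
  set.seed(11)
  xyz <- get_coords(st)
  frames <- lapply(1:6, function(f) xyz + matrix(rnorm(length(xyz), sd = 0.3),
                                                 ncol = 3))
  plain <- windowed_rmsf(mk_traj(st, frames), "VL", fab$map, window_ns = 1)
  set.seed(12)
  rigidised <- lapply(frames, random_rigid)
  moved <- windowed_rmsf(mk_traj(st, rigidised), "VL", fab$map, window_ns = 1)
  expect_equal(plain$rmsf, moved$rmsf, tolerance = 1e-6)
})

test_that("radius of gyration follows its definition", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two, c(1, 1)), 2.0)
  set.seed(2)
  xyz <- matrix(rnorm(15, sd = 3), 5, 3)
  m <- c(12, 14, 16, 32, 1)
  com <- colSums(xyz * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(xyz, m), direct)
  # translation and rotation invariance
  set.seed(3)
  expect_equal(radius_of_gyration(random_rigid(xyz), m), direct,
               tolerance = 1e-9)
  expect_error(radius_of_gyration(two, c(0, 0)), "positive")
})

test_that("replicate aggregation computes mean and SEM with n-1 sd", {
  s <- function(v) data.frame(region = "CL", time_ns = 0:1, value = v)
  agg <- aggregate_replicates(lapply(1:6, function(i) s(c(1, 2))))
  expect_equal(agg$sem, c(0, 0))
  agg2 <- aggregate_replicates(list(s(c(1, 1)), s(c(3, 3))))
  expect_equal(agg2$mean, c(2, 2))
  expect_equal(agg2$sem, c(1, 1))   # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_warning(agg1 <- aggregate_replicates(list(s(c(5, 6)))), "single")
  expect_equal(agg1$mean, c(5, 6))
  expect_equal(agg1$sem, c(0, 0))
  bad <- data.frame(region = "CL", time_ns = c(0, 2), value = c(1, 1))
  expect_error(aggregate_replicates(list(s(c(1, 1)), bad)), "time axes")
})
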