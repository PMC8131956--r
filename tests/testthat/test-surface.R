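# analytic SASA of two overlapping spheres (expanded radii r1, r2 at
# centre distance d): exposed area of sphere 1 = 4 pi r1^2 minus the cap
# buried inside sphere 2
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)   # distance from centre 1 to cap plane
  4 * pi * r1^2 - 2 * pi * r1 * (r1 - x)
}

test_that("an isolated atom reproduces the analytic sphere area", {
  s <- mk_structure("CA", "C", 1L, matrix(0, 1, 3))
  got <- residue_sasa(s)
  want <- 4 * pi * (1.70 + 1.4)^2      # 120.76 A^2
  expect_equal(unname(got), want, tolerance = 0.02)
  expect_equal(round(want, 2), 120.76)
})

test_that("a fully caged atom has zero accessible area", {
  dirs <- stressmap:::.sphere_dots_r(30)
  xyz <- rbind(c(0, 0, 0), 2.0 * dirs)
  s <- mk_structure(rep("CA", 31), rep("C", 31), 1:31, xyz)
  expect_equal(unname(residue_sasa(s)[1]), 0)
})

test_that("two-atom SASA matches the exact two-sphere closed form", {
  for (d in c(2.5, 4.0, 5.5)) {
    s <- mk_structure(c("CA", "N"), c("C", "N"), 1:2,
                      rbind(c(0, 0, 0), c(d, 0, 0)))
    got <- residue_sasa(s)
    r1 <- 1.70 + 1.4; r2 <- 1.55 + 1.4
    expect_equal(unname(got[1]), two_sphere_sasa(r1, r2, d), tolerance = 0.02)
    expect_equal(unname(got[2]), two_sphere_sasa(r2, r1, d), tolerance = 0.02)
  }
})

test_that("SASA agrees with an independent reference implementation", {
  # expected per-atom areas computed once with an independent Shrake-Rupley
  # implementation (mdtraj 1.11, probe 1.4 A, 960 sphere points, radii
  # C 1.70 / N 1.55 / O 1.52 / S 1.80 A) on this frozen 8-atom toy
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.4, 1.4, 0.3),
               c(1.9, -1.2, 1.0), c(3.3, -2.0, 1.5), c(4.5, 0.6, -0.8),
               c(5.8, 1.9, 0.4))
  el <- c("N", "C", "C", "O", "C", "S", "N", "O")
  s <- mk_structure(paste0("X", 1:8), el, 1:8, xyz)
  ref <- c(52.8568, 9.4346, 31.8260, 10.6030, 23.7752, 68.3611,
           33.4911, 60.8276)
  got <- unname(residue_sasa(s))
  expect_equal(got, ref, tolerance = 0.02)
})

test_that("dot-count refinement converges towards the analytic value", {
  d <- 3.2
  r1 <- 1.70 + 1.4; r2 <- 1.70 + 1.4
  want <- two_sphere_sasa(r1, r2, d)
  errs <- vapply(c(240L, 960L, 3840L), function(k) {
    s <- mk_structure(c("CA", "CB"), c("C", "C"), 1:2,
                      rbind(c(0, 0, 0), c(d, 0, 0)))
    abs(unname(residue_sasa(s, params = sasa_params(dots = k))[1]) - want)
  }, 1.0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / want, 0.01)
})

test_that("OSP is zero when exposed and matches a brute-force ray oracle", {
  iso <- mk_structure("CA", "C", 1L, matrix(0, 1, 3))
  expect_equal(unname(occluded_surface_packing(iso)), 0)
  # two atoms in exact vdW contact; oracle re-simulates the dot rays in R
  d <- 3.4
  s <- mk_structure(c("CA", "CB"), c("C", "C"), 1:2,
                    rbind(c(0, 0, 0), c(d, 0, 0)))
  par <- osp_params(dots = 240L)
  got <- occluded_surface_packing(s, params = par)
  dots <- stressmap:::.sphere_dots_r(par$dots)
  oracle_atom <- function(centre, r, nb_centre, nb_r) {
    w <- 0
    for (k in seq_len(nrow(dots))) {
      u <- dots[k, ]
      p <- centre + r * u
      cv <- nb_centre - p
      if (sum(cv^2) <= nb_r^2) { w <- w + 1; next }
      b <- sum(cv * u)
      disc <- b^2 - (sum(cv^2) - nb_r^2)
      if (b > 0 && disc > 0) {
        t <- b - sqrt(disc)
        if (t < par$rl_max) w <- w + (1 - t / par$rl_max)
      }
    }
    w / nrow(dots)
  }
  want1 <- oracle_atom(c(0, 0, 0), 1.7, c(d, 0, 0), 1.7)
  expect_equal(unname(got[1]), want1, tolerance = 1e-10)
})

test_that("adding a neighbour never decreases OSP; rigid motion changes nothing", {
  set.seed(17)
  xyz <- matrix(rnorm(12, sd = 2.5), 4, 3)
  s4 <- mk_structure(rep("CA", 4), rep("C", 4), 1:4, xyz)
  s5 <- mk_structure(rep("CA", 5), rep("C", 5), 1:5,
                     rbind(xyz, colMeans(xyz) + c(3, 0, 0)))
  par <- osp_params(dots = 240L)
  o4 <- occluded_surface_packing(s4, params = par)
  o5 <- occluded_surface_packing(s5, params = par)
  expect_true(all(o5[1:4] >= o4 - 1e-12))
  moved <- random_rigid(xyz)
  # rigid-motion invariance up to the orientation of the fixed dot lattice
  # (the residual shrinks as the dot count grows)
  par_fine <- osp_params(dots = 3840L)
  expect_equal(occluded_surface_packing(s4, moved, params = par_fine),
               occluded_surface_packing(s4, params = par_fine),
               tolerance = 0.02)
  sp_fine <- sasa_params(dots = 3840L)
  expect_equal(residue_sasa(s4, moved, params = sp_fine),
               residue_sasa(s4, params = sp_fine), tolerance = 0.01)
})

test_that("OSP and SASA are anticorrelated on the mini-Fab", {
  fab <- toy_fab_cached()
  sasa <- residue_sasa(fab$structure)
  osp <- occluded_surface_packing(fab$structure, params = osp_params(dots = 240L))
  rho <- cor(osp, sasa[names(osp)], method = "spearman")
  expect_lt(rho, 0)
})

test_that("APR exposure change recovers simple designed schedules", {
  # two separated clusters; the "APR" cluster loses its occluders halfway
  core <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(-2.8, 0, 0),
                c(0, 2.8, 0), c(0, -2.8, 0))
  far <- c(40, 0, 0)
  xyz <- rbind(core, sweep(matrix(0, 1, 3), 2, far, "+"))
  s <- mk_structure(c(rep("CA", 5), "CA"), rep("C", 6),
                    c(1L, 2L, 3L, 4L, 5L, 9L), xyz)
  aprs <- apr_set(list(APR1 = c(1, 1)), max_residue = 9)
  opened <- xyz
  opened[2:5, ] <- sweep(opened[2:5, ], 2, c(0, 0, 50), "+")
  ref <- mk_traj(s, rep(list(xyz), 4))
  stress <- mk_traj(s, rep(list(opened), 4))
  same <- apr_sasa_change(list(ref), list(ref), aprs)
  expect_equal(same$change, 0)
  change <- apr_sasa_change(list(stress), list(ref), aprs)
  s_open <- residue_sasa(s, opened)[["1"]]
  s_closed <- residue_sasa(s, xyz)[["1"]]
  expect_equal(change$change, 100 * (s_open - s_closed) / s_closed)
  expect_gt(change$change, 50)
  bad <- apr_set(list(APR1 = c(1, 99)), max_residue = 99)
  expect_error(apr_sasa_change(list(stress), list(ref), bad), "beyond")
})
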