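test_that("ideal backbones have peptide-bond geometry", {
  s <- build_backbone(10)
  ca <- get_coords(s)[s$atoms$name == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.80) < 0.05))
  s2 <- build_backbone(2)
  expect_equal(nrow(s2$atoms), 8L)
  # C-N peptide bond between consecutive residues
  xyz <- get_coords(s2)
  c1 <- xyz[s2$atoms$resno == 1 & s2$atoms$name == "C", ]
  n2 <- xyz[s2$atoms$resno == 2 & s2$atoms$name == "N", ]
  expect_equal(sqrt(sum((c1 - n2)^2)), 1.329, tolerance = 1e-6)
  expect_error(build_backbone(10, phi = NaN), "non-finite")
})

test_that("the mini-Fab carries its designed ground truth", {
  fab <- toy_fab_cached()
  st <- fab$structure
  # frame 0 salt bridges are exactly the designed set
  det <- detect_salt_bridges(get_coords(st), st)
  want <- fab$bridges[order(fab$bridges$acid_resno),
                      c("acid_resno", "base_resno")]
  got <- det[order(det$acid_resno), ]
  expect_equal(got$acid_resno, want$acid_resno)
  expect_equal(got$base_resno, want$base_resno)
  # designed APR loops are substantially buried in frame 0
  rs <- residue_sasa(st)
  rn <- as.integer(names(rs))
  apr_res <- unlist(lapply(fab$aprs, function(iv) iv[1]:iv[2]))
  expect_lt(mean(rs[rn %in% apr_res]), 0.5 * mean(rs))
  # both interfaces have designed native contacts
  for (rg in c("VL-VH", "CL-CH1"))
    expect_gt(nrow(build_reference_contacts(st, rg, fab$map)$pairs), 10)
  # a spec without designed bridges yields a bridge-free structure
  sp <- toy_fab_spec()
  sp$bridges <- sp$bridges[0, ]
  sp$schedules <- lapply(sp$schedules, function(x) x[0])
  fab0 <- build_toy_fab(sp)
  expect_equal(nrow(detect_salt_bridges(get_coords(fab0$structure),
                                        fab0$structure)), 0L)
})

test_that("zero-jitter reference trajectories are static", {
  fab <- toy_fab_cached()
  prof <- stress_profile("reference", sigma = 0, seed = 1,
                         occupancy = rep(1, nrow(fab$bridges)))
  trajs <- simulate_stress_trajectory(fab, prof, n_frames = 5, n_replicates = 1)
  tr <- trajs[[1]]
  for (f in 2:5) expect_equal(tr$coords[, , f], tr$coords[, , 1])
  rs <- domain_rmsd_series(tr, fab$structure, "CL", fab$map)
  expect_equal(rs$value, rep(0, 5), tolerance = 1e-9)
})

test_that("trajectories are reproducible from the master seed", {
  fab <- toy_fab_cached()
  a <- simulate_stress_trajectory(fab, stress_profile("low_ph_like", seed = 9),
                                  n_frames = 7, n_replicates = 2)
  b <- simulate_stress_trajectory(fab, stress_profile("low_ph_like", seed = 9),
                                  n_frames = 7, n_replicates = 2)
  expect_identical(a[[1]]$coords, b[[1]]$coords)
  expect_identical(a[[2]]$coords, b[[2]]$coords)
  expect_false(identical(a[[1]]$coords, a[[2]]$coords))
  c_ <- simulate_stress_trajectory(fab, stress_profile("low_ph_like", seed = 10),
                                   n_frames = 7, n_replicates = 1)
  expect_false(identical(a[[1]]$coords, c_[[1]]$coords))
})

test_that("scheduled bridge occupancies are recovered exactly", {
  fab <- toy_fab_cached()
  n_f <- 50L
  p <- c(0.4, rep(0, nrow(fab$bridges) - 1))
  prof <- stress_profile("reference", seed = 2, occupancy = p)
  tr <- simulate_stress_trajectory(fab, prof, n_frames = n_f, n_replicates = 1)[[1]]
  occ <- bridge_occurrence(tr)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$occurrence, 100 * round(0.4 * n_f) / n_f)  # exactly 40%
  # the emitted ground truth states the same occurrence
  gt <- attr(simulate_stress_trajectory(fab, prof, n_frames = n_f,
                                        n_replicates = 1), "ground_truth")
  expect_equal(gt$bridge_schedule$occurrence_pct[1], 40)
})

test_that("low-pH-like stress singles out the target domain", {
  fab <- toy_fab_cached()
  st <- fab$structure
  csets <- lapply(setNames(names(fab$map$domains), names(fab$map$domains)),
                  function(rg) build_reference_contacts(st, rg, fab$map))
  hits_rmsd <- hits_q <- 0L
  seeds <- 1:3
  for (seed in seeds) {
    ref <- simulate_stress_trajectory(fab, stress_profile("reference", seed = seed),
                                      n_frames = 41, n_replicates = 2)
    low <- simulate_stress_trajectory(fab, stress_profile("low_ph_like", seed = seed),
                                      n_frames = 41, n_replicates = 2)
    d_rmsd <- vapply(names(fab$map$domains), function(rg) {
      mean(vapply(low, function(tr) tail(domain_rmsd_series(tr, st, rg, fab$map)$value, 1), 1)) -
        mean(vapply(ref, function(tr) tail(domain_rmsd_series(tr, st, rg, fab$map)$value, 1), 1))
    }, 1.0)
    d_q <- vapply(names(fab$map$domains), function(rg) {
      mean(vapply(low, function(tr) tail(contact_series(tr, csets[[rg]])$q, 1), 1)) -
        mean(vapply(ref, function(tr) tail(contact_series(tr, csets[[rg]])$q, 1), 1))
    }, 1.0)
    if (names(which.max(d_rmsd)) == "CL") hits_rmsd <- hits_rmsd + 1L
    if (names(which.min(d_q)) == "CL") hits_q <- hits_q + 1L
  }
  expect_equal(hits_rmsd, length(seeds))
  expect_equal(hits_q, length(seeds))
})

test_that("high-temperature-like stress opens the interfaces first", {
  fab <- toy_fab_cached()
  st <- fab$structure
  regions <- region_names(fab$map)
  csets <- lapply(setNames(regions, regions),
                  function(rg) build_reference_contacts(st, rg, fab$map))
  ref <- simulate_stress_trajectory(fab, stress_profile("reference", seed = 6),
                                    n_frames = 41, n_replicates = 2)
  hot <- simulate_stress_trajectory(fab, stress_profile("high_temp_like", seed = 6),
                                    n_frames = 41, n_replicates = 2)
  frac_loss <- vapply(regions, function(rg) {
    qr <- mean(vapply(ref, function(tr) tail(contact_series(tr, csets[[rg]])$q, 1), 1))
    qh <- mean(vapply(hot, function(tr) tail(contact_series(tr, csets[[rg]])$q, 1), 1))
    (qr - qh) / qr
  }, 1.0)
  ifaces <- c("VL-VH", "CL-CH1")
  doms <- setdiff(regions, ifaces)
  expect_gt(min(frac_loss[ifaces]), max(frac_loss[doms]))
  # every domain still fluctuates more than at reference
  d_rmsd <- vapply(doms, function(rg) {
    mean(vapply(hot, function(tr) tail(domain_rmsd_series(tr, st, rg, fab$map)$value, 1), 1)) -
      mean(vapply(ref, function(tr) tail(domain_rmsd_series(tr, st, rg, fab$map)$value, 1), 1))
  }, 1.0)
  expect_true(all(d_rmsd > 0))
})

test_that("written fixtures round-trip through PDB files", {
  dir <- file.path(tempdir(), "fixture-roundtrip")
  fx <- write_toy_fixture(dir, n_frames = 5, n_replicates = 1, seed = 3,
                          modes = "reference")
  expect_true(file.exists(fx$reference_pdb))
  tr <- read_trajectory(fx$trajectories$reference[1])
  expect_equal(n_frames(tr), 5L)
  expect_equal(nrow(tr$topology$atoms), nrow(fx$fab$structure$atoms))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$reference$mode, "reference")
  unlink(dir, recursive = TRUE)
})
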