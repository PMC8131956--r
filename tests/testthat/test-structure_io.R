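test_that("single ATOM records are parsed field for field", {
  txt <- pdb_atom_line(1, "CA", "ALA", "A", 7, 12.345, -3.210, 0.007, "C")
  s <- read_structure(txt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$resno, 7L)
  expect_equal(s$atoms$resname, "ALA")
  expect_equal(c(s$atoms$x, s$atoms$y, s$atoms$z), c(12.345, -3.210, 0.007))
})

test_that("chains are renumbered onto one continuous residue axis", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "L", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "ALA", "L", 2, 4, 0, 0),
             pdb_atom_line(3, "CA", "ALA", "L", 214, 8, 0, 0),
             "TER",
             pdb_atom_line(4, "CA", "ALA", "H", 1, 12, 0, 0),
             pdb_atom_line(5, "CA", "ALA", "H", 228, 16, 0, 0))
  s <- read_structure(paste(lines, collapse = "\n"))
  # heavy chain residue 1 continues after the light chain's last residue
  expect_equal(s$atoms$resno, c(1L, 2L, 214L, 215L, 442L))
  # renumbering can be disabled
  s2 <- read_structure(paste(lines, collapse = "\n"), renumber = FALSE)
  expect_equal(s2$atoms$resno, c(1L, 2L, 214L, 1L, 228L))
})

test_that("malformed and empty inputs give informative errors", {
  bad <- pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "   abc  "
  expect_error(read_structure(paste(c("REMARK", bad), collapse = "\n")),
               "line 2")
  expect_error(read_structure("REMARK nothing here\nEND"), "empty input")
  ins <- pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, icode = "A")
  expect_error(read_structure(ins), "nsertion")
})

test_that("hydrogens are dropped unless kept; first altloc wins", {
  lines <- c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
             pdb_atom_line(2, "H", "ALA", "A", 1, 0.5, 0, 0, "H"),
             pdb_atom_line(3, "CA", "ALA", "A", 1, 1.5, 0, 0, "C", altloc = "A"),
             pdb_atom_line(4, "CA", "ALA", "A", 1, 9.9, 0, 0, "C", altloc = "B"))
  s <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1.5)  # first altloc kept
  s_h <- read_structure(paste(lines, collapse = "\n"), keep_h = TRUE)
  expect_true("H" %in% s_h$atoms$element)
})

test_that("multi-model files become ordered frames and shapes are checked", {
  model <- function(k, n_atoms) {
    c(sprintf("MODEL %8d", k),
      vapply(seq_len(n_atoms), function(i)
        pdb_atom_line(i, "CA", "GLY", "A", i, i * 4 + k, 0, 0), ""),
      "ENDMDL")
  }
  txt <- paste(c(model(1, 5), model(2, 5), model(3, 5), "END"), collapse = "\n")
  tr <- read_trajectory(txt)
  expect_equal(n_frames(tr), 3L)
  expect_equal(nrow(tr$topology$atoms), 5L)
  expect_equal(tr$coords[1, 1, ], c(5, 6, 7))  # frames in MODEL order
  bad <- paste(c(model(1, 5), model(2, 4), "END"), collapse = "\n")
  expect_error(read_trajectory(bad), "model 1 has 5 atoms, model 2 has 4")
})

test_that("default frame cadence spans 100 ns over 1001 frames", {
  topo <- mk_structure("CA", "C", 1L, matrix(0, 1, 3))
  tr <- stressmap:::new_fab_trajectory(topo, array(0, c(1, 3, 1001)), 0.1)
  expect_equal(max(frame_times(tr)), 100.0)
  expect_equal(length(frame_times(tr)), 1001L)
})

test_that("coordinates survive a write/read round trip to 3 decimals", {
  fab <- toy_fab_cached()
  f <- tempfile(fileext = ".pdb")
  write_structure(fab$structure, f)
  rt <- read_structure(f)
  expect_equal(nrow(rt$atoms), nrow(fab$structure$atoms))
  # PDB coordinate columns carry 3 decimals
  expect_lt(max(abs(get_coords(rt) - get_coords(fab$structure))), 5.001e-4)
})

test_that("score projection writes clamped B-factors recoverable to 2 dp", {
  s <- mk_structure(c("N", "CA", "C", "CA"), c("N", "C", "C", "C"),
                    c(10L, 10L, 10L, 11L), matrix(rnorm(12), 4, 3))
  txt <- write_score_projection(s, c("10" = 0.25))
  b <- as.numeric(substr(grep("^ATOM", txt, value = TRUE), 61, 66))
  expect_equal(b, c(0.25, 0.25, 0.25, 0))   # all atoms of residue 10, rest 0
  expect_warning(txt2 <- write_score_projection(s, c("10" = -12)), "clamp")
  b2 <- as.numeric(substr(grep("^ATOM", txt2, value = TRUE), 61, 66))
  expect_equal(b2[1], -9.99)
  expect_error(write_score_projection(s, c("10" = NaN)), "residue 10")
  # values in the typical display range survive a round trip unchanged
  scores <- setNames(seq(-1.5, 1.5, length.out = 2), c("10", "11"))
  f <- tempfile(fileext = ".pdb")
  write_score_projection(s, scores, f)
  rt <- suppressWarnings(bio3d::read.pdb(f, verbose = FALSE))
  expect_equal(unique(round(rt$atom$b[rt$atom$resno == 10], 2)), -1.5)
  expect_equal(unique(round(rt$atom$b[rt$atom$resno == 11], 2)), 1.5)
})

test_that("region selection follows the Fab domain map", {
  resno <- 1:442
  s <- mk_structure(rep("CA", 442), rep("C", 442), resno,
                    cbind(resno, 0, 0))
  map <- fab_domain_map()
  expect_equal(sort(unique(s$atoms$resno[select_region(s, map, "CL")])),
               109:214)
  iface <- select_region(s, map, "CL-CH1")
  expect_equal(sort(unique(s$atoms$resno[iface[[1]]])), 109:214)
  expect_equal(sort(unique(s$atoms$resno[iface[[2]]])), 335:429)
  # the four domains are disjoint and exclude the hinge 430-442
  all_idx <- unlist(lapply(names(map$domains), select_region,
                           structure = s, map = map))
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_equal(setdiff(resno, s$atoms$resno[all_idx]), 430:442)
  expect_error(select_region(s, map, "CL2"), "valid regions")
  trunc <- mk_structure("CA", "C", 1L, matrix(0, 1, 3))
  expect_warning(idx <- select_region(trunc, map, "VH"), "no residues")
  expect_length(idx, 0L)
})
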