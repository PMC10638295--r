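# PDB parsing, site selection, and minimum-distance classification.

test_that("parse_structure loads ATOM and HETATM records", {
  atoms <- do.call(rbind, c(
    lapply(1:10, function(i) pdb_atom(resno = i, x = 4 * i)),
    list(pdb_atom("HETATM", name = "C1", resn = "NAP", resno = 99,
                  x = 20, y = 8),
         pdb_atom("HETATM", name = "O", resn = "HOH", resno = 100,
                  x = 1, y = 1))))
  m <- parse_structure(write_fixture_pdb(atoms))
  expect_equal(nrow(m$atoms), 12)
  expect_equal(sum(m$atoms$kind == "hetero"), 2)
  # waters carried as hetero atoms; filtering happens at site selection
  expect_true("HOH" %in% m$atoms$resid)
})

test_that("multi-model files keep model 1; altlocs resolve by occupancy", {
  a1 <- pdb_atom(resno = 1, x = 0)
  a2 <- pdb_atom(resno = 1, x = 50)
  p <- tempfile(fileext = ".pdb")
  m1 <- write_fixture_pdb(a1, tempfile())
  m2 <- write_fixture_pdb(a2, tempfile())
  writeLines(c("MODEL        1", readLines(m1)[1], "ENDMDL",
               "MODEL        2", readLines(m2)[1], "ENDMDL", "END"), p)
  m <- parse_structure(p)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 0)

  alt <- rbind(pdb_atom(resno = 1, x = 0, occ = 0.3, alt = "A"),
               pdb_atom(resno = 1, x = 9, occ = 0.7, alt = "B"))
  m <- parse_structure(write_fixture_pdb(alt))
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 9)
})

test_that("empty or atom-free files error", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST", "END"), p)
  expect_error(parse_structure(p))
  expect_error(parse_structure(tempfile()), "not found")
})

ligand_fixture <- function() {
  atoms <- do.call(rbind, c(
    lapply(1:5, function(i) pdb_atom(resno = i, x = 4 * i)),
    list(pdb_atom("HETATM", name = "C1", resn = "NAP", resno = 90,
                  x = 12, y = 5),
         pdb_atom("HETATM", name = "C2", resn = "NAP", resno = 90,
                  x = 16, y = 5)),
    lapply(1:30, function(i) pdb_atom("HETATM", name = "O", resn = "HOH",
                                      resno = 100 + i, x = i, y = -30))))
  parse_structure(write_fixture_pdb(atoms))
}

test_that("ligand-auto site selection drops waters and ions", {
  m <- ligand_fixture()
  site <- select_site_atoms(m, site_definition())
  expect_equal(nrow(site), 2)
  expect_true(all(site$resid == "NAP"))
})

test_that("apo model in ligand-auto mode gives an instructive error", {
  atoms <- do.call(rbind, lapply(1:5, function(i) pdb_atom(resno = i, x = 4 * i)))
  m <- parse_structure(write_fixture_pdb(atoms))
  expect_error(select_site_atoms(m, site_definition()), "residue_list")
  site <- select_site_atoms(m, site_definition("residue_list",
    residues = data.frame(chain = "A", resno = c(2, 4))))
  expect_equal(sort(site$resno), c(2, 4))
  expect_error(site_definition("residue_list"), "non-empty")
})

test_that("min distance: 3-4-5 triangle and bin boundaries", {
  mk <- function(x, y) {
    atoms <- rbind(pdb_atom(resno = 1, x = 0),
                   pdb_atom("HETATM", name = "C1", resn = "LIG", resno = 9,
                            x = x, y = y))
    parse_structure(write_fixture_pdb(atoms))
  }
  m <- mk(3, 4)
  pr <- min_distance_to_site(m, select_site_atoms(m, site_definition()),
                             "A", 1)
  expect_equal(pr$min_distance, 5.0)
  expect_equal(pr$bin, "hit_le10")

  # boundary distances placed axially so they are exact at the PDB
  # format's 3-decimal precision
  bound <- function(y, bin) {
    m <- mk(0, y)
    pr <- min_distance_to_site(m, select_site_atoms(m, site_definition()),
                               "A", 1)
    expect_equal(pr$min_distance, y)
    expect_equal(pr$bin, bin, label = sprintf("y=%g", y))
  }
  bound(10.0, "hit_le10")        # exactly 10.0: inclusive
  bound(12.3, "marginal_10_15")
  bound(15.0, "marginal_10_15")  # exactly 15.0: inclusive
  bound(20.0, "distant_gt15")
})

test_that("absent residue is flagged, not an error", {
  m <- ligand_fixture()
  pr <- min_distance_to_site(m, select_site_atoms(m, site_definition()),
                             "A", 999)
  expect_false(pr$residue_found)
  expect_true(is.na(pr$min_distance))
})

test_that("min distance matches the all-pairs oracle on random fixtures", {
  set.seed(31)
  for (rep in 1:25) {
    n_res <- 10
    # round to the PDB format's 3-decimal precision so the file round-trips
    xyz <- round(matrix(runif(3 * 50, -20, 20), ncol = 3), 3)
    atoms <- do.call(rbind, lapply(1:40, function(i) {
      pdb_atom(resno = ((i - 1) %% n_res) + 1,
               name = c("CA", "CB", "CG", "CD")[((i - 1) %/% n_res) + 1],
               x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
    }))
    lig <- do.call(rbind, lapply(41:50, function(i) {
      pdb_atom("HETATM", name = sprintf("C%d", i - 40), resn = "LIG",
               resno = 99, x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
    }))
    m <- parse_structure(write_fixture_pdb(rbind(atoms, lig)))
    site <- select_site_atoms(m, site_definition())
    target <- sample.int(n_res, 1)
    pr <- min_distance_to_site(m, site, "A", target)
    res_rows <- which(rep(1:n_res, 4) == target)
    expect_equal(pr$min_distance,
                 oracle_min_distance(xyz[res_rows, , drop = FALSE],
                                     xyz[41:50, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("distance is rigid-motion invariant and scales linearly", {
  set.seed(7)
  xyz <- round(matrix(runif(3 * 20, -10, 10), ncol = 3), 3)
  build <- function(xyz) {
    atoms <- do.call(rbind, lapply(1:15, function(i) {
      pdb_atom(resno = i, x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
    }))
    lig <- do.call(rbind, lapply(16:20, function(i) {
      pdb_atom("HETATM", name = sprintf("C%d", i - 15), resn = "LIG",
               resno = 99, x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
    }))
    m <- parse_structure(write_fixture_pdb(rbind(atoms, lig)))
    min_distance_to_site(m, select_site_atoms(m, site_definition()), "A", 7)
  }
  base <- build(xyz)$min_distance
  theta <- 0.83; phi <- 1.91
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(phi), -sin(phi), 0, sin(phi), cos(phi)), 3, 3)
  moved <- xyz %*% R + matrix(rep(c(5.5, -2.25, 8.125), each = 20), ncol = 3)
  expect_equal(build(round(moved, 3))$min_distance, base, tolerance = 1e-2)
  # PDB files carry 3 decimals; exact rotation invariance is checked on
  # coordinates directly in the acceptance suite
  expect_equal(build(xyz * 2)$min_distance, 2 * base, tolerance = 1e-6)
})

test_that("enlarging the site never increases the minimum distance", {
  m <- ligand_fixture()
  site_small <- select_site_atoms(m, site_definition())[1, , drop = FALSE]
  site_big <- select_site_atoms(m,
    site_definition(ligand_exclusions = character(0)))  # waters included
  d_small <- min_distance_to_site(m, site_small, "A", 3)$min_distance
  d_big <- min_distance_to_site(m, site_big, "A", 3)$min_distance
  expect_lte(d_big, d_small)
})

test_that("residue numbering maps by constant offset", {
  expect_equal(map_residue_numbering(400, -209), 191L)
  expect_equal(map_residue_numbering(132, 0), 132L)
  expect_error(map_residue_numbering(100, -150), "non-positive")
})

test_that("generated toy structures carry their ground-truth distance", {
  for (d in c(5, 12, 20)) {
    p <- tempfile(fileext = ".pdb")
    truth <- gen_structure(n_residues = 30, target_residue = 11,
                           ligand_distance = d, seed = 2, path = p)
    m <- parse_structure(p)
    site <- select_site_atoms(m, site_definition())
    pr <- min_distance_to_site(m, site, "A", truth$target_residue)
    expect_equal(pr$min_distance, d, tolerance = 1e-6)
    expect_equal(pr$bin, c(`5` = "hit_le10", `12` = "marginal_10_15",
                           `20` = "distant_gt15")[[as.character(d)]])
  }
})
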