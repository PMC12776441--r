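# Structural photoreactivity geometry: parsers, distances, frames,
# step parameters, stacking overlap, sugar pucker, state comparison.

test_that("PDB and mmCIF structures parse and round-trip atom counts", {
  dup <- synthetic_duplex("GATTC")
  # write a minimal mmCIF and re-read
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_test", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "label_atom_id",
                                   "label_comp_id", "auth_asym_id",
                                   "auth_seq_id", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "B_iso_or_equiv")))
  rows <- sprintf("ATOM %d \"%s\" %s %s %d %.4f %.4f %.4f %.2f",
                  seq_len(nrow(dup)), dup$atom, dup$resname, dup$chain,
                  dup$resno, dup$x, dup$y, dup$z, dup$b)
  writeLines(c(hdr, rows, "#"), cif)
  m <- load_structure(cif)
  expect_equal(nrow(m), nrow(dup))
  expect_equal(sort(unique(m$chain)), c("A", "B"))
  expect_equal(nrow(dna_residues(m)), 10)
  # PDB path via bio3d
  pdb <- withr::local_tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(dup)), dup$atom, dup$resname, dup$chain, dup$resno,
    dup$x, dup$y, dup$z, 1.0, dup$b)
  writeLines(c(lines, "END"), pdb)
  mp <- quiet(load_structure(pdb))
  expect_equal(nrow(mp), nrow(dup))
  # a residue with a missing ring atom is reported
  broken <- dup[!(dup$resno == 2 & dup$chain == "A" & dup$atom == "N3"), ]
  mr <- missing_ring_atoms(structure_model(broken))
  expect_equal(mr$missing, "N3")
  expect_equal(mr$resno, 2)
  expect_error(structure_model(dup[dup$resname == "XXX", ]), "no DNA")
})

test_that("confidence filtering trims termini then thresholds residues", {
  dup <- synthetic_duplex("GATTCCGA", b = 80)
  cf <- confidence_filter(dup)
  expect_true(cf$pass)
  expect_equal(nrow(cf$residues), 2 * (8 - 6))  # 3 bp trimmed each end
  # one interior residue just below 70 fails the structure
  low <- dup
  low$b[low$chain == "A" & low$resno == 4] <- 69.9
  cf2 <- confidence_filter(low)
  expect_false(cf2$pass)
  expect_equal(cf2$failing$resno, 4)
  # a terminal residue can be arbitrarily bad if within the trim
  term <- dup
  term$b[term$chain == "A" & term$resno == 1] <- 10
  expect_true(confidence_filter(term)$pass)
})

test_that("d22 and d64 follow their atom definitions", {
  # hand-built: C5/C6 midpoints at (0,0,0) and (3,4,0) -> d22 = 5
  at <- function(chain, resno, resname, atom, x, y, z) {
    tibble::tibble(chain = chain, resno = resno, resname = resname,
                   atom = atom, x = x, y = y, z = z, b = 90)
  }
  m <- structure_model(dplyr::bind_rows(
    at("A", 1, "DT", "C5", -0.5, 0, 0), at("A", 1, "DT", "C6", 0.5, 0, 0),
    at("A", 1, "DT", "O4", 1, 1, 1),
    at("A", 2, "DC", "C5", 2.5, 4, 0), at("A", 2, "DC", "C6", 3.5, 4, 0),
    at("A", 2, "DC", "N4", 2, 2, 2),
    at("A", 3, "DT", "C5", 9, 9, 9), at("A", 3, "DT", "C6", 9, 9, 10),
    at("A", 3, "DT", "O4", -0.5, 0, 0)))
  r1 <- list(chain = "A", resno = 1); r2 <- list(chain = "A", resno = 2)
  r3 <- list(chain = "A", resno = 3)
  expect_equal(d22(m, r1, r2), 5)
  # d64: 3' C uses N4; distance C5(1) to N4(2)
  expect_equal(d64(m, r1, r2), sqrt(sum((c(-0.5, 0, 0) - c(2, 2, 2))^2)))
  # 3' T uses O4; coincident atoms give zero
  expect_equal(d64(m, r1, r3), 0)
  # missing atom errors name the atom
  m2 <- structure_model(dplyr::bind_rows(
    at("A", 1, "DT", "C5", 0, 0, 0), at("A", 1, "DT", "C6", 1, 0, 0),
    at("A", 2, "DC", "C6", 3, 4, 0), at("A", 2, "DC", "N4", 2, 2, 2)))
  expect_error(d22(m2, list(chain = "A", resno = 1),
                   list(chain = "A", resno = 2)), "C5")
  # purines are rejected
  dup <- synthetic_duplex("GA")
  expect_error(d22(dup, list(chain = "A", resno = 1),
                   list(chain = "A", resno = 2)), "pyrimidine")
})

test_that("distances and overlap are invariant under rigid motion", {
  dup <- synthetic_duplex("ATTCG")
  moved <- rigid_move(dup)
  r5 <- list(chain = "A", resno = 2); r3 <- list(chain = "A", resno = 3)
  expect_equal(d22(moved, r5, r3), d22(dup, r5, r3), tolerance = 1e-9)
  expect_equal(d64(moved, r5, r3), d64(dup, r5, r3), tolerance = 1e-9)
  expect_equal(stacking_overlap(moved, r5, r3),
               stacking_overlap(dup, r5, r3), tolerance = 1e-9)
  g1 <- dipyrimidine_geometry(dup, "A", partner_chain = "B")
  g2 <- dipyrimidine_geometry(moved, "A", partner_chain = "B")
  for (col in c("d22", "d64", "stacking_overlap", "shift", "slide",
                "propeller", "buckle", "phase5", "phase3")) {
    expect_equal(g2[[col]], g1[[col]], tolerance = 1e-6)
  }
})

test_that("base frames fit by rigid superposition without reflection", {
  dup <- synthetic_duplex("T")
  f <- fit_base_frame(dup, "A", 1)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(f$axes, diag(3), tolerance = 1e-9)
  # axes are the applied rotation for a rotated standard base
  R <- uvfootprint:::.rot_exp(c(0.3, -0.8, 1.2))
  rot <- rigid_move(dup, rotation_deg = c(0.3, -0.8, 1.2) * 180 / pi,
                    translation = c(1, 2, 3))
  f2 <- fit_base_frame(rot, "A", 1)
  expect_equal(f2$axes, R, tolerance = 1e-9)
  expect_equal(f2$rmsd, 0, tolerance = 1e-9)
  # noisy base: RMSD agrees with a brute-force numeric Kabsch oracle
  set.seed(8)
  noisy <- dup
  pick <- noisy$chain == "A" & noisy$atom %in%
    uvfootprint:::PYRIMIDINE_RING
  noisy$x[pick] <- noisy$x[pick] + rnorm(sum(pick), 0, 0.1)
  noisy$y[pick] <- noisy$y[pick] + rnorm(sum(pick), 0, 0.1)
  noisy$z[pick] <- noisy$z[pick] + rnorm(sum(pick), 0, 0.1)
  f3 <- fit_base_frame(noisy, "A", 1)
  S <- uvfootprint:::.standard_base("T")$atoms
  O <- as.matrix(noisy[pick, c("x", "y", "z")])
  expect_equal(f3$rmsd, kabsch_rmsd_oracle(S, O), tolerance = 1e-6)
})

test_that("step parameters invert the mid-frame construction exactly", {
  f1 <- identity_frame()
  # coincident frames -> all parameters zero
  sp0 <- base_step_params(f1, f1)
  expect_true(all(abs(unlist(sp0[c("shift", "slide", "rise", "tilt",
                                   "roll", "twist")])) < 1e-12))
  # pure mid-frame slide
  fs <- compose_frame(f1, c(0, 1.5, 0), c(0, 0, 0))
  sp <- base_step_params(f1, fs)
  expect_equal(sp$slide, 1.5, tolerance = 1e-12)
  expect_true(abs(sp$shift) + abs(sp$rise) + abs(sp$twist) < 1e-12)
  # helix round trip: twist 36, rise 3.4 (plus small off-axis values)
  params <- c(shift = 0.4, slide = -1.1, rise = 3.4,
              tilt = -2, roll = 6, twist = 36)
  f2 <- compose_frame(f1, params[1:3], params[4:6])
  got <- base_step_params(f1, f2)
  expect_equal(unlist(got[names(params)]), params, tolerance = 1e-6)
  # recovered from a built duplex too
  dup <- synthetic_duplex("TTT", twist = 36, rise = 3.4)
  pr <- pair_and_step_params(
    lapply(1:3, function(i) fit_base_frame(dup, "A", i)),
    lapply(3:1, function(i) fit_base_frame(dup, "B", i)))
  expect_equal(pr$steps$twist, c(36, 36), tolerance = 1e-6)
  expect_equal(pr$steps$rise, c(3.4, 3.4), tolerance = 1e-6)
  expect_true(all(abs(pr$pairs$propeller) < 1e-6))
  # interbase angle arithmetic
  expect_equal(interbase_angle(3, 4), 5)
  expect_equal(interbase_angle(0, 0), 0)
  expect_equal(interbase_angle(-6, 8), 10)
})

test_that("stacking overlap clips convex polygons correctly", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(convex_overlap_area(sq, sq), 1)
  expect_equal(convex_overlap_area(sq, sweep(sq, 2, c(0.5, 0), "+")),
               0.5)
  expect_equal(convex_overlap_area(sq, sweep(sq, 2, c(5, 5), "+")), 0)
  # symmetry and boundedness on random convex polygons
  set.seed(11)
  for (i in 1:5) {
    a <- sq * runif(1, 0.5, 2)
    b <- sweep(sq * runif(1, 0.5, 2), 2, runif(2, -0.5, 0.5), "+")
    o1 <- convex_overlap_area(a, b); o2 <- convex_overlap_area(b, a)
    expect_equal(o1, o2, tolerance = 1e-12)
    expect_lte(o1, min(uvfootprint:::.poly_area(a),
                       uvfootprint:::.poly_area(b)) + 1e-12)
  }
  # eclipsed identical rings overlap by the single projected ring area
  dup <- synthetic_duplex("TT", twist = 0, rise = 3.4)
  ring <- uvfootprint:::.standard_base("T")$atoms[, 1:2]
  expect_equal(stacking_overlap(dup, list(chain = "A", resno = 1),
                                list(chain = "A", resno = 2)),
               uvfootprint:::.poly_area(ring), tolerance = 1e-9)
  # laterally separated rings do not overlap
  far <- synthetic_duplex("TT", twist = 0, rise = 3.4)
  shifted <- far
  sel <- shifted$resno == 2 & shifted$chain == "A"
  shifted$x[sel] <- shifted$x[sel] + 50
  expect_equal(stacking_overlap(structure_model(shifted),
                                list(chain = "A", resno = 1),
                                list(chain = "A", resno = 2)), 0)
})

test_that("pseudorotation reproduces the phase-angle formula by hand", {
  # construct puckered sugars over a phase sweep and compare against a
  # hand evaluation of the formula from independently computed torsions
  for (P0 in c(10, 100, 150, 200, 340)) {
    ring <- t(vapply(0:4, function(j) {
      a <- 2 * pi * j / 5
      c(1.2 * cos(a), 1.2 * sin(a),
        0.35 * cos(P0 * pi / 180 + 4 * pi * j / 5))
    }, numeric(3)))
    atoms <- tibble::tibble(chain = "A", resno = 1, resname = "DT",
                            atom = c("C1'", "C2'", "C3'", "C4'", "O4'"),
                            x = ring[, 1], y = ring[, 2], z = ring[, 3],
                            b = 90)
    base <- ring_atoms_at("T", identity_frame(), "A", 1)
    m <- structure_model(dplyr::bind_rows(atoms,
                                          base[base$atom != "C1'", ]))
    pk <- pseudorotation(m, "A", 1)
    # independent oracle: dihedrals + the arctangent formula
    xyz <- function(a) as.numeric(ring[match(a, c("C1'", "C2'", "C3'",
                                                  "C4'", "O4'")), ])
    nu <- c(dihedral_oracle(xyz("C4'"), xyz("O4'"), xyz("C1'"), xyz("C2'")),
            dihedral_oracle(xyz("O4'"), xyz("C1'"), xyz("C2'"), xyz("C3'")),
            dihedral_oracle(xyz("C1'"), xyz("C2'"), xyz("C3'"), xyz("C4'")),
            dihedral_oracle(xyz("C2'"), xyz("C3'"), xyz("C4'"), xyz("O4'")),
            dihedral_oracle(xyz("C3'"), xyz("C4'"), xyz("O4'"), xyz("C1'")))
    Phand <- atan(((nu[5] + nu[2]) - (nu[4] + nu[1])) /
                    (2 * nu[3] * (sin(36 * pi / 180) +
                                    sin(72 * pi / 180)))) * 180 / pi
    if (nu[3] < 0) Phand <- Phand + 180
    Phand <- Phand %% 360
    expect_equal(pk$phase, Phand, tolerance = 1e-9)
    expect_equal(pk$nu, nu, tolerance = 1e-9)
    expect_equal(pk$pucker,
                 uvfootprint:::PUCKER_LABELS[floor(Phand / 36) + 1])
  }
})

test_that("pucker labels follow the 36-degree windows", {
  expect_equal(uvfootprint:::PUCKER_LABELS[floor(0 / 36) + 1], "C3'-endo")
  expect_equal(uvfootprint:::PUCKER_LABELS[floor(150 / 36) + 1],
               "C2'-endo")
})

test_that("state comparisons report medians, fold changes and flags", {
  set.seed(12)
  bound <- tibble::tibble(d22 = rnorm(20, 4, 0.1),
                          overlap = rnorm(20, 2, 0.2))
  # identical sets: fold change 1, p = 1
  cmp0 <- quiet(compare_states(bound, bound))
  expect_true(all(cmp0$fold_change == 1))
  expect_true(all(cmp0$p == 1))
  # a large shift gives an extreme U / tiny p
  unbound <- dplyr::mutate(bound, d22 = d22 + 10)
  cmp <- quiet(compare_states(bound, unbound))
  expect_lt(cmp$p[cmp$parameter == "d22"], 1e-4)
  # no thresholds -> no flags; configured range -> flag evaluated
  expect_true(all(is.na(cmp$in_reactive_range)))
  cmp2 <- quiet(compare_states(bound, unbound,
                               thresholds = list(d22 = c(3.5, 4.5))))
  expect_true(cmp2$in_reactive_range[cmp2$parameter == "d22"])
})

test_that("structure-input helper picks top non-redundant sequences", {
  g0 <- generate_genome(1, 3e4, 0.5, seed = 121)
  pl <- plant_sites(g0, "ACGTTAGC", 60, 220, seed = 121)
  sel <- select_structure_sites(pl$sites, pl$genome, n = 20, length = 20)
  expect_lte(nrow(sel), 20)
  expect_true(all(nchar(sel$sequence) == 20))
  expect_false(any(duplicated(sel$sequence)))
  # sequences are centered on the motif: consensus at positions 7..14
  expect_true(all(substr(sel$sequence, 7, 14) == "ACGTTAGC"))
})
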