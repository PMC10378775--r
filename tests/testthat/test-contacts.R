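## two-chain peptides for trajectory fixtures
traj_chains <- function() list(A = ab16_peptide("D7H"), B = ab16_peptide("D7H"))

## hand-written two-frame, two-chain PDB: one CA+CB pair per chain, with
## CB-CB distances 3.0 A (frame 1) and 10.0 A (frame 2)
tiny_pdb <- function(path) {
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  mk <- function(model, d) c(
    sprintf("MODEL     %4d", model),
    sprintf(fmt, 1, "CA", "GLU", "A", 3, 0, 0, 1.5, 1, 0),
    sprintf(fmt, 2, "CB", "GLU", "A", 3, 0, 0, 0, 1, 0),
    sprintf(fmt, 3, "CA", "HIS", "B", 6, d, 0, 1.5, 1, 0),
    sprintf(fmt, 4, "CB", "HIS", "B", 6, d, 0, 0, 1, 0),
    "ENDMDL")
  writeLines(c(mk(1, 3.0), mk(2, 10.0), "END"), path)
  path
}

test_that("multi-model PDB loading and contact counting work frame-wise", {
  f <- tempfile(fileext = ".pdb")
  tiny_pdb(f)
  traj <- load_trajectory(f)
  expect_equal(traj$n_frames, 2L)
  st <- pair_contact_frames(traj, c("A", 3), c("B", 6))
  expect_equal(st$frames_in_contact, 1L)   # only the 3.0 A frame
  expect_equal(st$frames_total, 2L)
  expect_equal(st$pair, "E3/H6")
  ## a 10 A-only pair never contacts at 4.5 A
  st2 <- pair_contact_frames(traj, c("A", 3), c("B", 6),
                             contact_config(cutoff = 2.0))
  expect_equal(st2$frames_in_contact, 0L)
})

test_that("frame-split coordinate files reproduce the single-file census", {
  res <- synth_trajectory(traj_chains(),
                          data.frame(chain_a = "A", res_a = 3, chain_b = "B",
                                     res_b = 6, rate = 0.5),
                          n_frames = 40, seed = 5)
  ## split the multi-model file into two halves
  lines <- readLines(res$file)
  model_starts <- grep("^MODEL", lines)
  mid <- model_starts[21]
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  writeLines(c(lines[1:(mid - 1)], "END"), f1)
  writeLines(c(lines[mid:length(lines)]), f2)
  whole <- pair_contact_frames(res$trajectory, c("A", 3), c("B", 6))
  split <- pair_contact_frames(load_trajectory(c(f1, f2)), c("A", 3), c("B", 6))
  expect_equal(split$frames_in_contact, whole$frames_in_contact)
  expect_equal(split$frames_total, whole$frames_total)
})

test_that("sequence validation catches mismatched chains", {
  res <- synth_trajectory(traj_chains(),
                          data.frame(chain_a = "A", res_a = 3, chain_b = "B",
                                     res_b = 6, rate = 1),
                          n_frames = 2, seed = 1)
  expect_silent(load_trajectory(res$file,
                                expected_sequences = traj_chains()))
  expect_error(load_trajectory(res$file,
                               expected_sequences = list(A = ab16_peptide("WT"))),
               "does not match")
})

test_that("contact counting is symmetric and monotone in the cutoff", {
  res <- synth_trajectory(traj_chains(),
                          data.frame(chain_a = "A", res_a = c(3, 7),
                                     chain_b = "B", res_b = c(6, 13),
                                     rate = c(0.4, 0.1)),
                          n_frames = 150, seed = 7)
  traj <- res$trajectory
  ab <- pair_contact_frames(traj, c("A", 3), c("B", 6))
  ba <- pair_contact_frames(traj, c("B", 6), c("A", 3))
  expect_equal(ab$frames_in_contact, ba$frames_in_contact)
  counts <- vapply(c(2, 4.5, 7, 13), function(cut)
    pair_contact_frames(traj, c("A", 3), c("B", 6),
                        contact_config(cutoff = cut))$frames_in_contact,
    integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("the census matches the brute-force distance oracle", {
  res <- synth_trajectory(traj_chains(),
                          data.frame(chain_a = "A", res_a = c(3, 7),
                                     chain_b = "B", res_b = c(6, 13),
                                     rate = c(0.3, 0.8)),
                          n_frames = 50, seed = 3)
  traj <- res$trajectory
  for (pp in list(list(c("A", 3), c("B", 6)), list(c("A", 7), c("B", 13)),
                  list(c("A", 11), c("B", 14)))) {
    got <- pair_contact_frames(traj, pp[[1]], pp[[2]])
    idx_a <- znoligomer:::residue_atom_idx(traj, pp[[1]][1],
                                           as.integer(pp[[1]][2]), "sidechain")
    idx_b <- znoligomer:::residue_atom_idx(traj, pp[[2]][1],
                                           as.integer(pp[[2]][2]), "sidechain")
    want <- oracle_contact_frames(traj, idx_a, idx_b, 4.5)
    expect_equal(got$frames_in_contact, want)
  }
})

test_that("planted contact rates are reproduced within binomial error", {
  rates <- data.frame(chain_a = "A", res_a = c(3, 7, 11),
                      chain_b = "B", res_b = c(6, 13, 14),
                      rate = c(1, 0, 0.1))
  res <- synth_trajectory(traj_chains(), rates, n_frames = 1000, seed = 11)
  census <- interface_census(res$trajectory, list(
    list(c("A", 3), c("B", 6)), list(c("A", 7), c("B", 13)),
    list(c("A", 11), c("B", 14))))
  expect_equal(census$fraction[1], 1)      # rate 1 is exact
  expect_equal(census$fraction[2], 0)      # rate 0 is exact
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(census$fraction[3] - 0.1), 3 * se)
  ## an uncontrolled pair never contacts
  far <- pair_contact_frames(res$trajectory, c("A", 1), c("B", 16))
  expect_equal(far$frames_in_contact, 0L)
})

test_that("census tables are deterministic and serializable", {
  rates <- data.frame(chain_a = "A", res_a = 3, chain_b = "B", res_b = 6,
                      rate = 0.5)
  r1 <- synth_trajectory(traj_chains(), rates, n_frames = 30, seed = 9)
  r2 <- synth_trajectory(traj_chains(), rates, n_frames = 30, seed = 9)
  expect_identical(readLines(r1$file), readLines(r2$file))
  pairs <- list(list(c("A", 3), c("B", 6)))
  c1 <- interface_census(r1$trajectory, pairs)
  c2 <- interface_census(r2$trajectory, pairs)
  f1 <- tempfile(); f2 <- tempfile()
  write_census_table(c1, f1); write_census_table(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("feasible interfaces reproduce the steric-exclusion outcome", {
  ## census shaped like the published dimer analysis: E3/H13 never in
  ## contact, all other candidate pairs observed at least once
  census <- data.frame(
    pair = c("E3/H6", "E3/H7", "H7/H13", "H6/H13", "E3/H13", "H6/H7"),
    frames_in_contact = c(253L, 2141L, 36L, 3L, 0L, 12L),
    frames_total = 20000L, cutoff = 4.5)
  feas <- feasible_interfaces(census)
  expect_setequal(feas$name, c("E11/H14:ZN:E11/H14", "E3/H6:ZN:E3/H6",
                               "H7/H13:ZN:H7/H13"))
  expect_equal(feas$affinity_class[feas$pair == "E11/H14"], "high")
  ## no interface may use the never-contacting E3/H13 pairing
  expect_false(any(grepl("E3/H13", feas$name)))
  ## empty census yields no interfaces
  empty <- census[0, ]
  expect_equal(nrow(feasible_interfaces(empty)), 0L)
  ## mixed cutoffs are rejected
  bad <- census; bad$cutoff[1] <- 6
  expect_error(feasible_interfaces(bad), "cutoff")
})

test_that("generator rejects unsatisfiable constraint sets", {
  expect_error(synth_trajectory(traj_chains(),
                                data.frame(chain_a = "A", res_a = c(3, 3),
                                           chain_b = "B", res_b = c(6, 13),
                                           rate = c(0.5, 0.5)),
                                n_frames = 5, seed = 1),
               "unsatisfiable")
  expect_error(synth_trajectory(traj_chains(),
                                data.frame(chain_a = "A", res_a = 3,
                                           chain_b = "B", res_b = 6,
                                           rate = 1.2),
                                n_frames = 5, seed = 1),
               "rates")
  expect_error(interface_census(structure(list(n_frames = 0L),
                                          class = "zn_trajectory"),
                                list()),
               "non-empty")
})
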