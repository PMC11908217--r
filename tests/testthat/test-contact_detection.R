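# Salt-bridge fixture: ARG sidechain N and ASP carboxylate O at a chosen
# separation.
arg_asp_fixture <- function(no_dist) {
  arg <- data.frame(name = c("N", "CA", "NH1"),
                    x = c(-1.2, 0, 2), y = c(0.8, 0, 0), z = 0,
                    elem = c("N", "C", "N"), stringsAsFactors = FALSE)
  asp <- data.frame(name = c("N", "CA", "OD1"),
                    x = 50 + c(-1.2, 0, -2), y = c(0.8, 0, 0), z = 0,
                    elem = c("N", "C", "O"), stringsAsFactors = FALSE)
  # place ASP OD1 exactly no_dist from ARG NH1 (which sits at x = 2)
  shift <- (2 + no_dist) - 48
  asp$x <- asp$x + shift
  write_fixture_pdb(list(
    list(resno = 10, resname = "ARG", atoms = arg),
    list(resno = 40, resname = "ASP", atoms = asp)
  ))
}

model_coords <- function(m) as.matrix(m$atom[, c("x", "y", "z")])

test_that("salt bridges are detected inside but not outside the cutoff", {
  m <- load_structure(arg_asp_fixture(3.5))
  keys <- detect_contacts_frame(model_coords(m), m, types = "salt_bridge")
  expect_equal(keys, "A:10:ARG|A:40:ASP|salt_bridge")

  m2 <- load_structure(arg_asp_fixture(4.5))
  expect_length(detect_contacts_frame(model_coords(m2), m2,
                                      types = "salt_bridge"), 0)
})

test_that("sequence-separation rule excludes |i - j| <= 2 pairs", {
  leu <- function(x0) data.frame(
    name = c("N", "CA", "CB"), x = x0 + c(-1.2, 0, 1), y = c(0.8, 0, -1),
    z = 0, elem = c("N", "C", "C"), stringsAsFactors = FALSE)
  near <- write_fixture_pdb(list(
    list(resno = 10, resname = "LEU", atoms = leu(0)),
    list(resno = 12, resname = "VAL", atoms = leu(4))  # CB-CB 4.0 A
  ))
  m <- load_structure(near)
  expect_length(detect_contacts_frame(model_coords(m), m,
                                      types = "hydrophobic"), 0)
  far <- write_fixture_pdb(list(
    list(resno = 10, resname = "LEU", atoms = leu(0)),
    list(resno = 13, resname = "VAL", atoms = leu(4))
  ))
  m2 <- load_structure(far)
  expect_length(detect_contacts_frame(model_coords(m2), m2,
                                      types = "hydrophobic"), 1)
})

test_that("unknown interaction types are rejected with the supported list", {
  m <- load_structure(arg_asp_fixture(3.5))
  expect_error(detect_contacts_frame(model_coords(m), m, types = "vdw"),
               "salt_bridge")
})

test_that("contact keys are canonical and emitted once per pair and type", {
  m <- load_structure(arg_asp_fixture(3.0))
  # both carboxylate-like O and several N atoms could pair; still one key
  keys <- detect_contacts_frame(model_coords(m), m, types = "salt_bridge")
  expect_equal(length(keys), 1)
  kd <- parse_contact_keys(keys)
  expect_true(kd$res_a < kd$res_b || kd$res_a == kd$res_b)
})

test_that("frequencies equal scheduled occupancies exactly", {
  sched <- data.frame(i = 5, j = 40, type = "salt_bridge")
  se <- synth_ensemble(sched, occupancy = matrix(0.75), temperatures = 300,
                       n_frames = 4, n_residues = 40, seed = 11)
  tab <- contact_frequencies(se$ensembles[[1]], types = "salt_bridge")
  expect_equal(unname(tab$freq[se$truth$contact]), 0.75)

  se2 <- synth_ensemble(sched, occupancy = matrix(1), temperatures = 300,
                        n_frames = 4, n_residues = 40, seed = 11)
  tab2 <- contact_frequencies(se2$ensembles[[1]], types = "salt_bridge")
  expect_equal(unname(tab2$freq[se2$truth$contact]), 1.0)
})

test_that("a 1000-frame schedule recovers the independently counted rate", {
  # schedule: present in 1 of every 5 frames; independent oracle counts the
  # schedule occurrences directly
  n_frames <- 1000
  occ <- sum(seq_len(n_frames) %% 5 == 0) / n_frames
  sched <- data.frame(i = 2, j = 8, type = "hydrophobic")
  se <- synth_ensemble(sched, occupancy = matrix(occ), temperatures = 310,
                       n_frames = n_frames, n_residues = 10, seed = 3)
  tab <- contact_frequencies(se$ensembles[[1]], types = "hydrophobic")
  expect_equal(unname(tab$freq[se$truth$contact]), 0.2)
})

test_that("striding subsamples frames and zero frames error", {
  sched <- data.frame(i = 2, j = 8, type = "hbond")
  se <- synth_ensemble(sched, occupancy = matrix(0.5), temperatures = 300,
                       n_frames = 8, n_residues = 10, seed = 5)
  tab <- contact_frequencies(se$ensembles[[1]], types = "hbond", stride = 2)
  expect_equal(tab$n_frames, 4)
})

test_that("assemble_matrix takes the union, fills zeros, sorts columns", {
  sched <- data.frame(i = c(2, 10), j = c(8, 20),
                      type = c("hbond", "hbond"))
  occ <- rbind(c(1, 0), c(1, 1))  # contact 1 vanishes at the 2nd temperature
  se <- synth_ensemble(sched, occ, temperatures = c(350, 300),
                       n_frames = 4, n_residues = 20, seed = 9)
  tabs <- lapply(se$ensembles, contact_frequencies, types = "hbond")
  mat <- assemble_matrix(tabs)
  expect_equal(mat$temperatures, c(300, 350))  # sorted ascending
  expect_equal(nrow(mat$freq), 2)
  k1 <- se$truth$contact[1]
  # occupancy columns in truth follow the supplied (unsorted) ladder
  expect_equal(unname(mat$freq[k1, c("350", "300")]),
               unname(unlist(se$truth[1, c("350", "300")])))
  expect_equal(unname(mat$freq[k1, "300"]), 0)

  expect_error(assemble_matrix(list(tabs[[1]], tabs[[1]])), "duplicate")
})

test_that("raising cutoffs never removes a detected contact", {
  cfg <- run_config(seed = 21)
  inp <- thermocontact:::.default_synthetic_inputs(cfg)
  m <- inp$se$model
  fr <- inp$se$ensembles[[1]]$get_frame(1)
  base <- detect_contacts_frame(fr, m, params = contact_params())
  wider <- detect_contacts_frame(fr, m, params = contact_params(
    salt_bridge = 5, hydrophobic = 5.5, hbond = 4.5, cation_pi = 7,
    pi_stack = 6.5))
  expect_true(all(base %in% wider))
})
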