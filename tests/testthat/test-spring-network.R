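isolated_duplex <- function(n_bp) {
  secondary_structure(2 * n_bp, data.frame(
    a_start = 1, a_end = n_bp, b_start = n_bp + 1, b_end = 2 * n_bp))
}

test_that("duplex spring sets match exhaustive rule enumeration", {
  p <- model_parameters()
  for (n_bp in 3:7) {
    net <- build_spring_network(isolated_duplex(n_bp), p)
    got <- lapply(seq_len(nrow(net$springs)),
                  function(k) c(net$springs$i[k], net$springs$j[k]))
    want <- oracle_duplex_pairs(n_bp)
    expect_setequal(sapply(got, paste, collapse = "-"),
                    sapply(want, paste, collapse = "-"))
    expect_equal(nrow(net$springs), 9 * n_bp - 14)
  }
})

test_that("loop-only chains get first-neighbor springs only", {
  net <- build_spring_network(secondary_structure(6, NULL))
  expect_equal(nrow(net$springs), 5)
  expect_true(all(net$springs$j - net$springs$i == 1))
  expect_true(all(net$springs$kind == "loop"))
})

test_that("every bead is sprung, consecutive beads once, one component", {
  fx <- load_fixture("trna_phe")
  net <- build_spring_network(fx$ss)
  n <- net$n_beads
  expect_true(all(seq_len(n) %in% c(net$springs$i, net$springs$j)))
  key <- paste(net$springs$i, net$springs$j)
  consec <- paste(1:(n - 1), 2:n)
  expect_true(all(consec %in% key))
  expect_false(anyDuplicated(key) > 0)
  expect_true(rnabd:::network_connected(net))
  # rules truncate at helix boundaries: no bend/torsion spring involves an
  # unpaired bead
  unpaired <- which(fx$ss$pairing == 0)
  bt <- net$springs[net$springs$kind %in% c("bend", "torsion"), ]
  expect_false(any(bt$i %in% unpaired | bt$j %in% unpaired))
})

test_that("equilibrium lengths come from the reference geometry", {
  p <- model_parameters()
  ss <- isolated_duplex(5)
  ref <- ideal_conformation(ss, p)
  net <- assign_equilibrium_lengths(build_spring_network(ss, p), ref, p)
  sp <- net$springs
  bb <- sp$l_e[sp$kind == "backbone"]
  expect_true(all(abs(bb - 6.292) < 1e-3)) # ideal A-form strand chord
  expect_true(all(abs(bb - p$l_e1) / p$l_e1 < 0.005)) # touching-beads match
  # loop springs pinned to the touching-bead length exactly
  fx <- load_fixture("trna_phe")
  refT <- ideal_conformation(fx$ss, p)
  netT <- assign_equilibrium_lengths(build_spring_network(fx$ss, p), refT, p)
  expect_true(all(netT$springs$l_e[netT$springs$kind == "loop"] == p$l_e1))
  expect_true(all(netT$springs$l_e > 0 & netT$springs$l_e <= 5 * p$l_e1))
})

test_that("geometry inconsistencies in the reference are rejected", {
  p <- model_parameters()
  ss <- secondary_structure(2, NULL)
  net <- build_spring_network(ss, p)
  ref_far <- rbind(c(0, 0, 0), c(40, 0, 0)) # > 5 * l_e1
  expect_error(assign_equilibrium_lengths(net, ref_far, p),
               "geometry inconsistency")
  ref_zero <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(assign_equilibrium_lengths(net, ref_zero, p),
               "geometry inconsistency")
})

test_that("helices with invalid base-pair counts are rejected", {
  expect_error(secondary_structure(4, data.frame(
    a_start = 2, a_end = 1, b_start = 3, b_end = 4)), "fewer than 1")
})

test_that("spring networks export to TSV and read back consistently", {
  p <- model_parameters()
  ss <- isolated_duplex(4)
  net <- assign_equilibrium_lengths(build_spring_network(ss, p),
                                    ideal_conformation(ss, p), p)
  path <- tempfile(fileext = ".tsv")
  write_spring_network(net, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 22) # 9 * 4 - 14
  expect_equal(tab$i, net$springs$i)
  expect_equal(tab$l_e, net$springs$l_e, tolerance = 1e-12)
})
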