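test_that("cross-link tables read, deduplicate and round-trip", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("protein1,residue1,protein2,residue2",
               "CUL2,382,NEDD8,33",
               "NEDD8,33,CUL2,382",
               "CUL2,433,NEDD8,6"), path)
  expect_message(xl <- read_crosslinks(path), "1 duplicate")
  expect_equal(nrow(xl), 2L)
  expect_equal(xl$protein1[1], "CUL2")
  expect_equal(xl$residue1[1], 382L)
  expect_equal(xl$upper_bound, c(35, 35))

  out <- tempfile(fileext = ".csv")
  write_crosslinks(xl, out)
  back <- read_crosslinks(out)
  key <- function(l) sort(paste(l$protein1, l$residue1, l$protein2, l$residue2))
  expect_equal(key(back), key(xl))

  empty <- tempfile(fileext = ".csv")
  writeLines("protein1,residue1,protein2,residue2", empty)
  expect_equal(nrow(read_crosslinks(empty)), 0L)
})

test_that("the published cross-link subset parses with the expected pairs", {
  path <- system.file("extdata", "csn_crl2n8_published_crosslinks.csv",
                      package = "xlhdx")
  xl <- read_crosslinks(path)
  expect_equal(nrow(xl), 10L)
  expect_true(all(xl$upper_bound == 35))
  key <- paste(xl$protein1, xl$residue1, xl$protein2, xl$residue2)
  # the NEDD8- and WHB-positioning links are present
  expect_true("CUL2 382 NEDD8 33" %in% key)
  expect_true("CUL2 433 NEDD8 6" %in% key)
  expect_equal(sum(xl$protein1 == "CUL2" & xl$protein2 == "WHB"), 3L)
  expect_equal(unname(count_crosslinks(xl)["inter"]), 10L)
})

test_that("malformed cross-link tables fail with named errors", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("protein1,residue1,protein2", "A,1,B"), p1)
  expect_error(read_crosslinks(p1), "residue2")
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("protein1,residue1,protein2,residue2", "A,x7,B,2"), p2)
  expect_error(read_crosslinks(p2), "row 1")
  expect_error(crosslinks("A", 5, "A", 5), "self")
})

test_that("cross-link distances are Euclidean bead distances with NA for unmapped", {
  m <- bead_model(chain = c("P", "Q"), resno = c(1, 1),
                  xyz = rbind(c(0, 0, 0), c(3, 4, 0)),
                  body = c("P", "Q"), mobile = c(FALSE, TRUE))
  links <- crosslinks(c("P", "P", "P"), c(1, 1, 1),
                      c("Q", "P", "Z"), c(1, 2, 9))
  d <- crosslink_distance(m, links)
  expect_equal(d[1], 5)
  expect_true(is.na(d[2]) && is.na(d[3]))
  coincident <- crosslink_distance(
    bead_model(c("P", "Q"), c(1, 1), rbind(c(1, 1, 1), c(1, 1, 1)),
               c("P", "Q"), c(FALSE, TRUE)),
    crosslinks("P", 1, "Q", 1))
  expect_equal(coincident, 0)
})

test_that("simulated link distances match the generator ground truth", {
  toy <- make_toy_complex(seed = 42)
  xl <- simulate_crosslinks(toy$truth, seed = 42)
  expect_equal(crosslink_distance(toy$truth, xl),
               attr(xl, "truth")$true_distance, tolerance = 1e-9)
})

test_that("satisfaction classification is inclusive at the bound and partitions fully", {
  m <- bead_model(chain = rep("S", 4), resno = 1:4,
                  xyz = rbind(c(0, 0, 0), c(10, 0, 0), c(34.9, 0, 0),
                              c(35.1, 0, 0)),
                  body = "S", mobile = FALSE)
  # beads all in one chain; links from bead 1 at distances 10, 34.9, 35.1
  links <- crosslinks(rep("S", 3), 1, rep("S", 3), 2:4)
  rep35 <- classify_satisfaction(m, links, bound = 35)
  expect_equal(unname(rep35$counts), c(2L, 1L, 0L))
  expect_equal(rep35$max_distance, 35.1)
  # boundary: exactly at the bound counts as satisfied
  at_bound <- classify_satisfaction(m, crosslinks("S", 1, "S", 2),
                                    bound = 10)
  expect_equal(unname(at_bound$counts["satisfied"]), 1L)

  empty <- classify_satisfaction(m, crosslinks(character(0), integer(0),
                                               character(0), integer(0)))
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$max_distance))

  # partition property over random models and link sets
  set.seed(5)
  for (k in 1:5) {
    toy <- make_toy_complex(seed = k)
    xl <- simulate_crosslinks(toy$truth, seed = k, decoy_fraction = 0.3)
    rpt <- classify_satisfaction(toy$start, xl)
    expect_equal(sum(rpt$counts), nrow(xl))
  }
})

test_that("satisfaction is invariant under rigid motion of the whole model", {
  set.seed(21)
  toy <- make_toy_complex(seed = 7)
  xl <- simulate_crosslinks(toy$truth, seed = 7, decoy_fraction = 0.2)
  base <- classify_satisfaction(toy$truth, xl)
  for (k in 1:5) {
    moved <- transform_model(toy$truth, random_rigid())
    rpt <- classify_satisfaction(moved, xl)
    expect_equal(rpt$counts, base$counts)
    expect_equal(rpt$links$distance, base$links$distance, tolerance = 1e-6)
  }
})

test_that("exclusive satisfaction flags two-conformer ensembles", {
  conf <- make_two_conformers()
  links <- crosslinks(c("S", "S"), c(1, 2), c("M", "M"), c(1, 1))
  part <- exclusive_satisfaction(conf$closed, conf$open, links, bound = 35)
  expect_equal(part$only_in_A, 1L)   # 30 A closed vs 45 A open
  expect_equal(part$only_in_B, 2L)   # 50 A closed vs 35 A open (inclusive)
  expect_true(part$ensemble_flag)

  same <- exclusive_satisfaction(conf$closed, conf$closed, links)
  expect_length(same$only_in_A, 0)
  expect_length(same$only_in_B, 0)
  expect_false(same$ensemble_flag)

  # partition property: the four sets plus unmapped cover all links
  withmiss <- crosslinks(c("S", "S", "S"), c(1, 2, 3),
                         c("M", "M", "X"), c(1, 1, 1))
  p2 <- exclusive_satisfaction(conf$closed, conf$open, withmiss)
  all_idx <- sort(c(p2$only_in_A, p2$only_in_B, p2$both, p2$neither,
                    p2$unmapped))
  expect_equal(all_idx, 1:3)
  expect_equal(p2$unmapped, 3L)
})

test_that("restraint sets assign the covalent, isopeptide and interface bounds", {
  exp_links <- crosslinks(c("CUL2", "CUL2", "CUL2"), c(382, 382, 433),
                          c("WHB", "WHB", "WHB"), c(720, 677, 677))
  topo <- list(
    covalent = data.frame(protein1 = "CUL2", residue1 = 655,
                          protein2 = "WHB", residue2 = 656),
    isopeptide = data.frame(protein1 = "WHB", residue1 = 689,
                            protein2 = "N8", residue2 = 76),
    interface = data.frame(protein1 = "VHL", residue1 = 10,
                           protein2 = "ELOB", residue2 = 50)
  )
  rs <- build_restraints(exp_links, topo)
  expect_equal(sum(rs$provenance == "experimental"), 3L)
  expect_equal(rs$upper_bound[rs$provenance == "experimental"],
               rep(35, 3))
  cov <- rs$residue1 == 655 | rs$residue2 == 655
  expect_equal(rs$upper_bound[cov], 5)
  iso <- rs$residue1 == 689 | rs$residue2 == 689
  expect_equal(rs$upper_bound[iso], 10)
  expect_equal(rs$upper_bound[rs$protein1 == "VHL"], 35)

  # topology endpoints must exist in the model when one is supplied
  m <- bead_model(c("A", "B"), c(1, 1), rbind(c(0, 0, 0), c(4, 0, 0)),
                  c("A", "B"), c(FALSE, TRUE))
  expect_error(
    build_restraints(topology = list(covalent = data.frame(
      protein1 = "A", residue1 = 1, protein2 = "B", residue2 = 99)),
      model = m),
    "absent")
  # duplicate pairs with conflicting bounds are rejected
  expect_error(
    build_restraints(topology = list(
      covalent = data.frame(protein1 = "A", residue1 = 1,
                            protein2 = "B", residue2 = 1),
      isopeptide = data.frame(protein1 = "A", residue1 = 1,
                              protein2 = "B", residue2 = 1))),
    "conflicting")
})
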