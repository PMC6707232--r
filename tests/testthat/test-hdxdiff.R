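write_uptake_rows <- function(df) {
  path <- tempfile(fileext = ".csv")
  write_state_table(df, path)
  path
}

test_that("state tables aggregate replicates into means and SDs", {
  df <- data.frame(protein = "P", sequence = "PEPTIDE", start = 1, end = 7,
                   state = "apo", exposure = 15, replicate = 1:3,
                   uptake = c(1.0, 1.1, 1.2))
  tab <- read_state_table(write_uptake_rows(df))
  expect_equal(tab$n, 3L)
  expect_equal(tab$mean, 1.1, tolerance = 1e-12)
  expect_equal(tab$sd, 0.1, tolerance = 1e-12)

  empty <- tempfile(fileext = ".csv")
  writeLines("Protein,Sequence,Start,End,State,Exposure,Uptake", empty)
  expect_equal(nrow(read_state_table(empty)), 0L)

  p1 <- tempfile(fileext = ".csv")
  writeLines(c("Protein,Sequence,Start,End,State,Exposure",
               "P,AAA,1,3,apo,15"), p1)
  expect_error(read_state_table(p1), "uptake")

  # same sequence reported with two different spans is inconsistent
  bad <- rbind(df, transform(df, end = 9))
  expect_error(read_state_table(write_uptake_rows(bad)), "inconsistent")
})

test_that("simulated exports read back to the generator means exactly", {
  sim <- simulate_hdx_tables(n_residues = 80, noise_sd = 0, seed = 4)
  tab <- read_state_table(write_uptake_rows(sim$apo))
  truth <- sim$truth_record$peptides
  for (k in c(1, 5, nrow(truth))) {
    mu <- truth$d_inf[k] * (1 - exp(-truth$rate[k] * 15))
    got <- tab$mean[tab$sequence == truth$sequence[k] & tab$exposure == 15]
    expect_equal(got, mu, tolerance = 1e-9)
  }
})

test_that("differential uptake is the difference of state means with propagated SD", {
  sim <- simulate_hdx_tables(n_residues = 60, seed = 9)
  apo <- read_state_table(write_uptake_rows(sim$apo))
  bound <- read_state_table(write_uptake_rows(sim$bound))
  d0 <- compute_diff(apo, apo)
  expect_true(all(d0$delta == 0))

  d <- compute_diff(bound, apo)
  expect_equal(nrow(d), nrow(apo))
  one <- d[1, ]
  expect_equal(one$sd_diff, sqrt(one$sd_bound^2 + one$sd_apo^2))

  # worked numbers: means 1.5 vs 1.0, per-state SD 0.1
  mk <- function(state, shift) {
    data.frame(protein = "P", sequence = "AAAA", start = 1, end = 4,
               state = state, exposure = 15, replicate = 1:3,
               uptake = c(0.9, 1.0, 1.1) + shift)
  }
  db <- compute_diff(read_state_table(write_uptake_rows(mk("bound", 0.5))),
                     read_state_table(write_uptake_rows(mk("apo", 0))))
  expect_equal(db$delta, 0.5, tolerance = 1e-12)
  expect_equal(db$sd_diff, sqrt(2) * 0.1, tolerance = 1e-9)

  # peptides present in only one state are reported as uncovered
  apo2 <- apo[apo$start != apo$start[1], ]
  d2 <- compute_diff(bound, apo2)
  expect_gt(length(attr(d2, "uncovered")), 0)
  expect_error(compute_diff(bound[0, ], apo), "shared")
})

test_that("the blanket threshold pools replicate variance per timepoint", {
  sim <- simulate_hdx_tables(n_residues = 100, noise_sd = 0, seed = 3)
  apo <- read_state_table(write_uptake_rows(sim$apo))
  bound <- read_state_table(write_uptake_rows(sim$bound))
  d <- compute_diff(bound, apo)
  th0 <- confidence_threshold(d)
  expect_equal(th0$DU, rep(0, 3))

  sim2 <- simulate_hdx_tables(n_residues = 100, noise_sd = 0.05, seed = 3)
  d2 <- compute_diff(read_state_table(write_uptake_rows(sim2$bound)),
                     read_state_table(write_uptake_rows(sim2$apo)))
  th1 <- confidence_threshold(d2)
  # doubling every replicate SD doubles DU
  d2x <- d2
  d2x$sd_bound <- 2 * d2$sd_bound
  d2x$sd_apo <- 2 * d2$sd_apo
  th2 <- confidence_threshold(d2x)
  expect_equal(th2$DU, 2 * th1$DU, tolerance = 1e-12)
  expect_error(confidence_threshold(d2, level = 1.2), "level")
})

test_that("classification is three-way with a strict boundary", {
  d <- data.frame(protein = "P", sequence = c("A", "B", "C"),
                  start = 1:3, end = 2:4, exposure = 15,
                  delta = c(0.3, 0.1, -0.3), sd_diff = 0.01,
                  n_bound = 3, n_apo = 3, sd_bound = 0.01, sd_apo = 0.01)
  th <- data.frame(exposure = 15, DU = 0.1, pooled_sd = 0.01, n1 = 3, n2 = 3)
  class(th) <- c("significance_threshold", "data.frame")
  cl <- classify_peptides(d, th)
  expect_equal(cl$class, c("destabilised", "non-significant", "stabilised"))
  # delta exactly at +DU is inside 0 +/- DU, hence non-significant
  expect_equal(cl$class[2], "non-significant")
  expect_equal(sum(table(cl$class)), nrow(d))
  expect_error(classify_peptides(transform(d, exposure = 99), th),
               "missing")
})

test_that("swapping the states negates deltas and mirrors the classes", {
  sim <- simulate_hdx_tables(
    n_residues = 120, noise_sd = 0.05, seed = 8,
    effect_regions = list(list(start = 20, end = 40, shift = 0.5),
                          list(start = 70, end = 85, shift = -0.4)))
  apo <- read_state_table(write_uptake_rows(sim$apo))
  bound <- read_state_table(write_uptake_rows(sim$bound))
  fwd <- compute_diff(bound, apo)
  rev <- compute_diff(apo, bound)
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
  th_f <- confidence_threshold(fwd)
  th_r <- confidence_threshold(rev)
  expect_equal(th_r$DU, th_f$DU, tolerance = 1e-12)
  cf <- classify_peptides(fwd, th_f)
  cr <- classify_peptides(rev, th_r)
  swap <- c(stabilised = "destabilised", destabilised = "stabilised",
            `non-significant` = "non-significant")
  expect_equal(unname(swap[cf$class]), cr$class)
})

test_that("an injected destabilising region is recovered and exported in order", {
  sim <- simulate_hdx_tables(
    n_residues = 150, noise_sd = 0.05, seed = 6,
    effect_regions = list(list(start = 60, end = 80, shift = 0.5)))
  apo <- read_state_table(write_uptake_rows(sim$apo))
  bound <- read_state_table(write_uptake_rows(sim$bound))
  d <- compute_diff(bound, apo)
  cl <- classify_peptides(d, confidence_threshold(d))
  truth <- sim$truth_record$peptides
  eff <- truth$sequence[truth$shift > 0]
  hit <- cl$sequence %in% eff
  # effect is 10x the noise SD: every overlapping peptide is called
  expect_true(all(cl$class[hit] == "destabilised"))
  # deltas in the region match the injected shift within noise
  expect_equal(mean(cl$delta[hit]), 0.5, tolerance = 0.05)

  woods <- woods_export(cl)
  expect_equal(nrow(woods), nrow(cl))
  expect_true(!is.unsorted(woods$start))
  out <- tempfile(fileext = ".csv")
  woods_export(cl, out)
  expect_equal(nrow(utils::read.csv(out)), nrow(cl))
  # segments exceeding the band are exactly the significant ones
  expect_equal(abs(woods$delta) > woods$DU, woods$class != "non-significant")

  agg <- aggregate_classes(cl)
  expect_true(all(agg$class[agg$sequence %in% eff] == "destabilised"))
})
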