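test_that("bin edges follow the sqrt(2)-spaced log scale", {
  b <- bin_edges()
  expect_length(b, 21L)
  expect_equal(b[1], 0.2)
  expect_equal(b[21], 204.8)
  expect_equal(b[-1] / b[-21], rep(sqrt(2), 20))
  expect_true(all(diff(b) > 0))
})

test_that("individual_profile bins tracts lower-inclusively", {
  map <- genetic_map(c("chr1", "chrX"), c(250, 60), is_x = c(FALSE, TRUE))
  # ancestry-1 autosomal tracts of 0.15, 0.25 and 1.0 cM -> windows 1, 2, 6
  hap <- make_hap(c(0.15, 0.40, 1.40, 250), c(1, 3, 1, 3))
  # second tract is 0.25 (anc 3), third is 1.0 (anc 1)
  ind <- make_ind("F", list(list(hap, make_hap(250, 2)),
                            list(make_hap(60, 2), make_hap(60, 2))))
  pc <- individual_profile(ind, map)
  expect_equal(unname(pc[, 1, 1]),
               c(1, 0, 0, 0, 0, 1, rep(0, 16)))   # 0.15 -> w1, 1.0 -> w6
  expect_equal(unname(pc[2, 3, 1]), 1)            # 0.25 -> w2
  expect_equal(unname(pc[22, 3, 1]), 1)           # 248.6 -> w22
  # bin boundaries: a 0.2 cM tract belongs to window 2, not 1
  ind2 <- make_ind("F", list(list(make_hap(c(0.2, 250), c(1, 2)),
                                  make_hap(250, 2)),
                             list(make_hap(60, 2), make_hap(60, 2))))
  pc2 <- individual_profile(ind2, map)
  expect_equal(unname(pc2[1:2, 1, 1]), c(0, 1))
  # totals conserve the tract-list lengths exactly
  expect_equal(sum(pc), 4 + 1 + 2)
  # unadmixed 250 cM founder chromosome lands in window 22 (>= 204.8)
  f <- admixmate:::founder_individual(2L, "F", map)
  pf <- individual_profile(f, map)
  expect_equal(unname(pf[22, 2, 1]), 2)
  # male X excluded by default, included on request
  m <- admixmate:::founder_individual(2L, "M", map)
  expect_equal(sum(individual_profile(m, map)[, , 2]), 0)
  expect_equal(sum(individual_profile(m, map,
                                      female_x_only = FALSE)[, , 2]), 1)
})

test_that("population_profile averages per-individual counts", {
  map <- tiny_map()
  f1 <- admixmate:::founder_individual(1L, "F", map)
  f2 <- admixmate:::founder_individual(3L, "F", map)
  m1 <- admixmate:::founder_individual(1L, "M", map)
  prof <- population_profile(list(f1, f2, m1), map)
  expect_s3_class(prof, "tract_profile")
  # autosome slab: f1 and m1 carry 4 ancestry-1 autosomal tracts each
  # (2 autosomes x 2 haplotypes), averaged over all 3 individuals
  expect_equal(sum(prof$counts[, 1, 1]), 8 / 3)
  # X slab averaged over the 2 females only: one anc-1 female with 2 X tracts
  expect_equal(sum(prof$counts[, 1, 2]), 2 / 2)
  # single individual equals its own counts; order is irrelevant
  p1 <- population_profile(list(f1), map)
  expect_equal(p1$counts, individual_profile(f1, map) + 0)
  expect_equal(population_profile(list(m1, f2, f1), map)$counts, prof$counts)
  expect_error(population_profile(list(), map), "at least one")
})

test_that("normalize_profile handles slabs, windows and degenerate input", {
  counts <- admixmate:::empty_profile_counts()
  counts[1, 1, 1] <- 10; counts[5, 2, 1] <- 30; counts[3, 1, 2] <- 8
  prof <- admixmate:::tract_profile_obj(counts)
  norm <- normalize_profile(prof)
  expect_equal(sum(norm$counts[, , 1]), 1)
  expect_equal(sum(norm$counts[, , 2]), 1)
  expect_equal(unname(norm$counts[1, 1, 1]), 0.25)
  # no_shortest drops window 1 before dividing
  ns <- normalize_profile(prof, windows = "no_shortest")
  expect_equal(dim(ns$counts)[1], 21L)
  expect_equal(unname(ns$counts[4, 2, 1]), 1)   # w5 is row 4 after the drop
  # all-zero X slab warns and stays zero
  counts0 <- counts; counts0[, , 2] <- 0
  prof0 <- admixmate:::tract_profile_obj(counts0)
  expect_warning(n0 <- normalize_profile(prof0), "zero total")
  expect_equal(sum(n0$counts[, , 2]), 0)
  # counts only in window 1 + no_shortest -> zero profile (and a warning)
  counts1 <- admixmate:::empty_profile_counts(); counts1[1, 1, 1] <- 5
  expect_warning(
    z <- normalize_profile(admixmate:::tract_profile_obj(counts1),
                           mode = "raw", windows = "no_shortest"),
    NA)
  expect_equal(sum(z$counts), 0)
  # double normalization is refused
  expect_error(normalize_profile(norm), "raw")
})

test_that("bootstrap_profile is unbiased and seed-stable", {
  counts <- admixmate:::empty_profile_counts()
  counts[7, 1, 1] <- 12
  # point mass: resampling cannot move it
  set.seed(1)
  b <- bootstrap_profile(list(counts), B = 50)
  expect_equal(b$mean_profile$counts, counts + 0)
  # spread histogram: bootstrap mean approaches the observation
  counts2 <- admixmate:::empty_profile_counts()
  counts2[, 2, 1] <- c(rep(10, 10), rep(5, 12))
  set.seed(2)
  b2 <- bootstrap_profile(list(counts2), B = 1000)
  expect_equal(b2$mean_profile$counts[, 2, 1], counts2[, 2, 1],
               tolerance = 0.02)
  set.seed(3)
  r1 <- bootstrap_profile(list(counts2), B = 20)
  set.seed(3)
  r2 <- bootstrap_profile(list(counts2), B = 20)
  expect_identical(r1, r2)
})

test_that("flatten/unflatten round-trip both window layouts", {
  counts <- admixmate:::empty_profile_counts()
  counts[] <- seq_len(length(counts))
  prof <- admixmate:::tract_profile_obj(counts)
  norm <- normalize_profile(prof)
  v <- flatten_profile(norm)
  expect_length(v, 132L)
  back <- unflatten_profile(v, n_individuals = norm$n_individuals)
  expect_equal(back$counts, norm$counts)
  ns <- normalize_profile(prof, windows = "no_shortest")
  expect_length(flatten_profile(ns), 126L)
  expect_equal(unflatten_profile(flatten_profile(ns))$windows, "no_shortest")
  expect_error(unflatten_profile(numeric(100)), "126 or 132")
})

test_that("profile TSV round-trips", {
  cfg <- tiny_config(seed = 12L)
  sim <- run_scenario(cfg, feasible_params())
  prof <- normalize_profile(population_profile(sim$population))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  back <- read_profile_tsv(path)
  expect_equal(back$counts, prof$counts)
  expect_equal(back$normalization, prof$normalization)
  expect_equal(back$n_individuals, prof$n_individuals)
})

test_that("more generations mean shorter admixed-ancestry tracts", {
  # scaled down (8 replicates, N = 100, 2 autosomes); mean autosomal tract
  # length of ancestry 1 must fall as generations accumulate
  map <- toy_genetic_map(c(100, 80), include_x = FALSE)
  gens <- c(2L, 6L, 19L)
  mean_len <- vapply(gens, function(g) {
    mean(vapply(1:8, function(r) {
      cfg <- scenario_config(c(0.5, 0, 0.5), population_size = 100L,
                             generations = g, map = map, seed = g * 131 + r)
      pop <- run_scenario(cfg, mating_params(c(0, 0, 0), c(0, 0)))$population
      lens <- unlist(lapply(pop$individuals, function(ind) {
        unlist(lapply(unlist(ind$haps, recursive = FALSE), function(h) {
          diff(c(0, h$ends))[h$anc == 1]
        }))
      }))
      mean(lens)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_len) < 0))
})

test_that("strong assortment preserves long-tract mass", {
  # paired replicates: ancestry-1 mass in windows >= 25.6 cM at G = 19 is
  # larger under AM = 1 than under random mating
  map <- toy_genetic_map(c(100, 80), include_x = FALSE)
  long_mass <- function(am_level, r) {
    cfg <- scenario_config(c(0.5, 0, 0.5), population_size = 100L,
                           generations = 19L, map = map, seed = 500 + r)
    p <- mating_params(am = rep(am_level, 3), sb = c(0, 0))
    prof <- population_profile(run_scenario(cfg, p)$population)
    long_bins <- which(c(0, bin_edges()) >= 25.6)
    sum(prof$counts[long_bins, 1, 1])
  }
  diffs <- vapply(1:8, function(r) {
    long_mass(1, r) - long_mass(0, r)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
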