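test_that("diallel plans enumerate unordered pairs without selfs", {
  expect_equal(nrow(diallel_crosses(2)), 1)
  expect_equal(nrow(diallel_crosses(15)), 105)
  expect_equal(nrow(diallel_crosses(100)), 4950)
  plan <- diallel_crosses(10)
  expect_true(all(plan$p1 < plan$p2))
  expect_false(any(duplicated(paste(plan$p1, plan$p2))))
  expect_error(diallel_crosses(1), "2 parents")
})

test_that("truncation selection honors proportion, count and scope", {
  map <- one_qtl_map()
  pop <- random_pop(map, 20)
  pop$family <- rep(c("f1", "f2", "f3", "f4"), each = 5)
  vals <- seq_len(20)
  expect_equal(select_individuals(pop, vals, "population", prop = 1), 1:20)
  expect_equal(select_individuals(pop, vals, "population", count = 1), 20)
  # among-family: whole top families survive
  sel <- select_individuals(pop, vals, "among_family", prop = 0.5)
  expect_equal(sel, 11:20)
  # within-family: the best of each family
  sel <- select_individuals(pop, vals, "within_family", prop = 0.2)
  expect_equal(sel, c(5, 10, 15, 20))
  expect_error(select_individuals(pop, vals, "population", count = 30), "30")
  expect_error(select_individuals(pop, vals[1:3], "population", prop = 0.5),
    "all candidates")
})

test_that("realized selection differential matches order-statistic theory", {
  map <- one_qtl_map()
  pop <- random_pop(map, 1000)
  set.seed(30)
  diffs <- replicate(30, {
    vals <- rnorm(1000)
    sel <- select_individuals(pop, vals, "population", prop = 0.1)
    mean(vals[sel]) - mean(vals)
  })
  # intensity for the top 10% of a standard normal
  i <- stats::dnorm(stats::qnorm(0.9)) / 0.1
  expect_equal(mean(diffs), i, tolerance = 0.05 * i)
})

test_that("generation advance bookkeeping follows the harvest mode", {
  map <- one_qtl_map()
  pop <- random_pop(map, 6)
  pop$family <- rep(c("fa", "fb"), each = 3)
  set.seed(31)
  ped <- advance_generation(pop, c(1, 3, 5), "pedigree", size = 10,
    generation = "F3")
  expect_equal(n_ind(ped), 30)
  expect_equal(length(unique(ped$family)), 3)
  expect_true(all(table(ped$family) == 10))

  sb <- advance_generation(pop, 1:6, "superbulk", size = 40)
  expect_equal(length(unique(sb$family)), 1)
  expect_equal(n_ind(sb), 40)

  blk <- advance_generation(pop, 1:6, "bulk", size = 7)
  expect_equal(sort(unique(blk$family)), c("fa", "fb"))
  expect_true(all(table(blk$family) == 7))

  ssd <- advance_generation(pop, 1:6, "single_seed", size = 99)
  expect_equal(n_ind(ssd), 6) # exactly one seed per plant, size ignored
  expect_equal(ssd$family, pop$family)

  expect_error(advance_generation(pop, integer(0), "bulk", 5),
    "misconfiguration")
})

test_that("selfed advance of a homozygous family breeds true", {
  map <- toy_map()
  h <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), 4), 4, byrow = TRUE)
  pop <- bean_pop(map, h, h)
  set.seed(32)
  off <- advance_generation(pop, 1:4, "bulk", size = 12)
  expect_true(all(off$hap1 == matrix(h[1, ], n_ind(off), 5, byrow = TRUE)))
  expect_identical(off$hap1, off$hap2)
})

test_that("strategy presets encode their defining structure", {
  prof <- reduced_profile()
  ssd <- build_program("ssd", 15, prof)
  expect_true(all(ssd$steps$advance[ssd$steps$gen %in% c("F2", "F3", "F4")] ==
    "single_seed"))
  expect_true(all(ssd$steps$criterion[ssd$steps$gen %in% c("F2", "F3", "F4")] ==
    "none"))

  blk <- build_program("bulk", 15, prof)
  early <- blk$steps$gen %in% c("F2", "F3", "F4")
  expect_true(all(blk$steps$criterion[early] == "none"))
  expect_true(all(blk$steps$advance[early] == "bulk"))
  expect_equal(blk$steps$criterion[blk$steps$gen == "F5"], "phenotype")

  mp <- build_program("modified_pedigree", 15, prof)
  winter <- mp$steps$gen %in% c("F3", "F5")
  expect_true(all(mp$steps$env[winter] == "winter_nursery"))
  expect_true(all(mp$steps$advance[winter] == "bulk"))

  ped <- build_program("pedigree", 15, prof)
  expect_true(all(ped$steps$criterion[ped$steps$gen %in%
    paste0("F", 2:5)] == "phenotype"))
  expect_true(all(ped$steps$scope[ped$steps$gen %in%
    paste0("F", 2:5)] == "among_within"))

  ms <- build_program("mass", 15, prof)
  expect_true(all(ms$steps$advance == "superbulk"))
  expect_true(all(ms$steps$scope[ms$steps$criterion == "phenotype"] ==
    "population"))

  expect_error(build_program("speed", 15), "mass, bulk, ssd")
})

test_that("a cycle from identical inbred parents returns identical lines", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 22), arch)
  set.seed(33)
  h <- matrix(rbinom(nrow(map), 1, 0.5), 1)
  parents <- bean_pop(map, h[rep(1, 2), ], h[rep(1, 2), ],
    family = c("P1", "P2"), generation = "P")
  prog <- build_program("ssd", 2, reduced_profile())
  Ve <- setNames(c(1, 1, 1), c("nursery", "winter_nursery", "field"))
  set.seed(33)
  res <- run_cycle(prog, parents, arch, Ve)
  expect_equal(n_ind(res$parents), 2)
  expect_true(all(res$parents$hap1 == matrix(h, 2, ncol(h), byrow = TRUE)))
  expect_true(all(res$parents$hap2 == matrix(h, 2, ncol(h), byrow = TRUE)))
})

test_that("selection moves the population mean when heritability is high", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 22), arch)
  set.seed(34)
  pool <- burn_in_founders(map, n = 60, generations = 5)
  parents <- sample_parents(pool, 15)
  Ve <- setNames(c(0, 0, 0), c("nursery", "winter_nursery", "field")) # H2 = 1
  prog <- build_program("mass", 15, reduced_profile())
  res <- run_cycle(prog, parents, arch, Ve)
  expect_gt(
    mean(oriented_value(res$parents, arch)),
    mean(oriented_value(parents, arch))
  )
})

test_that("a multi-cycle program is deterministic and closed", {
  arch <- trait_architecture("WM")
  map <- reduced_map(55)
  set.seed(35)
  pool <- burn_in_founders(map, 60, 5)
  parents <- sample_parents(pool, 15)
  run_once <- function() {
    set.seed(36)
    simulate_breeding(parents, arch, "ssd",
      cycles = 3,
      profile = reduced_profile()
    )
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$records, b$records)
  expect_identical(a$parents$hap1, b$parents$hap1)
  # closed system: census of the recycle set never changes
  expect_true(all(a$log$selected[a$log$gen == "F8"] == 15))
  expect_equal(n_ind(a$parents), 15)
  # heterozygosity collapses over the selfing generations within a cycle
  expect_lt(
    observed_heterozygosity(a$parents),
    observed_heterozygosity(parents) / 4
  )
})

test_that("with uninformative phenotypes the expected gain is zero", {
  arch <- trait_architecture("WM")
  map <- reduced_map(55)
  prof <- sim_profile(
    census = 200, f1_per_cross = 1, founder_n = 60,
    founder_gens = 5
  )
  # near-zero heritability everywhere: selection is blind
  h2 <- tibble::tibble(
    trait = "WM",
    environment = c("nursery", "winter_nursery", "field"),
    h2 = 1e-4
  )
  set.seed(37)
  pool <- burn_in_founders(map, 60, 5)
  gains <- replicate(50, {
    parents <- sample_parents(pool, 10)
    sim <- simulate_breeding(parents, arch, "bulk",
      cycles = 1,
      profile = prof, h2_table = h2
    )
    sim$records$adjusted_gain[2]
  })
  se <- stats::sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains)), 3 * se)
})
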