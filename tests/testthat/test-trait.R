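test_that("bundled QTL table matches the published counts and ranges", {
  tbl <- load_qtl_table()
  expect_equal(nrow(tbl), 38)
  expect_equal(sum(tbl$trait == "DF"), 19)
  expect_equal(sum(tbl$trait == "WM"), 8)
  expect_equal(sum(tbl$trait == "SY"), 11)
  sy <- tbl$effect_size[tbl$trait == "SY"]
  expect_equal(max(sy), -36.91)
  expect_equal(min(sy), -197.46)
  wm <- tbl$effect_size[tbl$trait == "WM"]
  expect_equal(max(wm), 3.16)
  expect_equal(min(wm), -7.2)
  df <- tbl$effect_size[tbl$trait == "DF"]
  expect_equal(max(df), 0.68)
  expect_equal(min(df), -1.21)
})

test_that("malformed QTL tables are rejected with a row number", {
  tbl <- load_qtl_table()
  bad <- tbl
  bad$trait[5] <- "ZZ"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(load_qtl_table(path), "row 5")
})

test_that("genotypic value follows the 2s / 0 / -2s mapping", {
  # DF414 has printed effect 0.68
  arch <- one_qtl_arch(0.68)
  map <- one_qtl_map()
  pop <- pop_from_haps(
    map,
    list(1L, 1L, 0L),
    list(1L, 0L, 0L)
  )
  expect_equal(genotypic_value(pop, arch), c(1.36, 0, -1.36))
})

test_that("an individual heterozygous at every QTL scores 0", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 11), arch)
  pop <- het_pop(map)
  expect_equal(genotypic_value(pop, arch), 0)
})

test_that("target bounds are symmetric sums of 2|s|", {
  # WM2010 has printed effect -7.2
  b <- target_bounds(one_qtl_arch(-7.2))
  expect_equal(b$TG_l, -14.4)
  expect_equal(b$TG_h, 14.4)

  two <- trait_architecture("SY", qtl_table = tibble::tibble(
    trait = "SY", qtl_name = c("A", "B"), linkage_group = 1L,
    position_cM = c(0, 10), effect_size = c(1, -1),
    population = "toy", reference = "toy"
  ))
  b2 <- target_bounds(two)
  expect_equal(c(b2$TG_l, b2$TG_h), c(-4, 4))

  # full DF architecture against an independent hand-sum of the table
  tbl <- load_qtl_table()
  expected <- 2 * sum(abs(tbl$effect_size[tbl$trait == "DF"]))
  expect_equal(target_bounds(trait_architecture("DF"))$TG_h, expected)
})

test_that("the all-favorable homozygote attains TG_h on the oriented scale", {
  for (trait in c("DF", "WM", "SY")) {
    arch <- trait_architecture(trait)
    map <- insert_qtl(consensus_map(n_markers = 11), arch)
    fav <- arch$qtl$favorable_allele[match(
      map$locus_id[map$kind == "qtl"],
      arch$qtl$locus_id
    )]
    h <- integer(nrow(map))
    h[map$kind == "qtl"] <- fav
    pop <- bean_pop(map, matrix(h, 1), matrix(h, 1))
    expect_equal(oriented_value(pop, arch), target_bounds(arch)$TG_h)
  }
})

test_that("brute-force enumeration of all WM genotypes matches the bounds", {
  arch <- trait_architecture("WM")
  s <- arch$qtl$effect
  k <- length(s)
  expect_equal(k, 8)
  # enumerate all 3^8 dosage combinations and score them independently
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  values <- drop((grid - 1) %*% (2 * s))
  b <- target_bounds(arch)
  expect_equal(min(values), b$TG_l)
  expect_equal(max(values), b$TG_h)
})

test_that("genotypic value is linear and order-invariant", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 11), arch)
  set.seed(10)
  pop <- random_pop(map, 20)
  v <- genotypic_value(pop, arch)
  # permuted-QTL architecture gives identical values
  perm <- arch
  ix <- sample(nrow(arch$qtl))
  perm$qtl <- arch$qtl[ix, ]
  expect_equal(genotypic_value(pop, perm), v)
  # per-QTL contributions sum to the total
  contrib <- sapply(seq_len(nrow(arch$qtl)), function(i) {
    a1 <- arch
    a1$qtl <- arch$qtl[i, ]
    genotypic_value(pop, a1)
  })
  expect_equal(rowSums(contrib), v)
})

test_that("per-plant heritability conversion is exact and monotone", {
  expect_equal(per_plant_H2(0.5, 1, 1), 0.5)
  expect_equal(per_plant_H2(1.0, 25, 3), 1.0)
  expect_equal(per_plant_H2(0.70, 10, 1), 1 / (1 + 10 * (1 / 0.7 - 1)))
  hs <- per_plant_H2(0.6, n = 1:20)
  expect_true(all(diff(hs) < 0))
  hy <- sapply(1:5, function(y) per_plant_H2(0.6, n = 10, y = y))
  expect_true(all(diff(hy) > 0))
  expect_error(per_plant_H2(0), "0, 1")
  expect_error(per_plant_H2(1.2), "0, 1")
})

test_that("error variance hits the requested heritability exactly", {
  arch <- one_qtl_arch(2)
  map <- one_qtl_map()
  # population with dosages 0/1/2 -> genotypic values -4, 0, 4
  pop <- pop_from_haps(map, list(0L, 1L, 1L), list(0L, 0L, 1L))
  vg <- var(genotypic_value(pop, arch))
  expect_equal(error_variance(arch, pop, 0.5), vg)
  expect_equal(error_variance(arch, pop, 1), 0)
  uniform <- pop_from_haps(map, list(1L, 1L), list(1L, 1L))
  expect_error(error_variance(arch, uniform, 0.5), "founder")
})

test_that("simulated phenotypes recover the configured heritability", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 11), arch)
  set.seed(11)
  pop <- random_pop(map, 50000)
  H2 <- 0.33 # white mold nursery estimate
  ve <- error_variance(arch, pop, H2)
  pheno <- simulate_phenotype(pop, arch, ve)
  g <- genotypic_value(pop, arch)
  fit <- stats::lm(pheno ~ g)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.02)
  realized <- var(g) / var(pheno)
  expect_equal(realized, H2, tolerance = 0.02)
})

test_that("phenotype noise has the configured moments", {
  arch <- one_qtl_arch(3)
  map <- one_qtl_map()
  pop <- pop_from_haps(map, list(1L), list(1L)) # value +6
  expect_equal(simulate_phenotype(pop, arch, 0), 6)
  set.seed(12)
  n <- 100000
  big <- pop_from_haps(map, rep(list(1L), 100), rep(list(1L), 100))
  draws <- replicate(n / 100, simulate_phenotype(big, arch, 4))
  expect_lt(abs(mean(draws) - 6), 3 * 2 / sqrt(n))
  expect_equal(var(as.numeric(draws)), 4, tolerance = 0.02 * 4)
})
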