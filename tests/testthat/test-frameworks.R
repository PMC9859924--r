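test_that("ridge solution matches the brute-force normal-equations oracle", {
  set.seed(40)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    m <- sample(3:20, 1)
    geno <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n, m)
    colnames(geno) <- paste0("m", seq_len(m))
    y <- rnorm(n)
    fx <- tryCatch(train_marker_effects(geno, y), error = function(e) NULL)
    if (is.null(fx)) next # degenerate draw (too few polymorphic markers)
    M <- sweep(geno, 2, colMeans(geno))
    r <- y - fx$intercept
    beta_oracle <- solve(
      crossprod(M) + fx$lambda * diag(m),
      crossprod(M, r)
    )
    expect_equal(fx$effects$effect, unname(drop(beta_oracle)),
      tolerance = 1e-8)
  }
})

test_that("a single causal marker is recovered; monomorphic markers get 0", {
  geno <- cbind(
    causal = c(-1, -1, 0, 0, 1, 1, -1, 0, 1, 1),
    mono1 = rep(1, 10),
    mono2 = rep(0, 10),
    other = c(1, -1, 0, 1, -1, 0, 0, 1, -1, 0)
  )
  y <- 3 * geno[, "causal"]
  fx <- train_marker_effects(geno, y)
  b <- setNames(fx$effects$effect, fx$effects$locus_id)
  expect_true(b[["causal"]] >= 2.5 && b[["causal"]] <= 3)
  expect_equal(b[["mono1"]], 0)
  expect_equal(b[["mono2"]], 0)
  expect_lt(abs(b[["other"]]), abs(b[["causal"]]) / 5)
})

test_that("degenerate training sets are rejected", {
  geno <- matrix(sample(c(-1, 0, 1), 30, TRUE), 10, 3)
  expect_error(train_marker_effects(geno, rep(2, 10)), "constant")
  expect_error(train_marker_effects(geno[1, , drop = FALSE], 1), "2 training")
  mono <- matrix(1, 10, 3)
  expect_error(train_marker_effects(mono, rnorm(10)), "polymorphic")
})

test_that("GEBV equals intercept plus summed centered effects", {
  set.seed(41)
  geno <- matrix(sample(c(-1, 0, 1), 60, TRUE), 12, 5)
  colnames(geno) <- paste0("m", 1:5)
  y <- rnorm(12)
  fx <- train_marker_effects(geno, y)
  # refit check: predictions on the training rows equal the ridge fit
  pred <- predict_gebv(geno, fx)
  fitted <- fx$intercept +
    drop(sweep(geno, 2, fx$centers) %*% fx$effects$effect)
  expect_equal(pred, fitted)
  # zero effects predict the intercept everywhere
  fx0 <- fx
  fx0$effects$effect <- rep(0, 5)
  expect_equal(predict_gebv(geno, fx0), rep(fx0$intercept, 12))
  expect_error(predict_gebv(geno[, 1:3], fx), "marker set")
})

test_that("an oracle marker panel predicts genotypic value accurately", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 11), arch)
  set.seed(42)
  founders <- burn_in_founders(map, 300, 10)
  fx <- train_gs_model(founders, arch, Ve = 0, include_qtl = TRUE)
  # fresh progeny from random founder crosses
  mothers <- sample.int(300, 400, TRUE)
  fathers <- sample.int(300, 400, TRUE)
  progeny <- bean_pop(map,
    make_gametes(founders, mothers),
    make_gametes(founders, fathers)
  )
  r <- stats::cor(predict_gebv(progeny, fx), genotypic_value(progeny, arch))
  expect_gte(r, 0.95)
})

test_that("GEBV selection beats random selection with oracle markers", {
  arch <- trait_architecture("WM")
  map <- insert_qtl(consensus_map(n_markers = 11), arch)
  set.seed(43)
  founders <- burn_in_founders(map, 200, 10)
  fx <- train_gs_model(founders, arch, Ve = 0, include_qtl = TRUE)
  dir_sign <- if (arch$direction == "maximize") 1 else -1
  wins <- replicate(100, {
    prog <- bean_pop(
      map,
      make_gametes(founders, sample.int(200, 100, TRUE)),
      make_gametes(founders, sample.int(200, 100, TRUE))
    )
    sel <- select_individuals(prog, dir_sign * predict_gebv(prog, fx),
      "population",
      prop = 0.1
    )
    mean(oriented_value(pop_subset(prog, sel), arch)) >
      mean(oriented_value(prog, arch))
  })
  expect_gte(sum(wins), 95)
})

test_that("framework overlays set cycle length and selection criteria", {
  prof <- reduced_profile()
  base <- build_program("pedigree", 15, prof)
  conv <- apply_framework(base, "conventional")
  expect_identical(conv$steps, base$steps)
  expect_equal(conv$cycle_length_years, 8)

  sp <- apply_framework(base, "speed")
  expect_equal(sp$cycle_length_years, 5)
  compressed <- sp$steps$gen %in% c("F2", "F3")
  expect_true(all(sp$steps$criterion[compressed] == "none"))
  expect_true(all(sp$steps$advance[compressed] == "single_seed"))

  gs <- apply_framework(base, "gs")
  expect_equal(gs$steps$criterion[gs$steps$gen == "F2"], "gebv")
  expect_equal(gs$steps$criterion[gs$steps$gen == "F4"], "gebv")
  expect_equal(gs$steps$criterion[gs$steps$gen == "F3"], "phenotype")

  gs2 <- apply_framework(build_program("ssd", 15, prof), "gs")
  expect_equal(gs2$steps$criterion[gs2$steps$gen == "F5"], "gebv")
})

test_that("per-year rescaling gives the 1.6x speed-breeding rate ratio", {
  g <- 4.2
  expect_equal(
    per_year_rescale(g, 5) / per_year_rescale(g, 8), 1.6
  )
  expect_equal(per_year_rescale(g, 1), g)
  expect_equal(per_year_rescale(0, 5), 0)
  expect_error(per_year_rescale(1, 0), "> 0")
})

test_that("speed and conventional share per-cycle genetics on average", {
  arch <- trait_architecture("WM")
  map <- reduced_map(55)
  prof <- sim_profile(census = 200, f1_per_cross = 1)
  set.seed(44)
  pool <- burn_in_founders(map, 80, 10)
  gain_of <- function(fw, seed) {
    set.seed(seed)
    parents <- sample_parents(pool, 12)
    set.seed(seed + 1)
    sim <- simulate_breeding(parents, arch, "ssd",
      framework = fw,
      cycles = 1, profile = prof
    )
    sim$records$adjusted_gain[2]
  }
  g_conv <- sapply(1:15, function(s) gain_of("conventional", 100 + s))
  g_speed <- sapply(1:15, function(s) gain_of("speed", 100 + s))
  pooled_se <- sqrt(var(g_conv) / 15 + var(g_speed) / 15)
  expect_lt(abs(mean(g_conv) - mean(g_speed)), 3 * pooled_se)
})
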