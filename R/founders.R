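#' Generate LD-bearing founder populations by drift burn-in
#'
#' The breeding engine needs founder material that carries linkage
#' disequilibrium between linked markers and QTLs (marker-based selection is
#' useless at linkage equilibrium). Starting from linkage equilibrium with
#' per-locus allele frequencies drawn uniformly on `init_freq`, the population
#' random-mates at finite size `n` for `generations` generations; genetic
#' drift in the small population builds LD between linked loci while leaving
#' allele-frequency expectations unchanged (neutral burn-in). An optional
#' viability-selection hook can bias which offspring survive.
#'
#' Defaults (`n = 100`, `generations = 50`) are calibration choices of this
#' package, documented in the methods vignette.
#'
#' @param map A [linkage_map()] (markers plus any inserted QTLs).
#' @param n Census size during burn-in (>= 2).
#' @param generations Number of random-mating generations (>= 0).
#' @param init_freq Range of initial allele-1 frequencies, default
#'   `c(0.1, 0.9)`.
#' @param fitness Optional function `function(pop) numeric` returning a
#'   relative viability per individual; offspring parents are then sampled
#'   proportionally to it. Default `NULL` (neutral drift).
#' @return A phased founder [bean_pop()] (generation `"F0"`).
#' @export
burn_in_founders <- function(map, n = 100, generations = 50,
                             init_freq = c(0.1, 0.9), fitness = NULL) {
  if (n < 2) abort("burn-in population size must be >= 2")
  if (generations < 0) abort("generations must be >= 0")
  L <- nrow(map)
  p <- runif(L, init_freq[1], init_freq[2])
  draw <- function() {
    matrix(rbinom(n * L, 1L, rep(p, each = n)), n, L)
  }
  pop <- bean_pop(map, draw(), draw(), family = "founder", generation = "F0")
  for (g in seq_len(generations)) {
    w <- if (is.null(fitness)) NULL else {
      wt <- fitness(pop)
      if (any(wt < 0)) abort("fitness must be non-negative")
      wt
    }
    mothers <- sample.int(n, n, replace = TRUE, prob = w)
    fathers <- sample.int(n, n, replace = TRUE, prob = w)
    pop <- bean_pop(map,
      make_gametes(pop, mothers), make_gametes(pop, fathers),
      family = "founder", generation = "F0"
    )
  }
  freq <- colMeans(geno_dosage(pop)) / 2
  if (all(freq %in% c(0, 1))) {
    abort("all loci fixed after burn-in; increase n or reduce generations")
  }
  pop
}

#' Sample initial parents from a founder pool
#'
#' Draws `k` distinct founders and clone-copies them (genotype-preserving)
#' into the crossing block of cycle 1. The founder pool doubles as the
#' genomic-selection training population.
#'
#' @param pop Founder [bean_pop()].
#' @param k Number of parents (the study grid uses 15, 30, 60 or 100).
#' @return A [bean_pop()] of `k` parents, generation `"P"`.
#' @export
sample_parents <- function(pop, k) {
  if (k > n_ind(pop)) {
    abort(paste0("requested ", k, " parents from a pool of ", n_ind(pop)))
  }
  idx <- sample.int(n_ind(pop), k)
  out <- clone_progeny(pop, idx, generation = "P")
  out$family <- sprintf("P%03d", seq_len(k))
  out
}

#' Pairwise linkage disequilibrium statistics
#'
#' Computes `D`, `D'` and `r^2` on gametic (haplotype) frequencies for a set
#' of locus pairs: `D = p_AB - p_A p_B`, `D' = D / D_max`, and
#' `r^2 = D^2 / (p_A p_a p_B p_b)`. Pairs involving a monomorphic locus are
#' flagged undefined (`NA`) rather than reported as 0.
#'
#' @param pop A phased [bean_pop()].
#' @param pairs Optional two-column data frame (`locus_a`, `locus_b`) of locus
#'   ids. By default all within-group pairs are used, down-sampled to at most
#'   `max_pairs`.
#' @param max_pairs Cap on the number of default pairs (default 5000).
#' @return A tibble: `locus_a`, `locus_b`, `group_a`, `group_b`,
#'   `distance_cM` (`NA` across groups), `D`, `Dprime`, `r2`.
#' @export
ld_stats <- function(pop, pairs = NULL, max_pairs = 5000) {
  map <- pop$map
  if (is.null(pairs)) {
    pieces <- lapply(split(seq_len(nrow(map)), map$group), function(ix) {
      if (length(ix) < 2) return(NULL)
      cmb <- utils::combn(ix, 2)
      tibble::tibble(ia = cmb[1, ], ib = cmb[2, ])
    })
    pr <- dplyr::bind_rows(pieces)
    if (nrow(pr) > max_pairs) pr <- pr[sort(sample.int(nrow(pr), max_pairs)), ]
  } else {
    ia <- match(pairs[[1]], map$locus_id)
    ib <- match(pairs[[2]], map$locus_id)
    if (anyNA(ia) || anyNA(ib)) abort("pair locus ids not all present in map")
    pr <- tibble::tibble(ia = ia, ib = ib)
  }
  H <- rbind(pop$hap1, pop$hap2) # gametic phase known: haplotypes pooled
  pA <- colMeans(H)[pr$ia]
  pB <- colMeans(H)[pr$ib]
  pAB <- colMeans(H[, pr$ia, drop = FALSE] * H[, pr$ib, drop = FALSE])
  D <- pAB - pA * pB
  dmax <- ifelse(D >= 0,
    pmin(pA * (1 - pB), (1 - pA) * pB),
    pmin(pA * pB, (1 - pA) * (1 - pB))
  )
  denom <- pA * (1 - pA) * pB * (1 - pB)
  poly <- denom > 0
  tibble::tibble(
    locus_a = map$locus_id[pr$ia],
    locus_b = map$locus_id[pr$ib],
    group_a = map$group[pr$ia],
    group_b = map$group[pr$ib],
    distance_cM = ifelse(map$group[pr$ia] == map$group[pr$ib],
      abs(map$position_cM[pr$ib] - map$position_cM[pr$ia]), NA_real_
    ),
    D = ifelse(poly, D, NA_real_),
    Dprime = ifelse(poly & dmax > 0, abs(D) / dmax, NA_real_),
    r2 = ifelse(poly, D^2 / denom, NA_real_)
  )
}

#' Binned r-squared decay with map distance
#'
#' Convenience summary of an [ld_stats()] table: mean `r^2` by distance bin
#' for within-group pairs.
#'
#' @param ld An [ld_stats()] tibble.
#' @param breaks Bin breaks in cM.
#' @return A tibble with `bin`, `mid_cM`, `n_pairs`, `mean_r2`.
#' @export
ld_decay <- function(ld, breaks = c(0, 5, 10, 25, 50, 100, Inf)) {
  ld <- ld[!is.na(ld$distance_cM) & !is.na(ld$r2), ]
  bin <- cut(ld$distance_cM, breaks, include.lowest = TRUE, right = FALSE)
  mids <- (head(breaks, -1) + pmin(breaks[-1], max(ld$distance_cM, 1))) / 2
  out <- tibble::tibble(bin = bin, r2 = ld$r2) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2)) |>
    dplyr::filter(!is.na(.data$bin))
  out$mid_cM <- mids[match(out$bin, levels(bin))]
  out[, c("bin", "mid_cM", "n_pairs", "mean_r2")]
}
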