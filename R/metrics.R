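#' Adjusted fitness on the 0-100 scale
#'
#' Rescales an oriented genotypic (fitness) value `F` between the lowest and
#' highest target genotypic values: `(F - TG_l) / (TG_h - TG_l) * 100`. The
#' all-unfavorable homozygote scores 0, the ideotype 100.
#'
#' @param f Oriented genotypic value(s) (see [oriented_value()]).
#' @param bounds A [target_bounds()] list.
#' @return Percentage(s) in `[0, 100]`.
#' @export
adjusted_fitness <- function(f, bounds) {
  if (bounds$TG_h <= bounds$TG_l) abort("TG_h must exceed TG_l")
  if (any(f < bounds$TG_l - 1e-8 | f > bounds$TG_h + 1e-8)) {
    abort("fitness outside target bounds: architecture mismatch")
  }
  (f - bounds$TG_l) / (bounds$TG_h - bounds$TG_l) * 100
}

#' @rdname adjusted_fitness
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @return `pop_adjusted_fitness()`: the population mean adjusted fitness.
#' @export
pop_adjusted_fitness <- function(pop, arch) {
  mean(adjusted_fitness(oriented_value(pop, arch), target_bounds(arch)))
}

#' Per-cycle adjusted genetic gain
#'
#' First differences of the mean adjusted-fitness series:
#' `dG(n) = F_Ad(n) - F_Ad(n-1)`. The cumulative sum telescopes to
#' `F_Ad(last) - F_Ad(first)`.
#'
#' @param fitness_series Mean adjusted fitness per cycle (cycle 0 first).
#' @return Numeric vector of per-cycle gains (length = cycles - 1).
#' @export
adjusted_gain <- function(fitness_series) {
  if (length(fitness_series) < 2) abort("need at least 2 cycles")
  diff(fitness_series)
}

#' Fixation of favorable and unfavorable alleles
#'
#' A QTL counts as fixed-favorable when every individual is homozygous for
#' the favorable allele (fixed-unfavorable analogously); segregating loci
#' count in neither bucket. Percentages are over the architecture's QTL
#' count.
#'
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @return A list: `favorable` and `unfavorable` percentages in `[0, 100]`.
#' @export
fixation_percentages <- function(pop, arch) {
  d <- geno_dosage(pop, arch$qtl$locus_id)
  fav <- arch$qtl$favorable_allele
  fav_dose <- sweep(d, 2, 2 * fav) # 0 where all-favorable-homozygous
  fixed_fav <- colSums(fav_dose != 0) == 0
  unfav_dose <- sweep(d, 2, 2 * (1 - fav))
  fixed_unfav <- colSums(unfav_dose != 0) == 0
  k <- nrow(arch$qtl)
  list(
    favorable = 100 * sum(fixed_fav) / k,
    unfavorable = 100 * sum(fixed_unfav) / k
  )
}

#' Hamming distance to the target genotype
#'
#' Counts, per individual, the alleles that differ from the ideotype (the
#' homozygote carrying every favorable allele): at each QTL locus the
#' contribution is `2 - copies of the favorable allele`. The population value
#' is the mean; lower is better. By default the count runs over the QTL loci
#' (the ideotype is defined on them); `loci = "all"` also scores marker loci
#' against allele 1.
#'
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @param loci `"qtl"` (default) or `"all"`.
#' @param per_individual Return the per-individual vector instead of the mean.
#' @return Mean allele-count distance (or per-individual vector).
#' @export
hamming_distance <- function(pop, arch, loci = c("qtl", "all"),
                             per_individual = FALSE) {
  loci <- match.arg(loci)
  if (loci == "qtl") {
    d <- geno_dosage(pop, arch$qtl$locus_id)
    fav <- arch$qtl$favorable_allele
    cnt <- sweep(d, 2, 2 * fav)
    h <- rowSums(abs(cnt))
  } else {
    d <- geno_dosage(pop)
    fav <- rep(1L, ncol(d))
    fav[match(arch$qtl$locus_id, pop$map$locus_id)] <- arch$qtl$favorable_allele
    h <- rowSums(abs(sweep(d, 2, 2 * fav)))
  }
  if (per_individual) h else mean(h)
}

#' Additive genetic variance and its relative series
#'
#' `additive_variance()` is the sample variance of genotypic values (with a
#' warning and `NA` for fewer than 2 individuals). `relative_variance()`
#' rescales a per-cycle series so that cycle 0 is 100%.
#'
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @return Variance in squared trait units.
#' @export
additive_variance <- function(pop, arch) {
  if (n_ind(pop) < 2) {
    warn("additive variance undefined for a single individual")
    return(NA_real_)
  }
  var(genotypic_value(pop, arch))
}

#' @rdname additive_variance
#' @param series Per-cycle variance series (cycle 0 first).
#' @export
relative_variance <- function(series) {
  if (!is.finite(series[1]) || series[1] <= 0) {
    abort("cycle-0 variance must be positive to form a relative series")
  }
  100 * (series / series[1])
}

#' Effective population size from heterozygosity decay
#'
#' Estimates `Ne = 1 / (2 dF)` where `dF = 1 - H_t / H_{t-1}` is the realized
#' one-step proportional decline in expected heterozygosity (gene diversity)
#' between two consecutive generations (or breeding cycles). A non-positive
#' decline leaves `Ne` undefined (`NA`), not infinite.
#'
#' @param h_prev,h_curr Expected heterozygosities of consecutive generations,
#'   or two [bean_pop()]s.
#' @return Estimated `Ne`, or `NA` when heterozygosity did not decline.
#' @export
effective_population_size <- function(h_prev, h_curr) {
  if (inherits(h_prev, "bean_pop")) h_prev <- expected_heterozygosity(h_prev)
  if (inherits(h_curr, "bean_pop")) h_curr <- expected_heterozygosity(h_curr)
  if (!is.finite(h_prev) || h_prev <= 0) return(NA_real_)
  dF <- 1 - h_curr / h_prev
  if (dF <= 0) return(NA_real_)
  1 / (2 * dF)
}

#' Summarise a gain series
#'
#' Computes the cumulative gain, the mean per-cycle gain, the per-year
#' equivalents for the framework's cycle length, and the (fractional) number
#' of cycles until 95% of the total cumulative gain is reached, using linear
#' interpolation of the cumulative-gain path between integer cycles — so a
#' program that realizes all of its gain in cycle 1 needs 0.95 cycles.
#' Zero (or negative) total gain leaves `cycles_to_95` undefined.
#'
#' @param gains Per-cycle adjusted gains (cycle 1 first), as from
#'   [adjusted_gain()].
#' @param cycle_length_years Cycle length in years (default 8).
#' @return A one-row tibble: `cycles`, `cumulative_gain`, `mean_gain_cycle`,
#'   `mean_gain_year`, `cycles_to_95`.
#' @export
gain_summary <- function(gains, cycle_length_years = 8) {
  if (length(gains) < 1) abort("need at least one cycle of gain")
  total <- sum(gains)
  cum <- c(0, cumsum(gains))
  cycles_to_95 <- NA_real_
  if (total > 0) {
    target <- 0.95 * total
    idx <- which(cum >= target)[1] # first integer cycle at/past target
    if (idx == 1) {
      cycles_to_95 <- 0
    } else {
      lo <- cum[idx - 1]
      hi <- cum[idx]
      cycles_to_95 <- (idx - 2) + (target - lo) / (hi - lo)
    }
  } else {
    warn("non-positive total gain: cycles_to_95 undefined")
  }
  tibble::tibble(
    cycles = length(gains),
    cumulative_gain = total,
    mean_gain_cycle = mean(gains),
    mean_gain_year = per_year_rescale(mean(gains), cycle_length_years),
    cycles_to_95 = cycles_to_95
  )
}

#' Per-cycle record of the reported statistics
#'
#' Snapshot of one population (typically the recycle set at the end of a
#' cycle): mean adjusted fitness, fixation percentages, mean Hamming
#' distance, additive variance and expected heterozygosity.
#'
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @param cycle Cycle index to stamp on the row.
#' @return A one-row tibble.
#' @export
cycle_record <- function(pop, arch, cycle = 0L) {
  fx <- fixation_percentages(pop, arch)
  tibble::tibble(
    cycle = as.integer(cycle),
    adjusted_fitness = pop_adjusted_fitness(pop, arch),
    fixed_favorable = fx$favorable,
    fixed_unfavorable = fx$unfavorable,
    hamming = hamming_distance(pop, arch),
    additive_variance = additive_variance(pop, arch),
    expected_het = expected_heterozygosity(pop)
  )
}
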