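#' Published QTL architecture and heritability tables
#'
#' `load_qtl_table()` reads a QTL table (by default the bundled one built from
#' published dry-bean QTL reports: 38 QTLs — 19 for days to flowering, 8 for
#' white mold tolerance, 11 for seed yield) and validates it.
#' `load_heritability_table()` reads the per-environment narrow-sense
#' heritabilities for the three traits (nursery, winter nursery, field).
#'
#' @param path CSV path; default is the copy bundled with the package.
#' @return A tibble. The QTL table has columns `trait`, `qtl_name`,
#'   `linkage_group`, `position_cM`, `effect_size`, `population`, `reference`;
#'   the heritability table has `trait`, `environment`, `h2`.
#' @export
load_qtl_table <- function(path = system.file("extdata", "qtl_table.csv",
                             package = "beansim"
                           )) {
  tbl <- readr::read_csv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      trait = readr::col_character(),
      qtl_name = readr::col_character(),
      linkage_group = readr::col_integer(),
      position_cM = readr::col_double(),
      effect_size = readr::col_double(),
      population = readr::col_character(),
      reference = readr::col_character()
    )
  )
  bad <- which(!tbl$trait %in% c("DF", "WM", "SY"))
  if (length(bad)) {
    abort(paste0("unknown trait code in row ", bad[1], ": ", tbl$trait[bad[1]]))
  }
  bad <- which(!is.finite(tbl$effect_size) | tbl$effect_size == 0)
  if (length(bad)) {
    abort(paste0("non-numeric or zero effect size in row ", bad[1]))
  }
  tbl
}

#' @rdname load_qtl_table
#' @export
load_heritability_table <- function(path = system.file("extdata",
                                      "heritability.csv",
                                      package = "beansim"
                                    )) {
  readr::read_csv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      trait = readr::col_character(),
      environment = readr::col_character(),
      h2 = readr::col_double()
    )
  )
}

# Default optimization directions. Seed yield is maximized; days to flowering
# and white mold severity (1-9 score) are minimized. Configurable because the
# source material never states the favorable direction explicitly.
default_directions <- c(DF = "minimize", WM = "minimize", SY = "maximize")

#' Build a trait architecture
#'
#' Collects the QTL set of one trait into an additive architecture. Each QTL
#' carries the published additive effect `s` of its reference allele; by
#' convention allele `1` at a QTL is the allele whose homozygote contributes
#' `+2s` to the genotypic value (heterozygote 0, other homozygote `-2s`). The
#' favorable allele is the one whose homozygote moves the trait in the
#' architecture's optimization direction.
#'
#' @param trait `"DF"`, `"WM"` or `"SY"`.
#' @param qtl_table A QTL table as from [load_qtl_table()].
#' @param direction `"maximize"` or `"minimize"`; defaults to maximize for SY
#'   and minimize for DF and WM.
#' @return An object of class `trait_architecture`: a list with `trait`,
#'   `units`, `direction`, and a `qtl` tibble (`locus_id`, `group`,
#'   `position_cM`, `effect`, `favorable_allele`).
#' @export
trait_architecture <- function(trait, qtl_table = load_qtl_table(),
                               direction = NULL) {
  if (!trait %in% c("DF", "WM", "SY")) {
    abort("trait must be one of DF, WM, SY")
  }
  direction <- direction %||% default_directions[[trait]]
  direction <- match.arg(direction, c("maximize", "minimize"))
  rows <- qtl_table[qtl_table$trait == trait, ]
  if (nrow(rows) == 0) abort(paste0("no QTLs for trait ", trait))
  if (anyDuplicated(rows$qtl_name)) abort("QTL loci must be distinct")
  sign_dir <- if (direction == "maximize") 1 else -1
  qtl <- tibble::tibble(
    locus_id = rows$qtl_name,
    group = rows$linkage_group,
    position_cM = rows$position_cM,
    effect = rows$effect_size,
    favorable_allele = as.integer(sign(rows$effect_size) * sign_dir > 0)
  )
  structure(
    list(
      trait = trait,
      units = c(DF = "days", WM = "1-9 score", SY = "kg/ha")[[trait]],
      direction = direction,
      qtl = qtl
    ),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(
    "<trait_architecture> ", x$trait, " (", x$units, "), ",
    nrow(x$qtl), " additive QTLs, direction: ", x$direction, "\n",
    sep = ""
  )
  invisible(x)
}

#' Additive genotypic value
#'
#' Sums per-QTL contributions `2s`, `0`, `-2s` for the allele-1 homozygote,
#' heterozygote and allele-0 homozygote respectively (purely additive; no
#' dominance, no epistasis). `oriented_value()` multiplies by -1 for
#' minimized traits so that larger is always better; it is the scale on which
#' selection and adjusted fitness operate, and the all-favorable homozygote
#' attains the upper target bound on it.
#'
#' @param pop A [bean_pop()] whose map contains all the architecture's QTLs.
#' @param arch A [trait_architecture()].
#' @return Numeric vector, one value per individual, in trait units.
#' @export
genotypic_value <- function(pop, arch) {
  d <- geno_dosage(pop, arch$qtl$locus_id)
  drop((d - 1) %*% (2 * arch$qtl$effect))
}

#' @rdname genotypic_value
#' @export
oriented_value <- function(pop, arch) {
  s <- if (arch$direction == "maximize") 1 else -1
  s * genotypic_value(pop, arch)
}

#' Target genotypic bounds
#'
#' The highest (`TG_h`) and lowest (`TG_l`) achievable oriented genotypic
#' values: `TG_h = sum(2|s|)` is attained by the homozygote carrying every
#' favorable allele, `TG_l = -TG_h` by the all-unfavorable homozygote.
#'
#' @param arch A [trait_architecture()].
#' @return A list with elements `TG_l` and `TG_h`.
#' @export
target_bounds <- function(arch) {
  tg <- sum(2 * abs(arch$qtl$effect))
  list(TG_l = -tg, TG_h = tg)
}

#' Per-plant broad-sense heritability from a per-plot estimate
#'
#' Converts a published per-plot heritability into the per-plant value used to
#' draw individual-plant error deviates. With the genetic variance normalized
#' to 1, the plot-level phenotypic variance is `1/h2_plot`, the error variance
#' `V_e = 1/h2_plot - 1`, and the per-plant heritability
#' `H2 = 1 / (1 + (V_e / y) * n)` for plot size `n` plants and `y` years.
#' With only additive QTL effects, narrow- and broad-sense heritability
#' coincide.
#'
#' @param h2_plot Per-plot heritability in `(0, 1]`.
#' @param n Plot size (number of plants), default 1.
#' @param y Number of years, default 1.
#' @return Per-plant heritability in `(0, 1]`.
#' @examples
#' per_plant_H2(0.70, n = 10) # seed yield in the field, 10-plant plots
#' @export
per_plant_H2 <- function(h2_plot, n = 1, y = 1) {
  if (any(h2_plot <= 0 | h2_plot > 1)) abort("h2_plot must be in (0, 1]")
  if (any(n < 1) || any(y < 1)) abort("n and y must be >= 1")
  ve <- 1 / h2_plot - 1
  1 / (1 + ve / y * n)
}

#' Environmental error variance for a target heritability
#'
#' Scales the error variance against the realized additive variance of
#' genotypic values in a reference (cycle-0) population so that
#' `V_g / (V_g + V_e)` equals the requested per-plant heritability.
#'
#' @param arch A [trait_architecture()].
#' @param ref_pop The reference [bean_pop()] (typically the initial parents).
#' @param H2 Per-plant heritability in `(0, 1]`.
#' @return Error variance `V_e` (squared trait units).
#' @export
error_variance <- function(arch, ref_pop, H2) {
  if (any(H2 <= 0 | H2 > 1)) abort("H2 must be in (0, 1]")
  vg <- var(genotypic_value(ref_pop, arch))
  if (!is.finite(vg) || vg <= 0) {
    abort(paste0(
      "reference population has zero genetic variance for ", arch$trait,
      "; use a wider founder set"
    ))
  }
  vg * (1 - H2) / H2
}

#' Simulate phenotypes
#'
#' Phenotype = genotypic value + independent Gaussian error of variance `Ve`
#' (optionally averaged over `reps` replicated plots, which divides the error
#' variance by `reps`).
#'
#' @param pop A [bean_pop()].
#' @param arch A [trait_architecture()].
#' @param Ve Per-plant error variance (from [error_variance()]).
#' @param reps Number of replications averaged, default 1.
#' @return Numeric phenotype per individual.
#' @export
simulate_phenotype <- function(pop, arch, Ve, reps = 1) {
  if (Ve < 0) abort("Ve must be >= 0")
  g <- genotypic_value(pop, arch)
  g + rnorm(length(g), 0, sqrt(Ve / reps))
}

# error variances per environment for one trait, anchored to a reference
# population; plot size/years come from the profile
environment_error_variances <- function(arch, ref_pop,
                                        h2_table = load_heritability_table(),
                                        n = 1, y = 1) {
  rows <- h2_table[h2_table$trait == arch$trait, ]
  envs <- c("nursery", "winter_nursery", "field")
  missing <- setdiff(envs, rows$environment)
  if (length(missing)) {
    abort(paste0(
      "unknown or missing environment(s): ", paste(missing, collapse = ", "),
      "; expected nursery, winter_nursery, field"
    ))
  }
  H2 <- per_plant_H2(rows$h2, n = n, y = y)
  setNames(
    vapply(H2, function(h) error_variance(arch, ref_pop, h), numeric(1)),
    rows$environment
  )
}
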