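#' Simulate a closed recurrent breeding program
#'
#' Runs `cycles` breeding cycles of one scenario (trait x strategy x
#' framework x parental population size) in a closed system: the lines
#' selected at the end of each cycle clone-migrate into the next cycle's
#' crossing block. Error variances are anchored once to the cycle-0 parents;
#' under genomic selection the marker-effect model is trained on the cycle-0
#' parents with nursery phenotypes (retraining each cycle is optional).
#'
#' @param parents Initial parent [bean_pop()] (from [sample_parents()]).
#' @param arch A [trait_architecture()].
#' @param strategy Strategy name for [build_program()].
#' @param framework Framework name for [apply_framework()].
#' @param cycles Number of breeding cycles (default 10).
#' @param profile A [sim_profile()].
#' @param h2_table Heritability table (trait, environment, h2).
#' @param retrain_gs Retrain the GEBV model on each cycle's parents
#'   (default `FALSE`: one static training, mirroring a program that trains
#'   once per scenario).
#' @param gs_include_qtl Use the oracle marker panel (markers on QTLs) for
#'   GEBV training and prediction.
#' @return A list of class `breeding_sim`: `records` (tibble of per-cycle
#'   statistics including adjusted gain, relative variance and Ne), `parents`
#'   (final recycle set), `program`, and `arch`.
#' @export
simulate_breeding <- function(parents, arch, strategy,
                              framework = "conventional", cycles = 10,
                              profile = sim_profile(),
                              h2_table = load_heritability_table(),
                              retrain_gs = FALSE,
                              gs_include_qtl = FALSE) {
  program <- build_program(strategy, n_ind(parents), profile = profile)
  program <- apply_framework(program, framework)
  Ve <- environment_error_variances(arch, parents, h2_table,
    n = profile$plot_size, y = profile$years
  )
  effects <- NULL
  if (framework == "gs") {
    effects <- train_gs_model(parents, arch, Ve[["nursery"]],
      include_qtl = gs_include_qtl
    )
  }
  records <- list(cycle_record(parents, arch, cycle = 0L))
  logs <- list()
  current <- parents
  for (cy in seq_len(cycles)) {
    if (framework == "gs" && retrain_gs && cy > 1) {
      effects <- train_gs_model(current, arch, Ve[["nursery"]],
        include_qtl = gs_include_qtl
      )
    }
    res <- run_cycle(program, current, arch, Ve, effects = effects)
    current <- res$parents
    records[[cy + 1L]] <- cycle_record(current, arch, cycle = cy)
    logs[[cy]] <- dplyr::mutate(res$log, cycle = cy, .before = 1)
  }
  rec <- dplyr::bind_rows(records)
  rec$adjusted_gain <- c(NA_real_, diff(rec$adjusted_fitness))
  rec$relative_variance <- relative_variance(rec$additive_variance)
  ne <- rep(NA_real_, nrow(rec))
  for (i in 2:nrow(rec)) {
    ne[i] <- effective_population_size(rec$expected_het[i - 1], rec$expected_het[i])
  }
  rec$ne <- ne
  structure(
    list(
      records = rec, parents = current, program = program, arch = arch,
      log = dplyr::bind_rows(logs)
    ),
    class = "breeding_sim"
  )
}

#' @export
print.breeding_sim <- function(x, ...) {
  cat(
    "<breeding_sim> ", x$arch$trait, " | ", x$program$name, " | ",
    x$program$framework, " | ", x$program$n_parents, " parents | ",
    max(x$records$cycle), " cycles\n",
    sep = ""
  )
  print(x$records)
  invisible(x)
}

#' @rdname simulate_breeding
#' @param x A `breeding_sim`.
#' @param ... Unused.
#' @return `tidy()`: the per-cycle record tibble; `glance()`: a one-row
#'   summary with the [gain_summary()] columns.
#' @method tidy breeding_sim
#' @export
tidy.breeding_sim <- function(x, ...) {
  dplyr::mutate(x$records,
    trait = x$arch$trait, strategy = x$program$name,
    framework = x$program$framework, parents = x$program$n_parents,
    .before = 1
  )
}

#' @rdname simulate_breeding
#' @method glance breeding_sim
#' @export
glance.breeding_sim <- function(x, ...) {
  gains <- x$records$adjusted_gain[-1]
  dplyr::mutate(
    gain_summary(gains, x$program$cycle_length_years),
    trait = x$arch$trait, strategy = x$program$name,
    framework = x$program$framework, parents = x$program$n_parents,
    fixed_favorable_final = dplyr::last(x$records$fixed_favorable),
    .before = 1
  )
}
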