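#' Simulation scale profile
#'
#' Bundles the program parameters that the source material leaves open
#' (per-generation family sizes, selection proportions, plot design). The
#' default profile targets a census of about 2000 plants in the segregating
#' generations; `reduced_profile()` is a smaller calibration used by the test
#' suite and the acceptance script (census 600, single F1 per cross) so that
#' full strategy grids run on a desktop.
#'
#' @param census Target census of the segregating generations (F2-F5).
#' @param f1_per_cross F1 plants per diallel cross.
#' @param select_prop Selected proportion at each artificial-selection step
#'   of the line-based strategies.
#' @param mass_prop Retained fraction per generation of mass selection's
#'   visual single-plant culling (milder than line truncation; its cumulative
#'   F2-F5 intensity, about `mass_prop^4`, is comparable to one
#'   `select_prop` event).
#' @param trial_prop Proportion of lines kept at each staged yield trial
#'   (F6 preliminary, F7 advanced) of the line-based strategies.
#' @param trial_reps Replications averaged in the multi-environment trial.
#' @param plot_size Plants per plot (`n` in the per-plant heritability
#'   conversion). Published heritabilities are per-plot; with the default
#'   short-row plots of 20 plants, single-plant phenotypes are substantially
#'   noisier than the plot-level h2, which is what makes plant-by-plant
#'   (mass) selection weak while replicated family means stay informative.
#' @param years Years per evaluation (`y` in the same conversion).
#' @param founder_n Census of the drift burn-in founder pool.
#' @param founder_gens Burn-in generations.
#' @return A named list of class `sim_profile`.
#' @export
sim_profile <- function(census = 2000, f1_per_cross = 2, select_prop = 0.1,
                        mass_prop = 0.5, trial_prop = 0.5, trial_reps = 2, plot_size = 20,
                        years = 1, founder_n = 150, founder_gens = 40) {
  structure(
    list(
      census = census, f1_per_cross = f1_per_cross,
      select_prop = select_prop, mass_prop = mass_prop,
      trial_prop = trial_prop, trial_reps = trial_reps,
      plot_size = plot_size, years = years,
      founder_n = founder_n, founder_gens = founder_gens
    ),
    class = "sim_profile"
  )
}

#' @rdname sim_profile
#' @export
reduced_profile <- function() {
  sim_profile(
    census = 600, f1_per_cross = 1, select_prop = 0.1,
    trial_reps = 2, founder_n = 150, founder_gens = 30
  )
}

step_row <- function(gen, env, advance, size_role, criterion = "none",
                     scope = "population", prop = NA_real_, reps = 1) {
  tibble::tibble(
    gen = gen, env = env, advance = advance, size_role = size_role,
    criterion = criterion, scope = scope, prop = prop, reps = reps
  )
}

#' Build a selection-strategy program
#'
#' Encodes one of the five classical self-pollinated-crop selection strategies
#' as an ordered table of generation steps spanning one breeding cycle
#' (crossing through F8, where the recycle set is selected). Each row
#' describes the harvest of one generation: the evaluation environment, an
#' optional truncation-selection rule applied before harvest, and the advance
#' mode used to produce the next generation.
#'
#' Presets:
#' * `"mass"` — whole-population phenotypic selection every generation F2-F5
#'   with superbulk advance; trial phase F6-F8.
#' * `"bulk"` — no artificial selection F2-F4 (bulk advance; natural selection
#'   is modelled as neutral random survival), population-wide selection at F5.
#' * `"ssd"` — single seed descent: one selfed seed per plant F2-F5 with no
#'   selection, selection at F5.
#' * `"pedigree"` — among- plus within-family selection every generation from
#'   F2, pedigree advance (each selected plant founds a family).
#' * `"modified_pedigree"` — plant/row selection at F2 and F4; winter-nursery
#'   bulk harvests at F3 and F5.
#'
#' All strategies finish with a replicated field trial and final truncation
#' selection of `n_parents` lines at F8 (the closed-system recycle set).
#'
#' @param name One of `"mass"`, `"bulk"`, `"ssd"`, `"pedigree"`,
#'   `"modified_pedigree"`.
#' @param n_parents Parental population size; equals the number of lines
#'   selected at the end of the cycle (closed system).
#' @param profile A [sim_profile()].
#' @return An object of class `strategy_program`.
#' @export
build_program <- function(name, n_parents,
                          profile = sim_profile()) {
  strategies <- c("mass", "bulk", "ssd", "pedigree", "modified_pedigree")
  if (!name %in% strategies) {
    abort(paste0(
      "unknown strategy '", name, "'; available: ",
      paste(strategies, collapse = ", ")
    ))
  }
  p <- profile$select_prop
  # mass selection culls single plants by eye each generation: a mild retained
  # fraction repeated F2-F5, in contrast to the one intense truncation event
  # of the line-based strategies
  pm <- profile$mass_prop
  # line strategies pass through staged yield trials (preliminary at F6,
  # advanced at F7): among-line selection on replicated family means; an
  # unstructured mass bulk has no lines to trial
  pt <- profile$trial_prop
  steps <- switch(name,
    mass = dplyr::bind_rows(
      step_row("F1", "nursery", "superbulk", "census"),
      step_row("F2", "nursery", "superbulk", "census", "phenotype", "population", pm),
      step_row("F3", "nursery", "superbulk", "census", "phenotype", "population", pm),
      step_row("F4", "nursery", "superbulk", "census", "phenotype", "population", pm),
      step_row("F5", "nursery", "superbulk", "census", "phenotype", "population", pm),
      step_row("F6", "field", "superbulk", "census"),
      step_row("F7", "field", "superbulk", "census")
    ),
    bulk = dplyr::bind_rows(
      step_row("F1", "nursery", "bulk", "family"),
      step_row("F2", "nursery", "bulk", "family"),
      step_row("F3", "nursery", "bulk", "family"),
      step_row("F4", "nursery", "bulk", "family"),
      step_row("F5", "nursery", "pedigree", "per_plant", "phenotype", "population", p),
      step_row("F6", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps),
      step_row("F7", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps)
    ),
    ssd = dplyr::bind_rows(
      step_row("F1", "nursery", "pedigree", "per_plant"),
      step_row("F2", "nursery", "single_seed", "per_plant"),
      step_row("F3", "nursery", "single_seed", "per_plant"),
      step_row("F4", "nursery", "single_seed", "per_plant"),
      step_row("F5", "nursery", "pedigree", "per_plant", "phenotype", "population", p),
      step_row("F6", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps),
      step_row("F7", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps)
    ),
    pedigree = dplyr::bind_rows(
      step_row("F1", "nursery", "bulk", "family"),
      step_row("F2", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F3", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F4", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F5", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F6", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps),
      step_row("F7", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps)
    ),
    modified_pedigree = dplyr::bind_rows(
      step_row("F1", "nursery", "bulk", "family"),
      step_row("F2", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F3", "winter_nursery", "bulk", "family"),
      step_row("F4", "nursery", "pedigree", "per_plant", "phenotype", "among_within", p),
      step_row("F5", "winter_nursery", "bulk", "family"),
      step_row("F6", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps),
      step_row("F7", "field", "bulk", "family", "phenotype", "among_family",
        pt, reps = profile$trial_reps)
    )
  )
  structure(
    list(
      name = name, n_parents = as.integer(n_parents), steps = steps,
      framework = "conventional", cycle_length_years = 8,
      final_env = "field", final_reps = profile$trial_reps,
      profile = profile
    ),
    class = "strategy_program"
  )
}

#' @export
print.strategy_program <- function(x, ...) {
  cat(
    "<strategy_program> ", x$name, " | framework: ", x$framework,
    " (", x$cycle_length_years, " yr/cycle) | ", x$n_parents,
    " parents recycled\n",
    sep = ""
  )
  print(x$steps)
  invisible(x)
}

# resolve a step's advance size from the profile and the current state
step_size <- function(size_role, census, n_harvested, n_families) {
  switch(size_role,
    census = census,
    family = max(1, round(census / max(1, n_families))),
    per_plant = max(1, round(census / max(1, n_harvested)))
  )
}

#' Run one breeding cycle
#'
#' Executes a full cycle of a strategy program in a closed system: a full
#' diallel among the parents, F1 through F8 generation advance with the
#' program's selection rules, and final truncation selection of exactly
#' `n_parents` lines on a replicated field trial at F8. The selected lines
#' are returned as a clone-copied parent set for the next cycle.
#'
#' Selection criteria are evaluated on the oriented scale (larger = better):
#' phenotypes are the genotypic value plus Gaussian error with the
#' environment's error variance `Ve[env]`; GEBV criteria require trained
#' `marker_effects`.
#'
#' @param program A [build_program()] product (possibly after
#'   [apply_framework()]).
#' @param parents A [bean_pop()] with `n_parents` individuals.
#' @param arch A [trait_architecture()].
#' @param Ve Named error variances per environment (from
#'   [environment_error_variances()]).
#' @param effects Optional [train_marker_effects()] fit for GEBV criteria.
#' @return A list: `parents` (next-cycle parent set) and `log`, a tibble with
#'   one row per generation (census, families, selected count, environment).
#' @export
run_cycle <- function(program, parents, arch, Ve, effects = NULL) {
  if (n_ind(parents) != program$n_parents) {
    abort(paste0(
      "expected ", program$n_parents, " parents, got ", n_ind(parents)
    ))
  }
  profile <- program$profile
  dir_sign <- if (arch$direction == "maximize") 1 else -1
  census <- profile$census

  criterion_values <- function(pop, criterion, env, reps) {
    if (criterion == "phenotype") {
      if (!env %in% names(Ve)) {
        abort(paste0(
          "unknown environment '", env,
          "'; expected one of ", paste(names(Ve), collapse = ", ")
        ))
      }
      dir_sign * simulate_phenotype(pop, arch, Ve[[env]], reps = reps)
    } else if (criterion == "gebv") {
      if (is.null(effects)) abort("GEBV selection requires trained marker effects")
      dir_sign * predict_gebv(pop, effects)
    } else {
      abort(paste0("unknown selection criterion '", criterion, "'"))
    }
  }

  # crossing block: full diallel
  plan <- diallel_crosses(parents, profile$f1_per_cross)
  f1 <- purrr::pmap(plan, function(p1, p2, n) {
    make_cross(parents, p1, p2, n,
      family = sprintf("C%03dx%03d", p1, p2), generation = "F1"
    )
  })
  pop <- bind_pops(f1, generation = "F1")

  log <- list()
  for (i in seq_len(nrow(program$steps))) {
    st <- program$steps[i, ]
    if (st$criterion != "none") {
      vals <- criterion_values(pop, st$criterion, st$env, st$reps)
      harvested <- select_individuals(pop, vals,
        scope = st$scope, prop = st$prop
      )
    } else {
      harvested <- seq_len(n_ind(pop))
    }
    log[[i]] <- tibble::tibble(
      gen = st$gen, env = st$env, census = n_ind(pop),
      families = length(unique(pop$family)),
      selected = length(harvested), criterion = st$criterion
    )
    next_gen <- paste0("F", as.integer(sub("F", "", st$gen)) + 1L)
    size <- step_size(
      st$size_role, census, length(harvested),
      length(unique(pop$family[harvested]))
    )
    pop <- advance_generation(pop, harvested,
      advance = st$advance,
      size = size, generation = next_gen
    )
  }

  # F8 replicated field trial and final selection of the recycle set.
  # Where the program has produced distinct lines (families), the trial ranks
  # replicated family means and the best plant of each of the top n_parents
  # families is recycled; an unstructured bulk (mass selection) can only
  # offer single-plant values.
  fams <- unique(pop$family)
  if (length(fams) >= program$n_parents) {
    vals <- criterion_values(pop, "phenotype", program$final_env,
      reps = program$final_reps
    )
    fam_idx <- split(seq_len(n_ind(pop)), pop$family)
    fam_means <- vapply(fam_idx, function(ix) mean(vals[ix]), numeric(1))
    top <- order(-fam_means, runif(length(fam_idx)))[seq_len(program$n_parents)]
    sel <- vapply(fam_idx[top], function(ix) ix[which.max(vals[ix])], integer(1))
    sel <- sort(unname(sel))
  } else {
    # an unstructured bulk offers no line seed to replicate: single plants
    # are scored once
    vals <- criterion_values(pop, "phenotype", program$final_env, reps = 1)
    sel <- select_individuals(pop, vals,
      scope = "population",
      count = program$n_parents
    )
  }
  log[[length(log) + 1L]] <- tibble::tibble(
    gen = "F8", env = program$final_env, census = n_ind(pop),
    families = length(unique(pop$family)),
    selected = length(sel), criterion = "phenotype"
  )
  next_parents <- clone_progeny(pop, sel, generation = "P")
  next_parents$family <- sprintf("P%03d", seq_len(n_ind(next_parents)))
  list(parents = next_parents, log = dplyr::bind_rows(log))
}

# row-bind populations sharing a map
bind_pops <- function(pops, generation) {
  map <- pops[[1]]$map
  bean_pop(
    map,
    do.call(rbind, lapply(pops, `[[`, "hap1")),
    do.call(rbind, lapply(pops, `[[`, "hap2")),
    family = unlist(lapply(pops, `[[`, "family"), use.names = FALSE),
    generation = generation
  )
}
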