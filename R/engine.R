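#' Scenario grid configuration
#'
#' Describes a simulation experiment: the grid axes (traits, frameworks,
#' strategies, parental population sizes), the number of cycles and runs per
#' cell, and the master seed. Defaults mirror the full study grid: 10 cycles,
#' 50 runs, parents 15/30/60/100, all traits, frameworks and strategies.
#'
#' @param traits Subset of `c("DF", "WM", "SY")`.
#' @param frameworks Subset of `c("conventional", "speed", "gs")`.
#' @param strategies Subset of the five strategy names.
#' @param parents Parental population sizes (positive integers).
#' @param cycles Cycles per run (>= 1), default 10.
#' @param runs Runs per scenario (>= 1), default 50.
#' @param seed Master seed (integer).
#' @param profile A [sim_profile()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(traits = c("DF", "WM", "SY"),
                            frameworks = c("conventional", "speed", "gs"),
                            strategies = c(
                              "mass", "bulk", "ssd", "pedigree",
                              "modified_pedigree"
                            ),
                            parents = c(15, 30, 60, 100),
                            cycles = 10, runs = 50, seed = 1,
                            profile = sim_profile()) {
  check_subset <- function(x, allowed, what) {
    bad <- setdiff(x, allowed)
    if (length(bad)) {
      abort(paste0(
        "unknown ", what, ": ", paste(bad, collapse = ", "),
        " (allowed: ", paste(allowed, collapse = ", "), ")"
      ))
    }
    if (length(x) == 0) abort(paste0(what, " must be non-empty"))
    x
  }
  if (cycles < 1) abort("cycles must be >= 1")
  if (runs < 1) abort("runs must be >= 1")
  if (any(parents < 2)) abort("parents must be >= 2")
  structure(
    list(
      traits = check_subset(traits, c("DF", "WM", "SY"), "traits"),
      frameworks = check_subset(
        frameworks, c("conventional", "speed", "gs"), "frameworks"
      ),
      strategies = check_subset(strategies, c(
        "mass", "bulk", "ssd", "pedigree", "modified_pedigree"
      ), "strategies"),
      parents = as.integer(parents),
      cycles = as.integer(cycles),
      runs = as.integer(runs),
      seed = as.integer(seed),
      profile = profile
    ),
    class = "scenario_config"
  )
}

#' Read and validate a scenario configuration file
#'
#' YAML key-value file with any subset of the [scenario_config()] arguments
#' (plus an optional `profile:` block of [sim_profile()] arguments). Missing
#' keys take the full-grid defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  allowed <- c(
    "traits", "frameworks", "strategies", "parents", "cycles",
    "runs", "seed", "profile"
  )
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  prof <- if (!is.null(raw$profile)) {
    pa <- names(formals(sim_profile))
    badp <- setdiff(names(raw$profile), pa)
    if (length(badp)) {
      abort(paste0("unknown profile key(s): ", paste(badp, collapse = ", ")))
    }
    do.call(sim_profile, raw$profile)
  } else {
    sim_profile()
  }
  raw$profile <- NULL
  do.call(scenario_config, c(raw, list(profile = prof)))
}

# deterministic 31-bit seed from a master seed and a cell key
stable_seed <- function(master, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

#' Run a scenario grid
#'
#' Executes every cell of the configured grid. Per-run seeds are derived from
#' the master seed and the cell coordinates by a stable hash, so any cell can
#' be re-run independently with identical results; the founder burn-in and
#' parent sampling are seeded per (parents, run), so all strategies and
#' frameworks of a run start from the same initial parents (paired
#' comparisons). The map is the consensus-map emulator with the trait QTLs
#' inserted; its size comes from `n_markers`.
#'
#' @param config A [scenario_config()].
#' @param n_markers Marker count of the map emulator (default 1010; the test
#'   and acceptance profiles use a sparser panel for speed).
#' @param out_dir Optional directory: writes the four per-cycle metric CSVs
#'   (fit/fix/ham/var roles), the run-level snapshot table and a manifest.
#' @param quiet Suppress progress output.
#' @return A list of class `grid_result`: `cycles` (long tibble keyed by
#'   trait, framework, strategy, parents, run, cycle), `runs` (cycle-1
#'   snapshot per run, the PCA input), `summary` (per-scenario
#'   [gain_summary()] rows) and `config`.
#' @export
run_grid <- function(config, n_markers = 1010, out_dir = NULL, quiet = TRUE) {
  prof <- config$profile
  qtl <- load_qtl_table()
  archs <- setNames(
    lapply(config$traits, trait_architecture, qtl_table = qtl),
    config$traits
  )
  map <- consensus_map(n_markers = n_markers)
  map <- insert_qtl(map, unname(archs))
  h2 <- load_heritability_table()

  founder_cache <- new.env(parent = emptyenv())
  get_parents <- function(k, run) {
    key <- paste0("f", run)
    if (is.null(founder_cache[[key]])) {
      set.seed(stable_seed(config$seed, paste0("founders|", run)))
      founder_cache[[key]] <- burn_in_founders(
        map,
        n = max(prof$founder_n, max(config$parents)),
        generations = prof$founder_gens
      )
    }
    set.seed(stable_seed(config$seed, paste0("parents|", k, "|", run)))
    sample_parents(founder_cache[[key]], k)
  }

  cells <- tidyr::expand_grid(
    trait = config$traits, framework = config$frameworks,
    strategy = config$strategies, parents = config$parents
  )
  all_cycles <- list()
  all_summary <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (!quiet) {
      message(sprintf(
        "[%d/%d] %s %s %s %d parents", ci, nrow(cells), cell$trait,
        cell$framework, cell$strategy, cell$parents
      ))
    }
    for (run in seq_len(config$runs)) {
      par <- get_parents(cell$parents, run)
      cell_key <- paste(cell$trait, cell$framework, cell$strategy,
        cell$parents, run,
        sep = "|"
      )
      set.seed(stable_seed(config$seed, cell_key))
      sim <- tryCatch(
        simulate_breeding(par, archs[[cell$trait]], cell$strategy,
          framework = cell$framework, cycles = config$cycles,
          profile = prof, h2_table = h2
        ),
        error = function(e) e
      )
      if (inherits(sim, "error")) {
        warn(paste0("cell ", cell_key, " failed: ", conditionMessage(sim)))
        next
      }
      all_cycles[[length(all_cycles) + 1L]] <-
        dplyr::mutate(tidy(sim), run = run, .before = "cycle")
      all_summary[[length(all_summary) + 1L]] <-
        dplyr::mutate(glance(sim), run = run)
    }
  }
  cycles <- dplyr::bind_rows(all_cycles)
  runs <- cycles |>
    dplyr::filter(.data$cycle == 1L) |>
    dplyr::transmute(
      trait = .data$trait, framework = .data$framework,
      strategy = .data$strategy, parents = .data$parents, run = .data$run,
      gain = .data$adjusted_gain, hamming = .data$hamming,
      fixed_favorable = .data$fixed_favorable,
      additive_variance = .data$additive_variance, ne = .data$ne
    )
  out <- structure(
    list(
      cycles = cycles, runs = runs,
      summary = dplyr::bind_rows(all_summary), config = config
    ),
    class = "grid_result"
  )
  if (!is.null(out_dir)) write_grid_outputs(out, out_dir)
  out
}

write_grid_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  keys <- c("trait", "framework", "strategy", "parents", "run", "cycle")
  roles <- list(
    fit = c("adjusted_fitness", "adjusted_gain"),
    fix = c("fixed_favorable", "fixed_unfavorable"),
    ham = "hamming",
    var = c("additive_variance", "relative_variance")
  )
  for (nm in names(roles)) {
    readr::write_csv(
      result$cycles[, c(keys, roles[[nm]])],
      file.path(out_dir, paste0(nm, ".csv"))
    )
  }
  readr::write_csv(result$runs, file.path(out_dir, "runs.csv"))
  readr::write_csv(result$summary, file.path(out_dir, "gain_summary.csv"))
  cfg <- result$config
  manifest <- c(
    paste0("package: beansim ", as.character(utils::packageVersion("beansim"))),
    paste0("seed: ", cfg$seed),
    paste0("traits: ", paste(cfg$traits, collapse = ",")),
    paste0("frameworks: ", paste(cfg$frameworks, collapse = ",")),
    paste0("strategies: ", paste(cfg$strategies, collapse = ",")),
    paste0("parents: ", paste(cfg$parents, collapse = ",")),
    paste0("cycles: ", cfg$cycles),
    paste0("runs: ", cfg$runs),
    paste0("census: ", cfg$profile$census)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Principal component report of run-level statistics
#'
#' Standardizes the run-level statistics (zero mean, unit variance) and
#' decomposes them by PCA, following the run-as-point view of simulation
#' output immediately after the first cycle. Constant columns are dropped
#' with a warning.
#'
#' @param run_table A data frame with one row per run, e.g. the `runs`
#'   element of [run_grid()].
#' @param columns Statistic columns to decompose (default: the five
#'   run-level statistics present).
#' @return An object of class `beansim_pca`: `scores` (with any identifier
#'   columns carried along), `loadings`, and `variance` (proportion explained
#'   per component).
#' @export
pca_report <- function(run_table,
                       columns = intersect(
                         c(
                           "gain", "hamming", "fixed_favorable",
                           "additive_variance", "ne"
                         ),
                         names(run_table)
                       )) {
  x <- as.data.frame(run_table[, columns, drop = FALSE])
  keep_rows <- stats::complete.cases(x)
  x <- x[keep_rows, , drop = FALSE]
  if (nrow(x) < 3) abort("need at least 3 complete rows for a PCA")
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    warn(paste0(
      "dropping constant column(s): ",
      paste(names(x)[const], collapse = ", ")
    ))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) abort("need at least 2 non-constant columns")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  ids <- run_table[keep_rows, setdiff(names(run_table), columns), drop = FALSE]
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::as_tibble(ids),
        tibble::as_tibble(fit$x)
      ),
      loadings = dplyr::bind_cols(
        tibble::tibble(statistic = rownames(fit$rotation)),
        tibble::as_tibble(fit$rotation)
      ),
      variance = tibble::tibble(
        component = colnames(fit$x),
        sdev = fit$sdev,
        proportion = fit$sdev^2 / sum(fit$sdev^2)
      )
    ),
    class = "beansim_pca"
  )
}

#' @export
print.beansim_pca <- function(x, ...) {
  cat(
    "<beansim_pca> ", nrow(x$scores), " runs, ", nrow(x$loadings),
    " statistics; PC1+PC2 explain ",
    sprintf("%.1f%%", 100 * sum(x$variance$proportion[1:2])), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname pca_report
#' @param x A `beansim_pca`.
#' @param ... Unused.
#' @return `tidy()`: the loadings in long form; `glance()`: one row with the
#'   variance explained by the first two components.
#' @method tidy beansim_pca
#' @export
tidy.beansim_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"statistic",
    names_to = "component", values_to = "loading"
  )
}

#' @rdname pca_report
#' @method glance beansim_pca
#' @export
glance.beansim_pca <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$variance),
    prop_pc1 = x$variance$proportion[1],
    prop_pc12 = sum(x$variance$proportion[1:2])
  )
}
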