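#' Full diallel crossing plan
#'
#' All `k(k-1)/2` unordered parent pairs, selfs excluded and reciprocals
#' collapsed (under selfing reproduction, reciprocal crosses are genetically
#' identical).
#'
#' @param parents A [bean_pop()] of parents, or an integer parent count.
#' @param f1_per_cross F1 family size per cross.
#' @return A tibble `p1`, `p2`, `n` — the crossing plan.
#' @export
diallel_crosses <- function(parents, f1_per_cross = 1) {
  k <- if (inherits(parents, "bean_pop")) n_ind(parents) else as.integer(parents)
  if (k < 2) abort("a diallel needs at least 2 parents")
  cmb <- utils::combn(k, 2)
  tibble::tibble(p1 = cmb[1, ], p2 = cmb[2, ], n = as.integer(f1_per_cross))
}

#' Truncation selection within a scope
#'
#' Selects the top fraction (or count) of candidates on a per-individual
#' criterion, within the stated scope:
#' * `"population"` — truncation over all candidates;
#' * `"among_family"` — whole families ranked by family mean, top families kept;
#' * `"within_family"` — top fraction within each family;
#' * `"among_within"` — among-family then within-family truncation (each at
#'   `sqrt(prop)` so the overall selected fraction is about `prop`).
#'
#' Given the criterion values the result is deterministic; exact ties are
#' broken by a draw from the session RNG. At least one individual (or family)
#' always survives a proportional selection.
#'
#' @param pop A [bean_pop()].
#' @param values Numeric criterion, one per individual; larger is better.
#' @param scope Selection scope, see above.
#' @param prop Selected proportion in `(0, 1]` (used unless `count` given).
#' @param count Selected count (population scope only).
#' @return Integer indices of the selected individuals.
#' @export
select_individuals <- function(pop, values,
                               scope = c(
                                 "population", "among_family",
                                 "within_family", "among_within"
                               ),
                               prop = NULL, count = NULL) {
  scope <- match.arg(scope)
  n <- n_ind(pop)
  if (length(values) != n) abort("criterion must be defined for all candidates")
  tie <- runif(n)
  top_k <- function(idx, k) idx[order(-values[idx], tie[idx])][seq_len(k)]
  if (scope == "population") {
    k <- if (!is.null(count)) count else max(1L, floor(prop * n))
    if (k > n) abort(paste0("requested ", k, " individuals from ", n, " candidates"))
    return(sort(top_k(seq_len(n), k)))
  }
  fam <- split(seq_len(n), pop$family)
  fam_prop <- switch(scope,
    among_family = prop, within_family = 1, among_within = sqrt(prop)
  )
  ind_prop <- switch(scope,
    among_family = 1, within_family = prop, among_within = sqrt(prop)
  )
  fam_means <- vapply(fam, function(ix) mean(values[ix]), numeric(1))
  nf_keep <- max(1L, floor(fam_prop * length(fam)))
  fam_tie <- runif(length(fam))
  keep_f <- order(-fam_means, fam_tie)[seq_len(nf_keep)]
  out <- unlist(lapply(fam[keep_f], function(ix) {
    top_k(ix, max(1L, floor(ind_prop * length(ix))))
  }), use.names = FALSE)
  sort(out)
}

#' Advance a generation
#'
#' Produces the next selfed generation from the harvested plants under one of
#' the generation-advance modes:
#' * `"pedigree"` — each harvested plant founds its own family, contributing
#'   `size` selfed offspring;
#' * `"bulk"` — seed is pooled within families (family labels preserved); each
#'   surviving family is regrown to `size` plants whose seed parents are drawn
#'   from the family's harvested plants;
#' * `"superbulk"` — all seed pooled into a single family; `size` is the total
#'   census of the next generation;
#' * `"single_seed"` — exactly one selfed seed per harvested plant (single
#'   seed descent), family labels preserved.
#'
#' @param pop Current [bean_pop()].
#' @param harvested Indices of harvested plants (default: all).
#' @param advance Advance mode, see above.
#' @param size Per-plant, per-family or total size depending on mode.
#' @param generation Generation tag of the offspring.
#' @return A [bean_pop()] for the next generation.
#' @export
advance_generation <- function(pop, harvested = seq_len(n_ind(pop)),
                               advance = c(
                                 "pedigree", "bulk", "superbulk",
                                 "single_seed"
                               ),
                               size = 1, generation = "F?") {
  advance <- match.arg(advance)
  if (length(harvested) == 0) {
    abort("no plants harvested: strategy misconfiguration")
  }
  if (advance == "single_seed") {
    out <- self_progeny(pop, harvested, family = pop$family[harvested],
      generation = generation
    )
    return(out)
  }
  if (advance == "pedigree") {
    size <- max(1L, as.integer(round(size)))
    parent_idx <- rep(harvested, each = size)
    fam <- rep(sprintf("%s.%s", pop$generation, pop$id[harvested]), each = size)
    return(self_progeny(pop, parent_idx, family = fam, generation = generation))
  }
  if (advance == "bulk") {
    size <- max(1L, as.integer(round(size)))
    fams <- split(harvested, pop$family[harvested])
    parent_idx <- unlist(lapply(fams, function(ix) {
      ix[sample.int(length(ix), size, replace = TRUE)]
    }), use.names = FALSE)
    fam <- rep(names(fams), each = size)
    return(self_progeny(pop, parent_idx, family = fam, generation = generation))
  }
  # superbulk: one pooled population
  size <- max(1L, as.integer(round(size)))
  parent_idx <- harvested[sample.int(length(harvested), size, replace = TRUE)]
  self_progeny(pop, parent_idx, family = "bulk", generation = generation)
}
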