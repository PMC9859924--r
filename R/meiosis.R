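# Recombination fractions between adjacent loci; 0.5 across group boundaries,
# Haldane within groups. First element is the (irrelevant) fraction "before"
# locus 1, set to 0.5 so the starting haplotype is chosen uniformly.
adjacent_recomb <- function(map) {
  L <- nrow(map)
  r <- numeric(L)
  r[1] <- 0.5
  if (L > 1) {
    d <- diff(map$position_cM)
    same <- diff(map$group) == 0L
    r[-1] <- ifelse(same, haldane_r(pmax(d, 0)), 0.5)
  }
  r
}

#' Generate gametes by simulated meiosis
#'
#' Performs meiosis under the Haldane (no-interference) model: along each
#' linkage group the transmitted haplotype follows a Markov walk that switches
#' between the parent's two haplotypes with probability [haldane_r()] of the
#' inter-locus distance; linkage groups assort independently. Uses the session
#' RNG (`set.seed()` for reproducibility).
#'
#' `make_gametes()` draws one gamete per entry of `parent_idx` (indices may
#' repeat); `make_gamete()` is the single-gamete convenience wrapper.
#'
#' @param pop A [bean_pop()].
#' @param parent_idx Integer vector of parent row indices, one gamete each.
#' @return An integer 0/1 matrix with one gamete per row (`make_gametes`), or
#'   a single 0/1 vector (`make_gamete`).
#' @export
make_gametes <- function(pop, parent_idx) {
  L <- ncol(pop$hap1)
  n <- length(parent_idx)
  r <- adjacent_recomb(pop$map)
  # switch indicators, then cumulative parity = which haplotype is tracked
  state <- matrix(FALSE, n, L)
  s <- runif(n) < r[1]
  state[, 1] <- s
  if (L > 1) {
    for (j in 2:L) {
      s <- xor(s, runif(n) < r[j])
      state[, j] <- s
    }
  }
  h1 <- pop$hap1[parent_idx, , drop = FALSE]
  h2 <- pop$hap2[parent_idx, , drop = FALSE]
  g <- h1
  g[state] <- h2[state]
  g
}

#' @rdname make_gametes
#' @param i Single parent index.
#' @export
make_gamete <- function(pop, i) {
  drop(make_gametes(pop, i))
}

#' Cross, self, or clone individuals
#'
#' `make_cross()` produces `n` offspring of one parent pair (each offspring =
#' one independent gamete from each parent). `self_progeny()` produces selfed
#' offspring, one per entry of `parent_idx` (both gametes drawn from the same
#' plant by independent meioses). `clone_progeny()` copies individuals
#' unchanged, the "clone" propagation used to migrate parents between breeding
#' cycles.
#'
#' @param pop A [bean_pop()].
#' @param p1,p2 Parent row indices. Equal indices amount to selfing.
#' @param n Number of offspring.
#' @param family Family label(s) for the offspring.
#' @param generation Generation tag for the offspring.
#' @return A [bean_pop()] of offspring.
#' @export
make_cross <- function(pop, p1, p2, n = 1, family = paste0(p1, "x", p2),
                       generation = "F1") {
  if (n < 1) abort("n must be >= 1")
  bean_pop(pop$map,
    make_gametes(pop, rep(p1, n)),
    make_gametes(pop, rep(p2, n)),
    family = family, generation = generation
  )
}

#' @rdname make_cross
#' @param parent_idx Parent row indices, one offspring per entry.
#' @export
self_progeny <- function(pop, parent_idx, family = pop$family[parent_idx],
                         generation = pop$generation) {
  bean_pop(pop$map,
    make_gametes(pop, parent_idx),
    make_gametes(pop, parent_idx),
    family = family, generation = generation
  )
}

#' @rdname make_cross
#' @export
clone_progeny <- function(pop, parent_idx, generation = pop$generation) {
  pop_subset(pop, parent_idx, generation = generation)
}
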