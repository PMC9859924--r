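# Small in-code fixtures shared across the suite.

# a two-group toy map: positions in cM
toy_map <- function(pos1 = c(0, 20, 50), pos2 = c(0, 30)) {
  linkage_map(
    locus_id = c(paste0("a", seq_along(pos1)), paste0("b", seq_along(pos2))),
    group = c(rep(1L, length(pos1)), rep(2L, length(pos2))),
    position_cM = c(pos1, pos2)
  )
}

# population from explicit haplotype rows (lists of 0/1 vectors)
pop_from_haps <- function(map, hap1_rows, hap2_rows, family = "0") {
  bean_pop(map,
    do.call(rbind, hap1_rows), do.call(rbind, hap2_rows),
    family = family
  )
}

# n fully heterozygous individuals (hap1 all 1, hap2 all 0)
het_pop <- function(map, n = 1) {
  L <- nrow(map)
  bean_pop(map, matrix(1L, n, L), matrix(0L, n, L))
}

# single-QTL architecture with effect s at the only locus of a 1-locus map
one_qtl_arch <- function(s, direction = "maximize", trait = "SY") {
  tbl <- tibble::tibble(
    trait = trait, qtl_name = "Q1", linkage_group = 1L,
    position_cM = 0, effect_size = s, population = "toy", reference = "toy"
  )
  trait_architecture(trait, qtl_table = tbl, direction = direction)
}

one_qtl_map <- function() {
  linkage_map("Q1", 1L, 0, kind = "qtl")
}

# random biallelic population at given allele frequency
random_pop <- function(map, n, p = 0.5) {
  L <- nrow(map)
  bean_pop(map,
    matrix(rbinom(n * L, 1L, p), n, L),
    matrix(rbinom(n * L, 1L, p), n, L)
  )
}

# the reduced map used for engine-level tests: sparse marker panel with the
# three trait architectures inserted
reduced_map <- function(n_markers = 110) {
  archs <- lapply(c("DF", "WM", "SY"), trait_architecture)
  insert_qtl(consensus_map(n_markers = n_markers), archs)
}
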