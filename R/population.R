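#' Construct a phased diploid population
#'
#' A `bean_pop` stores phased biallelic genotypes for a set of individuals as
#' two 0/1 haplotype matrices (rows = individuals, columns = loci in map
#' order), together with family labels and a generation tag. All breeding
#' machinery — meiosis, crossing, selfing, selection, metrics — operates on
#' this container.
#'
#' @param map A [linkage_map()].
#' @param hap1,hap2 Integer matrices of 0/1 alleles, one row per individual,
#'   one column per map locus.
#' @param family Character vector of family labels (recycled).
#' @param generation Single generation tag, e.g. `"F2"`.
#' @param id Optional character individual ids.
#' @return An object of class `bean_pop`.
#' @export
bean_pop <- function(map, hap1, hap2, family = "0", generation = "F0",
                     id = NULL) {
  hap1 <- as.matrix(hap1)
  hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2))) abort("haplotype matrices differ in shape")
  if (ncol(hap1) != nrow(map)) {
    abort(paste0(
      "haplotype length (", ncol(hap1), ") does not match map locus count (",
      nrow(map), ")"
    ))
  }
  if (length(hap1) && !all(hap1 %in% c(0L, 1L) & hap2 %in% c(0L, 1L))) {
    abort("alleles must be 0 or 1")
  }
  n <- nrow(hap1)
  structure(
    list(
      map = map,
      hap1 = hap1,
      hap2 = hap2,
      family = rep_len(as.character(family), n),
      generation = as.character(generation)[1],
      id = if (is.null(id)) sprintf("i%06d", seq_len(n)) else as.character(id)
    ),
    class = "bean_pop"
  )
}

#' @rdname bean_pop
#' @param pop A `bean_pop`.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

#' @export
print.bean_pop <- function(x, ...) {
  cat(
    "<bean_pop> ", n_ind(x), " individuals (", x$generation, "), ",
    length(unique(x$family)), " families, ", ncol(x$hap1), " loci\n",
    sep = ""
  )
  invisible(x)
}

#' Subset or clone individuals
#'
#' `pop_subset()` keeps the given individuals (genotype-preserving "clone"
#' semantics, as used to migrate selected lines between breeding cycles).
#'
#' @param pop A [bean_pop()].
#' @param idx Integer indices of individuals to keep.
#' @param generation Optional new generation tag.
#' @return A [bean_pop()].
#' @export
pop_subset <- function(pop, idx, generation = pop$generation) {
  bean_pop(pop$map, pop$hap1[idx, , drop = FALSE], pop$hap2[idx, , drop = FALSE],
    family = pop$family[idx], generation = generation, id = pop$id[idx]
  )
}

#' Genotype dosage matrix
#'
#' Counts of the `1` allele per individual and locus (0, 1 or 2).
#'
#' @param pop A [bean_pop()].
#' @param loci Optional character vector of locus ids (default: all loci).
#' @return Integer matrix, individuals by loci.
#' @export
geno_dosage <- function(pop, loci = NULL) {
  d <- pop$hap1 + pop$hap2
  colnames(d) <- pop$map$locus_id
  if (!is.null(loci)) {
    missing <- setdiff(loci, pop$map$locus_id)
    if (length(missing)) {
      abort(paste0("loci absent from map: ", paste(head(missing, 5), collapse = ", ")))
    }
    d <- d[, loci, drop = FALSE]
  }
  d
}

#' Export phased genotypes as TSV
#'
#' Writes one row per individual with `"a|b"` phased allele pairs per locus,
#' preceded by `id` and `family` columns.
#'
#' @param pop A [bean_pop()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path) {
  cells <- matrix(paste0(pop$hap1, "|", pop$hap2), nrow = n_ind(pop))
  colnames(cells) <- pop$map$locus_id
  tbl <- dplyr::bind_cols(
    tibble::tibble(id = pop$id, family = pop$family),
    tibble::as_tibble(cells)
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Observed and expected heterozygosity
#'
#' `observed_heterozygosity()` is the mean, over individuals and loci, of the
#' indicator that the two alleles differ. `expected_heterozygosity()` (gene
#' diversity) is the mean over loci of \eqn{2p(1-p)} computed from allele
#' frequencies; it is the quantity whose generation-to-generation decay drives
#' the effective-population-size estimator.
#'
#' @param pop A [bean_pop()].
#' @param loci Optional locus id subset.
#' @return Scalar in `[0, 0.5]` (expected) or `[0, 1]` (observed).
#' @export
expected_heterozygosity <- function(pop, loci = NULL) {
  d <- geno_dosage(pop, loci)
  p <- colMeans(d) / 2
  mean(2 * p * (1 - p))
}

#' @rdname expected_heterozygosity
#' @export
observed_heterozygosity <- function(pop, loci = NULL) {
  h <- pop$hap1 != pop$hap2
  colnames(h) <- pop$map$locus_id
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  mean(h)
}
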