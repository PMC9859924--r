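#' Construct a linkage map
#'
#' A linkage map is a tibble of loci ordered by linkage group and genetic
#' position, with one row per locus. It is the recombination substrate for all
#' meiosis in the simulator: recombination fractions between adjacent loci are
#' derived from their cM distance via [haldane_r()], and loci on different
#' groups assort independently.
#'
#' @param locus_id Character vector of unique locus identifiers.
#' @param group Integer vector of linkage-group indices (1-based).
#' @param position_cM Numeric genetic positions within group, in centimorgans.
#'   Must be non-decreasing within each group and non-negative.
#' @param kind `"marker"` or `"qtl"` per locus.
#' @param group_length Optional named numeric vector of nominal group lengths
#'   (cM). Defaults to the maximum position observed per group.
#'
#' @return A tibble with class `linkage_map` and columns `locus_id`, `group`,
#'   `position_cM`, `kind`, carrying a `group_length` attribute.
#' @seealso [consensus_map()], [read_linkage_map()], [insert_qtl()]
#' @export
linkage_map <- function(locus_id, group, position_cM, kind = "marker",
                        group_length = NULL) {
  tbl <- tibble::tibble(
    locus_id = as.character(locus_id),
    group = as.integer(group),
    position_cM = as.numeric(position_cM),
    kind = rep_len(as.character(kind), length(locus_id))
  )
  tbl <- dplyr::arrange(tbl, .data$group, .data$position_cM)
  if (is.null(group_length)) {
    group_length <- tapply(tbl$position_cM, tbl$group, max)
    group_length <- setNames(as.numeric(group_length), names(group_length))
  }
  map <- structure(tbl,
    class = c("linkage_map", class(tbl)),
    group_length = group_length
  )
  validate_linkage_map(map)
  map
}

validate_linkage_map <- function(map) {
  if (nrow(map) < 1L) abort("a linkage map needs at least one locus")
  if (anyDuplicated(map$locus_id)) {
    dup <- unique(map$locus_id[duplicated(map$locus_id)])
    abort(paste0("duplicate locus_id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(map$position_cM < 0)) abort("locus positions must be >= 0")
  if (!all(map$kind %in% c("marker", "qtl"))) {
    abort("locus kind must be 'marker' or 'qtl'")
  }
  for (g in unique(map$group)) {
    pos <- map$position_cM[map$group == g]
    if (is.unsorted(pos)) {
      abort(paste0("positions not sorted within linkage group ", g))
    }
  }
  invisible(map)
}

#' Map-level summaries
#'
#' `map_length()` is the total genetic length (sum of nominal group lengths);
#' `n_loci()` counts loci, optionally by kind.
#'
#' @param map A [linkage_map()].
#' @param kind Optional locus kind filter (`"marker"` or `"qtl"`).
#' @return A scalar numeric (length in cM) or integer count.
#' @export
map_length <- function(map) {
  sum(attr(map, "group_length"))
}

#' @rdname map_length
#' @export
n_loci <- function(map, kind = NULL) {
  if (is.null(kind)) nrow(map) else sum(map$kind == kind)
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans into a recombination fraction
#' under the Haldane (no-interference) model,
#' \eqn{r = (1 - e^{-2d/100}) / 2}.
#'
#' @param distance_cM Non-negative genetic distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 10, 50))
#' @export
haldane_r <- function(distance_cM) {
  if (any(distance_cM < 0)) abort("map distances must be >= 0")
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

#' Emulate the dry-bean consensus linkage map
#'
#' Builds a marker map with the summary statistics of the Mesoamerican
#' consensus map used for the simulations: by default 1010 markers on
#' 11 linkage groups totalling 2041 cM. Group lengths are equal
#' (`total_length / n_groups`) and markers are spread evenly over each group
#' (or placed uniformly at random with `placement = "random"`, using the
#' session RNG). Marker counts are allocated as evenly as possible across
#' groups, the remainder going to the lowest-numbered groups.
#'
#' @param n_markers Total marker count (default 1010).
#' @param n_groups Number of linkage groups (default 11).
#' @param total_length Total map length in cM (default 2041).
#' @param placement `"even"` (deterministic) or `"random"`.
#' @return A [linkage_map()] of `n_markers` marker loci.
#' @examples
#' map <- consensus_map()
#' n_loci(map)
#' map_length(map)
#' @export
consensus_map <- function(n_markers = 1010, n_groups = 11,
                          total_length = 2041,
                          placement = c("even", "random")) {
  placement <- match.arg(placement)
  if (n_markers < n_groups) abort("need at least one marker per linkage group")
  if (total_length <= 0) abort("total_length must be positive")
  per <- rep(n_markers %/% n_groups, n_groups)
  extra <- n_markers %% n_groups
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  glen <- total_length / n_groups
  pieces <- lapply(seq_len(n_groups), function(g) {
    m <- per[g]
    pos <- if (placement == "even") {
      if (m == 1L) glen / 2 else seq(0, glen, length.out = m)
    } else {
      sort(runif(m, 0, glen))
    }
    tibble::tibble(
      locus_id = sprintf("M%02d_%03d", g, seq_len(m)),
      group = g,
      position_cM = pos,
      kind = "marker"
    )
  })
  tbl <- dplyr::bind_rows(pieces)
  linkage_map(tbl$locus_id, tbl$group, tbl$position_cM, tbl$kind,
    group_length = setNames(rep(glen, n_groups), seq_len(n_groups))
  )
}

#' Insert QTL loci into a map at their published coordinates
#'
#' Adds the QTL loci of one or more trait architectures (or a raw QTL tibble)
#' to a marker map at their printed (linkage group, cM) coordinates. A QTL
#' lying beyond its group's nominal length extends the group, with a warning.
#'
#' @param map A [linkage_map()].
#' @param qtl A tibble with columns `locus_id` (or `qtl_name`), `group` (or
#'   `linkage_group`) and `position_cM`, or a [trait_architecture()] /
#'   list of them.
#' @return The map with the QTL loci inserted (`kind = "qtl"`).
#' @export
insert_qtl <- function(map, qtl) {
  qtl <- qtl_coords(qtl)
  glen <- attr(map, "group_length")
  for (i in seq_len(nrow(qtl))) {
    g <- as.character(qtl$group[i])
    if (!g %in% names(glen)) {
      abort(paste0("QTL ", qtl$locus_id[i], " targets unknown linkage group ", g))
    }
    if (qtl$position_cM[i] > glen[[g]] + 1e-9) {
      warn(paste0(
        "QTL ", qtl$locus_id[i], " at ", qtl$position_cM[i],
        " cM extends linkage group ", g, " beyond ", signif(glen[[g]], 6), " cM"
      ))
      glen[[g]] <- qtl$position_cM[i]
    }
  }
  tbl <- dplyr::bind_rows(
    map[, c("locus_id", "group", "position_cM", "kind")],
    tibble::tibble(
      locus_id = qtl$locus_id, group = as.integer(qtl$group),
      position_cM = qtl$position_cM, kind = "qtl"
    )
  )
  linkage_map(tbl$locus_id, tbl$group, tbl$position_cM, tbl$kind,
    group_length = glen
  )
}

# normalise the accepted QTL inputs to locus_id/group/position_cM
qtl_coords <- function(qtl) {
  if (inherits(qtl, "trait_architecture")) qtl <- list(qtl)
  if (is.list(qtl) && !is.data.frame(qtl) &&
    all(vapply(qtl, inherits, logical(1), "trait_architecture"))) {
    qtl <- dplyr::bind_rows(lapply(qtl, function(a) a$qtl))
  }
  if (!is.data.frame(qtl)) abort("qtl must be a data frame or trait architecture(s)")
  nm <- names(qtl)
  id <- if ("locus_id" %in% nm) qtl$locus_id else qtl$qtl_name
  grp <- if ("group" %in% nm) qtl$group else qtl$linkage_group
  out <- tibble::tibble(
    locus_id = as.character(id), group = as.integer(grp),
    position_cM = as.numeric(qtl$position_cM)
  )
  dplyr::distinct(out)
}

#' Read / write a linkage map as TSV
#'
#' The interchange format is a UTF-8 tab-delimited file with a header line and
#' columns `locus_id`, `group`, `position_cM`, `kind`. Writing then reading a
#' map reproduces it exactly (up to the nominal group lengths, which are
#' stored as a `#group_length:` comment line).
#'
#' @param path File path.
#' @param map A [linkage_map()].
#' @return `read_linkage_map()` returns a [linkage_map()];
#'   `write_linkage_map()` returns `path` invisibly.
#' @export
read_linkage_map <- function(path) {
  first <- readLines(path, n = 1L)
  glen <- NULL
  skip <- 0L
  if (startsWith(first, "#group_length:")) {
    vals <- strsplit(sub("^#group_length:", "", first), ",", fixed = TRUE)[[1]]
    kv <- strsplit(vals, "=", fixed = TRUE)
    glen <- setNames(
      vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
      vapply(kv, function(x) x[1], character(1))
    )
    skip <- 1L
  }
  tbl <- readr::read_tsv(path,
    skip = skip, show_col_types = FALSE,
    col_types = readr::cols(
      locus_id = readr::col_character(),
      group = readr::col_integer(),
      position_cM = readr::col_double(),
      kind = readr::col_character()
    )
  )
  for (g in unique(tbl$group)) {
    pos <- tbl$position_cM[tbl$group == g]
    if (is.unsorted(pos)) {
      line <- which(tbl$group == g)[which(diff(pos) < 0)[1] + 1L] + 1L + skip
      abort(paste0(
        "positions not sorted in linkage group ", g,
        " (file line ", line, ")"
      ))
    }
  }
  linkage_map(tbl$locus_id, tbl$group, tbl$position_cM, tbl$kind,
    group_length = glen
  )
}

#' @rdname read_linkage_map
#' @export
write_linkage_map <- function(map, path) {
  glen <- attr(map, "group_length")
  header <- paste0(
    "#group_length:",
    paste(names(glen), signif(glen, 12), sep = "=", collapse = ",")
  )
  writeLines(header, path, useBytes = TRUE)
  readr::write_tsv(tibble::as_tibble(map)[, c(
    "locus_id", "group",
    "position_cM", "kind"
  )], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(
    "<linkage_map> ", nrow(x), " loci (", sum(x$kind == "marker"),
    " markers, ", sum(x$kind == "qtl"), " QTLs), ",
    length(unique(x$group)), " groups, ",
    signif(map_length(x), 6), " cM\n",
    sep = ""
  )
  NextMethod()
}
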