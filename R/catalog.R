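#' Load the packaged rotamer catalog
#'
#' The catalog holds, for each of the 46 consensus RNA backbone suite
#' rotamers, a 2-character id, the seven mean suite torsions
#' (delta(i-1), epsilon(i-1), zeta(i-1), alpha, beta, gamma, delta(i)) in
#' degrees on \[0, 360), seven circular standard deviations, and an observed
#' frequency.  The packaged asset is a synthetic stand-in: the ids and the
#' four printed representative rows (1a, 1b, 2a, 2\[) are the published
#' values, the remaining rows are constructed values consistent with the
#' pucker-family structure (see the asset header and the methods vignette).
#'
#' @param path Path to a delimited rotamer table.  Defaults to the packaged
#'   synthetic catalog.
#' @return A data.frame with columns `rotamer_id`, mean torsions
#'   `d1,e1,z1,a,b,g,d2`, spreads `sd_*`, and `frequency`.
#' @export
#' @examples
#' cat46 <- load_catalog()
#' nrow(cat46)
#' rotamer_means(cat46, "1a")
load_catalog <- function(path = rotasuite_file("rotamer_table_synthetic.tsv")) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  tab <- read_hash_commented(path)
  need <- c("rotamer_id", torsion_cols(), paste0("sd_", torsion_cols()),
            "frequency")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("catalog is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$rotamer_id))
    stop("catalog integrity: duplicate rotamer_id")
  if (nrow(tab) != 46L)
    stop("catalog integrity: expected 46 rotamers, got ", nrow(tab))
  ang <- as.matrix(tab[, torsion_cols()])
  if (any(!is.finite(ang)) || any(ang < 0 | ang >= 360))
    stop("catalog integrity: torsions must lie in [0, 360)")
  if (any(as.matrix(tab[, paste0("sd_", torsion_cols())]) <= 0))
    stop("catalog integrity: spreads must be positive")
  if (sum(tab$frequency) <= 0)
    stop("catalog integrity: frequencies must sum to a positive total")
  tab <- tab[order(tab$rotamer_id), , drop = FALSE]
  rownames(tab) <- tab$rotamer_id
  class(tab) <- c("rotamer_catalog", "data.frame")
  tab
}

#' Load the rotamer-to-family map
#'
#' Seven grouping schemes over the 46 rotamers: `dd_ag` (22 families,
#' delta/delta/alpha/gamma), `dd_a` (10), `dd_g` (10), `ag` (7), `dd`
#' (4, the ribose pucker pairs), `A_noA` (A-form helix rotamer 1a vs the
#' rest) and `Astar_noA` (A-form-related rotamers vs the rest).  Labels are
#' the published single characters, stored verbatim.
#'
#' @param path Path to a delimited family map; defaults to the packaged one.
#' @return A data.frame with column `rotamer_id` plus one column per scheme.
#' @export
load_family_map <- function(path = rotasuite_file("family_map.tsv")) {
  if (!file.exists(path)) stop("family map file not found: ", path)
  fm <- read_hash_commented(path)
  miss <- setdiff(c("rotamer_id", family_schemes()), names(fm))
  if (length(miss)) stop("family map is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(fm) != 46L || anyDuplicated(fm$rotamer_id))
    stop("family map integrity: need 46 unique rotamer ids")
  fm[order(fm$rotamer_id), , drop = FALSE]
}

#' @export
#' @rdname load_family_map
family_schemes <- function() {
  c("dd_ag", "dd_a", "dd_g", "ag", "dd", "A_noA", "Astar_noA")
}

#' Family label of a rotamer under a grouping scheme
#'
#' @param rotamer_id Character vector of rotamer ids (e.g. "1a").  The
#'   pseudo-scheme `"rotamer"` returns the id itself, so classification code
#'   can treat the 46-rotamer task as just another labelling.
#' @param scheme_id One of [family_schemes()] or `"rotamer"`.
#' @param family_map As returned by [load_family_map()].
#' @return Character vector of single-character family labels.
#' @export
#' @examples
#' family_of("1a", "dd")
#' family_of(c("1a", "3d"), "A_noA")
family_of <- function(rotamer_id, scheme_id,
                      family_map = load_family_map()) {
  if (identical(scheme_id, "rotamer")) {
    bad <- setdiff(rotamer_id, family_map$rotamer_id)
    if (length(bad)) stop("unknown rotamer id(s): ",
                          paste(bad, collapse = ", "))
    return(rotamer_id)
  }
  if (!scheme_id %in% family_schemes())
    stop("unknown family scheme: ", scheme_id)
  idx <- match(rotamer_id, family_map$rotamer_id)
  if (anyNA(idx)) stop("unknown rotamer id(s): ",
                       paste(rotamer_id[is.na(idx)], collapse = ", "))
  family_map[[scheme_id]][idx]
}

#' Number of distinct families in a scheme
#'
#' @inheritParams family_of
#' @return Integer count of distinct labels in the scheme's column.
#' @export
#' @examples
#' count_families("dd")     # 4 pucker-pair families
#' count_families("dd_ag")  # 22
count_families <- function(scheme_id, family_map = load_family_map()) {
  if (identical(scheme_id, "rotamer")) return(nrow(family_map))
  if (!scheme_id %in% family_schemes())
    stop("unknown family scheme: ", scheme_id)
  length(unique(family_map[[scheme_id]]))
}

#' Mean torsions of one catalog rotamer
#'
#' @param catalog As returned by [load_catalog()].
#' @param rotamer_id Single rotamer id.
#' @return Named numeric vector of 7 torsions in degrees.
#' @export
rotamer_means <- function(catalog, rotamer_id) {
  i <- match(rotamer_id, catalog$rotamer_id)
  if (is.na(i)) stop("unknown rotamer id: ", rotamer_id)
  unlist(catalog[i, torsion_cols()])
}

#' @rdname rotamer_means
#' @export
rotamer_spreads <- function(catalog, rotamer_id) {
  i <- match(rotamer_id, catalog$rotamer_id)
  if (is.na(i)) stop("unknown rotamer id: ", rotamer_id)
  x <- unlist(catalog[i, paste0("sd_", torsion_cols())])
  names(x) <- torsion_cols()
  x
}

# ---- internal helpers -----------------------------------------------------

torsion_cols <- function() c("d1", "e1", "z1", "a", "b", "g", "d2")

nucleus_cols <- function() c("C1p", "C2p", "C3p", "C4p", "C5p")

rotasuite_file <- function(...) {
  system.file("extdata", ..., package = "rotasuite", mustWork = FALSE)
}

# Reads a TSV whose header comments start with "# " (rotamer id "#a" makes
# plain comment.char = "#" unusable).
read_hash_commented <- function(path) {
  lns <- readLines(path)
  lns <- lns[!grepl("^# ", lns)]
  utils::read.delim(text = paste(lns, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
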