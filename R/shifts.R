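#' Reference schemes for converting shieldings to chemical shifts
#'
#' A computed isotropic shielding sigma_comp becomes a theoretical chemical
#' shift by subtraction from a reference shielding,
#' delta_comp = sigma_ref - sigma_comp.  The `simple` scheme uses the
#' single scalar sigma_ref = 185.00 ppm (close to the theoretical TMS
#' shielding); `by_sequence`, `by_pucker_family` and `by_nucleus` hold a
#' lookup table of effective references per context cell; `regression`
#' maps sigma to delta through a fitted line.
#'
#' @param sigma_ref Scalar reference shielding in ppm.
#' @return A `reference_scheme` list.
#' @export
#' @examples
#' reference_shift(0, simple_reference())        # 185.00
#' reference_shift(185, simple_reference())      # 0
simple_reference <- function(sigma_ref = 185.00) {
  structure(list(kind = "simple", sigma_ref = sigma_ref),
            class = "reference_scheme")
}

#' Convert shieldings to shifts under a reference scheme
#'
#' @param sigma_comp Numeric vector of computed shieldings (ppm).
#' @param scheme A `reference_scheme` (see [simple_reference()],
#'   [fit_effective_reference()]).
#' @param context For lookup kinds, a character vector (recycled) naming
#'   the context cell of each value: the nucleus (`by_nucleus`), the DN
#'   sequence (`by_sequence`) or the dd family (`by_pucker_family`).
#' @return Chemical shifts in ppm.
#' @export
reference_shift <- function(sigma_comp, scheme, context = NULL) {
  stopifnot(inherits(scheme, "reference_scheme"))
  if (scheme$kind == "simple")
    return(scheme$sigma_ref - sigma_comp)
  if (scheme$kind == "regression")
    return(scheme$intercept + scheme$slope * sigma_comp)
  if (is.null(context))
    stop("reference-resolution error: scheme '", scheme$kind,
         "' needs a context")
  context <- rep_len(as.character(context), length(sigma_comp))
  ref <- scheme$table[context]
  if (anyNA(ref)) {
    if (is.null(scheme$fallback))
      stop("reference-resolution error: no reference for context(s) ",
           paste(unique(context[is.na(ref)]), collapse = ", "))
    ref[is.na(ref)] <- scheme$fallback
  }
  unname(ref - sigma_comp)
}

#' Fit an effective reference from paired theory/experiment records
#'
#' For subtractive kinds the reference of each context cell is the moment
#' match sigma_ref(cell) = mean(sigma_comp + delta_exp) over the cell
#' (making the mean referenced theoretical shift equal the mean
#' experimental shift in that cell); `regression` fits delta_exp on
#' sigma_comp by least squares.  Cells with fewer than `min_n` pairs fall
#' back to the 185.00 ppm global reference and are flagged.
#'
#' @param pairs Data.frame with columns `sigma` (computed shielding),
#'   `delta_exp` (observed shift) and, as needed, `nucleus`, `sequence`,
#'   `family`.
#' @param kind One of `"simple"`, `"by_sequence"`, `"by_pucker_family"`,
#'   `"by_nucleus"`, `"regression"`.
#' @param min_n Minimum pairs per cell (3 for regression).
#' @return A `reference_scheme`.
#' @export
fit_effective_reference <- function(pairs, kind, min_n = 2) {
  stopifnot(all(c("sigma", "delta_exp") %in% names(pairs)))
  if (kind == "simple") {
    if (nrow(pairs) < min_n) stop("too few pairs to fit a simple reference")
    return(structure(list(kind = "simple",
                          sigma_ref = mean(pairs$sigma + pairs$delta_exp)),
                     class = "reference_scheme"))
  }
  if (kind == "regression") {
    if (nrow(pairs) < max(3, min_n))
      stop("too few pairs to fit a regression reference")
    fit <- stats::lm(delta_exp ~ sigma, data = pairs)
    return(structure(list(kind = "regression",
                          intercept = unname(stats::coef(fit)[1]),
                          slope = unname(stats::coef(fit)[2])),
                     class = "reference_scheme"))
  }
  cell_col <- switch(kind,
                     by_sequence = "sequence",
                     by_pucker_family = "family",
                     by_nucleus = "nucleus",
                     stop("unknown reference kind: ", kind))
  if (!cell_col %in% names(pairs))
    stop("pairs must carry a '", cell_col, "' column for kind ", kind)
  cells <- split(pairs, pairs[[cell_col]])
  tab <- vapply(cells, function(p) {
    if (nrow(p) < min_n) NA_real_ else mean(p$sigma + p$delta_exp)
  }, numeric(1))
  flagged <- names(tab)[is.na(tab)]
  if (length(flagged))
    warning("cells with too few pairs fall back to 185.00 ppm: ",
            paste(flagged, collapse = ", "))
  tab <- tab[!is.na(tab)]
  structure(list(kind = kind, table = tab, fallback = 185.00,
                 flagged = flagged),
            class = "reference_scheme")
}

#' @export
print.reference_scheme <- function(x, ...) {
  cat("reference_scheme:", x$kind, "\n")
  if (x$kind == "simple") cat("  sigma_ref =", x$sigma_ref, "ppm\n")
  else if (x$kind == "regression")
    cat("  delta =", signif(x$intercept, 6), "+", signif(x$slope, 6),
        "* sigma\n")
  else print(round(x$table, 3))
  invisible(x)
}

#' Apply a reference scheme to generated shielding records
#'
#' Fills the five shift columns `C1p ... C5p` from the `sigma_*` columns
#' of a theoretical record table.
#'
#' @param records Data.frame from [generate_theoretical()].
#' @param scheme A `reference_scheme`.
#' @param family_map Needed for the `by_pucker_family` kind.
#' @return The records with updated shift columns.
#' @export
reference_records <- function(records, scheme,
                              family_map = load_family_map()) {
  for (nuc in nucleus_cols()) {
    sig <- records[[paste0("sigma_", nuc)]]
    ctx <- switch(scheme$kind,
                  by_nucleus = rep(nuc, nrow(records)),
                  by_sequence = records$sequence,
                  by_pucker_family = family_of(records$rotamer_id, "dd",
                                               family_map),
                  NULL)
    records[[nuc]] <- reference_shift(sig, scheme, ctx)
  }
  records
}
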