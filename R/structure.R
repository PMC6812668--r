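#' Read an RNA 3D structure
#'
#' Reads a PDB file via \pkg{bio3d} or an mmCIF file via a minimal
#' `atom_site` loop reader, returning a uniform atom table.  Only ATOM
#' records of standard ribonucleotides (residue names A, C, G, U) are kept;
#' HETATM and modified nucleotides are ignored.
#'
#' @param path Path to a `.pdb` or `.cif` file (dialect chosen by
#'   extension, override with `format`).
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer from the extension.
#' @return A data.frame with columns `model`, `chain`, `resno`, `resid`,
#'   `elety` (atom name, primes normalised to `'`), `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  at <- if (format == "cif") read_mmcif_atoms(path) else read_pdb_atoms(path)
  at$elety <- gsub("\\*", "'", at$elety)
  at <- at[at$resid %in% c("A", "C", "G", "U"), , drop = FALSE]
  rownames(at) <- NULL
  at
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  nmod <- nrow(pdb$xyz)
  out <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    out[[m]] <- data.frame(
      model = m, chain = a$chain, resno = a$resno, resid = a$resid,
      elety = a$elety, element = guess_element(a$elety, a$elesy),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, out)
  at[a$type[rep(seq_len(nrow(a)), nmod)] == "ATOM", , drop = FALSE]
}

# Minimal mmCIF atom_site loop reader (no installed R package reads mmCIF).
read_mmcif_atoms <- function(path) {
  lns <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lns)
  if (!length(hdr_idx)) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lns[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character()
  for (i in body_start:length(lns)) {
    ln <- trimws(lns[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  tok <- strsplit(body, "[[:space:]]+")
  ok <- vapply(tok, length, 1L) == length(fields)
  tok <- tok[ok]
  if (!length(tok)) stop("empty _atom_site loop in ", path)
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  grab <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  keep <- grab("group_PDB") %in% c("ATOM", NA_character_)
  at <- data.frame(
    model = as.integer(ifelse(is.na(grab("pdbx_PDB_model_num")), 1,
                              grab("pdbx_PDB_model_num"))),
    chain = grab("auth_asym_id", "label_asym_id"),
    resno = as.integer(grab("auth_seq_id", "label_seq_id")),
    resid = grab("auth_comp_id", "label_comp_id"),
    elety = gsub('"', "", grab("auth_atom_id", "label_atom_id")),
    element = grab("type_symbol"),
    x = as.numeric(grab("Cartn_x")),
    y = as.numeric(grab("Cartn_y")),
    z = as.numeric(grab("Cartn_z")),
    stringsAsFactors = FALSE)
  at[keep, , drop = FALSE]
}

guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- trimws(elesy)
    if (all(nzchar(e))) return(e)
  }
  substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", elety)), 1, 1)
}

#' Extract backbone suites from a structure
#'
#' A suite spans sugar-to-sugar, from delta(i-1) to delta(i): for every
#' bonded interior residue pair (i-1, i) with a complete backbone, the
#' seven torsions (delta(i-1), epsilon(i-1), zeta(i-1), alpha(i), beta(i),
#' gamma(i), delta(i)) are computed with the standard nucleic-acid atom
#' quadruples.  Consecutive residues count as bonded when the
#' O3'(i-1)-P(i) distance is at most `bond_cut` (chain breaks therefore
#' yield no suite); residues with missing backbone atoms are skipped with
#' a warning.
#'
#' @param structure Atom table from [read_structure()], or a path.
#' @param model Model number to use (NMR ensembles: the first model by
#'   default, matching the one-CS-set-per-structure convention).
#' @param all_models If TRUE, extract from every model.
#' @param structure_id Identifier copied into the output rows.
#' @param bond_cut O3'-P bond distance cutoff in Angstrom.
#' @return A data.frame with one row per suite: `structure_id`, `model`,
#'   `chain`, `resno_i`, `sequence` (2-letter dinucleotide), the 7 torsion
#'   columns `d1,e1,z1,a,b,g,d2` in degrees on \[0, 360).
#' @export
extract_suites <- function(structure, model = 1, all_models = FALSE,
                           structure_id = "struct", bond_cut = 2.0) {
  if (is.character(structure)) {
    structure_id <- sub("\\.[^.]*$", "", basename(structure))
    structure <- read_structure(structure)
  }
  models <- if (all_models) sort(unique(structure$model)) else model
  out <- list()
  for (m in models) {
    at <- structure[structure$model == m, , drop = FALSE]
    for (ch in unique(at$chain)) {
      a <- at[at$chain == ch, , drop = FALSE]
      resnos <- sort(unique(a$resno))
      if (length(resnos) < 2) next
      coord <- function(rn, name) {
        i <- which(a$resno == rn & a$elety == name)
        if (length(i) != 1) return(NULL)
        as.numeric(a[i[1], c("x", "y", "z")])
      }
      for (k in 2:length(resnos)) {
        r0 <- resnos[k - 1]; r1 <- resnos[k]
        o3p <- coord(r0, "O3'"); p1 <- coord(r1, "P")
        if (is.null(o3p) || is.null(p1)) next
        if (sqrt(sum((o3p - p1)^2)) > bond_cut) next
        need0 <- lapply(c("C5'", "C4'", "C3'", "O3'"), coord, rn = r0)
        need1 <- lapply(c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
                        coord, rn = r1)
        if (any(vapply(c(need0, need1), is.null, TRUE))) {
          warning("suite at ", ch, ":", r1, " skipped: missing backbone atom")
          next
        }
        names(need0) <- c("C5'", "C4'", "C3'", "O3'")
        names(need1) <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
        tor <- c(
          d1 = dihedral(need0[["C5'"]], need0[["C4'"]], need0[["C3'"]],
                        need0[["O3'"]]),
          e1 = dihedral(need0[["C4'"]], need0[["C3'"]], need0[["O3'"]],
                        need1[["P"]]),
          z1 = dihedral(need0[["C3'"]], need0[["O3'"]], need1[["P"]],
                        need1[["O5'"]]),
          a = dihedral(need0[["O3'"]], need1[["P"]], need1[["O5'"]],
                       need1[["C5'"]]),
          b = dihedral(need1[["P"]], need1[["O5'"]], need1[["C5'"]],
                       need1[["C4'"]]),
          g = dihedral(need1[["O5'"]], need1[["C5'"]], need1[["C4'"]],
                       need1[["C3'"]]),
          d2 = dihedral(need1[["C5'"]], need1[["C4'"]], need1[["C3'"]],
                        need1[["O3'"]]))
        seq2 <- paste0(a$resid[a$resno == r0][1], a$resid[a$resno == r1][1])
        out[[length(out) + 1L]] <- data.frame(
          structure_id = structure_id, model = m, chain = ch, resno_i = r1,
          sequence = seq2, t(tor), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(structure_id = character(), model = integer(),
                      chain = character(), resno_i = integer(),
                      sequence = character(), d1 = numeric(), e1 = numeric(),
                      z1 = numeric(), a = numeric(), b = numeric(),
                      g = numeric(), d2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign torsions to the nearest catalog rotamer
#'
#' Returns the catalog rotamer minimising the circular Euclidean distance
#' between the 7 suite torsions and the catalog means (each coordinate
#' difference wrapped into (-180, 180]).  Ties are broken by higher catalog
#' frequency, then lexicographic id.  Optionally each coordinate is scaled
#' by the catalog spread (Mahalanobis-like), and a maximum distance can
#' flag far suites as unassigned.
#'
#' @param torsions Numeric vector of 7 torsions in degrees, or a matrix /
#'   data.frame with the 7 torsion columns (one row per suite).
#' @param catalog From [load_catalog()].
#' @param scaled If TRUE, scale residuals by catalog spreads.
#' @param max_distance If finite, suites farther than this from every
#'   rotamer get `rotamer_id = NA`.
#' @return A data.frame with columns `rotamer_id` and `distance` (degrees).
#' @export
#' @examples
#' cat46 <- load_catalog()
#' assign_rotamer(c(81, 212, 289, 295, 174, 54, 81), cat46)  # "1a", 0
assign_rotamer <- function(torsions, catalog, scaled = FALSE,
                           max_distance = Inf) {
  if (is.data.frame(torsions)) torsions <- as.matrix(torsions[, torsion_cols()])
  if (is.null(dim(torsions))) torsions <- matrix(torsions, nrow = 1)
  stopifnot(ncol(torsions) == 7)
  M <- as.matrix(catalog[, torsion_cols()])
  S <- as.matrix(catalog[, paste0("sd_", torsion_cols())])
  n <- nrow(torsions)
  ids <- character(n); dst <- numeric(n)
  ord_freq <- catalog$frequency
  for (i in seq_len(n)) {
    D <- wrap180(sweep(M, 2, torsions[i, ], function(m, t) m - t))
    if (scaled) D <- D / S
    d <- sqrt(rowSums(D^2))
    best <- which(d == min(d))
    if (length(best) > 1) {
      best <- best[order(-ord_freq[best], catalog$rotamer_id[best])][1]
    }
    ids[i] <- catalog$rotamer_id[best]
    dst[i] <- min(d)
  }
  ids[dst > max_distance] <- NA_character_
  data.frame(rotamer_id = ids, distance = dst, stringsAsFactors = FALSE)
}

#' Read / write a per-suite chemical-shift table
#'
#' Delimited text with a header naming the five ribose carbon nuclei
#' (`C1p` ... `C5p`, primes written as `p`).  Rows missing any of the five
#' values are dropped and counted.
#'
#' @param path File path.
#' @return A data.frame of complete records, with attribute `"n_dropped"`
#'   giving the number of incomplete rows removed.
#' @export
read_shift_table <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse shift table ", path, ": ",
                             conditionMessage(e)))
  miss <- setdiff(nucleus_cols(), names(tab))
  if (length(miss))
    stop("shift table header must name the five nuclei; missing: ",
         paste(miss, collapse = ", "))
  vals <- as.matrix(tab[, nucleus_cols()])
  bad_rows <- which(!is.finite(vals) | vals < 0 | vals > 120, arr.ind = TRUE)
  incomplete <- rowSums(!is.finite(vals)) > 0
  if (length(bad_rows) && any(!incomplete[unique(bad_rows[, 1])]))
    stop("shift values outside the 0-120 ppm plausibility window at row(s) ",
         paste(unique(bad_rows[, 1]), collapse = ", "))
  out <- tab[!incomplete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(incomplete)
  out
}

#' @param x Data.frame of shift records.
#' @rdname read_shift_table
#' @export
write_shift_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal backbone geometry constants (Angstrom / degrees)
backbone_geom <- function() {
  list(
    len = c("P-O5'" = 1.593, "O5'-C5'" = 1.440, "C5'-C4'" = 1.510,
            "C4'-C3'" = 1.524, "C3'-O3'" = 1.423, "O3'-P" = 1.607),
    ang = c("C3'-O3'-P" = 119.7, "O3'-P-O5'" = 104.0, "P-O5'-C5'" = 120.9,
            "O5'-C5'-C4'" = 111.5, "C5'-C4'-C3'" = 115.5,
            "C4'-C3'-O3'" = 110.5))
}

#' Build a synthetic backbone chain from suite torsions
#'
#' Constructs Cartesian coordinates for an N-residue RNA backbone
#' (atoms C5', C4', C3', O3' for the first residue; P, O5', C5', C4', C3',
#' O3' thereafter) from ideal bond lengths and angles and the supplied
#' suite torsions, by sequential internal-coordinate (NeRF) placement.
#' Used to build test fixtures and demo structures with known torsions.
#'
#' @param suites A list of numeric length-7 torsion vectors (degrees),
#'   one per suite; suite k's delta(i) must equal suite k+1's delta(i-1)
#'   since they describe the same bond.  A single vector is recycled.
#' @param n_residues Number of residues when `suites` is a single vector.
#' @param sequence Character vector of residue names (A/C/G/U), recycled.
#' @return Atom table in the [read_structure()] layout (model 1, chain A).
#' @export
build_suite_chain <- function(suites, n_residues = NULL, sequence = "A") {
  if (is.numeric(suites)) {
    stopifnot(length(suites) == 7, !is.null(n_residues))
    suites <- rep(list(suites), n_residues - 1L)
  }
  nres <- length(suites) + 1L
  for (k in seq_along(suites)) {
    stopifnot(length(suites[[k]]) == 7)
    if (k > 1 && abs(wrap180(suites[[k]][1] - suites[[k - 1]][7])) > 1e-6)
      stop("inconsistent chain: suite ", k, " delta(i-1) != suite ",
           k - 1, " delta(i)")
  }
  sequence <- rep_len(sequence, nres)
  g <- backbone_geom()
  atoms <- list()
  add <- function(resno, name, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      model = 1L, chain = "A", resno = resno, resid = sequence[resno],
      elety = name, element = substr(name, 1, 1),
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    xyz
  }
  # seed residue 1: C5', C4', C3' in a plane
  c5 <- add(1L, "C5'", c(0, 0, 0))
  c4 <- add(1L, "C4'", c(g$len[["C5'-C4'"]], 0, 0))
  th <- (180 - g$ang[["C5'-C4'-C3'"]]) * pi / 180
  c3 <- add(1L, "C3'", c4 + g$len[["C4'-C3'"]] * c(cos(th), sin(th), 0))
  prev <- list(a = c5, b = c4, c = c3)
  for (k in seq_along(suites)) {
    tor <- suites[[k]]
    o3 <- add(k, "O3'", place_atom(prev$a, prev$b, prev$c,
                                   g$len[["C3'-O3'"]],
                                   g$ang[["C4'-C3'-O3'"]], tor[1]))
    p <- add(k + 1L, "P", place_atom(prev$b, prev$c, o3,
                                     g$len[["O3'-P"]],
                                     g$ang[["C3'-O3'-P"]], tor[2]))
    o5 <- add(k + 1L, "O5'", place_atom(prev$c, o3, p,
                                        g$len[["P-O5'"]],
                                        g$ang[["O3'-P-O5'"]], tor[3]))
    c5n <- add(k + 1L, "C5'", place_atom(o3, p, o5,
                                         g$len[["O5'-C5'"]],
                                         g$ang[["P-O5'-C5'"]], tor[4]))
    c4n <- add(k + 1L, "C4'", place_atom(p, o5, c5n,
                                         g$len[["C5'-C4'"]],
                                         g$ang[["O5'-C5'-C4'"]], tor[5]))
    c3n <- add(k + 1L, "C3'", place_atom(o5, c5n, c4n,
                                         g$len[["C4'-C3'"]],
                                         g$ang[["C5'-C4'-C3'"]], tor[6]))
    if (k == length(suites))
      add(k + 1L, "O3'", place_atom(c5n, c4n, c3n,
                                    g$len[["C3'-O3'"]],
                                    g$ang[["C4'-C3'-O3'"]], tor[7]))
    prev <- list(a = c5n, b = c4n, c = c3n)
  }
  out <- do.call(rbind, atoms)
  rownames(out) <- NULL
  out
}

#' Write an atom table as a PDB file
#'
#' @param atoms Atom table in the [read_structure()] layout.
#' @param path Output path.
#' @export
write_structure_pdb <- function(atoms, path) {
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, resid = atoms$resid,
                   chain = atoms$chain, elety = atoms$elety)
  invisible(path)
}
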