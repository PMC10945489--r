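#' Read a slab configuration from a GRO file
#'
#' Parses the fixed-column GRO dialect (coordinates in nm, converted to
#' Angstrom) and returns the oxygen-site positions as a [slab_config()].
#' Only orthorhombic box records are accepted. Malformed fixed-width lines
#' and truncated files produce a parse error carrying the line number, never
#' partial data.
#'
#' @param path Path to the `.gro` file.
#' @param atom_pattern Regular expression selecting the per-molecule
#'   reference atom by atom name (default: names starting with "O").
#' @param mass_per_molecule Molar mass in g/mol.
#' @param temperature Optional temperature label in K.
#' @return A [slab_config()] in Angstrom with coordinates wrapped into the
#'   box.
#' @export
read_gro <- function(path, atom_pattern = "^O", mass_per_molecule = 18.0153,
                     temperature = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort(sprintf("%s: truncated GRO file (%d lines)", path, length(lines)),
          class = "aquacoex_parse_error")
  }
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_atoms) || n_atoms <= 0) {
    abort(sprintf("%s: line 2: invalid atom count '%s'", path, lines[2]),
          class = "aquacoex_parse_error")
  }
  if (length(lines) < 2 + n_atoms + 1) {
    abort(sprintf("%s: truncated GRO file: %d atoms declared, %d atom lines present",
                  path, n_atoms, length(lines) - 3),
          class = "aquacoex_parse_error")
  }
  atom_lines <- lines[3:(2 + n_atoms)]
  parse_one <- function(ln, i) {
    if (nchar(ln) < 44) {
      abort(sprintf("%s: line %d: GRO atom line too short", path, i + 2),
            class = "aquacoex_parse_error")
    }
    name <- trimws(substr(ln, 11, 15))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (any(is.na(xyz))) {
      abort(sprintf("%s: line %d: malformed GRO coordinates", path, i + 2),
            class = "aquacoex_parse_error")
    }
    list(name = name, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  atoms <- purrr::imap(atom_lines, parse_one)
  box_fields <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[2 + n_atoms + 1]), "\\s+")[[1]]))
  if (length(box_fields) < 3 || any(is.na(box_fields[1:3]))) {
    abort(sprintf("%s: missing or malformed box record", path),
          class = "aquacoex_parse_error")
  }
  if (length(box_fields) > 3 && any(abs(box_fields[-(1:3)]) > 1e-12)) {
    abort(sprintf("%s: non-orthorhombic box records are not supported", path),
          class = "aquacoex_parse_error")
  }
  keep <- purrr::map_lgl(atoms, ~ grepl(atom_pattern, .x$name))
  if (!any(keep)) {
    abort(sprintf("%s: no atoms match pattern '%s'", path, atom_pattern),
          class = "aquacoex_parse_error")
  }
  pos <- tibble(
    x = purrr::map_dbl(atoms[keep], "x") * 10,
    y = purrr::map_dbl(atoms[keep], "y") * 10,
    z = purrr::map_dbl(atoms[keep], "z") * 10
  )
  slab_config(pos, box = box_fields[1:3] * 10,
              mass_per_molecule = mass_per_molecule,
              temperature = temperature)
}

#' Read a slab configuration from an XYZ file
#'
#' Parses plain or extended XYZ (coordinates in Angstrom). The box is taken
#' from an extended-XYZ `Lattice="..."` comment record when present (only
#' diagonal lattices accepted) or from the `box` argument; one of the two is
#' required.
#'
#' @param path Path to the `.xyz` file.
#' @param box Optional `(Lx, Ly, Lz)` in Angstrom, overriding the file.
#' @param element_pattern Regular expression selecting the reference atoms
#'   by element/name (default: "O...").
#' @inheritParams read_gro
#' @return A [slab_config()].
#' @export
read_xyz <- function(path, box = NULL, element_pattern = "^O",
                     mass_per_molecule = 18.0153, temperature = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) {
    abort(sprintf("%s: truncated XYZ file", path), class = "aquacoex_parse_error")
  }
  n_atoms <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_atoms) || n_atoms <= 0) {
    abort(sprintf("%s: line 1: invalid atom count", path),
          class = "aquacoex_parse_error")
  }
  if (length(lines) < 2 + n_atoms) {
    abort(sprintf("%s: truncated XYZ file: %d atoms declared", path, n_atoms),
          class = "aquacoex_parse_error")
  }
  if (is.null(box)) {
    m <- regmatches(lines[2], regexpr('Lattice="[^"]*"', lines[2]))
    if (length(m) == 1) {
      vals <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "\\s+")[[1]])
      if (length(vals) == 9) {
        off_diag <- vals[-c(1, 5, 9)]
        if (any(abs(off_diag) > 1e-12)) {
          abort(sprintf("%s: non-orthorhombic lattice not supported", path),
                class = "aquacoex_parse_error")
        }
        box <- vals[c(1, 5, 9)]
      }
    }
  }
  if (is.null(box)) {
    abort(sprintf("%s: no box: supply box= or an extended-XYZ Lattice record",
                  path), class = "aquacoex_parse_error")
  }
  fields <- strsplit(trimws(lines[3:(2 + n_atoms)]), "\\s+")
  bad <- which(purrr::map_int(fields, length) < 4)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: malformed XYZ atom line", path, bad[1] + 2),
          class = "aquacoex_parse_error")
  }
  el <- purrr::map_chr(fields, 1)
  coords <- purrr::map(fields, ~ suppressWarnings(as.numeric(.x[2:4])))
  if (any(purrr::map_lgl(coords, ~ any(is.na(.x))))) {
    abort(sprintf("%s: non-numeric XYZ coordinates", path),
          class = "aquacoex_parse_error")
  }
  keep <- grepl(element_pattern, el)
  if (!any(keep)) {
    abort(sprintf("%s: no atoms match pattern '%s'", path, element_pattern),
          class = "aquacoex_parse_error")
  }
  mat <- do.call(rbind, coords[keep])
  slab_config(tibble(x = mat[, 1], y = mat[, 2], z = mat[, 3]),
              box = box, mass_per_molecule = mass_per_molecule,
              temperature = temperature)
}

#' Read a coexistence-density table from CSV
#'
#' Expected columns: `T`, `rho_l`, `rho_v` and optional `sd_rho_l`,
#' `sd_rho_v`, `flag`.
#'
#' @param path CSV path.
#' @return A coexistence tibble suitable for [fit_critical_point()].
#' @export
read_coexistence_table <- function(path) {
  tbl <- as_tibble(readr::read_csv(path, show_col_types = FALSE))
  if (!all(c("T", "rho_l", "rho_v") %in% names(tbl))) {
    abort(sprintf("%s: coexistence table needs columns T, rho_l, rho_v", path),
          class = "aquacoex_parse_error")
  }
  tbl
}

#' Write an analysis report to CSV or JSON
#'
#' Data frames round-trip through CSV or JSON; fitted objects
#' (`critical_point_fit`, `interface_fit`, `max_density_fit`) are serialised
#' to JSON as their parameter fields. `read_report()` inverts
#' `write_report()` for all these types.
#'
#' @param x A data frame or fitted object.
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (is.data.frame(x)) {
    if (format == "csv") {
      readr::write_csv(as_tibble(x)[, , drop = FALSE], path)
    } else {
      jsonlite::write_json(as.data.frame(x), path, dataframe = "columns",
                           digits = NA, na = "null")
    }
  } else if (inherits(x, c("critical_point_fit", "interface_fit",
                           "max_density_fit"))) {
    if (format != "json") abort("fitted objects serialise to JSON only")
    fields <- x[!purrr::map_lgl(x, ~ is.data.frame(.x) || is.function(.x) ||
                                  is.list(.x))]
    fields$.class <- class(x)[1]
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    abort("unsupported report type")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    return(as_tibble(readr::read_csv(path, show_col_types = FALSE)))
  }
  obj <- jsonlite::fromJSON(path)
  if (!is.null(obj$.class)) {
    cls <- obj$.class
    obj$.class <- NULL
    obj <- purrr::map(obj, ~ if (is.null(.x)) NA else .x)
    return(structure(obj, class = cls))
  }
  as_tibble(as.data.frame(obj))
}
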