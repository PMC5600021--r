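# Minimal CIF reading and writing: cell block, symmetry loop, atom-site
# loop.  Covers the ordinary molecular-crystal subset of the format
# (single data block, no multi-line text fields in the loops we read).

strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

cif_tokens <- function(line) {
  # split a CIF data line into tokens, honouring single/double quotes
  out <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (startsWith(rest, "'") || startsWith(rest, "\"")) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "(\\s|$)"), substring(rest, 2))
      if (end < 0) stop("unterminated quote in CIF line: ", line)
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substring(rest, end + 2))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) { out <- c(out, rest); rest <- "" }
      else { out <- c(out, substr(rest, 1, sp - 1)); rest <- trimws(substring(rest, sp)) }
    }
  }
  out
}

# parse a CIF file into (items: named scalars, loops: list of data frames)
parse_cif_blocks <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  items <- list()
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^data_", ln, ignore.case = TRUE)) {
      i <- i + 1L
    } else if (tolower(ln) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, tolower(cif_tokens(lines[i])[1]))
        i <- i + 1L
      }
      rows <- list()
      buf <- character(0)
      while (i <= n && !startsWith(lines[i], "_") &&
             tolower(lines[i]) != "loop_" &&
             !grepl("^data_", lines[i], ignore.case = TRUE)) {
        buf <- c(buf, cif_tokens(lines[i]))
        while (length(buf) >= length(tags)) {
          rows[[length(rows) + 1L]] <- buf[seq_along(tags)]
          buf <- buf[-seq_along(tags)]
        }
        i <- i + 1L
      }
      if (length(buf) > 0) stop("ragged loop in CIF (tags: ",
                                paste(tags, collapse = " "), ")")
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      if (length(rows) > 0) names(df) <- tags
      loops[[length(loops) + 1L]] <- df
      next
    } else if (startsWith(ln, "_")) {
      tok <- cif_tokens(ln)
      val <- if (length(tok) >= 2) paste(tok[-1], collapse = " ") else {
        # value on the following line (possibly semicolon text field)
        i <- i + 1L
        if (i <= n && startsWith(lines[i], ";")) {
          v <- character(0)
          i <- i + 1L
          while (i <= n && !startsWith(lines[i], ";")) {
            v <- c(v, lines[i]); i <- i + 1L
          }
          paste(v, collapse = "\n")
        } else lines[i]
      }
      items[[tolower(tok[1])]] <- val
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(items = items, loops = loops)
}

find_loop <- function(loops, tag) {
  for (df in loops) if (tag %in% names(df)) return(df)
  NULL
}

#' Read a crystal structure from a CIF file
#'
#' Requires a cell block and an atom-site loop.  Symmetry is taken from an
#' explicit operator loop (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`) when present, otherwise from a small
#' built-in table keyed by space-group number or Hermann-Mauguin name.
#'
#' @param path Path to a CIF file.
#' @return A `ce_crystal` with all symmetry operations explicit.
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- parse_cif_blocks(readLines(path, warn = FALSE))
  it <- parsed$items
  need <- paste0("_cell_length_", c("a", "b", "c"))
  needang <- paste0("_cell_angle_", c("alpha", "beta", "gamma"))
  if (!all(c(need, needang) %in% names(it))) {
    stop("CIF format error: missing cell block item(s) ",
         paste(setdiff(c(need, needang), names(it)), collapse = ", "))
  }
  cell <- unit_cell(strip_su(it[["_cell_length_a"]]),
                    strip_su(it[["_cell_length_b"]]),
                    strip_su(it[["_cell_length_c"]]),
                    strip_su(it[["_cell_angle_alpha"]]),
                    strip_su(it[["_cell_angle_beta"]]),
                    strip_su(it[["_cell_angle_gamma"]]))
  atoms <- find_loop(parsed$loops, "_atom_site_fract_x")
  if (is.null(atoms)) stop("CIF format error: missing atom-site loop")
  elem_col <- intersect(c("_atom_site_type_symbol", "_atom_site_label"),
                        names(atoms))[1]
  if (is.na(elem_col)) stop("CIF format error: atom-site loop lacks element info")
  element <- sub("^([A-Za-z]+).*$", "\\1", atoms[[elem_col]])
  # labels like "C12" or type symbols like "O2-": keep the leading letters
  # and match case-insensitively against known symbols
  element <- vapply(element, function(e) {
    for (take in rev(seq_len(min(nchar(e), 2L)))) {
      cand <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, take)))
      if (cand %in% ELEMENTS) return(cand)
    }
    stop("unknown element symbol in CIF atom site: ", e)
  }, character(1))
  sites <- tibble::tibble(
    element = unname(element),
    fx = strip_su(atoms[["_atom_site_fract_x"]]),
    fy = strip_su(atoms[["_atom_site_fract_y"]]),
    fz = strip_su(atoms[["_atom_site_fract_z"]]),
    label = if ("_atom_site_label" %in% names(atoms)) {
      atoms[["_atom_site_label"]]
    } else paste0(element, seq_along(element))
  )
  symloop <- find_loop(parsed$loops, "_symmetry_equiv_pos_as_xyz")
  if (is.null(symloop)) {
    symloop <- find_loop(parsed$loops, "_space_group_symop_operation_xyz")
  }
  if (!is.null(symloop)) {
    col <- intersect(c("_symmetry_equiv_pos_as_xyz",
                       "_space_group_symop_operation_xyz"), names(symloop))[1]
    ops <- lapply(symloop[[col]], parse_symop)
  } else {
    key <- it[["_space_group_it_number"]] %||%
      it[["_symmetry_int_tables_number"]] %||%
      it[["_symmetry_space_group_name_h-m"]] %||%
      it[["_space_group_name_h-m_alt"]]
    ops <- if (!is.null(key)) builtin_spacegroup_ops(key) else NULL
    if (is.null(ops)) {
      stop("CIF has no symmetry operator loop and no space group known to ",
           "the built-in table; add _symmetry_equiv_pos_as_xyz")
    }
  }
  sg <- it[["_symmetry_space_group_name_h-m"]] %||%
    it[["_space_group_name_h-m_alt"]] %||% "P 1"
  ce_crystal(cell, sites, ops, space_group = sg)
}

#' Write a crystal structure to a CIF file
#'
#' Round-trips through [read_cif()]: sites are preserved within 1e-6
#' fractional units and the symmetry operator list is written explicitly.
#'
#' @param crystal A `ce_crystal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(crystal, path) {
  s <- crystal$sites
  lines <- c(
    "data_crystal",
    sprintf("_symmetry_space_group_name_H-M '%s'", crystal$space_group),
    sprintf("_cell_length_a %.6f", crystal$cell$a),
    sprintf("_cell_length_b %.6f", crystal$cell$b),
    sprintf("_cell_length_c %.6f", crystal$cell$c),
    sprintf("_cell_angle_alpha %.6f", crystal$cell$alpha),
    sprintf("_cell_angle_beta %.6f", crystal$cell$beta),
    sprintf("_cell_angle_gamma %.6f", crystal$cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(crystal$symmetry_ops, function(op) {
      sprintf("'%s'", format_symop(op))
    }, character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s %s %.8f %.8f %.8f", s$label, s$element, s$fx, s$fy, s$fz)
  )
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
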