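# Energy-framework graphs: cylinders joining molecular centroids with
# radius proportional to the pairwise energy magnitude.

#' Pair-energy table for a whole crystal
#'
#' For every symmetry-unique molecule, builds its neighbor cluster, merges
#' symmetry-equivalent pairs and computes the four-component energy for
#' each unique pair.  Ordering is deterministic: central label, then
#' decreasing `|E_tot|`, then centroid distance.
#'
#' @param crystal A `ce_crystal` (run [normalize_xh()] first if wanted).
#' @param model A [energy_model()].
#' @param contact_radius Cluster atom-contact radius in Angstrom.
#' @param config Species config for [assign_species()].
#' @return A `ce_pair_energy` tibble with one row per unique pair per
#'   unique central molecule; includes `central_label`, `origin`,
#'   `multiplicity_count`, `closest_contact` and list-columns
#'   `molecule_a`/`molecule_b`.
#' @export
pair_energy_table <- function(crystal, model = energy_model("ce-b3lyp"),
                              contact_radius = 3.8, config = list()) {
  mols <- assign_species(perceive_molecules(crystal), config)
  rows <- list()
  for (central in mols) {
    nbs <- build_cluster(crystal, central, contact_radius)
    if (length(nbs) == 0) next
    # neighbors inherit the central molecule's species assignment when they
    # are copies of a perceived unique molecule
    nbs <- lapply(nbs, function(nb) {
      for (um in mols) {
        if (nrow(um$atoms) == nrow(nb$atoms) &&
            identical(sort(um$atoms$element), sort(nb$atoms$element)) &&
            length(mol_fingerprint(mol_coords(um))) ==
              length(mol_fingerprint(mol_coords(nb))) &&
            (nrow(nb$atoms) == 1 ||
               max(abs(mol_fingerprint(mol_coords(um)) -
                         mol_fingerprint(mol_coords(nb)))) < 1e-3)) {
          nb$charge <- um$charge
          nb$multiplicity <- um$multiplicity
          nb$is_monatomic_ion <- um$is_monatomic_ion
          break
        }
      }
      nb
    })
    up <- unique_pairs(central, nbs)
    for (r in seq_len(nrow(up))) {
      pe <- pair_energy(central, up$molecule_b[[r]], model)
      pe$central_label <- central$label
      pe$origin <- up$origin[r]
      pe$multiplicity_count <- up$multiplicity_count[r]
      pe$closest_contact <- up$closest_contact[r]
      pe$molecule_a <- list(central)
      pe$molecule_b <- list(up$molecule_b[[r]])
      rows[[length(rows) + 1L]] <- pe
    }
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(model_id = character(), E_ele = numeric(),
                          E_pol = numeric(), E_dis = numeric(),
                          E_rep = numeric(), E_tot = numeric(),
                          E_tot_display = numeric(),
                          central_label = character(), origin = character(),
                          multiplicity_count = integer(),
                          closest_contact = numeric(),
                          centroid_distance = numeric(),
                          molecule_a = list(), molecule_b = list())
    class(out) <- c("ce_pair_energy", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$central_label, -abs(out$E_tot),
                   out$centroid_distance), ]
  class(out) <- c("ce_pair_energy", class(out))
  out
}

framework_palette <- function() {
  c(ele = "red", dis = "green", tot = "blue", destabilizing = "yellow")
}

#' Build an energy-framework graph from a pair-energy table
#'
#' Nodes sit at molecular centres of mass; each retained pair becomes an
#' edge whose cylinder radius is `|E| / cylinder_scale` (larger scale,
#' thinner cylinders).  Edges with `|E| < cutoff` are omitted.  Colors:
#' red = electrostatic, green = dispersion, blue = total, and yellow for
#' destabilizing (positive) electrostatic/total edges; dispersion is never
#' positive.
#'
#' @param pairs A `ce_pair_energy` table with `molecule_a`/`molecule_b`
#'   list-columns (e.g. from [pair_energy_table()]).
#' @param component `"tot"` (scaled total), `"ele"` or `"dis"` (unscaled
#'   components).
#' @param cylinder_scale Positive number; radius = `|E|/cylinder_scale`.
#' @param cutoff Minimum `|E|` (kJ/mol) for an edge to be drawn.
#' @param palette Named colors for `ele`, `dis`, `tot`, `destabilizing`.
#' @return A `ce_framework` with `nodes` and `edges` tibbles.
#' @export
build_framework <- function(pairs, component = c("tot", "ele", "dis"),
                            cylinder_scale = 150, cutoff = 0,
                            palette = framework_palette()) {
  component <- match.arg(component)
  if (!is.numeric(cylinder_scale) || cylinder_scale <= 0) {
    stop("cylinder_scale must be positive")
  }
  energy_col <- switch(component, tot = "E_tot", ele = "E_ele", dis = "E_dis")
  nodes <- tibble::tibble(id = integer(), label = character(),
                          x = numeric(), y = numeric(), z = numeric())
  node_id <- function(mol) {
    ct <- centroid(mol)
    if (nrow(nodes) > 0) {
      d <- sqrt((nodes$x - ct[1])^2 + (nodes$y - ct[2])^2 +
                  (nodes$z - ct[3])^2)
      hit <- which(d < 1e-6)
      if (length(hit) > 0) return(hit[1])
    }
    nodes <<- dplyr::bind_rows(nodes, tibble::tibble(
      id = nrow(nodes) + 1L, label = mol$label,
      x = ct[1], y = ct[2], z = ct[3]))
    nrow(nodes)
  }
  edges <- list()
  for (r in seq_len(nrow(pairs))) {
    e <- pairs[[energy_col]][r]
    if (abs(e) < cutoff) next
    i <- node_id(pairs$molecule_a[[r]])
    j <- node_id(pairs$molecule_b[[r]])
    color <- if (e > 0 && component %in% c("ele", "tot")) {
      palette[["destabilizing"]]
    } else {
      palette[[component]]
    }
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = i, to = j, component = component, energy = e,
      radius = abs(e) / cylinder_scale, color = color,
      multiplicity_count = if ("multiplicity_count" %in% names(pairs)) {
        pairs$multiplicity_count[r]
      } else 1L)
  }
  structure(list(
    nodes = nodes,
    edges = if (length(edges) > 0) dplyr::bind_rows(edges) else
      tibble::tibble(from = integer(), to = integer(),
                     component = character(), energy = numeric(),
                     radius = numeric(), color = character(),
                     multiplicity_count = integer()),
    component = component, cylinder_scale = cylinder_scale,
    cutoff = cutoff), class = "ce_framework")
}

#' @export
print.ce_framework <- function(x, ...) {
  cat(sprintf("<ce_framework %s: %d node(s), %d edge(s), scale %g, cutoff %g kJ/mol>\n",
              x$component, nrow(x$nodes), nrow(x$edges), x$cylinder_scale,
              x$cutoff))
  invisible(x)
}

#' Export a framework scene to JSON or OBJ
#'
#' JSON round-trips losslessly through [import_scene()]; OBJ contains one
#' cylinder mesh (12-sided prism) per edge for external viewers.
#'
#' @param graph A `ce_framework`.
#' @param path Output file path.
#' @param format `"json"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
export_scene <- function(graph, path, format = c("json", "obj")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      schema = "crystalce-framework", version = 1L,
      component = graph$component, cylinder_scale = graph$cylinder_scale,
      cutoff = graph$cutoff,
      nodes = as.data.frame(graph$nodes),
      edges = as.data.frame(graph$edges))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c("# crystalce energy-framework scene")
    voff <- 0L
    nseg <- 12L
    for (r in seq_len(nrow(graph$edges))) {
      ed <- graph$edges[r, ]
      p1 <- as.numeric(graph$nodes[ed$from, c("x", "y", "z")])
      p2 <- as.numeric(graph$nodes[ed$to, c("x", "y", "z")])
      axis <- p2 - p1
      len <- sqrt(sum(axis^2))
      if (len < 1e-9) next
      axis <- axis / len
      ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
      v <- c(axis[2] * u[3] - axis[3] * u[2],
             axis[3] * u[1] - axis[1] * u[3],
             axis[1] * u[2] - axis[2] * u[1])
      lines <- c(lines, sprintf("o edge_%d", r))
      ring <- function(ctr) {
        th <- 2 * pi * (seq_len(nseg) - 1) / nseg
        t(vapply(th, function(a) {
          ctr + ed$radius * (cos(a) * u + sin(a) * v)
        }, numeric(3)))
      }
      verts <- rbind(ring(p1), ring(p2))
      lines <- c(lines, sprintf("v %.6f %.6f %.6f",
                                verts[, 1], verts[, 2], verts[, 3]))
      for (k in seq_len(nseg)) {
        k2 <- if (k == nseg) 1L else k + 1L
        lines <- c(lines, sprintf("f %d %d %d %d", voff + k, voff + k2,
                                  voff + nseg + k2, voff + nseg + k))
      }
      voff <- voff + 2L * nseg
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Re-import a framework scene exported as JSON
#' @param path Path to a JSON scene from [export_scene()].
#' @return A `ce_framework`.
#' @export
import_scene <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "crystalce-framework")) {
    stop("not a crystalce framework scene: ", path)
  }
  empty_nodes <- tibble::tibble(id = integer(), label = character(),
                                x = numeric(), y = numeric(), z = numeric())
  empty_edges <- tibble::tibble(from = integer(), to = integer(),
                                component = character(), energy = numeric(),
                                radius = numeric(), color = character(),
                                multiplicity_count = integer())
  structure(list(
    nodes = if (length(p$nodes) > 0) tibble::as_tibble(p$nodes) else empty_nodes,
    edges = if (length(p$edges) > 0) tibble::as_tibble(p$edges) else empty_edges,
    component = p$component, cylinder_scale = p$cylinder_scale,
    cutoff = p$cutoff), class = "ce_framework")
}

#' Plot a framework graph (2D projection)
#'
#' Projects the scene onto the xy plane: edges drawn with width
#' proportional to cylinder radius in their framework colors, nodes as
#' points at molecular centroids.
#'
#' @param object A `ce_framework`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ce_framework <- function(object, ...) {
  ed <- object$edges
  seg <- tibble::tibble(
    x = object$nodes$x[ed$from], y = object$nodes$y[ed$from],
    xend = object$nodes$x[ed$to], yend = object$nodes$y[ed$to],
    radius = ed$radius, color = ed$color)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$radius),
      color = seg$color, lineend = "round") +
    ggplot2::geom_point(
      data = object$nodes,
      ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::scale_linewidth_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (Å)", y = "y (Å)",
      title = sprintf("Energy framework (%s), scale %g, cutoff %g kJ/mol",
                      object$component, object$cylinder_scale,
                      object$cutoff)) +
    ggplot2::theme_minimal()
}
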