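# 10-20 montage template and electrode neighbor graph.

# Template angles: inclination from the vertex (Cz) and azimuth from the
# anterior midline (degrees, positive toward the right ear).
.montage_template <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
              "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "FC1",
              "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6", "TP9", "TP10"),
    incl = c(90, 90, 60, 60, 45, 45, 60, 60, 90, 90,
             90, 90, 90, 90, 90, 90, 45, 0, 45, 32,
             32, 32, 32, 69, 69, 69, 69, 113, 113),
    az = c(-18, 18, -40, 40, -90, 90, -140, 140, -162, 162,
           -54, 54, -90, 90, -126, 126, 0, 0, 180, -45,
           45, -135, 135, -64, 64, -116, 116, -100, 100),
    stringsAsFactors = FALSE
  )
}

#' Standard 29-channel 10-20 montage
#'
#' Returns the fixed recording montage: 29 scalp Ag-AgCl positions on the
#' unit sphere, the online reference (FCz) and the auxiliary ocular channel.
#' Positions are template coordinates (head modeled as a unit sphere), not
#' digitized locations; they are used for neighbor definition and channel
#' interpolation only.
#'
#' @return An object of class `montage_spec` with elements `labels`
#'   (character, length 29), `positions` (29 x 3 matrix of unit-norm x/y/z,
#'   x right, y anterior, z superior), `reference_label` (`"FCz"`) and
#'   `eog_label` (`"EOG"`).
#' @export
#' @examples
#' m <- generate_montage()
#' length(m$labels)
generate_montage <- function() {
  tpl <- .montage_template()
  incl <- tpl$incl * pi / 180
  az <- tpl$az * pi / 180
  pos <- cbind(
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl)
  )
  rownames(pos) <- tpl$label
  structure(
    list(labels = tpl$label, positions = pos,
         reference_label = "FCz", eog_label = "EOG"),
    class = "montage_spec"
  )
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$labels), " scalp channels, reference ",
      x$reference_label, ", ocular channel ", x$eog_label, "\n", sep = "")
  invisible(x)
}

# Cached Delaunay adjacency of the template positions (2-D azimuthal
# projection), stored as a plain-text edge list in inst/extdata.
.montage_edge_list <- function() {
  path <- system.file("extdata", "neighbors_1020.csv", package = "qeegpipe")
  if (!nzchar(path)) {  # running from a source checkout
    path <- file.path("inst", "extdata", "neighbors_1020.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Electrode neighbor graph
#'
#' Builds the undirected electrode adjacency used for channel interpolation
#' and for spatial clustering in the permutation tests. Neighbors come from a
#' Delaunay triangulation of the template 10-20 positions (2-D azimuthal
#' projection) with implausibly long rim edges pruned; the triangulation is
#' precomputed and shipped as an explicit edge list.
#'
#' @param montage A `montage_spec`.
#' @param exclusions Character vector of labels to drop (default
#'   `c("TP9", "TP10")`, the mastoid-adjacent channels removed from all
#'   analyses).
#' @return An object of class `neighbor_graph`: list with `nodes` (labels),
#'   `edges` (two-column character matrix, each pair once), and `adjacency`
#'   (named list of character vectors).
#' @export
build_neighbor_graph <- function(montage, exclusions = c("TP9", "TP10")) {
  stopifnot(inherits(montage, "montage_spec"))
  nodes <- setdiff(montage$labels, exclusions)
  if (length(nodes) < 3) {
    stop("neighbor graph needs at least 3 electrodes after exclusions")
  }
  ed <- .montage_edge_list()
  keep <- ed$from %in% nodes & ed$to %in% nodes
  ed <- ed[keep, , drop = FALSE]
  adjacency <- lapply(stats::setNames(nodes, nodes), function(lab) {
    sort(unique(c(ed$to[ed$from == lab], ed$from[ed$to == lab])))
  })
  structure(
    list(nodes = nodes,
         edges = cbind(from = ed$from, to = ed$to),
         adjacency = adjacency),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# igraph view of the neighbor graph, used for validation and connectivity
# checks outside the permutation hot loop.
neighbor_igraph <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = graph$nodes
  )
}
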