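# Molecular graphs for the message-passing extractor.
#
# Edges are stored once (unordered pairs); the message-passing code expands
# them to two directed arcs. Node and edge feature blocks are one-hot heavy:
# element vocabulary (+ "other"), degree, formal charge, hybridization,
# aromatic flag, attached-H count, chirality tag; bonds carry a bond-type
# one-hot (single/double/triple/aromatic), conjugation, ring membership and
# a stereo tag.

#' Graph featurization configuration
#'
#' @param elements element vocabulary; anything outside it maps to an
#'   "other" slot. The default covers the organic subset plus halogens.
#' @param max_degree degrees 0..max_degree are one-hot encoded (clipped).
#' @param max_h attached-H counts 0..max_h are one-hot encoded (clipped).
#' @return a list of class \code{graph_config}.
#' @export
graph_config <- function(elements = c("B", "C", "N", "O", "F", "Si", "P",
                                      "S", "Cl", "Br", "I"),
                         max_degree = 4L, max_h = 4L) {
  structure(list(elements = elements, max_degree = as.integer(max_degree),
                 max_h = as.integer(max_h)),
            class = "graph_config")
}

.one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Number of node feature columns for a configuration
#' @param config a \code{graph_config}.
#' @return integer width.
#' @export
node_feature_width <- function(config = graph_config()) {
  # element(+other) + degree + charge(-2..2) + hybridization(4) +
  # aromatic + Hcount + chirality(3)
  (length(config$elements) + 1L) + (config$max_degree + 1L) + 5L + 4L + 1L +
    (config$max_h + 1L) + 3L
}

#' Number of edge feature columns
#' @return integer width: bond type one-hot (4) + conjugation + ring + stereo(3).
#' @export
edge_feature_width <- function() 4L + 1L + 1L + 3L

#' Convert a SMILES string to a molecular graph
#'
#' @param smiles SMILES of one reaction component (>= 1 heavy atom).
#' @param config a \code{graph_config}.
#' @return object of class \code{molecular_graph}: \code{x} the
#'   n_atoms x d_atom node feature matrix, \code{edges} a 2-column matrix of
#'   unordered atom index pairs, \code{edge_attr} the per-edge feature
#'   matrix (symmetric in the pair by construction).
#' @export
mol_to_graph <- function(smiles, config = graph_config()) {
  mol <- parse_molecule(smiles)
  n <- length(mol$elements)
  if (n < 1) stop("molecule has no heavy atoms: '", smiles, "'", call. = FALSE)

  el_idx <- match(mol$elements, config$elements)
  other <- is.na(el_idx)
  if (any(other))
    message("mol_to_graph: element(s) outside vocabulary mapped to 'other': ",
            paste(unique(mol$elements[other]), collapse = ", "))
  el_idx[other] <- length(config$elements) + 1L
  deg_idx <- pmin(mol$degree, config$max_degree) + 1L
  chg_idx <- pmin(pmax(mol$charge, -2L), 2L) + 3L
  hyb_idx <- match(mol$hybridization, c("sp", "sp2", "sp3", "other"))
  hyb_idx[is.na(hyb_idx)] <- 4L
  h_idx <- pmin(mol$n_h, config$max_h) + 1L
  # chirality: unspecified / CW / CCW. 2-D connection tables from the SMILES
  # reader carry no stereocentre parity, so the unspecified slot is set; the
  # slot layout is kept so stereo-aware sources can populate it.
  chir <- .one_hot(rep(1L, n), 3L)

  x <- cbind(
    .one_hot(el_idx, length(config$elements) + 1L),
    .one_hot(deg_idx, config$max_degree + 1L),
    .one_hot(chg_idx, 5L),
    .one_hot(hyb_idx, 4L),
    as.numeric(mol$aromatic_atom),
    .one_hot(h_idx, config$max_h + 1L),
    chir
  )

  b <- mol$bonds
  ne <- nrow(b)
  if (ne) {
    type_idx <- ifelse(b$aromatic, 4L, pmin(b$order, 3L))
    conj <- as.numeric(b$aromatic)  # conjugation beyond aromatic rings is
                                    # not perceived by the 2-D reader
    stereo <- .one_hot(rep(1L, ne), 3L)
    edge_attr <- cbind(.one_hot(type_idx, 4L), conj, as.numeric(b$in_ring),
                       stereo)
    edges <- cbind(b$i, b$j)
  } else {
    edge_attr <- matrix(0, 0, edge_feature_width())
    edges <- matrix(0L, 0, 2)
  }
  structure(list(x = x, edges = edges, edge_attr = edge_attr,
                 smiles = smiles, n_atoms = n),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges), " bonds, d_atom=", ncol(x$x), "\n", sep = "")
  invisible(x)
}

#' Featurize all components of a reaction list as graphs
#' @param reactions list of \code{reaction} objects.
#' @param config a \code{graph_config}.
#' @return list (per reaction) of lists (per role) of \code{molecular_graph}.
#' @export
reactions_to_graphs <- function(reactions, config = graph_config()) {
  roles <- reaction_roles(reactions)
  lapply(reactions, function(r) {
    g <- lapply(roles, function(role) mol_to_graph(r$components[[role]], config))
    names(g) <- roles
    g
  })
}
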