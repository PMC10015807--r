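#' Parse a SMILES string into a bidirectional molecular graph
#'
#' Converts a SMILES string into a hydrogen-suppressed heavy-atom graph in
#' which every bond is stored as two directed edges, the representation the
#' GIN encoder consumes. Parsing is delegated to Open Babel through
#' [ChemmineR::smiles2sdf()]; only graph topology, element symbols and bond
#' orders are retained, so the result is deterministic for a given SMILES.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Identifier attached to the graph (defaults to the SMILES
#'   itself).
#' @return An object of class `molecular_graph`: a list with `drug_id`,
#'   `atom_count`, `elements` (character vector of element symbols),
#'   `degrees` (heavy-atom degree per atom), `edges` (integer matrix with
#'   columns `from`/`to`, one row per directed edge), `bond_orders` (integer
#'   per directed edge: 1, 2, 3), and, after [featurize()], `node_features`
#'   and `edge_features` matrices.
#' @details Unparsable SMILES raise a condition of class
#'   `mvddi_smiles_parse_error` carrying the offending string and drug id, so
#'   callers can choose to skip with a warning or abort.
#' @examples
#' g <- parse_smiles("CCO", "ethanol")
#' g$atom_count      # 3 heavy atoms
#' nrow(g$edges)     # 4 directed edges (2 bonds x 2 directions)
#' @seealso [featurize()], [read_smiles_file()]
#' @export
parse_smiles <- function(smiles, drug_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) {
      stop(smiles_parse_error(smiles, drug_id, conditionMessage(e)))
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1L]])
  bb <- ChemmineR::bondblock(sdf[[1L]])
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms < 1L) {
    stop(smiles_parse_error(smiles, drug_id, "no atoms"))
  }
  elements <- sub("_.*$", "", rownames(ab))
  # single-atom molecules come back with a placeholder all-zero bond row
  bb <- bb[bb[, 1L] > 0 & bb[, 2L] > 0, , drop = FALSE]
  if (nrow(bb) > 0L) {
    from <- as.integer(bb[, 1L])
    to <- as.integer(bb[, 2L])
    order <- as.integer(bb[, 3L])
    if (any(from < 1L | from > n_atoms | to < 1L | to > n_atoms)) {
      stop(smiles_parse_error(smiles, drug_id, "bond index out of range"))
    }
    edges <- cbind(from = c(from, to), to = c(to, from))
    bond_orders <- c(order, order)
  } else {
    edges <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("from", "to")))
    bond_orders <- integer(0)
  }
  degrees <- tabulate(edges[, "to"], nbins = n_atoms)
  structure(
    list(
      drug_id = drug_id,
      atom_count = n_atoms,
      elements = elements,
      degrees = degrees,
      edges = edges,
      bond_orders = bond_orders,
      node_features = NULL,
      edge_features = NULL,
      scheme = NULL
    ),
    class = "molecular_graph"
  )
}

smiles_parse_error <- function(smiles, drug_id, reason) {
  structure(
    class = c("mvddi_smiles_parse_error", "error", "condition"),
    list(
      message = sprintf(
        "could not parse SMILES '%s' (drug '%s'): %s",
        smiles, drug_id, reason
      ),
      call = NULL, smiles = smiles, drug_id = drug_id
    )
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph '%s': %d atoms, %d directed edges%s>\n",
    x$drug_id, x$atom_count, nrow(x$edges),
    if (is.null(x$scheme)) "" else sprintf(", scheme '%s'", x$scheme)
  ))
  invisible(x)
}

# element alphabet of the "minimal" scheme; anything else maps to "other"
minimal_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
minimal_max_degree <- 6L

#' Attach numeric node and edge features to a molecular graph
#'
#' Populates `node_features` and `edge_features` under a named featurization
#' scheme. The built-in `"minimal"` scheme encodes each atom as a one-hot
#' element indicator over C/N/O/S/P/F/Cl/Br/I plus a reserved "other" slot,
#' concatenated with a one-hot heavy-atom degree (0--6), and each directed
#' edge as a one-hot bond order (single/double/triple plus an "other" slot;
#' aromatic rings arrive Kekulized, as alternating single/double bonds).
#'
#' @param graph A `molecular_graph` from [parse_smiles()].
#' @param scheme Name of the featurization scheme; only `"minimal"` is
#'   defined.
#' @return The graph with `node_features` (`atom_count` x 17),
#'   `edge_features` (n directed edges x 4) and `scheme` filled in.
#' @examples
#' g <- featurize(parse_smiles("CCO"))
#' rowSums(g$node_features)  # element one-hot + degree one-hot: each row sums to 2
#' @export
featurize <- function(graph, scheme = "minimal") {
  stopifnot(inherits(graph, "molecular_graph"))
  if (!identical(scheme, "minimal")) {
    stop("unknown featurization scheme: ", scheme, call. = FALSE)
  }
  n_el <- length(minimal_elements) + 1L
  n_deg <- minimal_max_degree + 1L
  node <- matrix(0, graph$atom_count, n_el + n_deg)
  el_idx <- match(graph$elements, minimal_elements)
  el_idx[is.na(el_idx)] <- n_el
  deg_idx <- pmin(graph$degrees, minimal_max_degree) + 1L
  node[cbind(seq_len(graph$atom_count), el_idx)] <- 1
  node[cbind(seq_len(graph$atom_count), n_el + deg_idx)] <- 1
  n_edge <- nrow(graph$edges)
  edge <- matrix(0, n_edge, 4L)
  if (n_edge > 0L) {
    bo <- graph$bond_orders
    bo_idx <- ifelse(bo %in% 1:3, bo, 4L)
    edge[cbind(seq_len(n_edge), bo_idx)] <- 1
  }
  graph$node_features <- node
  graph$edge_features <- edge
  graph$scheme <- scheme
  graph
}

#' @noRd
feature_dims <- function(scheme = "minimal") {
  stopifnot(identical(scheme, "minimal"))
  c(node = length(minimal_elements) + 1L + minimal_max_degree + 1L, edge = 4L)
}

#' Parse a table of drugs into featurized molecular graphs
#'
#' @param drugs A data frame with columns `drug_id` and `smiles` (as read by
#'   [read_smiles_file()] or produced by [generate_toy_world()]).
#' @param scheme Featurization scheme passed to [featurize()].
#' @param on_error `"skip"` drops unparsable SMILES with a warning;
#'   `"abort"` re-raises the parse error.
#' @return A named list of `molecular_graph` objects, one per successfully
#'   parsed drug, in input order.
#' @export
parse_drug_table <- function(drugs, scheme = "minimal",
                             on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  out <- list()
  failed <- character(0)
  for (i in seq_len(nrow(drugs))) {
    g <- tryCatch(
      featurize(parse_smiles(drugs$smiles[[i]], drugs$drug_id[[i]]), scheme),
      mvddi_smiles_parse_error = function(e) {
        if (on_error == "abort") stop(e)
        e
      }
    )
    if (inherits(g, "mvddi_smiles_parse_error")) {
      failed <- c(failed, drugs$drug_id[[i]])
    } else {
      out[[drugs$drug_id[[i]]]] <- g
    }
  }
  if (length(failed)) {
    warning(
      "skipped ", length(failed), " unparsable SMILES: ",
      paste(failed, collapse = ", "),
      call. = FALSE
    )
  }
  out
}
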