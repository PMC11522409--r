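#' Electrode map for a multinodal MEA layout
#'
#' An electrode map assigns every electrode to one of the four culture nodes
#' (`C`, the cortical node, or `H1`--`H3`, the hippocampal nodes) or to
#' `TUNNEL` for electrodes placed inside the microfluidic tunnels connecting
#' the nodes. Node order `C < H1 < H2 < H3` defines the feedforward direction
#' used throughout the propagation analysis.
#'
#' @param electrode_id character vector of unique electrode identifiers.
#' @param node_label character vector, one of `C`, `H1`, `H2`, `H3`, `TUNNEL`.
#' @param x,y optional electrode positions in micrometres.
#' @param is_reference logical, reference electrodes are excluded from
#'   analysis.
#' @return A data frame of class `electrode_map`.
#' @export
electrode_map <- function(electrode_id, node_label, x = NA_real_, y = NA_real_,
                          is_reference = FALSE) {
  map <- data.frame(
    electrode_id = as.character(electrode_id),
    node_label = as.character(node_label),
    x = as.numeric(x), y = as.numeric(y),
    is_reference = as.logical(is_reference),
    stringsAsFactors = FALSE
  )
  class(map) <- c("electrode_map", "data.frame")
  validate_electrode_map(map)
  map
}

#' @export
validate_electrode_map <- function(map) {
  if (anyDuplicated(map$electrode_id))
    stop("electrode_map: duplicated electrode_id(s): ",
         paste(unique(map$electrode_id[duplicated(map$electrode_id)]), collapse = ", "))
  bad <- setdiff(unique(map$node_label), NODE_LEVELS)
  if (length(bad))
    stop("electrode_map: unknown node label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(NODE_LEVELS, collapse = ", "), ")")
  invisible(map)
}

#' Standard 59-electrode four-nodal layout
#'
#' The standard layout has 50 electrodes spread across the four nodes
#' (13, 13, 12, 12) and 9 electrodes inside the microfluidic tunnels.
#'
#' @param n_per_node integer vector of length 4, electrodes per node.
#' @param n_tunnel number of tunnel electrodes.
#' @return An [electrode_map].
#' @export
standard_electrode_map <- function(n_per_node = c(13, 13, 12, 12), n_tunnel = 9) {
  stopifnot(length(n_per_node) == 4, all(n_per_node >= 1), n_tunnel >= 0)
  ids <- character(0); labs <- character(0)
  for (i in seq_along(NODE_ORDER)) {
    ids <- c(ids, sprintf("%s-%02d", NODE_ORDER[i], seq_len(n_per_node[i])))
    labs <- c(labs, rep(NODE_ORDER[i], n_per_node[i]))
  }
  if (n_tunnel > 0) {
    ids <- c(ids, sprintf("T-%02d", seq_len(n_tunnel)))
    labs <- c(labs, rep("TUNNEL", n_tunnel))
  }
  electrode_map(ids, labs)
}

# Electrode ids belonging to one node (never tunnel) in map order.
node_electrodes <- function(map, node) {
  map$electrode_id[map$node_label == node & !map$is_reference]
}
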