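#' Node-to-system partition with system types
#'
#' A `system_partition` maps each network node to exactly one functional
#' brain system and each system to a processing type: `"sensory-motor"`
#' (systems processing sensory input and motor output, e.g. visual,
#' auditory, somato-motor), `"association"` (systems supporting higher-order
#' integrative cognition, e.g. default, frontoparietal, attention,
#' salience), or `"unassigned"`. Systems typed `"unassigned"` are excluded
#' from all segregation pools.
#'
#' @param node_ids character vector of unique node identifiers, in matrix
#'   order.
#' @param system_of_node character vector, same length as `node_ids`: the
#'   system label of each node.
#' @param type_of_system named character vector mapping every system label
#'   to one of `"sensory-motor"`, `"association"`, `"unassigned"`.
#' @return An object of class `system_partition`: a list with elements
#'   `nodes` (data.frame: `node_id`, `system`) and `systems` (data.frame:
#'   `system`, `type`).
#' @examples
#' p <- system_partition(
#'   node_ids = paste0("n", 1:6),
#'   system_of_node = c("A", "A", "A", "B", "B", "B"),
#'   type_of_system = c(A = "association", B = "sensory-motor")
#' )
#' @export
system_partition <- function(node_ids, system_of_node, type_of_system) {
  node_ids <- as.character(node_ids)
  system_of_node <- as.character(system_of_node)
  if (length(node_ids) != length(system_of_node))
    stop("node_ids and system_of_node must have equal length")
  if (anyDuplicated(node_ids))
    stop("node_ids must be unique")
  types_ok <- c("sensory-motor", "association", "unassigned")
  if (is.null(names(type_of_system)) || any(names(type_of_system) == ""))
    stop("type_of_system must be a named vector (system -> type)")
  if (!all(type_of_system %in% types_ok))
    stop("system types must be one of: ", paste(types_ok, collapse = ", "))
  systems <- unique(system_of_node)
  missing_type <- setdiff(systems, names(type_of_system))
  if (length(missing_type))
    stop("no type assigned for system(s): ", paste(missing_type, collapse = ", "))

  # at least two assigned systems must have >= 2 nodes so that both a
  # within-system and a between-system pool exist
  assigned <- systems[type_of_system[systems] != "unassigned"]
  sizes <- table(system_of_node)[assigned]
  if (sum(sizes >= 2) < 2)
    stop("need >= 2 assigned systems with >= 2 nodes each")

  structure(
    list(
      nodes = data.frame(node_id = node_ids, system = system_of_node,
                         stringsAsFactors = FALSE),
      systems = data.frame(system = systems,
                           type = unname(type_of_system[systems]),
                           stringsAsFactors = FALSE)
    ),
    class = "system_partition"
  )
}

#' @export
print.system_partition <- function(x, ...) {
  cat("system_partition:", nrow(x$nodes), "nodes,",
      nrow(x$systems), "systems\n")
  tab <- merge(x$nodes, x$systems, by = "system")
  print(table(tab$system, tab$type))
  invisible(x)
}

#' Default desk-scale partition
#'
#' A 120-node, 10-system partition with unequal system sizes: six
#' association systems (default, frontoparietal, dorsal attention, ventral
#' attention, salience, memory retrieval; 72 nodes) and four sensory-motor
#' systems (visual, somatomotor hand, somatomotor mouth, auditory;
#' 48 nodes). This is a configurable stand-in for a full cortical
#' parcellation, preserving the feature that matters for the segregation
#' statistic: multiple systems of both processing types with heterogeneous
#' sizes.
#'
#' @param n_nodes total node count; system sizes are scaled proportionally
#'   (default 120).
#' @return A [system_partition()].
#' @export
default_partition <- function(n_nodes = 120) {
  base_sizes <- c(
    "default" = 20, "frontoparietal" = 15, "dorsal-attention" = 12,
    "ventral-attention" = 10, "salience" = 8, "memory-retrieval" = 7,
    "visual" = 18, "somatomotor-hand" = 14, "auditory" = 10,
    "somatomotor-mouth" = 6
  )
  types <- c(
    "default" = "association", "frontoparietal" = "association",
    "dorsal-attention" = "association", "ventral-attention" = "association",
    "salience" = "association", "memory-retrieval" = "association",
    "visual" = "sensory-motor", "somatomotor-hand" = "sensory-motor",
    "auditory" = "sensory-motor", "somatomotor-mouth" = "sensory-motor"
  )
  if (n_nodes < 20) stop("n_nodes must be >= 20")
  # proportional allocation with a floor of 2 nodes per system,
  # remainder distributed by largest fractional part
  raw <- base_sizes * (n_nodes - 20) / sum(base_sizes)
  sizes <- 2L + as.integer(floor(raw))
  left <- n_nodes - sum(sizes)
  if (left > 0) {
    ord <- order(raw - floor(raw), base_sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  system_of_node <- rep(names(base_sizes), times = sizes)
  node_ids <- sprintf("node%03d", seq_len(n_nodes))
  system_partition(node_ids, system_of_node, types)
}

#' Read / write a partition table
#'
#' Plain TSV with columns `node_id`, `system`, `system_type`.
#'
#' @param path file path.
#' @return `read_partition` returns a [system_partition()];
#'   `write_partition` returns `path` invisibly.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "system", "system_type")
  if (!all(need %in% names(tab)))
    stop("partition file must have columns: ", paste(need, collapse = ", "))
  type_map <- tapply(tab$system_type, tab$system, function(x) {
    ux <- unique(x)
    if (length(ux) > 1) stop("inconsistent system_type within a system")
    ux
  })
  system_partition(tab$node_id, tab$system,
                   stats::setNames(as.character(type_map), names(type_map)))
}

#' @rdname read_partition
#' @param partition a [system_partition()].
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "system_partition"))
  tab <- merge(partition$nodes, partition$systems, by = "system",
               sort = FALSE)
  tab <- tab[match(partition$nodes$node_id, tab$node_id),
             c("node_id", "system", "type")]
  names(tab)[3] <- "system_type"
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: system label per node (NA for unassigned-type systems),
# aligned to the node order of `node_ids` (or the partition's own order)
.partition_systems <- function(partition, node_ids = NULL) {
  nodes <- partition$nodes
  if (!is.null(node_ids)) {
    idx <- match(node_ids, nodes$node_id)
    if (anyNA(idx))
      stop("node ids not found in partition: ",
           paste(utils::head(node_ids[is.na(idx)], 5), collapse = ", "))
    nodes <- nodes[idx, ]
  }
  type <- partition$systems$type[match(nodes$system, partition$systems$system)]
  sys <- nodes$system
  sys[type == "unassigned"] <- NA_character_
  sys
}

# internal: types of assigned systems, named by system
.assigned_system_types <- function(partition) {
  keep <- partition$systems$type != "unassigned"
  stats::setNames(partition$systems$type[keep], partition$systems$system[keep])
}
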