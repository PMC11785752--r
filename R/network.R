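# Node categories recognised throughout the package. "other" is the fallback
# used when a category is not declared.
NODE_CATEGORIES <- c(
  "structural", "degrading-enzyme", "protease-inhibitor",
  "pro-inflammatory-cytokine", "anti-inflammatory-cytokine",
  "growth-factor", "chemokine", "angiogenic", "other"
)

EVIDENCE_COLUMNS <- c("reference_id", "cell_type", "species", "culture",
                      "pathology")
EVIDENCE_LEVELS <- list(
  cell_type = c("IVD-NPC", "chondrocyte", "other", "database"),
  species   = c("human", "animal", "n/a"),
  culture   = c("2D", "3D", "n/a"),
  pathology = c("normal", "degenerate", "n/a")
)

# ASCII aliases for node labels that mix Greek and Latin notation in the
# source corpora. Matching is case-sensitive after whitespace trimming.
NODE_ALIASES <- c(
  "IL-1b"  = "IL-1β",
  "IL-1a"  = "IL-1α",
  "TGF-b"  = "TGF-β",
  "IFN-g"  = "IFN-γ"
)

canonical_node_name <- function(x) {
  x <- trimws(x)
  hit <- match(x, names(NODE_ALIASES))
  x[!is.na(hit)] <- NODE_ALIASES[hit[!is.na(hit)]]
  x
}

#' Construct a signed regulatory network
#'
#' A regulatory network couples a node table (protein labels with functional
#' categories) to a signed, directed interaction table.  Each interaction may
#' carry any number of evidence records (literature or database provenance).
#' The constructor validates the structural invariants: unique non-empty node
#' names, interaction endpoints resolving to nodes, effects of exactly +1
#' (activation) or -1 (inhibition), and at most one interaction per ordered
#' (source, target) pair.
#'
#' @param nodes data.frame with columns `name` and optionally `category`
#'   (one of the recognised categories) and a list column `merged_from`.
#'   A character vector is accepted as shorthand for names only.
#' @param interactions data.frame with columns `source`, `target`, `effect`
#'   (+1/-1).
#' @param evidence optional data.frame with columns `source`, `target` and
#'   any of `reference_id`, `cell_type`, `species`, `culture`, `pathology`;
#'   one row per evidence record.  Unknown columns are preserved.
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes, interactions, evidence = NULL) {
  if (is.character(nodes)) nodes <- data.frame(name = nodes)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"name" %in% names(nodes)) format_error("node table lacks a 'name' column")
  nodes$name <- canonical_node_name(as.character(nodes$name))
  if (!"category" %in% names(nodes))
    nodes$category <- rep("other", nrow(nodes))
  nodes$category <- as.character(nodes$category)
  nodes$category[is.na(nodes$category) | nodes$category == ""] <- "other"
  if (!"merged_from" %in% names(nodes)) {
    nodes$merged_from <- I(replicate(nrow(nodes), character(0), simplify = FALSE))
  }

  if (is.null(interactions)) {
    interactions <- data.frame(source = character(0), target = character(0),
                               effect = integer(0))
  }
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  for (col in c("source", "target")) {
    if (!col %in% names(interactions))
      format_error(sprintf("interaction table lacks a '%s' column", col))
    interactions[[col]] <- canonical_node_name(as.character(interactions[[col]]))
  }
  if (!"effect" %in% names(interactions))
    format_error("interaction table lacks an 'effect' column")
  interactions$effect <- parse_effect(interactions$effect)

  if (!is.null(evidence)) {
    evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
    evidence$source <- canonical_node_name(as.character(evidence$source))
    evidence$target <- canonical_node_name(as.character(evidence$target))
    for (col in EVIDENCE_COLUMNS)
      if (!col %in% names(evidence)) evidence[[col]] <- "n/a"
  } else {
    evidence <- data.frame(source = character(0), target = character(0),
                           reference_id = character(0), cell_type = character(0),
                           species = character(0), culture = character(0),
                           pathology = character(0))
  }

  net <- structure(
    list(nodes = nodes, interactions = interactions, evidence = evidence),
    class = "regulatory_network"
  )
  validate_network(net)
}

parse_effect <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
  } else {
    x <- trimws(as.character(x))
    map <- c("1" = 1L, "+1" = 1L, "+" = 1L, "activation" = 1L, "activates" = 1L,
             "-1" = -1L, "−1" = -1L, "-" = -1L, "inhibition" = -1L,
             "inhibits" = -1L)
    out <- unname(map[x])
  }
  bad <- is.na(out) | !(out %in% c(-1L, 1L))
  if (any(bad))
    format_error(sprintf("unparseable interaction effect(s): %s",
                         paste(unique(x[bad]), collapse = ", ")))
  out
}

#' Validate a regulatory network
#'
#' Checks all structural invariants and returns the network invisibly, or
#' signals a classed error (`rnm_validation_error` / `rnm_conflict_error`)
#' describing every offending row.
#'
#' @param net a `regulatory_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  inter <- net$interactions

  if (any(is.na(nodes$name) | nodes$name == ""))
    validation_error("node names must be non-empty")
  if (anyDuplicated(nodes$name))
    validation_error(sprintf("duplicate node name(s): %s",
      paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", ")))
  merged <- unlist(nodes$merged_from)
  clash <- intersect(merged, nodes$name)
  if (length(clash))
    validation_error(sprintf(
      "merged_from label(s) also present as node name(s): %s",
      paste(clash, collapse = ", ")))

  if (nrow(inter)) {
    dangling <- !(inter$source %in% nodes$name) | !(inter$target %in% nodes$name)
    if (any(dangling))
      validation_error(sprintf(
        "interaction endpoint(s) not in node table (rows %s): %s",
        paste(which(dangling), collapse = ", "),
        paste(unique(c(inter$source[dangling], inter$target[dangling])
                     [!(c(inter$source[dangling], inter$target[dangling]) %in%
                        nodes$name)]), collapse = ", ")))
    key <- paste(inter$source, inter$target, sep = "\r")
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      # duplicates with a consistent sign are a validation error; opposite
      # signs are a conflict and named explicitly
      for (k in dups) {
        signs <- unique(inter$effect[key == k])
        pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
        if (length(signs) > 1L)
          conflict_error(sprintf(
            "conflicting signs for interaction (%s, %s)", pair[1], pair[2]),
            pair = pair)
      }
      validation_error(sprintf("duplicated interaction(s): %s",
        paste(vapply(strsplit(dups, "\r", fixed = TRUE),
                     function(p) sprintf("(%s, %s)", p[1], p[2]), ""),
              collapse = ", ")))
    }
  }
  ev <- net$evidence
  if (nrow(ev)) {
    dangling <- !(ev$source %in% nodes$name) | !(ev$target %in% nodes$name)
    if (any(dangling))
      validation_error("evidence rows reference unknown interactions")
  }
  invisible(net)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d interactions (%d inhibitory)\n",
              nrow(x$nodes), nrow(x$interactions),
              sum(x$interactions$effect == -1L)))
  if (nrow(x$evidence))
    cat(sprintf("  evidence: %d records, %d distinct references\n",
                nrow(x$evidence),
                length(unique(x$evidence$reference_id))))
  invisible(x)
}

node_names <- function(net) net$nodes$name

#' Regulator sets of a node
#'
#' @param net a `regulatory_network`.
#' @param node node name.
#' @return list with character vectors `activators` and `inhibitors`.
#' @export
regulators <- function(net, node) {
  node <- canonical_node_name(node)
  if (!node %in% net$nodes$name) lookup_error(sprintf("unknown node '%s'", node))
  inter <- net$interactions
  list(
    activators = inter$source[inter$target == node & inter$effect == 1L],
    inhibitors = inter$source[inter$target == node & inter$effect == -1L]
  )
}

#' Degree of connectivity
#'
#' The degree of connectivity (DoC) of a node is the number of interaction
#' edges incident to it, counting in- and out-edges once per endpoint and
#' self-loops once.  Under this undirected-incidence convention the DoC
#' values sum to twice the edge count on loop-free networks.
#'
#' @param net a `regulatory_network`.
#' @return named integer vector over all nodes (0 for isolated nodes).
#' @export
degree_of_connectivity <- function(net) {
  validate_network(net)
  inter <- net$interactions
  doc <- stats::setNames(integer(nrow(net$nodes)), net$nodes$name)
  if (nrow(inter)) {
    loops <- inter$source == inter$target
    ends <- c(inter$source[!loops], inter$target[!loops], inter$source[loops])
    tab <- table(ends)
    doc[names(tab)] <- as.integer(tab)
  }
  doc
}

#' Merge a group of nodes into one
#'
#' Re-targets every edge incident to the group onto a single replacement
#' node, collapsing duplicate (source, target) edges with equal sign and
#' merging their evidence.  Duplicates with opposite signs are a hard
#' conflict error, never auto-resolved.
#'
#' @param net a `regulatory_network`.
#' @param group character vector of existing node names to merge.
#' @param new_name label of the merged node.
#' @param category category of the merged node; defaults to the category of
#'   the first group member.
#' @return a new `regulatory_network`.
#' @export
merge_nodes <- function(net, group, new_name, category = NULL) {
  group <- canonical_node_name(group)
  new_name <- canonical_node_name(new_name)
  missing <- setdiff(group, net$nodes$name)
  if (length(missing))
    lookup_error(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")))
  if (is.null(category))
    category <- net$nodes$category[match(group[1], net$nodes$name)]

  remap <- function(x) ifelse(x %in% group, new_name, x)
  inter <- net$interactions
  inter$source <- remap(inter$source)
  inter$target <- remap(inter$target)
  key <- paste(inter$source, inter$target, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(inter$effect[key == k])) > 1L) {
      pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
      conflict_error(sprintf(
        "merging %s into '%s' creates conflicting signs for (%s, %s)",
        paste(group, collapse = "+"), new_name, pair[1], pair[2]), pair = pair)
    }
  }
  inter <- inter[!duplicated(key), , drop = FALSE]

  nodes <- net$nodes[!(net$nodes$name %in% group), , drop = FALSE]
  prior <- unlist(net$nodes$merged_from[net$nodes$name %in% group])
  nodes <- rbind(nodes, data.frame(
    name = new_name, category = category,
    merged_from = I(list(unique(c(group, prior))))))
  rownames(nodes) <- NULL

  ev <- net$evidence
  if (nrow(ev)) {
    ev$source <- remap(ev$source)
    ev$target <- remap(ev$target)
  }
  regulatory_network(nodes, inter, ev)
}

#' Remove nodes and their incident edges
#'
#' @param net a `regulatory_network`.
#' @param names character vector of node names to drop.
#' @return a new `regulatory_network`.
#' @export
remove_nodes <- function(net, names) {
  names <- canonical_node_name(names)
  missing <- setdiff(names, net$nodes$name)
  if (length(missing))
    lookup_error(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")))
  nodes <- net$nodes[!(net$nodes$name %in% names), , drop = FALSE]
  keep <- !(net$interactions$source %in% names) &
          !(net$interactions$target %in% names)
  inter <- net$interactions[keep, , drop = FALSE]
  ev <- net$evidence
  ev <- ev[!(ev$source %in% names) & !(ev$target %in% names), , drop = FALSE]
  rownames(nodes) <- rownames(inter) <- rownames(ev) <- NULL
  regulatory_network(nodes, inter, ev)
}
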