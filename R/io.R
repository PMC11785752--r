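# On-disk formats. The canonical format is an edge-list CSV with one row per
# evidence record (so a (source, target) pair can appear on several rows with
# the same sign); columns beyond the canonical set are preserved as
# annotations. GraphML goes through igraph for Cytoscape compatibility; SIF
# is the three-column Cytoscape text format.

canonical_columns <- function() {
  c("source", "target", "effect", "source_category", "target_category",
    EVIDENCE_COLUMNS)
}

#' Parse a signed edge-list table into a regulatory network
#'
#' Reads an interaction table with at least `source`, `target` and `effect`
#' columns.  `effect` accepts +1/-1, +/-, or the words
#' activation/activates/inhibition/inhibits.  Optional `source_category` /
#' `target_category` columns assign node categories; optional evidence
#' columns (`reference_id`, `cell_type`, `species`, `culture`, `pathology`)
#' are collected into per-interaction evidence records, one per row.  Any
#' other column is preserved as an evidence annotation.  Node labels are
#' whitespace-trimmed and ASCII aliases (e.g. "IL-1b") are canonicalised to
#' their Greek forms ("IL-1β").
#'
#' @param path file path.
#' @param dialect `"edge-list-csv"` (default) or `"edge-list-tsv"`.
#' @return a validated `regulatory_network`.
#' @export
parse_interaction_table <- function(path,
                                    dialect = c("edge-list-csv",
                                                "edge-list-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  sep <- if (dialect == "edge-list-csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           encoding = "UTF-8")
  need <- c("source", "target", "effect")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    format_error(sprintf("missing required column(s): %s",
                         paste(miss, collapse = ", ")))
  if (!nrow(tab)) {
    return(regulatory_network(character(0), NULL))
  }
  tab$source <- canonical_node_name(as.character(tab$source))
  tab$target <- canonical_node_name(as.character(tab$target))
  tab$effect <- parse_effect(tab$effect)

  # unique interactions; duplicate rows with consistent sign are evidence
  key <- paste(tab$source, tab$target, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(tab$effect[key == k])) > 1L) {
      pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
      conflict_error(sprintf(
        "rows with opposite signs for interaction (%s, %s)", pair[1], pair[2]),
        pair = pair)
    }
  }
  first <- !duplicated(key)
  inter <- tab[first, c("source", "target", "effect")]
  rownames(inter) <- NULL

  names_all <- unique(c(tab$source, tab$target))
  category <- stats::setNames(rep("other", length(names_all)), names_all)
  if ("source_category" %in% names(tab)) {
    ok <- !is.na(tab$source_category) & tab$source_category != ""
    category[tab$source[ok]] <- tab$source_category[ok]
  }
  if ("target_category" %in% names(tab)) {
    ok <- !is.na(tab$target_category) & tab$target_category != ""
    category[tab$target[ok]] <- tab$target_category[ok]
  }
  nodes <- data.frame(name = names_all, category = unname(category[names_all]))

  extra <- setdiff(names(tab), canonical_columns())
  ev_cols <- intersect(c(EVIDENCE_COLUMNS, extra), names(tab))
  if (length(ev_cols)) {
    ev <- tab[, c("source", "target", ev_cols), drop = FALSE]
    rownames(ev) <- NULL
  } else {
    ev <- NULL
  }
  regulatory_network(nodes, inter, ev)
}

#' Export a regulatory network
#'
#' Writes `net` to `path` in one of three formats: `"edge-list-csv"` (the
#' canonical round-trippable format, one row per evidence record, bare
#' interactions written with "n/a" evidence fields), `"sif"` (Cytoscape
#' simple-interaction format, relation `activates`/`inhibits`), or
#' `"graphml"` (via igraph, with the sign as an edge attribute and the node
#' category as a node attribute).
#'
#' @param net a `regulatory_network`.
#' @param path output file path.
#' @param format output format.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("edge-list-csv", "sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) usage_error(sprintf(
                       "unsupported export format '%s'", format[1])))
  validate_network(net)
  inter <- net$interactions
  switch(format,
    "edge-list-csv" = {
      cat_of <- stats::setNames(net$nodes$category, net$nodes$name)
      ev <- net$evidence
      key_i <- paste(inter$source, inter$target, sep = "\r")
      key_e <- paste(ev$source, ev$target, sep = "\r")
      rows <- lapply(seq_len(nrow(inter)), function(i) {
        hits <- which(key_e == key_i[i])
        base <- data.frame(source = inter$source[i], target = inter$target[i],
                           effect = inter$effect[i],
                           source_category = unname(cat_of[inter$source[i]]),
                           target_category = unname(cat_of[inter$target[i]]))
        if (length(hits)) {
          cbind(base[rep(1L, length(hits)), , drop = FALSE],
                ev[hits, setdiff(names(ev), c("source", "target")),
                   drop = FALSE], row.names = NULL)
        } else {
          for (col in EVIDENCE_COLUMNS) base[[col]] <- "n/a"
          base
        }
      })
      out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(source = character(0), target = character(0),
                   effect = integer(0))
      utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
    },
    "sif" = {
      rel <- ifelse(inter$effect == 1L, "activates", "inhibits")
      lines <- sprintf("%s\t%s\t%s", inter$source, rel, inter$target)
      isolated <- setdiff(net$nodes$name, c(inter$source, inter$target))
      con <- file(path, open = "wt", encoding = "UTF-8")
      on.exit(close(con))
      writeLines(c(lines, isolated), con)
    },
    "graphml" = {
      g <- igraph::graph_from_data_frame(
        d = transform(inter, sign = ifelse(effect == 1L, "activation",
                                           "inhibition")),
        directed = TRUE,
        vertices = data.frame(name = net$nodes$name,
                              category = net$nodes$category))
      igraph::write_graph(g, path, format = "graphml")
    }
  )
  invisible(path)
}

#' Read a GraphML or SIF network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"sif"`.
#' @return a `regulatory_network` (evidence-free; those formats carry
#'   topology and signs only).
#' @export
import_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    vd <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(name = vd$name,
                        category = if ("category" %in% names(vd))
                          vd$category else "other")
    inter <- if (nrow(ed)) {
      data.frame(source = ed$from, target = ed$to,
                 effect = ifelse(ed$sign == "activation", 1L, -1L))
    } else NULL
    regulatory_network(nodes, inter)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edge <- vapply(parts, length, 0L) >= 3L
    inter <- if (any(edge)) {
      data.frame(
        source = vapply(parts[edge], `[`, "", 1L),
        effect = ifelse(vapply(parts[edge], `[`, "", 2L) == "activates",
                        1L, -1L),
        target = vapply(parts[edge], `[`, "", 3L))
    } else NULL
    solo <- vapply(parts[!edge], `[`, "", 1L)
    nodes <- unique(c(if (!is.null(inter)) c(inter$source, inter$target), solo))
    regulatory_network(nodes, inter)
  }
}

#' Summarise the evidence corpus of a network
#'
#' Cross-tabulates interaction evidence by cell type, species and culture
#' (link counts and distinct reference counts), and separately by pathology.
#' Missing annotations are counted under `"n/a"`.  A "link" is one evidence
#' record (so an interaction supported by two papers contributes two links);
#' reference counts are distinct `reference_id` values.
#'
#' @param net a `regulatory_network` with evidence annotations.
#' @return list with data.frames `by_source` (cell_type, species, culture,
#'   links, papers), `by_pathology` (pathology, links, papers), and a
#'   `totals` list (links, papers).
#' @export
corpus_summary <- function(net) {
  validate_network(net)
  ev <- net$evidence
  if (!nrow(ev)) {
    empty <- data.frame(cell_type = character(0), species = character(0),
                        culture = character(0), links = integer(0),
                        papers = integer(0))
    return(list(by_source = empty,
                by_pathology = data.frame(pathology = character(0),
                                          links = integer(0),
                                          papers = integer(0)),
                totals = list(links = 0L, papers = 0L)))
  }
  for (col in EVIDENCE_COLUMNS) {
    ev[[col]] <- as.character(ev[[col]])
    ev[[col]][is.na(ev[[col]]) | ev[[col]] == ""] <- "n/a"
  }
  by_source <- do.call(rbind, lapply(
    split(ev, list(ev$cell_type, ev$species, ev$culture), drop = TRUE),
    function(d) data.frame(cell_type = d$cell_type[1], species = d$species[1],
                           culture = d$culture[1], links = nrow(d),
                           papers = length(unique(d$reference_id)))))
  by_source <- by_source[order(by_source$cell_type, by_source$species,
                               by_source$culture), , drop = FALSE]
  rownames(by_source) <- NULL
  by_pathology <- do.call(rbind, lapply(split(ev, ev$pathology), function(d)
    data.frame(pathology = d$pathology[1], links = nrow(d),
               papers = length(unique(d$reference_id)))))
  rownames(by_pathology) <- NULL
  list(by_source = by_source, by_pathology = by_pathology,
       totals = list(links = nrow(ev),
                     papers = length(unique(ev$reference_id))))
}
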