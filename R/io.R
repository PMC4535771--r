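#' Read a network from SIF, edge list, or GraphML
#'
#' Returns an undirected, simple [igraph][igraph::igraph-package] graph over
#' string node IDs. Self-loops and duplicate edges are removed; isolated
#' nodes are retained when the format declares them (a single-token line in
#' SIF/edge-list files, a `<node>` without incident edges in GraphML). The
#' interaction-type column of SIF files is ignored for topology: protein
#' interaction graphs are treated as undirected for the Laplacian.
#'
#' @param path path to the network file.
#' @param format one of `"sif"`, `"edgelist"`, `"graphml"`; default guesses
#'   from the file extension (`.sif`, `.graphml`/`.xml`, else edge list).
#' @return an undirected simple `igraph` object with vertex attribute `name`.
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("A pp B", "B pp C"), f)
#' g <- readNetwork(f)
#' igraph::vcount(g)  # 3
#' @export
readNetwork <- function(path, format = c("auto", "sif", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sif = "sif",
      graphml = "graphml",
      xml = "graphml",
      "edgelist"
    )
  }
  if (format == "graphml") {
    g <- readGraphml(path)$graph
  } else {
    lines <- readLines(path, warn = FALSE)
    nodes <- character()
    from <- character()
    to <- character()
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (nchar(ln) == 0L) next
      tok <- strsplit(ln, "[ \t]+")[[1]]
      if (format == "sif") {
        if (length(tok) == 1L) {
          nodes <- c(nodes, tok)
        } else if (length(tok) >= 3L) {
          # node relation target1 [target2 ...]
          from <- c(from, rep(tok[1], length(tok) - 2L))
          to <- c(to, tok[3:length(tok)])
        } else {
          stop(sprintf("unparsable SIF line %d: '%s'", i, lines[i]))
        }
      } else { # edgelist
        if (length(tok) == 1L) {
          nodes <- c(nodes, tok)
        } else if (length(tok) == 2L) {
          from <- c(from, tok[1])
          to <- c(to, tok[2])
        } else {
          stop(sprintf("unparsable edge-list line %d: '%s'", i, lines[i]))
        }
      }
    }
    g <- buildGraph(unique(c(nodes, from, to)), from, to)
  }
  if (igraph::vcount(g) == 0L) stop("network has an empty node set")
  g
}

# Assemble an undirected simple graph from endpoint vectors.
buildGraph <- function(nodes, from, to) {
  keep <- from != to
  if (any(!keep)) warning("self-loops dropped: ", sum(!keep))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network to SIF, edge list or GraphML
#'
#' SIF rows are `source pp target`; isolated nodes get a single-token row
#' (both SIF and edge list), so re-reading the file recovers the same graph.
#'
#' @param network an igraph network.
#' @param path output file path.
#' @param format `"sif"`, `"edgelist"` or `"graphml"`; default guesses from
#'   the extension.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(network, path,
                         format = c("auto", "sif", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml",
                     "edgelist")
  }
  ids <- igraph::V(network)$name
  el <- igraph::as_edgelist(network, names = TRUE)
  if (format == "graphml") {
    zeros <- matrix(0, length(ids), 2, dimnames = list(ids, c("x", "y")))
    # GraphML always carries x/y keys; a pure topology write uses zeros
    return(writeLayout(zeros, network, path, format = "graphml"))
  }
  isolated <- setdiff(ids, unique(as.vector(el)))
  lines <- character()
  if (nrow(el)) {
    lines <- if (format == "sif")
      paste(el[, 1], "pp", el[, 2], sep = "\t")
    else
      paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a node-attribute data matrix from TSV
#'
#' Expects a header row of attribute names, first column node IDs, tab
#' separated. Empty cells, `NA` and `NaN` denote missing values and become
#' `NA` in the returned matrix.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with node IDs as rownames; `NA` marks missing.
#' @export
readDataMatrix <- function(path) {
  if (!file.exists(path)) stop("data matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nchar(trimws(lines)) > 0L]
  if (length(lines) < 1L) stop("empty data matrix file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("zero data columns")
  cols <- header[-1]
  if (anyDuplicated(cols)) stop("duplicate column names")
  if (length(lines) < 2L) stop("zero data rows")
  ids <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, length(lines) - 1L, length(cols))
  for (i in 2:length(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(tok) < length(header)) tok <- c(tok, rep("", length(header) - length(tok)))
    if (length(tok) != length(header))
      stop(sprintf("row %d has %d fields, expected %d", i - 1L, length(tok), length(header)))
    ids[i - 1L] <- tok[1]
    for (j in 2:length(tok)) {
      cell <- trimws(tok[j])
      if (cell == "" || cell == "NA" || cell == "NaN") next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        stop(sprintf("non-numeric cell at row %d ('%s'), column '%s': '%s'",
                     i - 1L, tok[1], cols[j - 1L], cell))
      vals[i - 1L, j - 1L] <- v
    }
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate row IDs: ", paste(unique(dup), collapse = ", "))
  rownames(vals) <- ids
  colnames(vals) <- cols
  vals
}

#' Restrict a data matrix to nodes of a network
#'
#' Matrix rows whose ID does not occur among the network's nodes are dropped
#' with a warning; node IDs are case-sensitive exact strings.
#'
#' @param mat numeric data matrix with node IDs as rownames.
#' @param network an igraph network.
#' @return the matrix restricted to mapped rows, in original row order.
#' @export
matchToNetwork <- function(mat, network) {
  ids <- igraph::V(network)$name
  keep <- rownames(mat) %in% ids
  if (any(!keep))
    warning(sum(!keep), " matrix row(s) not present in the network dropped: ",
            paste(utils::head(rownames(mat)[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("no matrix rows map to network nodes")
  mat[keep, , drop = FALSE]
}

#' Write a layout to GraphML, XGMML or TSV
#'
#' GraphML stores coordinates as node data keys `x`/`y`; XGMML as
#' `<graphics x= y=>` attributes; TSV as columns `id`, `x`, `y`. Coordinates
#' are written with enough digits that reading the file back recovers them
#' to at least six decimal places.
#'
#' @param layout n x 2 coordinate matrix with node IDs as rownames.
#' @param network igraph network whose nodes must all have a position.
#' @param path output file path.
#' @param format `"graphml"`, `"xgmml"` or `"tsv"`; default guesses from the
#'   extension.
#' @return the path, invisibly.
#' @export
writeLayout <- function(layout, network, path,
                        format = c("auto", "graphml", "xgmml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", xgmml = "xgmml", "tsv")
  }
  layout <- asLayout(layout)
  ids <- igraph::V(network)$name
  missing <- setdiff(ids, rownames(layout))
  if (length(missing))
    stop("nodes without a position: ", paste(missing, collapse = ", "))
  layout <- layout[ids, , drop = FALSE]
  fmtNum <- function(v) sprintf("%.10f", v)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("id\tx\ty", con)
    writeLines(paste(ids, fmtNum(layout[, 1]), fmtNum(layout[, 2]), sep = "\t"), con)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  if (format == "graphml") {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (k in c("x", "y")) {
      xml2::xml_add_child(doc, "key", id = k, `for` = "node",
                          attr.name = k, attr.type = "double")
    }
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
    for (i in seq_along(ids)) {
      nd <- xml2::xml_add_child(gr, "node", id = ids[i])
      dx <- xml2::xml_add_child(nd, "data", key = "x")
      xml2::xml_text(dx) <- fmtNum(layout[i, 1])
      dy <- xml2::xml_add_child(nd, "data", key = "y")
      xml2::xml_text(dy) <- fmtNum(layout[i, 2])
    }
    if (nrow(el)) for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(gr, "edge", source = el[i, 1], target = el[i, 2])
    }
    xml2::write_xml(doc, path)
  } else { # xgmml
    doc <- xml2::xml_new_root("graph",
      label = "ddlayout", directed = "0",
      xmlns = "http://www.cs.rpi.edu/XGMML")
    for (i in seq_along(ids)) {
      nd <- xml2::xml_add_child(doc, "node", id = ids[i], label = ids[i])
      xml2::xml_add_child(nd, "graphics",
                          x = fmtNum(layout[i, 1]), y = fmtNum(layout[i, 2]))
    }
    if (nrow(el)) for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(doc, "edge", source = el[i, 1], target = el[i, 2])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

# Parse GraphML: graph topology plus x/y node data where present.
readGraphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keyNodes <- xml2::xml_find_all(doc, ".//g:key", ns)
  keyMap <- stats::setNames(
    xml2::xml_attr(keyNodes, "attr.name"),
    xml2::xml_attr(keyNodes, "id")
  )
  nodeEls <- xml2::xml_find_all(doc, ".//g:node", ns)
  if (length(nodeEls) == 0L) stop("GraphML file declares no nodes")
  ids <- xml2::xml_attr(nodeEls, "id")
  coords <- matrix(NA_real_, length(ids), 2, dimnames = list(ids, c("x", "y")))
  for (i in seq_along(nodeEls)) {
    datas <- xml2::xml_find_all(nodeEls[[i]], "./g:data", ns)
    for (d in datas) {
      key <- xml2::xml_attr(d, "key")
      nm <- if (!is.na(key) && key %in% names(keyMap)) keyMap[[key]] else key
      if (identical(nm, "x")) coords[i, 1] <- as.numeric(xml2::xml_text(d))
      if (identical(nm, "y")) coords[i, 2] <- as.numeric(xml2::xml_text(d))
    }
  }
  edgeEls <- xml2::xml_find_all(doc, ".//g:edge", ns)
  from <- xml2::xml_attr(edgeEls, "source")
  to <- xml2::xml_attr(edgeEls, "target")
  graph <- buildGraph(ids, from, to)
  layout <- if (all(is.finite(coords))) coords else NULL
  list(graph = graph, layout = layout)
}

readXgmml <- function(path) {
  doc <- xml2::read_xml(path)
  nsAll <- xml2::xml_ns(doc)
  pref <- names(nsAll)[1]
  q <- function(tag) paste0(".//", pref, ":", tag)
  nodeEls <- xml2::xml_find_all(doc, q("node"), nsAll)
  if (length(nodeEls) == 0L) { # unnamespaced XGMML
    nodeEls <- xml2::xml_find_all(doc, ".//node")
    edgeEls <- xml2::xml_find_all(doc, ".//edge")
  } else {
    edgeEls <- xml2::xml_find_all(doc, q("edge"), nsAll)
  }
  if (length(nodeEls) == 0L) stop("XGMML file declares no nodes")
  ids <- xml2::xml_attr(nodeEls, "id")
  coords <- matrix(NA_real_, length(ids), 2, dimnames = list(ids, c("x", "y")))
  for (i in seq_along(nodeEls)) {
    gfx <- xml2::xml_find_first(nodeEls[[i]], "./*[local-name()='graphics']")
    if (!inherits(gfx, "xml_missing")) {
      coords[i, 1] <- as.numeric(xml2::xml_attr(gfx, "x"))
      coords[i, 2] <- as.numeric(xml2::xml_attr(gfx, "y"))
    }
  }
  from <- xml2::xml_attr(edgeEls, "source")
  to <- xml2::xml_attr(edgeEls, "target")
  graph <- buildGraph(ids, from, to)
  layout <- if (all(is.finite(coords))) coords else NULL
  list(graph = graph, layout = layout)
}

#' Read a layout (node positions) from GraphML, XGMML or TSV
#'
#' @param path input file.
#' @param format `"graphml"`, `"xgmml"` or `"tsv"`; default guesses from the
#'   extension.
#' @return n x 2 coordinate matrix with node IDs as rownames.
#' @export
readLayout <- function(path, format = c("auto", "graphml", "xgmml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", xgmml = "xgmml", "tsv")
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y")
    if (!all(need %in% names(tab)))
      stop("layout TSV must have columns id, x, y")
    m <- as.matrix(tab[, c("x", "y")])
    rownames(m) <- as.character(tab$id)
    return(asLayout(m))
  }
  parsed <- if (format == "graphml") readGraphml(path) else readXgmml(path)
  if (is.null(parsed$layout))
    stop("file carries no complete x/y coordinates: ", path)
  asLayout(parsed$layout)
}

#' Export a pre-processed data matrix
#'
#' `tsv` writes the same dialect [readDataMatrix()] reads (missing cells as
#' `NA`), so the file round-trips. `dat` writes the ViDaExpert dialect: a
#' first line with the number of data columns, a second line of per-column
#' type flags (`FLOAT`), then tab-separated rows led by the node ID.
#'
#' @param mat numeric matrix with node IDs as rownames.
#' @param path output file path.
#' @param format `"tsv"` or `"dat"`.
#' @return the path, invisibly.
#' @export
exportPreprocessed <- function(mat, path, format = c("tsv", "dat")) {
  format <- match.arg(format)
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("matrix is empty")
  fmtCell <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  rows <- apply(mat, 1, function(r) paste(fmtCell(r), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
    writeLines(paste(rownames(mat), rows, sep = "\t"), con)
  } else {
    # ViDaExpert .dat: column count, then type flags (STRING label column
    # followed by one FLOAT per data column), then rows.
    writeLines(as.character(ncol(mat)), con)
    writeLines(paste(c("STRING", rep("FLOAT", ncol(mat))), collapse = "\t"), con)
    writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
    writeLines(paste(rownames(mat), rows, sep = "\t"), con)
  }
  invisible(path)
}
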