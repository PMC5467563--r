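#' @include ssn.R
NULL

.xgmml_num <- function(x) sprintf("%.17g", x)

.att_type <- function(x) {
  if (is.integer(x)) "integer" else if (is.numeric(x)) "real" else "string"
}

.att_value <- function(x) {
  if (is.numeric(x) && !is.integer(x)) .xgmml_num(x) else as.character(x)
}

#' Write / read a similarity network as XGMML
#'
#' Cytoscape-compatible XGMML: one `graph` element with `node` elements
#' (integer ids, sequence id as label, every node attribute as a typed
#' `att`) and undirected `edge` elements whose `att`s carry evalue,
#' bit_score and pct_identity. Numeric attributes are written with 17
#' significant digits so a write/read round trip reproduces node ids, the
#' edge set and all attribute values exactly.
#'
#' @param net a [SimilarityNetwork-class].
#' @param path XGMML file.
#' @param label graph label.
#' @return `path` invisibly (`writeXgmml`); a [SimilarityNetwork-class]
#'   (`readXgmml`).
#' @export
writeXgmml <- function(net, path, label = "ssn") {
  stopifnot(is(net, "SimilarityNetwork"))
  doc <- xml2::xml_new_root("graph", label = label, directed = "0",
                            `xmlns` = "http://www.cs.rpi.edu/XGMML")
  xml2::xml_set_attr(doc, "kind", net@kind)
  ids <- setNames(seq_len(nrow(net@nodes)), net@nodes$id)
  for (i in seq_len(nrow(net@nodes))) {
    nd <- xml2::xml_add_child(doc, "node", id = as.character(ids[i]),
                              label = net@nodes$id[i])
    for (attrname in setdiff(names(net@nodes), "id")) {
      v <- net@nodes[[attrname]][i]
      if (is.na(v)) next
      xml2::xml_add_child(nd, "att", name = attrname,
                          type = .att_type(net@nodes[[attrname]]),
                          value = .att_value(v))
    }
  }
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    ed <- xml2::xml_add_child(doc, "edge",
                              source = as.character(ids[[e$from]]),
                              target = as.character(ids[[e$to]]),
                              label = paste0(e$from, ",", e$to))
    for (attrname in c("evalue", "bit_score", "pct_identity"))
      xml2::xml_add_child(ed, "att", name = attrname, type = "real",
                          value = .xgmml_num(e[[attrname]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeXgmml
#' @export
readXgmml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(x = xml2::xml_ns(doc)[[1]])
  nodes_xml <- xml2::xml_find_all(doc, "./x:node", ns = ns)
  edges_xml <- xml2::xml_find_all(doc, "./x:edge", ns = ns)
  if (!length(nodes_xml)) stop("XGMML contains no nodes")
  idmap <- setNames(xml2::xml_attr(nodes_xml, "label"),
                    xml2::xml_attr(nodes_xml, "id"))
  parse_atts <- function(el) {
    atts <- xml2::xml_find_all(el, "./x:att", ns = ns)
    setNames(lapply(seq_along(atts), function(k) {
      ty <- xml2::xml_attr(atts[k], "type")
      v <- xml2::xml_attr(atts[k], "value")
      switch(ty, integer = as.integer(v), real = as.numeric(v), v)
    }), xml2::xml_attr(atts, "name"))
  }
  node_rows <- lapply(seq_along(nodes_xml), function(i) {
    c(list(id = unname(idmap[i])), parse_atts(nodes_xml[i]))
  })
  allcols <- unique(unlist(lapply(node_rows, names)))
  nodes <- do.call(rbind, lapply(node_rows, function(r) {
    for (col in setdiff(allcols, names(r))) r[[col]] <- NA
    as.data.frame(r[allcols], stringsAsFactors = FALSE)
  }))
  edges <- if (length(edges_xml)) {
    do.call(rbind, lapply(seq_along(edges_xml), function(i) {
      a <- parse_atts(edges_xml[i])
      data.frame(from = unname(idmap[[xml2::xml_attr(edges_xml[i], "source")]]),
                 to = unname(idmap[[xml2::xml_attr(edges_xml[i], "target")]]),
                 evalue = a$evalue, bit_score = a$bit_score,
                 pct_identity = a$pct_identity, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(from = character(), to = character(), evalue = numeric(),
               bit_score = numeric(), pct_identity = numeric(),
               stringsAsFactors = FALSE)
  }
  kind <- xml2::xml_attr(doc, "kind")
  if (is.na(kind)) kind <- "full"
  new("SimilarityNetwork", nodes = nodes, edges = edges, kind = kind,
      metadata = list(source = path))
}
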