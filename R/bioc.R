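#' Read an annotated corpus from BioC XML
#'
#' Expects the BioC collection/document/passage/annotation layout. Document
#' infons `year`, `journal` and `mesh_clusters` are carried onto each
#' passage; the passage infon `type` holds the passage type. Annotation
#' infons: `type` (entity type), `identifier` (semicolon-joined ontology
#' ids), `qualifier` (semicolon-joined, parallel to `identifier`),
#' `annotator`, `coordination`. Annotation locations use document-level
#' offsets; they are converted to passage-local 0-based half-open spans.
#'
#' Every span is validated on read: a location falling outside its passage,
#' or annotation text disagreeing with the passage slice, is an error naming
#' the annotation id. Identifiers are not resolved here; use
#' [validate_corpus()] with an ontology to flag unresolved ids.
#'
#' @param path BioC XML file path.
#' @return an [annotated_corpus()].
#' @export
read_bioc <- function(path) {
  doc <- xml2::read_xml(path)
  source_ <- xml2::xml_text(xml2::xml_find_first(doc, "./source"))
  infon <- function(node, key) {
    v <- xml2::xml_find_first(node, sprintf("./infon[@key='%s']", key))
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  pas_rows <- list()
  ann_rows <- list()
  for (dnode in xml2::xml_find_all(doc, "./document")) {
    doc_id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    year <- infon(dnode, "year")
    journal <- infon(dnode, "journal")
    mesh <- infon(dnode, "mesh_clusters")
    k <- 0L
    for (pnode in xml2::xml_find_all(dnode, "./passage")) {
      k <- k + 1L
      offset <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode, "./offset")))
      text <- xml2::xml_text(xml2::xml_find_first(pnode, "./text"))
      if (is.na(text)) text <- ""
      pid <- infon(pnode, "passage_id")
      if (is.na(pid)) pid <- sprintf("%s-p%d", doc_id, k)
      pas_rows[[length(pas_rows) + 1L]] <- data.frame(
        passage_id = pid, doc_id = doc_id,
        passage_type = infon(pnode, "type"), text = text,
        year = suppressWarnings(as.integer(year)),
        journal = journal,
        mesh_clusters = if (is.na(mesh)) "" else mesh,
        stringsAsFactors = FALSE)
      for (anode in xml2::xml_find_all(pnode, "./annotation")) {
        aid <- xml2::xml_attr(anode, "id")
        loc <- xml2::xml_find_first(anode, "./location")
        start <- as.integer(xml2::xml_attr(loc, "offset")) - offset
        len <- as.integer(xml2::xml_attr(loc, "length"))
        atext <- xml2::xml_text(xml2::xml_find_first(anode, "./text"))
        if (is.na(start) || start < 0 || len < 1 || start + len > nchar(text)) {
          stop(sprintf("annotation %s: span [%d,%d) outside passage %s (length %d)",
                       aid, start, start + len, pid, nchar(text)))
        }
        if (!identical(substr(text, start + 1L, start + len), atext)) {
          stop(sprintf("annotation %s: text does not match passage slice", aid))
        }
        ids <- infon(anode, "identifier")
        quals <- infon(anode, "qualifier")
        who <- infon(anode, "annotator")
        coord <- infon(anode, "coordination")
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          passage_id = pid, ann_id = aid, start = start, end = start + len,
          text = atext, entity_type = infon(anode, "type"),
          identifiers = if (is.na(ids)) "" else ids,
          qualifiers = if (is.na(quals)) "" else quals,
          annotator = if (is.na(who)) "annotator1" else who,
          coordination = identical(coord, "true"),
          stringsAsFactors = FALSE)
      }
    }
  }
  annotated_corpus(
    passages = do.call(rbind, pas_rows),
    annotations = if (length(ann_rows)) do.call(rbind, ann_rows) else NULL,
    provenance = if (is.na(source_)) "" else source_)
}

#' Write an annotated corpus to BioC XML
#'
#' Canonical, deterministic output: passages grouped by `doc_id` in first
#' appearance order, document-level offsets, annotations ordered as stored.
#' `write_bioc(read_bioc(f), f2)` reproduces `f` byte-for-byte when `f` is
#' canonical output of this writer.
#'
#' @param corpus an [annotated_corpus()].
#' @param path output file path.
#' @export
write_bioc <- function(corpus, path) {
  doc <- xml2::xml_new_root("collection")
  add_text <- function(parent, tag, text) {
    n <- xml2::xml_add_child(parent, tag)
    xml2::xml_set_text(n, as.character(text))
    n
  }
  add_infon <- function(parent, key, value) {
    if (is.null(value) || is.na(value) || !nzchar(as.character(value))) return(invisible())
    n <- xml2::xml_add_child(parent, "infon", key = key)
    xml2::xml_set_text(n, as.character(value))
  }
  add_text(doc, "source", if (nzchar(corpus$provenance)) corpus$provenance else "corpuscle")
  xml2::xml_add_child(doc, "date")
  xml2::xml_add_child(doc, "key")
  pas <- corpus$passages
  ann <- corpus$annotations
  for (did in unique(pas$doc_id)) {
    dnode <- xml2::xml_add_child(doc, "document")
    dpas <- pas[pas$doc_id == did, , drop = FALSE]
    add_text(dnode, "id", did)
    add_infon(dnode, "year", dpas$year[1])
    add_infon(dnode, "journal", dpas$journal[1])
    add_infon(dnode, "mesh_clusters", dpas$mesh_clusters[1])
    offset <- 0L
    for (i in seq_len(nrow(dpas))) {
      p <- dpas[i, ]
      pnode <- xml2::xml_add_child(dnode, "passage")
      add_infon(pnode, "type", p$passage_type)
      add_infon(pnode, "passage_id", p$passage_id)
      add_text(pnode, "offset", offset)
      add_text(pnode, "text", p$text)
      pann <- ann[ann$passage_id == p$passage_id, , drop = FALSE]
      for (j in seq_len(nrow(pann))) {
        a <- pann[j, ]
        anode <- xml2::xml_add_child(pnode, "annotation", id = a$ann_id)
        add_infon(anode, "type", a$entity_type)
        add_infon(anode, "identifier", a$identifiers)
        add_infon(anode, "qualifier", a$qualifiers)
        add_infon(anode, "annotator", a$annotator)
        if (isTRUE(a$coordination)) add_infon(anode, "coordination", "true")
        xml2::xml_add_child(anode, "location",
                            offset = as.character(offset + a$start),
                            length = as.character(a$end - a$start))
        add_text(anode, "text", a$text)
      }
      offset <- offset + nchar(p$text) + 1L
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
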