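#' Write and read PASCAL VOC XML annotations
#'
#' Boxes are held internally as half-open, 0-based `x0, y0, x1, y1`. On disk
#' the PASCAL VOC dialect is used: 1-based, inclusive pixel indices, so a box
#' covering pixel columns `x0 .. x1-1` is stored as `xmin = x0 + 1`,
#' `xmax = x1`. The round trip `read_voc(write_voc(x))` is the identity on
#' coordinates and labels.
#'
#' @param annotations A data.frame with columns `x0, y0, x1, y1` and
#'   optionally `label` (default `"grain"`). May have zero rows.
#' @param image_meta List with `filename`, `width`, `height` and optionally
#'   `depth` (default 1).
#' @param path Output XML path.
#' @return `write_voc` returns `path` invisibly; `read_voc` returns a list
#'   with `annotations` (data.frame as above) and `image_meta`.
#' @examples
#' ann <- data.frame(x0 = 10, y0 = 20, x1 = 40, y1 = 80, label = "grain")
#' f <- tempfile(fileext = ".xml")
#' write_voc(ann, list(filename = "a.png", width = 100, height = 100), f)
#' read_voc(f)$annotations
#' @export
write_voc <- function(annotations, image_meta, path) {
  if (is.null(annotations)) annotations <- empty_detections()
  if (!is.data.frame(annotations)) stopf("annotations must be a data.frame")
  if (nrow(annotations) &&
        !all(c("x0", "y0", "x1", "y1") %in% names(annotations))) {
    stopf("annotations need columns x0, y0, x1, y1")
  }
  if (is.null(annotations$label)) {
    annotations$label <- rep("grain", nrow(annotations))
  }
  if (!all(c("filename", "width", "height") %in% names(image_meta))) {
    stopf("image_meta needs filename, width and height")
  }
  wd <- image_meta$width
  ht <- image_meta$height
  if (nrow(annotations)) {
    bad <- annotations$x1 <= annotations$x0 | annotations$y1 <= annotations$y0
    if (any(bad)) {
      stopf("degenerate box at row %d: xmax > xmin and ymax > ymin required",
            which(bad)[1])
    }
    out <- annotations$x0 < 0 | annotations$y0 < 0 |
      annotations$x1 > wd | annotations$y1 > ht
    if (any(out)) {
      stopf("box at row %d lies outside the %d x %d image",
            which(out)[1], wd, ht)
    }
  }

  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", image_meta$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(wd)))
  xml2::xml_add_child(size, "height", as.character(as.integer(ht)))
  xml2::xml_add_child(size, "depth",
                      as.character(as.integer(image_meta$depth %||% 1L)))
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(annotations))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", annotations$label[i])
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    ## VOC: 1-based inclusive indices.
    xml2::xml_add_child(bb, "xmin", format_coord(annotations$x0[i] + 1))
    xml2::xml_add_child(bb, "ymin", format_coord(annotations$y0[i] + 1))
    xml2::xml_add_child(bb, "xmax", format_coord(annotations$x1[i]))
    xml2::xml_add_child(bb, "ymax", format_coord(annotations$y1[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

format_coord <- function(x) {
  if (abs(x - round(x)) < 1e-9) as.character(as.integer(round(x)))
  else as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_voc
#' @export
read_voc <- function(path) {
  if (!file.exists(path)) stopf("no such annotation file: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stopf("malformed VOC XML in %s: %s", path, conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "annotation") {
    stopf("%s is not a VOC annotation file (root <%s>)",
          path, xml2::xml_name(doc))
  }
  num <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, tag))
    if (is.na(v) || !nzchar(v)) stopf("missing <%s> in %s", tag, path)
    as.numeric(v)
  }
  wd <- num(doc, ".//size/width")
  ht <- num(doc, ".//size/height")
  objs <- xml2::xml_find_all(doc, ".//object")
  rows <- lapply(objs, function(o) {
    bb <- xml2::xml_find_first(o, "bndbox")
    if (is.na(xml2::xml_name(bb))) stopf("object without <bndbox> in %s", path)
    data.frame(
      x0 = num(bb, "xmin") - 1, y0 = num(bb, "ymin") - 1,
      x1 = num(bb, "xmax"), y1 = num(bb, "ymax"),
      label = xml2::xml_text(xml2::xml_find_first(o, "name")),
      stringsAsFactors = FALSE
    )
  })
  ann <- if (length(rows)) do.call(rbind, rows) else
    empty_detections()[, c("x0", "y0", "x1", "y1", "label")]
  if (nrow(ann)) {
    if (any(ann$x1 <= ann$x0 | ann$y1 <= ann$y0)) {
      stopf("degenerate box in %s", path)
    }
    if (any(ann$x0 < 0 | ann$y0 < 0 | ann$x1 > wd | ann$y1 > ht)) {
      stopf("box outside the %g x %g image in %s", wd, ht, path)
    }
  }
  list(
    annotations = ann,
    image_meta = list(
      filename = xml2::xml_text(xml2::xml_find_first(doc, "filename")),
      width = wd, height = ht
    )
  )
}
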