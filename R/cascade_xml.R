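#' Cascade model XML serialization
#'
#' Trained cascades serialize to an XML layout patterned on the standard
#' cascade-classifier format: a `<cascade>` node with the base window size and
#' feature type, a `<stages>` list (stage threshold + weak classifiers, each a
#' stump with feature index, threshold, polarity and vote weight), and a
#' `<features>` list of weighted rectangles. Numbers are written with full
#' `%.17g` precision, so a save→load round trip reproduces detections exactly.
#'
#' @param model a `haar_cascade` from [train_cascade()].
#' @param path output `.xml` path.
#' @return `path`, invisibly (`write_cascade_xml`); a `haar_cascade`
#'   (`read_cascade_xml`).
#' @export
write_cascade_xml <- function(model, path) {
  stopifnot(inherits(model, "haar_cascade"))
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root("opencv_storage")
  casc <- xml2::xml_add_child(doc, "cascade", type_id = "grimace-haar-cascade")
  xml2::xml_add_child(casc, "stageType", "BOOST")
  xml2::xml_add_child(casc, "featureType", "HAAR")
  xml2::xml_add_child(casc, "featureKind", model$feature_kind)
  xml2::xml_add_child(casc, "height", as.character(model$window))
  xml2::xml_add_child(casc, "width", as.character(model$window))
  xml2::xml_add_child(casc, "objectFraction",
                      num(model$object_frac %||% 0.8))
  stages <- xml2::xml_add_child(casc, "stages")
  for (stage in model$stages) {
    sn <- xml2::xml_add_child(stages, "_")
    xml2::xml_add_child(sn, "maxWeakCount", as.character(length(stage$weaks)))
    xml2::xml_add_child(sn, "stageThreshold", num(stage$threshold))
    wks <- xml2::xml_add_child(sn, "weakClassifiers")
    for (wk in stage$weaks) {
      wn <- xml2::xml_add_child(wks, "_")
      # feature index (0-based), stump threshold, polarity, vote weight
      xml2::xml_add_child(wn, "internalNodes",
                          paste(wk$feature - 1L, num(wk$thr), wk$pol))
      xml2::xml_add_child(wn, "leafValues", num(wk$alpha))
    }
  }
  feats <- xml2::xml_add_child(casc, "features")
  for (f in model$features) {
    fn <- xml2::xml_add_child(feats, "_")
    rn <- xml2::xml_add_child(fn, "rects")
    for (k in seq_len(nrow(f))) {
      xml2::xml_add_child(rn, "_", paste(f[k, 1], f[k, 2], f[k, 3], f[k, 4],
                                         num(f[k, 5])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_cascade_xml
#' @export
read_cascade_xml <- function(path) {
  doc <- xml2::read_xml(path)
  casc <- xml2::xml_find_first(doc, "./cascade")
  if (inherits(casc, "xml_missing")) stop("no <cascade> node in ", path)
  txt <- function(node, xp) xml2::xml_text(xml2::xml_find_first(node, xp))
  window <- as.integer(txt(casc, "./width"))
  feature_kind <- txt(casc, "./featureKind")
  ofrac_txt <- txt(casc, "./objectFraction")
  object_frac <- if (is.na(ofrac_txt)) 0.8 else as.numeric(ofrac_txt)
  features <- lapply(xml2::xml_find_all(casc, "./features/_"), function(fn) {
    rows <- lapply(xml2::xml_find_all(fn, "./rects/_"), function(r) {
      as.numeric(strsplit(trimws(xml2::xml_text(r)), "\\s+")[[1]])
    })
    do.call(rbind, rows)
  })
  stages <- lapply(xml2::xml_find_all(casc, "./stages/_"), function(sn) {
    weaks <- lapply(xml2::xml_find_all(sn, "./weakClassifiers/_"), function(wn) {
      parts <- strsplit(trimws(txt(wn, "./internalNodes")), "\\s+")[[1]]
      list(feature = as.integer(parts[1]) + 1L,
           thr = as.numeric(parts[2]),
           pol = as.numeric(parts[3]),
           alpha = as.numeric(txt(wn, "./leafValues")))
    })
    list(threshold = as.numeric(txt(sn, "./stageThreshold")), weaks = weaks)
  })
  model <- structure(
    list(feature_kind = feature_kind, window = window,
         object_frac = object_frac, features = features,
         stages = stages, n_pos = NA_integer_, n_neg = NA_integer_,
         train_fa = NA_real_),
    class = "haar_cascade"
  )
  model$.flat <- flatten_cascade(model)
  model
}
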