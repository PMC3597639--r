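#' The 15 connexin combination classes
#'
#' Every nonempty subset of \{Cx26, Cx30, Cx43, Cx45\}: four single-connexin
#' ("homomeric/homotypic") classes, six pairs, four triples and one quadruple.
#' Labels are slash-joined member names in fixed channel order, e.g.
#' \code{"Cx26/Cx30/Cx45"}.
#'
#' @return character vector of the 15 class labels, singletons first, then by
#'   increasing subset size.
#' @export
combination_classes <- function() {
  subsets <- unlist(lapply(1:4, function(k) {
    combn(CX_CHANNELS, k, paste, collapse = "/", simplify = FALSE)
  }))
  unlist(subsets)
}

#' @describeIn combination_classes member connexins of one class label.
#' @param class a class label such as \code{"Cx26/Cx45"}.
#' @export
class_members <- function(class) {
  m <- strsplit(class, "/", fixed = TRUE)[[1]]
  if (length(m) == 0 || !all(m %in% CX_CHANNELS) || anyDuplicated(m)) {
    stop("not a valid combination class: ", class)
  }
  m
}

#' @describeIn combination_classes canonical label for a set of member
#'   connexins (sorted into fixed channel order).
#' @param members character vector of connexin names.
#' @export
class_label <- function(members) {
  stopifnot(length(members) >= 1, all(members %in% CX_CHANNELS))
  paste(CX_CHANNELS[CX_CHANNELS %in% members], collapse = "/")
}
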