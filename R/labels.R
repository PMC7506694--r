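#' Knee-condition class labels
#'
#' The five admissible condition labels, in report order: healthy control
#' (`ctrl`), chondromalacia patellae stages I-III (`cmp1`, `cmp2`, `cmp3`)
#' and osteoarthritis (`oa`).
#'
#' @return Character vector of the five labels in canonical order.
#' @export
#' @examples
#' vag_labels()
vag_labels <- function() {
  c("ctrl", "cmp1", "cmp2", "cmp3", "oa")
}

#' Parse and validate condition labels
#'
#' @param x Character vector of labels.
#' @return Factor with levels in canonical order.
#' @keywords internal
as_vag_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), vag_labels())
  if (length(bad) > 0) {
    vag_stop(sprintf(
      "unknown class label(s): %s (admissible: %s)",
      paste(sQuote(bad), collapse = ", "),
      paste(vag_labels(), collapse = ", ")
    ))
  }
  factor(x, levels = vag_labels())
}

#' The ten class pairs in canonical (letter a-j) order
#'
#' Every unordered pair of the five condition classes, lettered `a` to `j`
#' in the order ctrl-cmp1, ctrl-cmp2, ..., cmp3-oa. This is the column
#' order of the ten-element feature vector.
#'
#' @return Data frame with columns `letter`, `class_a`, `class_b`.
#' @export
#' @examples
#' class_pairs()
class_pairs <- function() {
  labs <- vag_labels()
  idx <- utils::combn(5L, 2L)
  data.frame(
    letter = letters[seq_len(ncol(idx))],
    class_a = labs[idx[1L, ]],
    class_b = labs[idx[2L, ]],
    stringsAsFactors = FALSE
  )
}

# Canonical letter for an unordered pair of labels, or error.
pair_letter <- function(class_a, class_b) {
  p <- class_pairs()
  ab <- sort(factor(c(class_a, class_b), levels = vag_labels()))
  hit <- which(p$class_a == as.character(ab[1L]) & p$class_b == as.character(ab[2L]))
  if (length(hit) != 1L) {
    vag_stop(sprintf("not a valid class pair: (%s, %s)", class_a, class_b))
  }
  p$letter[hit]
}
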