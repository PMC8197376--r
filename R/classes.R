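#' Vocalization classes
#'
#' The study corpus distinguishes five vocalization classes from two anuran
#' species: three for the natterjack toad *Epidalea calamita* (standard
#' advertisement call, chorus, amplexus call) and two for the midwife toad
#' *Alytes obstetricans* (standard call, distress call). Because the chorus
#' of *E. calamita* is acoustically close to its standard call, a merged
#' four-class labelling is also used, in which `ec_standard` and `ec_chorus`
#' collapse into a single `ec_st&ch` label.
#'
#' @return `call_classes()` returns the character vector of the five fine
#'   class identifiers. `merged_classes()` returns the four merged labels.
#' @examples
#' call_classes()
#' merge_class(c("ec_standard", "ec_chorus", "ao_distress"))
#' @export
call_classes <- function() {
  c("ec_standard", "ec_chorus", "ec_amplexus", "ao_standard", "ao_distress")
}

#' @rdname call_classes
#' @export
merged_classes <- function() {
  c("ec_st&ch", "ec_amplexus", "ao_standard", "ao_distress")
}

#' @rdname call_classes
#' @param label character vector of fine class identifiers.
#' @return `merge_class()` maps fine labels to the merged four-class labels.
#' @export
merge_class <- function(label) {
  bad <- setdiff(unique(label), call_classes())
  if (length(bad))
    stop("unknown call class: ", paste(bad, collapse = ", "))
  out <- label
  out[label %in% c("ec_standard", "ec_chorus")] <- "ec_st&ch"
  out
}

assert_class <- function(label) {
  if (length(label) != 1L || !label %in% call_classes())
    stop("label must be one of: ", paste(call_classes(), collapse = ", "))
  invisible(label)
}
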