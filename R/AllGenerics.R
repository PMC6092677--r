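#' Accessor generics
#'
#' `eventTable()` returns the per-event data.frame of a sample or gated
#' object; `controlTable()` the paired negative-control table;
#' `halflife()` the fitted half-life in hours.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("controlTable", function(x) standardGeneric("controlTable"))

#' @rdname accessors
#' @export
setGeneric("halflife", function(x) standardGeneric("halflife"))
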