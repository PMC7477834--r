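#' @export
setGeneric("svCalls", function(x, ...) standardGeneric("svCalls"))

#' @export
setGeneric("signatures", function(x, ...) standardGeneric("signatures"))

#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @export
setGeneric("contigTable", function(x) standardGeneric("contigTable"))
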