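#' Free energy of duplex formation
#'
#' @param object a [DuplexThermo-class] object.
#' @param tempC evaluation temperature, degrees C (default 37).
#' @return dG in kcal/mol.
#' @export
setGeneric("deltaG", function(object, tempC = 37) standardGeneric("deltaG"))

#' Two-state melting temperature
#'
#' @param object a [DuplexThermo-class] object.
#' @param ... unused.
#' @return Tm in degrees C.
#' @export
setGeneric("meltingTemperature",
           function(object, ...) standardGeneric("meltingTemperature"))

#' Equilibrium unbound fraction of a duplex
#'
#' @param object a [DuplexThermo-class] object.
#' @param tempC temperature(s), degrees C.
#' @return Fraction of strands unbound, in \[0, 1\]; vectorized over `tempC`.
#' @export
setGeneric("unboundFraction",
           function(object, tempC) standardGeneric("unboundFraction"))

#' Strand sequences of a library
#' @param x a [StrandLibrary-class].
#' @return A [Biostrings::DNAStringSet] named by strand id.
#' @export
setGeneric("strands", function(x) standardGeneric("strands"))

#' Per-strand metadata of a library
#' @param x a [StrandLibrary-class].
#' @return data.frame with columns id, bit, position, sense, dye.
#' @export
setGeneric("strandInfo", function(x) standardGeneric("strandInfo"))

#' Information domains of a library
#' @param x a [StrandLibrary-class].
#' @return Named character: per bit, the 15-nt sense information domain.
#' @export
setGeneric("infoDomains", function(x) standardGeneric("infoDomains"))

#' Domain annotations of a library
#' @param x a [StrandLibrary-class].
#' @return data.frame of 1-based closed spans per strand.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
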