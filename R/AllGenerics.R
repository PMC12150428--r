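#' Stoichiometry matrix of a network
#' @param object a \linkS4class{ReactionNetwork}.
#' @return integer matrix, species x reactions.
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' Species names
#' @param object an object holding species.
#' @return character vector.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' Rate-parameter map
#' @param object a \linkS4class{ReactionNetwork}.
#' @return named numeric vector of rate constants (1/min).
#' @export
setGeneric("parameters", function(object) standardGeneric("parameters"))

#' Sink (truncation-error) mass of an FSP solution
#'
#' \eqn{g(t)} is the exact probability that the process has left the
#' truncated state space by time t; it is nondecreasing and bounds the
#' total variation error of the projected distribution.
#'
#' @param object an \linkS4class{FSPSolution}.
#' @return numeric vector, one value per grid time (named by time).
#' @export
setGeneric("sinkMass", function(object) standardGeneric("sinkMass"))

#' Number of retained states
#' @param object a \linkS4class{StateSpace} or \linkS4class{FSPSolution}.
#' @return integer.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
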