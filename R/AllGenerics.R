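#' @rdname SurvivalCohort
#' @param x,object a `SurvivalCohort`.
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname SurvivalCohort
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname SurvivalCohort
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @rdname RiskLabels-class
#' @param x a `RiskLabels`.
#' @export
setGeneric("riskGroups", function(x) standardGeneric("riskGroups"))

#' @rdname FeatureRanking-class
#' @param x a `FeatureRanking`.
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("eliminationStep", function(x) standardGeneric("eliminationStep"))
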