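#' Accessors for partcong containers
#'
#' Small generics giving read access to the S4 containers: taxon labels,
#' character ids, dimensions, charsets, trees and parsimony score.
#'
#' @param x a partcong object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("characterIds", function(x) standardGeneric("characterIds"))
#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setGeneric("nCharacters", function(x) standardGeneric("nCharacters"))
#' @rdname accessors
#' @export
setGeneric("charsets", function(x) standardGeneric("charsets"))
#' @rdname accessors
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))
#' @rdname accessors
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' @rdname accessors
#' @export
setMethod("taxa", "CharacterMatrix", function(x) rownames(x@masks))
#' @rdname accessors
#' @export
setMethod("characterIds", "CharacterMatrix", function(x) colnames(x@masks))
#' @rdname accessors
#' @export
setMethod("nTaxa", "CharacterMatrix", function(x) nrow(x@masks))
#' @rdname accessors
#' @export
setMethod("nCharacters", "CharacterMatrix", function(x) ncol(x@masks))
#' @rdname accessors
#' @export
setMethod("charsets", "CharacterMatrix", function(x) x@charsets)
#' @rdname accessors
#' @export
setMethod("trees", "TreeSet", function(x) x@trees)
#' @rdname accessors
#' @export
setMethod("score", "TreeSet", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("pValue", "IncongruenceResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("partitionLabels", "PartitionScheme", function(x) x@labels)

#' @export
setMethod("length", "TreeSet", function(x) length(x@trees))

setMethod("show", "CharacterMatrix", function(object) {
  cat(sprintf("CharacterMatrix: %d taxa x %d characters\n",
              nTaxa(object), nCharacters(object)))
  miss <- mean(object@special != 0L) * 100
  cat(sprintf("  missing/inapplicable: %.1f%% of cells\n", miss))
  if (length(object@charsets))
    cat("  charsets:", paste(sprintf("%s (%d)", names(object@charsets),
        lengths(object@charsets)), collapse = ", "), "\n")
})

setMethod("show", "PartitionScheme", function(object) {
  tb <- table(object@labels)
  cat(sprintf("PartitionScheme: %d craniodental, %d postcranial, %d other\n",
              tb[["craniodental"]], tb[["postcranial"]], tb[["other"]]))
})

setMethod("show", "TreeSet", function(object) {
  cat(sprintf("TreeSet: %d tree(s) on %d leaves, length %g steps\n",
              length(object@trees), length(object@leafLabels), object@score))
})

setMethod("show", "IncongruenceResult", function(object) {
  lab <- if (object@method == "ILD") "ILD" else
    sprintf("IRD (%s, %s)", object@mode, object@metric)
  cat(sprintf("%s test: observed = %g, p = %.4g (%d replicates)\n",
              lab, object@observed, object@pValue, object@replicates))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf(
    "Partition vs entire matrix (n = %d characters, %d resamples)\n",
    object@n, object@nResamples))
  cat(sprintf("  mean NND matching: craniodental %.4f, postcranial %.4f\n",
              object@means[["cranio"]], object@means[["post"]]))
  cat(sprintf("  winner: %s (paired Wilcoxon p = %.4g, Mann-Whitney p = %.4g)\n",
              object@winner, object@pPairedWilcoxon, object@pMannWhitney))
})

setMethod("show", "StratResult", function(object) {
  cat(sprintf("Stratigraphic congruence over %d tree(s):\n", nrow(object@perTree)))
  m <- object@means
  cat(sprintf("  mean GER = %.3f, GER* = %.3f, MSM* = %.3f, SCI = %.3f\n",
              m[["GER"]], m[["GERstar"]], m[["MSM"]], m[["SCI"]]))
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport: S = %g, M = %g, G = %g, CI = %.4f, RI = %s\n",
              object@S, object@M, object@G, object@CI,
              ifelse(is.na(object@RI), "undefined", sprintf("%.4f", object@RI))))
})

setMethod("show", "CurationReport", function(object) {
  cat(sprintf("CurationReport (threshold %.2f): %d taxa, %d characters removed\n",
              object@threshold, nrow(object@removedTaxa),
              nrow(object@removedCharacters)))
})

setMethod("show", "SearchConfig", function(object) {
  cat(sprintf(
    "SearchConfig: %d addition sequences, hold %d, maxtrees %d (swap %d), NND cap %d, collapse %s\n",
    object@nadd, object@hold, object@maxtrees, object@swapmax,
    object@nndTreeCap, object@collapseZero))
})
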