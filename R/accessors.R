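# generics, accessors and show methods

#' @rdname DescriptorMatrix-class
#' @param object,x a \linkS4class{DescriptorMatrix}.
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname DescriptorMatrix-class
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @rdname DescriptorMatrix-class
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @rdname DescriptorMatrix-class
#' @export
setMethod("descriptorNames", "DescriptorMatrix", function(x) colnames(x@values))

#' @rdname DescriptorMatrix-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname DescriptorMatrix-class
#' @export
setMethod("compoundIds", "DescriptorMatrix", function(x) rownames(x@values))
#' @rdname EndpointDataset-class
#' @export
setMethod("compoundIds", "EndpointDataset", function(x) x@compounds$cas)

#' @rdname DescriptorMatrix-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname DescriptorMatrix-class
#' @export
setMethod("provenance", "DescriptorMatrix", function(x) x@provenance)

#' Subset a DescriptorMatrix by compound and/or descriptor
#' @param i compound ids or indices.
#' @param j descriptor names or indices.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @rdname DescriptorMatrix-class
#' @export
setMethod("[", "DescriptorMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("DescriptorMatrix", values = v, provenance = x@provenance,
      pruneLog = x@pruneLog)
})

#' @rdname EndpointDataset-class
#' @param x an \linkS4class{EndpointDataset}.
#' @export
setGeneric("retainedCompounds", function(x) standardGeneric("retainedCompounds"))
#' @rdname EndpointDataset-class
#' @export
setMethod("retainedCompounds", "EndpointDataset", function(x)
  x@compounds[x@compounds$retained, , drop = FALSE])

#' @rdname EndpointDataset-class
#' @export
setGeneric("transformedResponse", function(x) standardGeneric("transformedResponse"))
#' @rdname EndpointDataset-class
#' @export
setMethod("transformedResponse", "EndpointDataset", function(x) {
  cp <- retainedCompounds(x)
  stats::setNames(cp$response_transformed, cp$cas)
})

#' @rdname BoxCoxTransform-class
#' @param x a \linkS4class{BoxCoxTransform}.
#' @export
setGeneric("lambdaOf", function(x) standardGeneric("lambdaOf"))
#' @rdname BoxCoxTransform-class
#' @export
setMethod("lambdaOf", "BoxCoxTransform", function(x) x@lambda)

#' @rdname ToxModelBundle-class
#' @param x a \linkS4class{ToxModelBundle}.
#' @export
setGeneric("selectedDescriptors", function(x) standardGeneric("selectedDescriptors"))
#' @rdname ToxModelBundle-class
#' @export
setMethod("selectedDescriptors", "ToxModelBundle", function(x)
  x@selectedDescriptors)

#' @rdname ToxModelBundle-class
#' @export
setGeneric("adConfig", function(x) standardGeneric("adConfig"))
#' @rdname ToxModelBundle-class
#' @export
setMethod("adConfig", "ToxModelBundle", function(x) x@ad)

setMethod("show", "BoxCoxTransform", function(object) {
  cat(sprintf("BoxCoxTransform: lambda = %.4f, mean_t = %.4f, sd_t = %.4f\n",
              object@lambda, object@meanT, object@sdT))
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d compounds x %d descriptors [%s]\n",
              nrow(object@values), ncol(object@values), object@provenance))
  if (length(object@pruneLog))
    cat("  pruning:", paste(object@pruneLog, collapse = "; "), "\n")
})

setMethod("show", "EndpointDataset", function(object) {
  cp <- object@compounds
  cat(sprintf("EndpointDataset: %s %s (%s)\n", object@species,
              object@endpoint, object@trophicLevel))
  cat(sprintf("  %d compounds retained, %d excluded\n",
              sum(cp$retained), sum(!cp$retained)))
  show(object@transform)
})

setMethod("show", "ADConfig", function(object) {
  cat(sprintf(
    "ADConfig: %s-%d, T_D %.3g (pct %.3g), T_E %.3g (pct %.3g)\n",
    object@metric, object@k, object@tdValue, object@tdPercentile,
    object@teValue, object@tePercentile))
})

setMethod("show", "ToxModelBundle", function(object) {
  cat(sprintf("ToxModelBundle: %d training compounds, %d descriptors\n",
              nrow(object@trainX), length(object@selectedDescriptors)))
  cat(sprintf("  forest: %d trees; error model: %s\n",
              object@config$n_trees,
              if (is.null(object@errorModel)) "absent" else "fitted"))
  show(object@ad)
})
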