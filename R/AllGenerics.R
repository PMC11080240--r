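#' @rdname Ontology-class
#' @param x an object.
#' @export
setGeneric("ontoTerms", function(x) standardGeneric("ontoTerms"))
#' @rdname Ontology-class
#' @export
setGeneric("ontoEdges", function(x) standardGeneric("ontoEdges"))
#' @rdname Ontology-class
#' @export
setGeneric("ontoAnnotations", function(x) standardGeneric("ontoAnnotations"))
#' @rdname Ontology-class
#' @export
setGeneric("ontoRoot", function(x) standardGeneric("ontoRoot"))

#' @rdname LayeredArchitecture-class
#' @param x an object.
#' @export
setGeneric("termOrder", function(x) standardGeneric("termOrder"))
#' @rdname LayeredArchitecture-class
#' @export
setGeneric("termNeurons", function(x) standardGeneric("termNeurons"))
#' @rdname LayeredArchitecture-class
#' @export
setGeneric("termInputs", function(x) standardGeneric("termInputs"))
#' @rdname LayeredArchitecture-class
#' @export
setGeneric("archDepth", function(x) standardGeneric("archDepth"))

#' Gene index of an object
#' @param x an object carrying an ordered gene list.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))

#' Fingerprint bits accessor
#' @param x a [DrugFingerprint-class].
#' @return integer 0/1 vector.
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

setMethod("ontoTerms", "Ontology", function(x) x@terms)
setMethod("ontoEdges", "Ontology", function(x) x@edges)
setMethod("ontoAnnotations", "Ontology", function(x) x@annotations)
setMethod("ontoRoot", "Ontology", function(x) x@root)
setMethod("geneIndex", "Ontology", function(x) x@genes)

setMethod("termOrder", "LayeredArchitecture", function(x) x@termOrder)
setMethod("termNeurons", "LayeredArchitecture", function(x) x@termNeurons)
setMethod("termInputs", "LayeredArchitecture", function(x) {
  out <- lapply(x@termOrder, function(t) {
    list(children = x@termChildren[[t]], genes = x@termGenes[[t]])
  })
  names(out) <- x@termOrder
  out
})
setMethod("archDepth", "LayeredArchitecture", function(x) x@depth)
setMethod("geneIndex", "LayeredArchitecture", function(x) x@geneIndex)
setMethod("geneIndex", "DrugResponseData", function(x) x@geneIndex)

setMethod("fpBits", "DrugFingerprint", function(x) x@bits)

setMethod("show", "Ontology", function(object) {
  cat(sprintf(
    "Ontology: %d terms, %d edges, %d annotated genes, root '%s'\n",
    length(object@terms), nrow(object@edges), length(object@genes),
    object@root))
})

setMethod("show", "LayeredArchitecture", function(object) {
  k <- object@termNeurons
  cat(sprintf(
    paste0("LayeredArchitecture: %d terms (depth %d), %d genes x width %d,",
           " neurons per term %d..%d\n"),
    length(object@termOrder), object@depth, length(object@geneIndex),
    object@geneChannelWidth, min(k), max(k)))
})

setMethod("show", "DrugResponseData", function(object) {
  cat(sprintf(
    "DrugResponseData: %d cells x %d genes (%s fusion%s), %d drugs, %d pairs\n",
    length(object@cellIds), length(object@geneIndex), object@fusion,
    if (object@gray) ", Gray-coded mutations" else "",
    length(object@drugIds), nrow(object@triples)))
})

setMethod("show", "DrugVNNModel", function(object) {
  cat(sprintf(
    paste0("DrugVNNModel: %d subsystem blocks (depth %d), drug branch ",
           "%s, %d parameters%s\n"),
    length(object@arch@termOrder), object@arch@depth,
    paste(object@annSizes, collapse = "-"),
    parameterCount(object),
    if (nrow(object@history)) sprintf("; trained %d epochs",
                                      max(object@history$epoch)) else ""))
})

setMethod("show", "DrugFingerprint", function(object) {
  cat(sprintf("DrugFingerprint '%s': %d bits, radius %d, popcount %d\n",
              object@drugId, object@nBits, object@radius, sum(object@bits)))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    paste0("SimSpec: %d terms (depth <= %d), %d genes, %d cells, %d drugs, ",
           "%d pairs; planted %s x bit %s; c0=%.2f c1=%.2f sd=%.2f seed=%d\n"),
    object@nTerms, object@maxDepth, object@nGenes, object@nCells,
    object@nDrugs, object@nPairs,
    ifelse(is.na(object@plantedTerm), "<auto>", object@plantedTerm),
    ifelse(is.na(object@plantedBit), "<auto>", object@plantedBit),
    object@c0, object@c1, object@noiseSd, object@seed))
})
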