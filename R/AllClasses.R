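#' @import methods
NULL

#' Biological-process ontology backing a visible neural network
#'
#' A validated rooted DAG of subsystem terms together with direct gene
#' annotations. Edges point child -> parent; the unique parentless term is the
#' root. Every term must carry at least one gene in the annotation union of
#' its descendant closure, otherwise it could contribute no input to the
#' network compiled from it.
#'
#' @slot terms character vector of term ids.
#' @slot edges data.frame with columns \code{child}, \code{parent}.
#' @slot annotations named list mapping gene id -> character vector of terms
#'   the gene is directly annotated to.
#' @slot genes ordered global gene index (all annotated genes).
#' @slot root id of the unique root term.
#'
#' @seealso [loadOntology()], [pruneToGenes()], [layerArchitecture()]
#' @export
setClass("Ontology",
  representation(
    terms = "character",
    edges = "data.frame",
    annotations = "list",
    genes = "character",
    root = "character"
  )
)

#' Compiled layer plan of the visible neural network
#'
#' The ontology compiled into an executable plan: a topological evaluation
#' order (children strictly before parents), a neuron count per term, and for
#' every term the child blocks and directly annotated genes that form its
#' input vector. The input width of a term is the sum of its children's neuron
#' counts plus (number of direct genes) x \code{geneChannelWidth}.
#'
#' @slot termOrder evaluation sequence over terms.
#' @slot termNeurons named integer, neurons k(t) per term.
#' @slot termChildren named list, lexicographically ordered child terms.
#' @slot termGenes named list, direct genes per term in gene-index order.
#' @slot depth longest root-to-leaf path, counted in terms.
#' @slot geneIndex ordered gene list the genotype matrices align to.
#' @slot geneChannelWidth input values contributed per gene (1 for mean
#'   fusion, 3 for stacked channels).
#' @slot root root term id.
#' @slot ontologyHash deterministic hash of the source ontology, used to
#'   verify checkpoints against data.
#' @export
setClass("LayeredArchitecture",
  representation(
    termOrder = "character",
    termNeurons = "integer",
    termChildren = "list",
    termGenes = "list",
    depth = "integer",
    geneIndex = "character",
    geneChannelWidth = "integer",
    root = "character",
    ontologyHash = "character"
  )
)

#' Aligned cell-line x drug response dataset
#'
#' Holds the fused genotype input matrix (cells x gene features), the raw
#' genotype channels, the drug fingerprint matrix and the response triples,
#' all aligned to a common gene index and id vocabularies.
#'
#' @slot cellIds,drugIds,geneIndex id vocabularies.
#' @slot cellX fused genotype inputs, cells x (G x channel width).
#' @slot channels list of the raw mutation/expression/cnv matrices.
#' @slot fpMatrix drugs x nBits binary fingerprint matrix.
#' @slot triples data.frame(cell_id, drug_id, auc).
#' @slot fusion "mean" or "stack"; @slot gray whether mutation bits were
#'   Gray-encoded before fusion.
#' @export
setClass("DrugResponseData",
  representation(
    cellIds = "character",
    drugIds = "character",
    geneIndex = "character",
    cellX = "matrix",
    channels = "list",
    fpMatrix = "matrix",
    triples = "data.frame",
    fusion = "character",
    gray = "logical"
  )
)

#' Two-branch visible-neural-network drug response model
#'
#' Parameters and batch-norm buffers of the full model: one subsystem block
#' per ontology term (weights, bias, post-tanh batch norm, auxiliary linear
#' head), a three-layer feed-forward drug branch over Morgan fingerprints, and
#' the fusion head combining the root genotype embedding with the drug
#' embedding into a scalar AUC prediction.
#'
#' @slot arch the [LayeredArchitecture-class] the VNN is wired from.
#' @slot annSizes the three hidden-layer widths of the drug branch.
#' @slot nBits fingerprint length expected by the drug branch.
#' @slot params named list of weight arrays.
#' @slot buffers named list of batch-norm running statistics.
#' @slot config training configuration used (see [trainConfig()]).
#' @slot history per-epoch loss trace from the last training run.
#' @slot hash ontology hash, verified when predicting on new data.
#' @export
setClass("DrugVNNModel",
  representation(
    arch = "LayeredArchitecture",
    annSizes = "integer",
    nBits = "integer",
    params = "list",
    buffers = "list",
    config = "list",
    history = "data.frame",
    hash = "character"
  )
)

#' Morgan fingerprint of a drug
#'
#' @slot drugId drug identifier. @slot smiles source SMILES (may be "" when
#'   the bits were supplied directly). @slot bits 0/1 integer vector of length
#'   \code{nBits}. @slot radius circular neighborhood radius. @slot nBits
#'   folded length.
#' @export
setClass("DrugFingerprint",
  representation(
    drugId = "character",
    smiles = "character",
    bits = "integer",
    radius = "integer",
    nBits = "integer"
  )
)

#' Specification of a synthetic study cohort
#'
#' Defines the toy ontology size, cohort dimensions and the planted response
#' mechanism AUC = clip(c0 - c1 * mean(fused genotype of the planted term's
#' descendant genes) * drugBit + noise, 0, 1). Both branches of the model are
#' needed to fit this law, which is what makes end-to-end training and RLIPP
#' recovery meaningful tests.
#'
#' @slot nTerms,maxDepth,nGenes,nCells,nDrugs,nPairs,nBits cohort dimensions.
#' @slot plantedTerm term carrying the genotype side of the mechanism
#'   (NA = auto-chosen deterministically).
#' @slot plantedBit fingerprint bit carrying the drug side (NA = auto).
#' @slot c0 baseline AUC; @slot c1 effect size; @slot noiseSd gaussian noise.
#' @slot mutRate per-gene mutation probability.
#' @slot meanBitsOn target mean fingerprint popcount.
#' @slot seed RNG seed driving every draw.
#' @export
setClass("SimSpec",
  representation(
    nTerms = "integer", maxDepth = "integer", nGenes = "integer",
    nCells = "integer", nDrugs = "integer", nPairs = "integer",
    nBits = "integer",
    plantedTerm = "character", plantedBit = "integer",
    c0 = "numeric", c1 = "numeric", noiseSd = "numeric",
    mutRate = "numeric", meanBitsOn = "numeric",
    seed = "integer"
  )
)
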