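## Ontology parsing, validation, pruning and compilation into a layer plan.

## ---- internal graph helpers ------------------------------------------------

## children/parent adjacency as named lists over all terms
.childMap <- function(terms, edges) {
  m <- split(edges$child, factor(edges$parent, levels = terms))
  lapply(m, function(v) sort(unique(v)))
}

.parentMap <- function(terms, edges) {
  m <- split(edges$parent, factor(edges$child, levels = terms))
  lapply(m, function(v) sort(unique(v)))
}

## Topological order, children before parents, lexicographic tie-break.
## Returns NULL if the graph has a cycle.
.topoOrder <- function(terms, edges) {
  childOf <- .childMap(terms, edges)
  nChild <- vapply(childOf, length, 0L)
  parentOf <- .parentMap(terms, edges)
  done <- integer(0)
  ready <- sort(names(nChild)[nChild == 0L])
  remaining <- nChild
  order <- character(0)
  while (length(ready)) {
    t <- ready[1]
    ready <- ready[-1]
    order <- c(order, t)
    for (p in parentOf[[t]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) {
        ready <- sort(c(ready, p))
      }
    }
  }
  if (length(order) != length(terms)) return(NULL)
  order
}

## An edge participating in a cycle, for error messages.
.findCycleEdge <- function(terms, edges) {
  ord <- .topoOrder(terms, edges)
  if (!is.null(ord)) return(NULL)
  ## any edge among the terms not placeable in topological order
  childOf <- .childMap(terms, edges)
  nChild <- vapply(childOf, length, 0L)
  parentOf <- .parentMap(terms, edges)
  remaining <- nChild
  ready <- sort(names(nChild)[nChild == 0L])
  while (length(ready)) {
    t <- ready[1]; ready <- ready[-1]
    remaining[t] <- -1L
    for (p in parentOf[[t]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) ready <- sort(c(ready, p))
    }
  }
  stuck <- names(remaining)[remaining > 0L]
  i <- which(edges$child %in% stuck & edges$parent %in% stuck)[1]
  c(edges$child[i], edges$parent[i])
}

## Per-term union of annotations over the descendant closure (term included).
.descendantGenes <- function(terms, edges, annotations, order = NULL) {
  if (is.null(order)) order <- .topoOrder(terms, edges)
  direct <- vector("list", length(terms))
  names(direct) <- terms
  for (t in terms) direct[[t]] <- character(0)
  for (g in names(annotations)) {
    for (t in annotations[[g]]) direct[[t]] <- c(direct[[t]], g)
  }
  childOf <- .childMap(terms, edges)
  desc <- vector("list", length(terms))
  names(desc) <- terms
  for (t in order) {
    acc <- direct[[t]]
    for (c in childOf[[t]]) acc <- c(acc, desc[[c]])
    desc[[t]] <- sort(unique(acc))
  }
  desc
}

## Longest root-to-term path length in terms, per term; depth = max of these.
.termDepths <- function(terms, edges, order = NULL) {
  if (is.null(order)) order <- .topoOrder(terms, edges)
  parentOf <- .parentMap(terms, edges)
  d <- stats::setNames(rep(1L, length(terms)), terms)
  for (t in rev(order)) {       # parents before children
    ps <- parentOf[[t]]
    if (length(ps)) d[t] <- 1L + max(d[ps])
  }
  d
}

## ---- validity --------------------------------------------------------------

setValidity("Ontology", function(object) {
  msgs <- character(0)
  terms <- object@terms
  edges <- object@edges
  if (!all(c("child", "parent") %in% names(edges))) {
    return("edges must have columns 'child' and 'parent'")
  }
  bad <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(bad)) {
    msgs <- c(msgs, paste0("edge endpoints not in terms: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  ord <- .topoOrder(terms, edges)
  if (is.null(ord)) {
    e <- .findCycleEdge(terms, edges)
    return(sprintf("not a DAG: cycle through edge %s -> %s", e[1], e[2]))
  }
  roots <- setdiff(terms, unique(edges$child))
  if (length(roots) != 1L) {
    msgs <- c(msgs, paste0("ontology must have exactly one root, found ",
                           length(roots), ": ",
                           paste(sort(roots), collapse = ", ")))
  } else if (roots != object@root) {
    msgs <- c(msgs, sprintf("root slot '%s' disagrees with parentless term '%s'",
                            object@root, roots))
  }
  annGenes <- names(object@annotations)
  if (length(annGenes)) {
    badT <- setdiff(unique(unlist(object@annotations)), terms)
    if (length(badT)) {
      msgs <- c(msgs, paste0("annotations reference unknown terms: ",
                             paste(badT, collapse = ", ")))
    }
    badG <- setdiff(annGenes, object@genes)
    if (length(badG)) {
      msgs <- c(msgs, paste0("annotated genes missing from gene index: ",
                             paste(badG, collapse = ", ")))
    }
  }
  ## gene coverage of every term's descendant closure is an invariant of
  ## PRUNED (model-ready) ontologies, enforced by pruneToGenes() and
  ## layerArchitecture(); raw loaded ontologies may carry uncovered terms
  if (length(msgs)) msgs else TRUE
})

## internal constructor used by parsers and prune
.newOntology <- function(terms, edges, annotations, genes = NULL) {
  terms <- sort(unique(terms))
  edges <- unique(edges[, c("child", "parent")])
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  annotations <- annotations[order(names(annotations))]
  annotations <- lapply(annotations, function(v) sort(unique(v)))
  if (is.null(genes)) genes <- sort(names(annotations))
  roots <- setdiff(terms, unique(edges$child))
  root <- if (length(roots) == 1L) roots else NA_character_
  new("Ontology", terms = terms, edges = edges, annotations = annotations,
      genes = genes, root = if (is.na(root)) "" else root)
}

## ---- parsing / writing -----------------------------------------------------

#' Load a subsystem ontology from disk
#'
#' Reads the hierarchy that will become the VNN skeleton. The canonical
#' on-disk dialect is a 3-column tab file, one row per edge:
#' \code{parent<TAB>child<TAB>relation} with relation \code{default} (term ->
#' term edge) or \code{gene} (direct annotation of \code{child}, a gene id, to
#' term \code{parent}). Lines starting with \code{#} are comments. A minimal
#' OBO reader (\code{is_a} relationships only) is provided for convenience;
#' OBO files carry no gene annotations, so these must be supplied as a
#' 2-column \code{term<TAB>gene} file via \code{annotationPath}.
#'
#' @param edgePath path to the ontology file.
#' @param dialect \code{"drugcell_tab"} (default) or \code{"obo"}.
#' @param annotationPath optional \code{term<TAB>gene} annotation file
#'   (required for OBO input).
#' @return a validated [Ontology-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("root\tA\tdefault", "root\tB\tdefault",
#'              "A\tg1\tgene", "B\tg2\tgene"), f)
#' loadOntology(f)
#' @export
loadOntology <- function(edgePath, dialect = c("drugcell_tab", "obo"),
                         annotationPath = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(edgePath)) {
    stop("ontology file does not exist: ", edgePath, call. = FALSE)
  }
  if (dialect == "drugcell_tab") {
    lines <- readLines(edgePath, encoding = "UTF-8")
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    badLen <- vapply(parts, length, 0L) != 3L
    if (any(badLen)) {
      stop(sprintf("unreadable row at line %d: expected 3 tab-separated %s",
                   idx[which(badLen)[1]], "fields (parent, child, relation)"),
           call. = FALSE)
    }
    parent <- vapply(parts, `[[`, "", 1L)
    child <- vapply(parts, `[[`, "", 2L)
    rel <- vapply(parts, `[[`, "", 3L)
    badRel <- !(rel %in% c("default", "gene"))
    if (any(badRel)) {
      stop(sprintf("unreadable row at line %d: relation '%s' (want %s)",
                   idx[which(badRel)[1]], rel[which(badRel)[1]],
                   "'default' or 'gene')"), call. = FALSE)
    }
    isEdge <- rel == "default"
    edges <- data.frame(child = child[isEdge], parent = parent[isEdge],
                        stringsAsFactors = FALSE)
    terms <- unique(c(edges$child, edges$parent, parent[!isEdge]))
    ann <- split(parent[!isEdge], child[!isEdge])   # gene -> terms
  } else {
    ob <- .parseOboTerms(edgePath)
    edges <- ob$edges
    terms <- ob$terms
    if (is.null(annotationPath)) {
      stop("OBO input carries no gene annotations; supply 'annotationPath' ",
           "(term<TAB>gene)", call. = FALSE)
    }
    at <- utils::read.table(annotationPath, sep = "\t", header = FALSE,
                            col.names = c("term", "gene"),
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    ann <- split(at$term, at$gene)
  }
  o <- .newOntology(terms, edges, ann)
  validObject(o)
  o
}

.parseOboTerms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  terms <- character(0)
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  cur <- NULL
  inTerm <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") { inTerm <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { inTerm <- FALSE; next }
    if (!inTerm) next
    if (grepl("^id:", ln)) {
      cur <- sub("^id:\\s*", "", ln)
      terms <- c(terms, cur)
    } else if (grepl("^is_a:", ln) && !is.null(cur)) {
      p <- sub("^is_a:\\s*", "", ln)
      p <- sub("\\s*!.*$", "", p)
      edges <- rbind(edges, data.frame(child = cur, parent = p,
                                       stringsAsFactors = FALSE))
    }
  }
  list(terms = unique(terms), edges = edges)
}

#' Write an ontology in the canonical tab dialect
#'
#' Term edges are written as \code{parent<TAB>child<TAB>default} rows and
#' annotations as \code{term<TAB>gene<TAB>gene} rows, both in sorted order so
#' identical ontologies serialize byte-identically.
#'
#' @param o an [Ontology-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOntology <- function(o, path) {
  stopifnot(is(o, "Ontology"))
  e <- o@edges[order(o@edges$parent, o@edges$child), , drop = FALSE]
  rows <- sprintf("%s\t%s\tdefault", e$parent, e$child)
  ann <- o@annotations
  if (length(ann)) {
    df <- data.frame(
      gene = rep(names(ann), lengths(ann)),
      term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
    df <- df[order(df$term, df$gene), ]
    rows <- c(rows, sprintf("%s\t%s\tgene", df$term, df$gene))
  }
  writeLines(rows, path)
  invisible(path)
}

## ---- pruning ---------------------------------------------------------------

#' Restrict an ontology to a gene screen
#'
#' Drops annotations outside \code{keep}, removes terms whose descendant
#' annotation union becomes empty, and re-splices the orphaned children of
#' removed terms to their nearest surviving ancestors (deduplicated). This is
#' the restriction step applied after an external gene screen has produced the
#' list of genes to model.
#'
#' @param o an [Ontology-class].
#' @param keep character vector of gene ids to retain (nonempty).
#' @return a validated, pruned [Ontology-class].
#' @export
pruneToGenes <- function(o, keep) {
  stopifnot(is(o, "Ontology"))
  if (!length(keep)) stop("'keep' must be a nonempty gene set", call. = FALSE)
  ann <- o@annotations[names(o@annotations) %in% keep]
  desc <- .descendantGenes(o@terms, o@edges, ann)
  surviving <- o@terms[vapply(desc, function(d) length(d) > 0L, TRUE)[o@terms]]
  if (!(o@root %in% surviving)) {
    stop("no annotated genes reachable from the root after pruning",
         call. = FALSE)
  }
  parentOf <- .parentMap(o@terms, o@edges)
  memo <- new.env(parent = emptyenv())
  survAnc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    res <- if (t %in% surviving) t else {
      unique(unlist(lapply(parentOf[[t]], survAnc)))
    }
    memo[[t]] <- res
    res
  }
  newEdges <- list()
  for (t in setdiff(surviving, o@root)) {
    ps <- unique(unlist(lapply(parentOf[[t]], survAnc)))
    ps <- setdiff(ps, t)
    newEdges[[t]] <- data.frame(child = t, parent = ps,
                                stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, unname(newEdges))
  out <- .newOntology(surviving, edges, ann)
  validObject(out)
  out
}

## ---- compilation -----------------------------------------------------------

#' Compile an ontology into a network layer plan
#'
#' Produces the topological evaluation order (children strictly before
#' parents, lexicographic tie-break for reproducibility), assigns a neuron
#' count to every term and records each term's input wiring: its child blocks
#' plus its directly annotated genes. Under the \code{fixed} rule every term
#' gets \code{k} neurons; under \code{proportional} a term with d descendant
#' genes gets \code{max(minK, ceiling(frac * d))}.
#'
#' @param o an [Ontology-class].
#' @param neuronRule either \code{list(fixed = k)} or
#'   \code{list(proportional = c(minK, frac))}.
#' @param geneChannelWidth input values per gene (1 for mean fusion, 3 for
#'   stacked channels).
#' @param geneIndex optional explicit gene ordering; defaults to the
#'   ontology's sorted annotated genes.
#' @return a [LayeredArchitecture-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("root\tA\tdefault", "A\tg1\tgene", "root\tg2\tgene"), f)
#' arch <- layerArchitecture(loadOntology(f), neuronRule = list(fixed = 2))
#' termOrder(arch)
#' @export
layerArchitecture <- function(o, neuronRule = list(fixed = 6L),
                              geneChannelWidth = 1L, geneIndex = NULL) {
  stopifnot(is(o, "Ontology"))
  validObject(o)
  if (is.null(geneIndex)) geneIndex <- o@genes
  if (!all(names(o@annotations) %in% geneIndex)) {
    stop("gene index is missing annotated genes", call. = FALSE)
  }
  ord <- .topoOrder(o@terms, o@edges)
  desc <- .descendantGenes(o@terms, o@edges, o@annotations, ord)
  uncovered <- o@terms[vapply(desc, length, 0L) == 0L]
  if (length(uncovered)) {
    stop("cannot compile: terms with no annotated gene in their descendant ",
         "closure (prune first): ", paste(sort(uncovered), collapse = ", "),
         call. = FALSE)
  }
  childOf <- .childMap(o@terms, o@edges)
  direct <- vector("list", length(o@terms))
  names(direct) <- o@terms
  for (t in o@terms) direct[[t]] <- character(0)
  for (g in names(o@annotations)) {
    for (t in o@annotations[[g]]) direct[[t]] <- c(direct[[t]], g)
  }
  ## genes per term in gene-index order
  direct <- lapply(direct, function(g) geneIndex[geneIndex %in% g])
  rule <- names(neuronRule)[1]
  if (rule == "fixed") {
    k <- stats::setNames(rep(as.integer(neuronRule$fixed), length(ord)), ord)
  } else if (rule == "proportional") {
    pr <- neuronRule$proportional
    minK <- as.integer(pr[1]); frac <- as.numeric(pr[2])
    k <- vapply(ord, function(t) {
      max(minK, as.integer(ceiling(frac * length(desc[[t]]))))
    }, 0L)
    names(k) <- ord
  } else {
    stop("neuronRule must be list(fixed=) or list(proportional=)",
         call. = FALSE)
  }
  if (any(k < 1L)) stop("every term needs at least one neuron", call. = FALSE)
  depth <- max(.termDepths(o@terms, o@edges, ord))
  new("LayeredArchitecture",
      termOrder = ord, termNeurons = k,
      termChildren = childOf[ord], termGenes = direct[ord],
      depth = as.integer(depth), geneIndex = geneIndex,
      geneChannelWidth = as.integer(geneChannelWidth),
      root = o@root, ontologyHash = ontologyHash(o))
}

setValidity("LayeredArchitecture", function(object) {
  ord <- object@termOrder
  pos <- stats::setNames(seq_along(ord), ord)
  for (t in ord) {
    for (c in object@termChildren[[t]]) {
      if (pos[[c]] >= pos[[t]]) {
        return(sprintf("child '%s' not ordered before parent '%s'", c, t))
      }
    }
  }
  if (any(object@termNeurons < 1L)) return("neuron counts must be >= 1")
  if (!all(unlist(object@termGenes) %in% object@geneIndex)) {
    return("termGenes outside geneIndex")
  }
  TRUE
})

#' Input width of each term's subsystem block
#'
#' Sum of the children's neuron counts plus direct genes times the gene
#' channel width.
#'
#' @param arch a [LayeredArchitecture-class].
#' @return named integer vector over terms.
#' @export
termInputWidth <- function(arch) {
  stopifnot(is(arch, "LayeredArchitecture"))
  vapply(arch@termOrder, function(t) {
    sum(arch@termNeurons[arch@termChildren[[t]]]) +
      length(arch@termGenes[[t]]) * arch@geneChannelWidth
  }, 0L)
}

#' Deterministic hash of ontology content
#'
#' Hashes the term, edge and annotation sets (order-canonicalized); stored in
#' compiled architectures and checkpoints so that a model is never applied to
#' data prepared against a different hierarchy.
#'
#' @param o an [Ontology-class].
#' @return character scalar.
#' @export
ontologyHash <- function(o) {
  stopifnot(is(o, "Ontology"))
  e <- o@edges[order(o@edges$parent, o@edges$child), , drop = FALSE]
  ann <- o@annotations
  annStr <- if (length(ann)) {
    paste(names(ann), vapply(ann, paste, "", collapse = ","), sep = ":")
  } else character(0)
  sprintf("%.0f", .hashStrings(c(sort(o@terms),
                                 paste(e$parent, e$child, sep = ">"),
                                 annStr)))
}
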