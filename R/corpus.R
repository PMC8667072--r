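#' Construct an AnnotationCorpus
#'
#' @param sets named list of character vectors: term ID -> annotated genes.
#' @param namespace character vector of namespace tags (\code{BP}, \code{CC},
#'   \code{MF}, \code{KEGG}), one per term; recycled if length 1.
#' @return an [AnnotationCorpus-class].
#' @examples
#' AnnotationCorpus(list(T1 = c("a", "b"), T2 = "c"), c("BP", "MF"))
#' @export
AnnotationCorpus <- function(sets, namespace = "BP") {
    if (length(namespace) == 1L)
        namespace <- rep(namespace, length(sets))
    sets <- lapply(sets, function(g) .lexSort(unique(as.character(g))))
    new("AnnotationCorpus", sets = sets,
        namespace = unname(as.character(namespace)))
}

#' @describeIn AnnotationCorpus term identifiers
#' @param x an \code{AnnotationCorpus}
#' @export
setMethod("termIds", "AnnotationCorpus", function(x) names(x@sets))

#' @describeIn AnnotationCorpus number of genes annotated by each term
#' @export
setMethod("termSize", "AnnotationCorpus",
    function(x) stats::setNames(lengths(x@sets), names(x@sets)))

#' @describeIn AnnotationCorpus the term -> gene-set map as a named list
#' @export
setMethod("geneSets", "AnnotationCorpus", function(x) x@sets)

#' @describeIn AnnotationCorpus namespace tag of each term
#' @export
setMethod("termNamespace", "AnnotationCorpus",
    function(x) stats::setNames(x@namespace, names(x@sets)))

setMethod("show", "AnnotationCorpus", function(object) {
    cat("AnnotationCorpus with", length(object@sets), "terms\n")
    print(table(object@namespace))
})

# sparse term x gene indicator matrix over a fixed universe
.termIndicator <- function(corpus, universe) {
    sets <- lapply(corpus@sets, intersect, universe)
    i <- rep(seq_along(sets), lengths(sets))
    j <- match(unlist(sets, use.names = FALSE), universe)
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(sets), length(universe)),
                         dimnames = list(names(sets), universe))
}
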