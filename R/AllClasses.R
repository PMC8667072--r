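#' PPINetwork: a weighted, undirected protein-protein interaction network
#'
#' Nodes are gene identifiers (opaque non-empty strings, e.g. Ensembl peptide
#' IDs) kept in a fixed lexicographic (C-locale byte) order so that every
#' vector and matrix derived from the network is reproducible across runs.
#' Edges are undirected and carry an integer confidence score in [1, 999],
#' the STRING convention where >= 900 is the "highest confidence" tier.
#'
#' @slot nodes character vector of gene identifiers, sorted, unique.
#' @slot adjacency symmetric sparse numeric matrix of confidence scores,
#'   zero diagonal, dimnames equal to \code{nodes}.
#'
#' @seealso [PPINetwork()] for construction from an edge table,
#'   [readStringLinks()] to load a STRING-links file.
#' @exportClass PPINetwork
setClass("PPINetwork",
    representation(nodes = "character", adjacency = "Matrix"))

setValidity("PPINetwork", function(object) {
    n <- object@nodes
    A <- object@adjacency
    msg <- character()
    if (length(n) == 0L)
        msg <- c(msg, "network has no nodes")
    if (any(n == "") || anyNA(n))
        msg <- c(msg, "gene identifiers must be non-empty strings")
    if (any(grepl("[[:space:]]", n)))
        msg <- c(msg, "gene identifiers must not contain whitespace")
    if (anyDuplicated(n))
        msg <- c(msg, "duplicated gene identifiers")
    if (is.unsorted(n))
        msg <- c(msg, "nodes must be stored in sorted order")
    if (!identical(dim(A), c(length(n), length(n))))
        msg <- c(msg, "adjacency dimensions do not match node count")
    if (!identical(rownames(A), n) || !identical(colnames(A), n))
        msg <- c(msg, "adjacency dimnames must equal nodes")
    x <- A@x
    if (length(x) && (any(x < 1) || any(x > 999) || any(x != round(x))))
        msg <- c(msg, "edge confidences must be integers in [1, 999]")
    if (any(Matrix::diag(A) != 0))
        msg <- c(msg, "self-loops are not allowed")
    if (!Matrix::isSymmetric(A))
        msg <- c(msg, "adjacency must be symmetric")
    if (length(msg)) msg else TRUE
})

#' AnnotationCorpus: functional terms mapped to gene sets
#'
#' A corpus of functional terms (GO biological process / cellular component /
#' molecular function, or KEGG pathways), each annotating a non-empty set of
#' genes in the same identifier namespace as the network. Used to build
#' per-gene enrichment vectors and for the final over-representation test.
#'
#' @slot sets named list; each element a character vector of gene IDs.
#' @slot namespace character vector parallel to \code{sets}, one of
#'   \code{"BP"}, \code{"CC"}, \code{"MF"}, \code{"KEGG"}.
#'
#' @seealso [AnnotationCorpus()], [readGMT()], [writeGMT()]
#' @exportClass AnnotationCorpus
setClass("AnnotationCorpus",
    representation(sets = "list", namespace = "character"))

setValidity("AnnotationCorpus", function(object) {
    msg <- character()
    if (length(object@sets) == 0L)
        msg <- c(msg, "corpus has no terms")
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "terms must have unique identifiers")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "every term's gene set must be non-empty")
    if (length(object@namespace) != length(object@sets))
        msg <- c(msg, "one namespace tag per term is required")
    ok <- object@namespace %in% c("BP", "CC", "MF", "KEGG")
    if (!all(ok))
        msg <- c(msg, "namespace tags must be BP, CC, MF or KEGG")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth of a simulated planted-module network
#'
#' Records which genes make up the planted disease module, which of them were
#' designated seeds (the "known" disease genes handed to the pipeline), and
#' which are the latent targets the screen is supposed to recover
#' (module members that are not seeds).
#'
#' @slot moduleMembers character, all planted-module gene IDs.
#' @slot seeds character, the seeded subset of the module.
#' @slot latentTargets character, \code{moduleMembers} minus \code{seeds}.
#'
#' @seealso [simulateNetwork()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(moduleMembers = "character", seeds = "character",
                   latentTargets = "character"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (!all(object@seeds %in% object@moduleMembers))
        msg <- c(msg, "seeds must be module members")
    if (length(object@latentTargets) == 0L)
        msg <- c(msg, "latent target set must be non-empty")
    if (!setequal(object@latentTargets,
                  setdiff(object@moduleMembers, object@seeds)))
        msg <- c(msg, "latentTargets must equal moduleMembers minus seeds")
    if (length(msg)) msg else TRUE
})

#' ScreenResult: output of the full screening cascade
#'
#' Holds the per-candidate record table (probability, Z-score, MAS, MFS and
#' the furthest stage passed), the stage survival counts, the putative genes,
#' the over-represented functional terms among them, and the confidence
#' matrix between putative and validated genes.
#'
#' @slot records a [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{probability}, \code{zScore}, \code{mas}, \code{mfs},
#'   \code{stagePassed}.
#' @slot stageCounts named integer vector, genes surviving each stage
#'   (\code{rwr}, \code{permutation}, \code{association}, \code{function}).
#' @slot putative character, final putative genes sorted by MFS descending.
#' @slot enriched a [S4Vectors::DataFrame] of over-represented terms
#'   (\code{term}, \code{namespace}, \code{pValue}, \code{overlap},
#'   \code{size}).
#' @slot confidenceMatrix numeric matrix, putative x validated confidences.
#' @slot seeds character, the validated seed genes used.
#' @slot params list of the pipeline parameters used.
#'
#' @seealso [screenGenes()]
#' @exportClass ScreenResult
setClass("ScreenResult",
    representation(records = "DataFrame", stageCounts = "integer",
                   putative = "character", enriched = "DataFrame",
                   confidenceMatrix = "matrix", seeds = "character",
                   params = "list"))

setValidity("ScreenResult", function(object) {
    msg <- character()
    sc <- object@stageCounts
    want <- c("rwr", "permutation", "association", "function")
    if (!identical(names(sc), want))
        msg <- c(msg, "stageCounts must be named rwr/permutation/association/function")
    if (length(sc) == 4L && any(diff(sc) > 0L))
        msg <- c(msg, "stage counts must be monotone non-increasing")
    if (length(object@putative) != unname(sc["function"]))
        msg <- c(msg, "putative gene count must match the function-stage count")
    if (length(msg)) msg else TRUE
})
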