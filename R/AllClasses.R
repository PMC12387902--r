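#' @import methods
#' @importFrom stats cmdscale dist median prcomp rbinom rnbinom rpois runif sd
#' @importFrom utils head read.csv write.csv packageVersion
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib RorschachMap, .registration = TRUE
NULL

#' Cohort of coded Rorschach protocols
#'
#' `RorschachCohort` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold a cohort of
#' coded protocols: one column per subject, one row per coding variable, and a
#' `"counts"` assay of non-negative integer response counts (binary particular
#' phenomena are 0/1 counts). The diagnostic group of each subject
#' (`"AD"` or `"INPH"`) is kept in `colData(x)$group`. After
#' [scaleCohort()] a second assay `"scaled"` holds the per-variable min-max
#' scaled values, with the scaling range in `rowData(x)$scaleMin` /
#' `rowData(x)$scaleMax`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [readCohort()], [rorschachFixture()], [describeCohort()],
#'   [scaleCohort()], [appendGroupIndicators()]
#' @export
setClass("RorschachCohort", contains = "SummarizedExperiment")

.validRorschachCohort <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)))
      msg <- c(msg, "counts must be finite")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(abs(cts - round(cts)) > 1e-8))
        msg <- c(msg, "counts must be integral")
    }
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids (colnames) must be present and unique")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- SummarizedExperiment::colData(object)$group
    if (!all(as.character(g) %in% c("AD", "INPH")))
      msg <- c(msg, "group labels must be 'AD' or 'INPH'")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "variable names (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("RorschachCohort", .validRorschachCohort)

#' Construct a RorschachCohort
#'
#' @param counts subjects x variables matrix of non-negative integers, with
#'   subject ids as rownames and variable names as colnames (the orientation
#'   used in the printed protocol tables; it is transposed into the
#'   variables x subjects assay internally).
#' @param group character or factor of length `nrow(counts)` with values
#'   `"AD"` or `"INPH"`.
#' @return a [RorschachCohort-class] object.
#' @examples
#' m <- matrix(c(2L, 1L, 1L, 3L, 2L, 1L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("NR", "G", "D")))
#' RorschachCohort(m, group = c("AD", "INPH"))
#' @export
RorschachCohort <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("subject", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("'counts' must have variable names as colnames")
  group <- factor(as.character(group), levels = c("AD", "INPH"))
  if (anyNA(group))
    stop("unknown group label; expected 'AD' or 'INPH'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(group = group, row.names = rownames(counts))
  )
  methods::new("RorschachCohort", se)
}

#' Result of protocol coding-consistency checks
#'
#' Holds the violations found by [validateProtocol()]: one row per
#' (subject, rule) pair where a structural sum rule of the coding scheme does
#' not hold, and a per-rule summary count. An empty violation table means all
#' rules hold.
#'
#' @slot violations data.frame with columns `subject_id`, `rule`, `expected`,
#'   `observed`.
#' @slot ruleCounts named integer vector, violations per rule.
#' @export
setClass("ProtocolValidation",
  representation(violations = "data.frame", ruleCounts = "integer"))

#' Two-dimensional embedding of the subjects
#'
#' Per-subject planar coordinates produced by [projectCohort()], together
#' with the residual stress of the configuration and the method/metric used.
#'
#' @slot coords subjects x 2 coordinate matrix (rownames = subject ids).
#' @slot stress Kruskal stress-1 of the 2-D configuration, >= 0.
#' @slot method character, `"classical"` or `"smacof"`.
#' @slot metric character, distance metric used on the scaled rows.
#' @export
setClass("CohortEmbedding",
  representation(coords = "matrix", stress = "numeric",
                 method = "character", metric = "character"),
  validity = function(object) {
    if (ncol(object@coords) != 2L) return("coords must have 2 columns")
    if (length(object@stress) != 1L || object@stress < 0)
      return("stress must be a single non-negative number")
    TRUE
  })

#' Best linear split of the embedded groups
#'
#' The outcome of the exhaustive linear-separator search of
#' [linearSeparation()]: the minimum achievable number of subjects on the
#' wrong side of any straight line in the embedding plane, the identity of
#' those subjects, and the separator that attains it.
#'
#' @slot misplacedCount integer >= 0.
#' @slot misplacedIds character vector of subject ids.
#' @slot direction numeric length 2, normal direction of the separator.
#' @slot offset numeric, threshold along `direction`.
#' @export
setClass("SeparationResult",
  representation(misplacedCount = "integer", misplacedIds = "character",
                 direction = "numeric", offset = "numeric"))

#' Trained self-organizing map
#'
#' A rectangular Kohonen map trained by [trainSOM()]. Units are indexed
#' row-major and named `"r.c"` (1-based row.column), the naming used when a
#' subject's class is reported.
#'
#' @slot codebook units x variables weight matrix, unit names as rownames.
#' @slot grid units x 2 integer matrix of (row, col) positions.
#' @slot qe numeric, mean quantization error after each epoch.
#' @slot config the [somConfig()] list used for training.
#' @export
setClass("SOMFit",
  representation(codebook = "matrix", grid = "matrix", qe = "numeric",
                 config = "list"))

#' Subject-to-class assignment of a SOM
#'
#' @slot classes named character vector, subject id -> class label `"r.c"`.
#' @slot occupancy data.frame with columns `class` and `n`, one row per
#'   occupied unit.
#' @export
setClass("SOMAssignment",
  representation(classes = "character", occupancy = "data.frame"))

#' Trained Auto Contractive Map
#'
#' State of the three-layer contractive network after [trainAutoCM()]: the
#' mono-connection weights `v` (input -> hidden, one per variable), the full
#' hidden -> output weight matrix `w`, and convergence diagnostics. The
#' normalized association matrix is derived with [associationMatrix()].
#'
#' @slot v numeric vector of mono-connection weights in \[0, C\].
#' @slot w N x N matrix of inter-unit weights in \[0, C\].
#' @slot active logical; which variables carried any non-zero scaled signal
#'   (only these are subject to the saturation convergence criterion).
#' @slot epochs integer, training epochs run.
#' @slot converged logical.
#' @slot config the [autoCMConfig()] list used.
#' @export
setClass("AutoCMFit",
  representation(v = "numeric", w = "matrix", active = "logical",
                 epochs = "integer", converged = "logical", config = "list"))

#' Normalized variable-variable association matrix
#'
#' A symmetric matrix of association strengths in \[0, 1\] (diagonal 1),
#' obtained from a trained [AutoCMFit-class] by symmetrizing the inter-unit
#' weights and normalizing by the contraction constant C.
#'
#' @export
setClass("AssociationMatrix", contains = "matrix",
  validity = function(object) {
    m <- object@.Data
    if (nrow(m) != ncol(m)) return("must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      return("row and column names must be present and identical")
    if (max(abs(m - t(m))) > 1e-8) return("must be symmetric")
    if (any(m < -1e-12) || any(m > 1 + 1e-12)) return("entries must lie in [0, 1]")
    if (any(abs(diag(m) - 1) > 1e-12)) return("diagonal must be 1")
    TRUE
  })

#' Weighted graph over the coding variables
#'
#' Edge-list representation of the association structure extracted from an
#' [AssociationMatrix-class]: a minimum spanning tree ([minimumSpanningTree()])
#' or its maximally-regular augmentation ([mrgAugment()]). Edge strengths are
#' the association-matrix entries.
#'
#' @slot nodes character vector of variable names.
#' @slot edges data.frame with columns `u`, `v`, `strength`.
#' @slot kind `"MST"` or `"MRG"`.
#' @export
setClass("VariableGraph",
  representation(nodes = "character", edges = "data.frame", kind = "character"),
  validity = function(object) {
    if (!object@kind %in% c("MST", "MRG")) return("kind must be 'MST' or 'MRG'")
    e <- object@edges
    if (!all(c("u", "v", "strength") %in% names(e)))
      return("edges must have columns u, v, strength")
    if (nrow(e) && !all(c(e$u, e$v) %in% object@nodes))
      return("edge endpoints must be declared nodes")
    TRUE
  })
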