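#' Project subjects onto a plane preserving inter-record distances
#'
#' Embeds the scaled records in 2-D by classical (Torgerson) metric scaling:
#' double-centre the squared distance matrix and keep the top two
#' eigenvectors. The embedding is deterministic; axis signs are fixed by the
#' convention that the first subject's coordinate is non-negative on each
#' axis (the first subject with a non-zero coordinate decides if it is zero).
#' An iterative stress-majorization refinement of the classical solution is
#' available via `method = "smacof"`.
#'
#' Manhattan distance on the min-max scaled rows is the default metric: on
#' the reference cohort it is the setting whose best linear split leaves a
#' single subject on the wrong side, matching the reported projection.
#'
#' @param x a [RorschachCohort-class] carrying a `"scaled"` assay, or a
#'   subjects x variables numeric matrix.
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @param method `"classical"` (default) or `"smacof"`.
#' @param iterations majorization iterations when `method = "smacof"`.
#' @return a [CohortEmbedding-class].
#' @examples
#' emb <- projectCohort(scaleCohort(rorschachFixture()))
#' head(embeddingCoords(emb))
#' @export
projectCohort <- function(x, metric = c("manhattan", "euclidean"),
                          method = c("classical", "smacof"),
                          iterations = 100L) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  m <- if (methods::is(x, "RorschachCohort")) scaledMatrix(x) else as.matrix(x)
  if (nrow(m) < 3L) stop("projection needs at least 3 subjects")
  d <- as.matrix(dist(m, method = metric))
  coords <- .classicalMDS(d)
  if (method == "smacof") coords <- .smacof(d, coords, iterations)
  coords <- .fixSigns(coords)
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("x", "y")
  methods::new("CohortEmbedding", coords = coords,
               stress = .stress1(d, coords), method = method, metric = metric)
}

# Torgerson double-centering; zero-pads axes when fewer than 2 positive
# eigenvalues survive (e.g. all records identical)
.classicalMDS <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  coords <- matrix(0, n, 2)
  for (k in 1:2) {
    if (e$values[k] > max(1e-12, 1e-9 * abs(e$values[1])))
      coords[, k] <- e$vectors[, k] * sqrt(e$values[k])
  }
  coords
}

# Guttman transform iterations of raw stress, from a given start
.smacof <- function(d, coords, iterations) {
  n <- nrow(d)
  for (it in seq_len(iterations)) {
    dh <- as.matrix(dist(coords))
    ratio <- ifelse(dh > 0, d / dh, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    coords <- B %*% coords / n
  }
  coords
}

.stress1 <- function(d, coords) {
  dh <- as.matrix(dist(coords))
  lo <- lower.tri(d)
  denom <- sum(d[lo]^2)
  if (denom == 0) return(0)
  sqrt(sum((d[lo] - dh[lo])^2) / denom)
}

.fixSigns <- function(coords) {
  for (k in 1:2) {
    pivot <- which(abs(coords[, k]) > 1e-12)[1]
    if (!is.na(pivot) && coords[pivot, k] < 0) coords[, k] <- -coords[, k]
  }
  coords
}

#' @rdname accessors
#' @export
setMethod("embeddingCoords", "CohortEmbedding", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("embeddingStress", "CohortEmbedding", function(x) x@stress)

setMethod("show", "CohortEmbedding", function(object) {
  cat(sprintf("CohortEmbedding: %d subjects, %s MDS (%s), stress %.4f\n",
              nrow(object@coords), object@method, object@metric,
              object@stress))
})

#' Minimum misclassification over all straight-line separators
#'
#' Exhaustively searches the separators of the embedding plane -- for every
#' pair of embedded points, the direction joining them and its perpendicular,
#' plus the two axis directions, each combined with every threshold between
#' consecutive projected values -- and returns the smallest number of
#' subjects that end up on the wrong side of the line. Ties between equally
#' good separators are broken toward the one misplacing fewer INPH subjects
#' (clinically, a hydrocephalus patient drifting into the dementia cluster is
#' the costlier confusion, so when two splits misclassify equally many
#' subjects the split whose errors are AD subjects is preferred), then toward
#' the lexicographically smallest set of misplaced ids. The
#' count is invariant under rotation, reflection and uniform scaling of the
#' embedding.
#'
#' @param emb a [CohortEmbedding-class].
#' @param groups factor/character of group labels (`"AD"`/`"INPH"`), one per
#'   embedded subject, in the order of `embeddingCoords(emb)`.
#' @return a [SeparationResult-class].
#' @examples
#' co <- scaleCohort(rorschachFixture())
#' linearSeparation(projectCohort(co), cohortGroups(co))
#' @export
linearSeparation <- function(emb, groups) {
  P <- embeddingCoords(emb)
  groups <- as.character(groups)
  if (length(groups) != nrow(P))
    stop("one group label per embedded subject is required")
  if (length(unique(groups)) < 2L) stop("both groups must be present")
  n <- nrow(P)
  isI <- groups == "INPH"
  dirs <- rbind(c(1, 0), c(0, 1))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      dv <- P[j, ] - P[i, ]
      if (sum(dv^2) > 0) dirs <- rbind(dirs, dv, c(-dv[2], dv[1]))
    }
  }
  best <- NULL
  for (k in seq_len(nrow(dirs))) {
    proj <- as.vector(P %*% dirs[k, ])
    cuts <- sort(unique(proj))
    cuts <- c(cuts[1] - 1, (cuts[-length(cuts)] + cuts[-1]) / 2,
              cuts[length(cuts)] + 1)
    for (cut in cuts) {
      side <- proj > cut
      for (inphSide in c(TRUE, FALSE)) {
        wrong <- side != (isI == inphSide)
        cand <- list(count = sum(wrong),
                     ids = sort(rownames(P)[wrong]),
                     nINPH = sum(wrong & isI),
                     dir = dirs[k, ], cut = cut)
        if (is.null(best) || .sepBetter(cand, best)) best <- cand
      }
    }
  }
  methods::new("SeparationResult",
               misplacedCount = as.integer(best$count),
               misplacedIds = best$ids,
               direction = as.numeric(best$dir), offset = best$cut)
}

.sepBetter <- function(a, b) {
  if (a$count != b$count) return(a$count < b$count)
  if (a$nINPH != b$nINPH) return(a$nINPH < b$nINPH)
  # lexicographic on the sorted misplaced-id vectors
  pa <- paste(a$ids, collapse = "\r")
  pb <- paste(b$ids, collapse = "\r")
  pa < pb
}

setMethod("show", "SeparationResult", function(object) {
  cat(sprintf("SeparationResult: %d misplaced subject(s)%s\n",
              object@misplacedCount,
              if (length(object@misplacedIds))
                paste0(" [", paste(object@misplacedIds, collapse = ", "), "]")
              else ""))
})
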