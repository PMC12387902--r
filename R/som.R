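#' Configuration for the self-organizing map
#'
#' Defaults reflect a two-regime schedule on the 5 x 5 grid: a broad
#' ordering phase (initial neighbourhood radius 2.5 grid units) decaying
#' exponentially into a fine-tuning regime (final radius 0.01, effectively
#' best-matching-unit-only) so that, on a cohort smaller than the grid, every
#' subject can claim its own unit. The codebook starts on the plane of the
#' first two principal components of the data by default, which makes the
#' occupancy structure stable across presentation-order seeds; seeded
#' uniform-random initialization is available with `init = "uniform"`.
#'
#' @param rows,cols grid size (default 5 x 5).
#' @param epochs training epochs; each epoch presents every record once in a
#'   seeded random order.
#' @param lrStart,lrEnd learning rate, decayed exponentially from start to
#'   end over training.
#' @param radiusStart,radiusEnd Gaussian neighbourhood radius in grid units,
#'   decayed exponentially.
#' @param init `"pca"` (default) or `"uniform"`.
#' @param seed integer seed for presentation order (and codebook, when
#'   `init = "uniform"`).
#' @return a validated config list for [trainSOM()].
#' @export
somConfig <- function(rows = 5L, cols = 5L, epochs = 500L,
                      lrStart = 0.5, lrEnd = 0.01,
                      radiusStart = 2.5, radiusEnd = 0.01,
                      init = c("pca", "uniform"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(rows >= 1, cols >= 1, epochs >= 1,
            lrStart > 0, lrEnd > 0, lrEnd <= lrStart,
            radiusStart > 0, radiusEnd > 0, radiusEnd <= radiusStart)
  list(rows = as.integer(rows), cols = as.integer(cols),
       epochs = as.integer(epochs), lrStart = lrStart, lrEnd = lrEnd,
       radiusStart = radiusStart, radiusEnd = radiusEnd,
       init = init, seed = as.integer(seed))
}

.somInput <- function(x) {
  m <- if (methods::is(x, "RorschachCohort")) scaledMatrix(x) else as.matrix(x)
  if (any(!is.finite(m))) stop("SOM input must be finite")
  m
}

# row-major unit order: unit 1 = (1,1), unit 2 = (1,2), ...
.somGrid <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

.unitNames <- function(grid) paste0(grid[, 1], ".", grid[, 2])

#' Train a Kohonen self-organizing map
#'
#' Standard online training: for each presented record the best-matching
#' unit (BMU) is found by Euclidean distance, and all units are pulled
#' toward the record with a Gaussian neighbourhood factor around the BMU.
#' Learning rate and radius decay exponentially between their configured
#' start and end values. Training is reproducible for a fixed seed; the seed
#' drives the per-epoch Fisher-Yates shuffle of the presentation order.
#'
#' @param x a [RorschachCohort-class] with a `"scaled"` assay, or a numeric
#'   subjects x variables matrix in \[0, 1\].
#' @param config a [somConfig()] list.
#' @return a [SOMFit-class]; `x@qe` tracks the mean quantization error
#'   (distance of each record to its BMU) after every epoch.
#' @examples
#' fit <- trainSOM(scaleCohort(rorschachFixture()), somConfig(seed = 3))
#' fit
#' @export
trainSOM <- function(x, config = somConfig()) {
  m <- .somInput(x)
  n <- nrow(m); nv <- ncol(m)
  grid <- .somGrid(config$rows, config$cols)
  nu <- nrow(grid)
  .withSeed(config$seed, {
    if (config$init == "uniform") {
      M <- matrix(runif(nu * nv), nu, nv)
    } else {
      M <- .pcaCodebook(m, grid)
    }
    tot <- config$epochs * n
    t0 <- 0
    qe <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      for (rix in sample.int(n)) {
        frac <- if (tot > 1) t0 / (tot - 1) else 0
        t0 <- t0 + 1
        lr <- config$lrStart * (config$lrEnd / config$lrStart)^frac
        rad <- config$radiusStart * (config$radiusEnd / config$radiusStart)^frac
        xm <- matrix(m[rix, ], nu, nv, byrow = TRUE)
        b <- which.min(rowSums((M - xm)^2))
        g2 <- (grid[, 1] - grid[b, 1])^2 + (grid[, 2] - grid[b, 2])^2
        M <- M + lr * exp(-g2 / (2 * rad^2)) * (xm - M)
      }
      qe[ep] <- .quantError(M, m)
    }
    rownames(M) <- .unitNames(grid)
    colnames(M) <- colnames(m)
    methods::new("SOMFit", codebook = M, grid = grid, qe = qe,
                 config = config)
  })
}

# codebook spanning the first two principal axes, +/- 2 sd along each
.pcaCodebook <- function(m, grid) {
  p <- prcomp(m)
  rows <- max(grid[, 1]); cols <- max(grid[, 2])
  z1 <- if (rows > 1) (grid[, 1] - (rows + 1) / 2) / ((rows - 1) / 2) else rep(0, nrow(grid))
  z2 <- if (cols > 1) (grid[, 2] - (cols + 1) / 2) / ((cols - 1) / 2) else rep(0, nrow(grid))
  M <- matrix(colMeans(m), nrow(grid), ncol(m), byrow = TRUE)
  if (ncol(p$rotation) >= 1 && p$sdev[1] > 0)
    M <- M + outer(z1 * 2 * p$sdev[1], p$rotation[, 1])
  if (ncol(p$rotation) >= 2 && p$sdev[2] > 0)
    M <- M + outer(z2 * 2 * p$sdev[2], p$rotation[, 2])
  M
}

.quantError <- function(M, m) {
  tot <- 0
  for (i in seq_len(nrow(m))) {
    xm <- matrix(m[i, ], nrow(M), ncol(M), byrow = TRUE)
    tot <- tot + sqrt(min(rowSums((M - xm)^2)))
  }
  tot / nrow(m)
}

#' @rdname accessors
#' @export
setMethod("somCodebook", "SOMFit", function(x) x@codebook)

setMethod("show", "SOMFit", function(object) {
  cat(sprintf("SOMFit: %d x %d grid, %d variables, %d epochs, final QE %.4f\n",
              object@config$rows, object@config$cols, ncol(object@codebook),
              object@config$epochs, utils::tail(object@qe, 1)))
})

#' Assign each subject to its best-matching SOM class
#'
#' Each record is mapped to its nearest codebook unit (Euclidean distance);
#' ties go to the lowest (row, col) unit. Class labels are `"r.c"` with
#' 1-based row and column.
#'
#' @param fit a trained [SOMFit-class].
#' @param x the cohort or matrix to assign (same variables as training).
#' @return a [SOMAssignment-class].
#' @export
assignClasses <- function(fit, x) {
  m <- .somInput(x)
  if (ncol(m) != ncol(fit@codebook))
    stop("variable dimension mismatch between model and data")
  M <- fit@codebook
  cls <- vapply(seq_len(nrow(m)), function(i) {
    xm <- matrix(m[i, ], nrow(M), ncol(M), byrow = TRUE)
    rownames(M)[which.min(rowSums((M - xm)^2))]
  }, character(1))
  names(cls) <- rownames(m)
  occ <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(occ) <- c("class", "n")
  methods::new("SOMAssignment", classes = cls, occupancy = occ)
}

#' @rdname accessors
#' @export
setMethod("classLabels", "SOMAssignment", function(x) x@classes)

setMethod("show", "SOMAssignment", function(object) {
  cat(sprintf("SOMAssignment: %d subjects in %d classes (%d shared)\n",
              length(object@classes), nrow(object@occupancy),
              sum(object@occupancy$n >= 2)))
})

#' Component plane of one variable
#'
#' The codebook values of a single variable arranged on the map grid, with a
#' concentration score (maximum cell minus grid mean). Variables that load a
#' few classes only -- high concentration -- are the ones that zone the map,
#' in contrast to variables spread over the whole grid.
#'
#' @param fit a [SOMFit-class].
#' @param variable variable name.
#' @return list with `plane` (rows x cols matrix) and `concentration`.
#' @export
componentPlane <- function(fit, variable) {
  if (!variable %in% colnames(fit@codebook))
    stop("unknown variable: ", variable)
  vals <- fit@codebook[, variable]
  rows <- fit@config$rows; cols <- fit@config$cols
  plane <- matrix(vals, rows, cols, byrow = TRUE)
  dimnames(plane) <- list(row = seq_len(rows), col = seq_len(cols))
  list(plane = plane, concentration = max(vals) - mean(vals))
}

#' Number of classes shared by two or more subjects
#'
#' @param assign a [SOMAssignment-class].
#' @return integer count of grid cells holding at least 2 subjects.
#' @export
classSharingCount <- function(assign) {
  sum(assign@occupancy$n >= 2L)
}
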