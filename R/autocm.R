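#' Configuration for the Auto Contractive Map
#'
#' The contraction constant `C` bounds every weight; trained weights are
#' reported on the normalized \[0, 1\] scale `w / C`. The default `C = 1.25`
#' is calibrated once on the bundled reference cohort as the smallest value
#' at which no inter-unit weight saturates at the bound, which keeps the
#' learned ordering free of clipping ties while reporting the strongest
#' associations on the familiar 0.9x scale. The default learning
#' coefficient `lambda = 0.01` keeps single-record steps small enough that
#' online training is insensitive to the record presentation order (the
#' online trajectory approaches the batch limit). See the package vignette
#' for the calibration details.
#'
#' @param C contraction constant, > 0.
#' @param lambda learning coefficient, > 0.
#' @param eps0 initial weight, in (0, C); default `0.01 * C`.
#' @param tol convergence tolerance: training stops when every active
#'   mono-weight is within `tol * C` of saturation.
#' @param maxEpochs epoch cap; hitting it sets the non-converged flag.
#' @param seed integer seed for the per-epoch record presentation order.
#' @return a validated config list for [trainAutoCM()].
#' @export
autoCMConfig <- function(C = 1.25, lambda = 0.01, eps0 = 0.01 * C,
                         tol = 1e-6, maxEpochs = 10000L, seed = 1L) {
  stopifnot(C > 0, lambda > 0, eps0 > 0, eps0 < C, tol > 0, maxEpochs >= 1)
  list(C = C, lambda = lambda, eps0 = eps0, tol = tol,
       maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
}

#' Single forward pass of the contractive map
#'
#' Given an input record `s` in \[0, 1\]^N and the current weights, computes
#' the hidden activations `h_i = s_i (1 - v_i / C)`, the aggregate input
#' `net_i = sum_j h_j (1 - w_ij / C)` and the output
#' `o_i = h_i (1 - net_i / C)`. `net` may transiently exceed `C`, driving
#' `o` negative; this is part of the dynamics, not an error.
#'
#' @param s numeric input record in \[0, 1\].
#' @param v mono-connection weight vector (same length as `s`).
#' @param w N x N inter-unit weight matrix.
#' @param C contraction constant.
#' @return list with `h`, `net`, `o`.
#' @export
autoCMForward <- function(s, v, w, C = 1.25) {
  N <- length(s)
  if (length(v) != N || !all(dim(w) == N))
    stop("dimension mismatch between record and weights")
  if (any(!is.finite(s)) || any(!is.finite(v)) || any(!is.finite(w)))
    stop("non-finite values in contractive-map state")
  h <- s * (1 - v / C)
  net <- as.vector((1 - w / C) %*% h)
  o <- h * (1 - net / C)
  list(h = h, net = net, o = o)
}

#' Single learning step of the contractive map
#'
#' Applies the weight updates for one presented record:
#' `dv_i = (s_i - h_i)(1 - v_i / C)` and
#' `dw_ij = (h_i - o_i)(1 - w_ij / C) h_j`, each scaled by `lambda` and
#' clipped into \[0, C\]. Mono-weights are non-decreasing under this rule
#' (for non-negative input), saturating toward `C`.
#'
#' @inheritParams autoCMForward
#' @param lambda learning coefficient.
#' @return list with updated `v` and `w`.
#' @export
autoCMUpdate <- function(s, v, w, C = 1.25, lambda = 0.01) {
  f <- autoCMForward(s, v, w, C)
  v2 <- v + lambda * (s - f$h) * (1 - v / C)
  w2 <- w + lambda * outer(f$h - f$o, f$h) * (1 - w / C)
  list(v = pmin(pmax(v2, 0), C), w = pmin(pmax(w2, 0), C))
}

#' Train the Auto Contractive Map
#'
#' Runs online passes over the scaled records in a seeded random order until
#' every active mono-weight is saturated to within `tol * C` of the
#' contraction constant, or the epoch cap is reached (in which case the fit
#' is returned with a warning and `isConverged(fit) == FALSE`). Variables
#' with no non-zero scaled signal can never saturate (their hidden unit is
#' silent) and are excluded from the convergence criterion; on an all-zero
#' input the weights simply remain at their initial value.
#'
#' The epoch loop runs in compiled code; [autoCMUpdate()] is the reference
#' single-step implementation with identical arithmetic.
#'
#' @param x a [RorschachCohort-class] with a `"scaled"` assay (typically
#'   after [appendGroupIndicators()] and [scaleCohort()]), or a numeric
#'   subjects x variables matrix in \[0, 1\].
#' @param config an [autoCMConfig()] list.
#' @return an [AutoCMFit-class].
#' @examples
#' co <- scaleCohort(appendGroupIndicators(rorschachFixture()))
#' fit <- trainAutoCM(co)
#' a <- associationMatrix(fit)
#' round(a["INPH", "A"], 2)
#' @export
trainAutoCM <- function(x, config = autoCMConfig()) {
  m <- if (methods::is(x, "RorschachCohort")) scaledMatrix(x) else as.matrix(x)
  if (nrow(m) < 1L) stop("at least one record is required")
  if (ncol(m) < 2L) stop("at least two variables are required")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("scaled input must lie in [0, 1]")
  n <- nrow(m); N <- ncol(m)
  active <- apply(m, 2, function(col) any(col > 0))
  v <- rep(config$eps0, N)
  w <- matrix(config$eps0, N, N)
  chunk <- 200L
  run <- 0L
  converged <- FALSE
  if (any(active)) {
    .withSeed(config$seed, {
      while (run < config$maxEpochs && !converged) {
        eps <- min(chunk, config$maxEpochs - run)
        ovec <- vapply(seq_len(eps), function(e) sample.int(n), integer(n))
        orders <- if (n == 1L) matrix(ovec, ncol = 1L) else t(ovec)
        res <- .autocm_epochs(unname(m), v, w, config$C, config$lambda,
                              orders, active, config$tol)
        v <- res$v
        w <- res$w
        run <- run + res$epochsRun
        converged <- res$converged
      }
    })
  }
  if (!converged)
    warning("contractive map did not reach mono-weight saturation within ",
            config$maxEpochs, " epochs")
  dimnames(w) <- list(colnames(m), colnames(m))
  names(v) <- colnames(m)
  methods::new("AutoCMFit", v = v, w = w, active = active,
               epochs = as.integer(run), converged = converged,
               config = config)
}

#' @rdname accessors
#' @export
setMethod("isConverged", "AutoCMFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("trainingEpochs", "AutoCMFit", function(x) x@epochs)

setMethod("show", "AutoCMFit", function(object) {
  resid <- if (any(object@active))
    max(object@config$C - object@v[object@active]) else NA_real_
  cat(sprintf(
    "AutoCMFit: %d units, %d epochs, %s (max residual %.2e of C = %g)\n",
    length(object@v), object@epochs,
    if (object@converged) "converged" else "NOT converged",
    resid, object@config$C))
})

#' @describeIn associationMatrix symmetrize the trained inter-unit weights
#'   by arithmetic mean, normalize by the contraction constant, clip into
#'   \[0, 1\] and set the diagonal to 1.
#' @export
setMethod("associationMatrix", "AutoCMFit", function(object, ...) {
  a <- (object@w + t(object@w)) / 2 / object@config$C
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  methods::new("AssociationMatrix", a)
})

setMethod("show", "AssociationMatrix", function(object) {
  m <- object@.Data
  off <- m[upper.tri(m)]
  cat(sprintf(
    "AssociationMatrix: %d variables; off-diagonal range [%.3f, %.3f]\n",
    nrow(m), min(off), max(off)))
})
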